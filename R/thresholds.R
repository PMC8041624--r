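#' Pipeline threshold configuration
#'
#' Returns the full set of thresholds used across the catalog pipeline, each
#' overridable by name or from a two-column (key, value) TSV file. Defaults
#' follow the published catalog rules: a quality score (completeness minus
#' five times contamination) of at least 50 with completeness >= 50% and
#' contamination <= 5%; species-level clustering at 95% ANI with a 30%
#' aligned fraction required of both genomes; CRISPR arrays kept with >= 3
#' spacers, repeat identity to consensus of at least 97% and at least 4 Cas
#' genes, spacers retained when longer than 25 bp and matched with at most
#' one mismatch over at least 95% of their length; sequence linkage above
#' 90% identity over 500 bp on contigs over 1.5 times the virus length;
#' decayed prophages
#' flagged at >= 30% Pfam-annotated genes; BGC redundancy at >= 75% identity
#' over >= 80% coverage; read filters at Q30, 70 bp and 5 edits per 100 bp.
#'
#' Boundary operators on the three catalog-quality bounds are configurable
#' (`completeness_op`, `contamination_op`, `score_op`); the defaults use
#' inclusive bounds. ANI comparisons use an inclusive bound within the
#' catalog (`ani_op_catalog = ">="`) and a strict bound for reference
#' novelty (`ani_op_reference = ">"`).
#'
#' @param ... named overrides of individual thresholds.
#' @param file optional path to a two-column TSV (`key`, `value`) of
#'   overrides; `...` takes precedence over the file.
#' @return an object of class `mag_thresholds` (a named list).
#' @examples
#' cfg <- mag_thresholds(af_min = 0.6)
#' cfg$ani_species
#' @export
mag_thresholds <- function(..., file = NULL) {
  cfg <- list(
    # catalog quality gate
    min_completeness   = 50,
    max_contamination  = 5,
    min_quality_score  = 50,
    completeness_op    = ">=",
    contamination_op   = "<=",
    score_op           = ">=",
    # MIMAG high-quality tier
    mimag_completeness = 90,
    mimag_contamination = 5,
    mimag_trna         = 18,
    # species clustering
    ani_species        = 0.95,
    ani_op_catalog     = ">=",
    ani_op_reference   = ">",
    af_min             = 0.30,
    af_mode            = "both",
    # sketch prefilter
    sketch_k           = 21,
    sketch_size        = 10000,
    hash_seed          = 42,
    mash_slack         = 0.05,
    # RED / rank clustering
    red_support_min    = 0.7,
    red_grid_step      = 0.001,
    # CRISPR arrays and spacers
    crispr_min_spacers = 3,
    crispr_repeat_ident = 0.97,
    crispr_min_cas     = 4,
    spacer_min_len     = 26,
    spacer_max_mismatch = 1,
    spacer_min_cov     = 0.95,
    # virus sequence linkage / prophages
    linkage_min_ident  = 0.90,
    linkage_min_len    = 500,
    prophage_len_ratio = 1.5,
    decayed_pfam_frac  = 0.30,
    # BGC novelty
    bgc_redundant_ident = 0.75,
    bgc_redundant_cov  = 0.80,
    # read recruitment
    read_min_qual      = 30,
    read_min_len       = 70,
    read_max_edit_per_100 = 5
  )
  if (!is.null(file)) {
    tab <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("key", "value") %in% names(tab)))
      stop("threshold config file needs columns 'key' and 'value'")
    for (i in seq_len(nrow(tab))) {
      key <- tab$key[i]
      if (!key %in% names(cfg)) stop("unknown threshold: ", key)
      val <- tab$value[i]
      cfg[[key]] <- if (is.character(cfg[[key]])) as.character(val)
                    else as.numeric(val)
    }
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_thresholds(cfg)
  structure(cfg, class = "mag_thresholds")
}

validate_thresholds <- function(cfg) {
  fracs <- c("ani_species", "af_min", "spacer_min_cov", "linkage_min_ident",
             "decayed_pfam_frac", "bgc_redundant_ident", "bgc_redundant_cov",
             "crispr_repeat_ident", "red_support_min", "red_grid_step")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0 || v > 1)
      stop("threshold '", f, "' must be a fraction in (0, 1]")
  }
  lens <- c("spacer_min_len", "linkage_min_len", "read_min_len", "sketch_k",
            "sketch_size")
  for (f in lens) {
    v <- cfg[[f]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop("threshold '", f, "' must be a positive length")
  }
  ops <- c("completeness_op", "contamination_op", "score_op",
           "ani_op_catalog", "ani_op_reference")
  for (f in ops) {
    if (!cfg[[f]] %in% c(">=", ">", "<=", "<"))
      stop("threshold '", f, "' must be one of >=, >, <=, <")
  }
  if (!cfg$af_mode %in% c("both", "either", "query", "target"))
    stop("af_mode must be one of both/either/query/target")
  invisible(cfg)
}

# apply a configurable comparison operator
cmp_op <- function(x, op, y) {
  switch(op,
    ">=" = x >= y,
    ">"  = x > y,
    "<=" = x <= y,
    "<"  = x < y,
    stop("unsupported operator: ", op))
}

#' @export
print.mag_thresholds <- function(x, ...) {
  cat("<mag_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
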