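#' Pipeline configuration
#'
#' Bundles every tunable threshold the pipeline uses. Defaults reproduce the
#' published gates: differential calls require a fold-change of at least 2
#' (`|log2 FC| >= 1`) at FDR <= 0.05; the novelty gate keeps genes with fewer
#' than two prior publications; the ligandability gate keeps genes at or above
#' the 75th druggability percentile; CpG shores extend up to 2 kb from an
#' island and shelves from 2 to 4 kb; genome tracks are averaged in 5-Mbp
#' bins.
#'
#' @param fc_up_threshold Log2 fold-change at or above which a gene can be
#'   called up (default `1`, i.e. FC >= 2).
#' @param fc_down_threshold Log2 fold-change at or below which a gene can be
#'   called down (default `-1`).
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff, inclusive (default
#'   `0.05`).
#' @param novelty_max_pubs Exclusive upper bound on prior publication count
#'   for the novelty gate (default `2`: zero or one citation passes).
#' @param ligand_percentile_min Minimum ligand-based druggability percentile,
#'   inclusive (default `75`).
#' @param posterior_cutoff Mixture posterior above which a sample is called
#'   marker-positive (default `0.5`; an exact tie is called negative).
#' @param shore_bp Maximum distance in bp from a CpG island for the "shore"
#'   context, inclusive (default `2000`).
#' @param shelf_bp Maximum distance in bp for the "shelf" context, inclusive
#'   (default `4000`).
#' @param bin_bp Genome bin width in bp for binned tracks (default `5e6`).
#' @param max_tss_distance Maximum probe-to-TSS distance in bp when rolling
#'   probes up to genes (default `2000`).
#' @param rng_seed Integer seed used by seeded pipeline steps (default `1`).
#'
#' @return A `pipeline_config` object (a validated named list).
#' @examples
#' cfg <- pipeline_config(fdr_threshold = 0.01)
#' cfg$fdr_threshold
#' @export
pipeline_config <- function(fc_up_threshold = 1,
                            fc_down_threshold = -1,
                            fdr_threshold = 0.05,
                            novelty_max_pubs = 2,
                            ligand_percentile_min = 75,
                            posterior_cutoff = 0.5,
                            shore_bp = 2000,
                            shelf_bp = 4000,
                            bin_bp = 5e6,
                            max_tss_distance = 2000,
                            rng_seed = 1L) {
  cfg <- list(
    fc_up_threshold = as.numeric(fc_up_threshold),
    fc_down_threshold = as.numeric(fc_down_threshold),
    fdr_threshold = as.numeric(fdr_threshold),
    novelty_max_pubs = as.numeric(novelty_max_pubs),
    ligand_percentile_min = as.numeric(ligand_percentile_min),
    posterior_cutoff = as.numeric(posterior_cutoff),
    shore_bp = as.numeric(shore_bp),
    shelf_bp = as.numeric(shelf_bp),
    bin_bp = as.numeric(bin_bp),
    max_tss_distance = as.numeric(max_tss_distance),
    rng_seed = as.integer(rng_seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!(cfg$fc_down_threshold < 0 && 0 < cfg$fc_up_threshold)) {
    abort("`fc_down_threshold` must be < 0 < `fc_up_threshold`.")
  }
  if (!(cfg$fdr_threshold > 0 && cfg$fdr_threshold < 1)) {
    abort("`fdr_threshold` must lie strictly between 0 and 1.")
  }
  if (!(cfg$posterior_cutoff > 0 && cfg$posterior_cutoff < 1)) {
    abort("`posterior_cutoff` must lie strictly between 0 and 1.")
  }
  if (!(cfg$shore_bp < cfg$shelf_bp)) {
    abort("`shore_bp` must be smaller than `shelf_bp`.")
  }
  for (key in c("shore_bp", "shelf_bp", "bin_bp", "max_tss_distance")) {
    if (!(cfg[[key]] > 0)) abort(sprintf("`%s` must be positive.", key))
  }
  if (cfg$novelty_max_pubs < 0) abort("`novelty_max_pubs` must be >= 0.")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Missing keys fall back to the [pipeline_config()] defaults; keys outside
#' the schema are an error so that typos never silently revert a threshold.
#'
#' @param path Path to a YAML file whose top-level keys are
#'   [pipeline_config()] argument names.
#' @return A `pipeline_config` object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf(
      "Unknown configuration key(s): %s. Allowed keys: %s.",
      paste(extra, collapse = ", "), paste(known, collapse = ", ")
    ))
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (key in names(x)) cat(sprintf("  %-22s %s\n", key, format(x[[key]])))
  invisible(x)
}

# Structured logging to stderr. Verbosity is controlled by
# options(tnbctriage.verbose = FALSE) when a run should be quiet.
log_msg <- function(level, fmt, ...) {
  if (!isTRUE(getOption("tnbctriage.verbose", TRUE))) {
    return(invisible(NULL))
  }
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

log_info <- function(fmt, ...) log_msg("INFO", fmt, ...)
log_warn <- function(fmt, ...) log_msg("WARN", fmt, ...)

as_pipeline_config <- function(cfg) {
  if (inherits(cfg, "pipeline_config")) {
    return(cfg)
  }
  if (is.null(cfg)) {
    return(pipeline_config())
  }
  do.call(pipeline_config, as.list(cfg))
}
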