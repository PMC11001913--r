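#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one list so that a
#' whole run can be reproduced from a single object (or a YAML file, see
#' [read_config()]). The defaults are the published decision rules:
#' an HRD score (HRD-LOH + LST + TAI) of at least 42 calls HR deficiency,
#' an NER composite score of at least 0.7 calls NER deficiency, and a
#' genomic LOH fraction of at least 16% calls LOH-high.
#'
#' @param hrd_cutoff HRD-score threshold (inclusive) for the HR-deficient
#'   call. Default 42.
#' @param ner_cutoff NER composite-score threshold (inclusive). Default 0.7.
#' @param loh_fraction_cutoff Genomic LOH fraction threshold (inclusive) for
#'   the LOH-high call. Default 0.16.
#' @param exposure_prune Minimum signature proportion retained during
#'   exposure refitting; smaller exposures are zeroed and the fit re-run.
#'   Default 0.06 (the deconstructSigs convention).
#' @param lst_smooth_mb Segments shorter than this (Mb) are smoothed away
#'   before scar scoring, and inter-segment gaps up to this size do not
#'   break a run. Default 3.
#' @param lst_flank_mb Minimum size (Mb) of both segments flanking a
#'   junction for it to count as a large-scale state transition. Default 10.
#' @param loh_min_mb LOH runs must exceed this size (Mb, strict) to count
#'   towards HRD-LOH. Default 15.
#' @param tai_min_mb Minimum size (Mb) of a telomeric allelic-imbalance
#'   run. Default 0 (no size filter).
#' @param min_snv_warn Catalogs with fewer total mutations than this get a
#'   low-count warning attached to the exposure fit. Default 20.
#' @param methylation_high_beta Median promoter beta value (inclusive) at or
#'   above which a gene is called promoter-methylated. Default 0.2.
#' @param extreme_fraction Fraction taken into each of the top/bottom
#'   strata when splitting a score distribution. Default 0.4.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return A list with class `repairscan_config`.
#' @examples
#' cfg <- repairscan_config()
#' cfg$hrd_cutoff
#' @export
repairscan_config <- function(hrd_cutoff = 42,
                              ner_cutoff = 0.7,
                              loh_fraction_cutoff = 0.16,
                              exposure_prune = 0.06,
                              lst_smooth_mb = 3,
                              lst_flank_mb = 10,
                              loh_min_mb = 15,
                              tai_min_mb = 0,
                              min_snv_warn = 20,
                              methylation_high_beta = 0.2,
                              extreme_fraction = 0.4,
                              seed = NULL) {
  cfg <- list(
    hrd_cutoff = hrd_cutoff,
    ner_cutoff = ner_cutoff,
    loh_fraction_cutoff = loh_fraction_cutoff,
    exposure_prune = exposure_prune,
    lst_smooth_mb = lst_smooth_mb,
    lst_flank_mb = lst_flank_mb,
    loh_min_mb = loh_min_mb,
    tai_min_mb = tai_min_mb,
    min_snv_warn = min_snv_warn,
    methylation_high_beta = methylation_high_beta,
    extreme_fraction = extreme_fraction,
    seed = seed
  )
  validate_config(cfg)
  structure(cfg, class = "repairscan_config")
}

validate_config <- function(cfg) {
  num <- cfg[setdiff(names(cfg), "seed")]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("config values must be finite numbers: ", paste(bad, collapse = ", ")))
  }
  fracs <- c("loh_fraction_cutoff", "exposure_prune", "extreme_fraction",
             "methylation_high_beta", "ner_cutoff")
  for (key in fracs) {
    if (cfg[[key]] <= 0 || cfg[[key]] >= 1) {
      abort(paste0("config key '", key, "' must lie in (0, 1), got ", cfg[[key]]))
    }
  }
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' The file holds a flat mapping whose keys are the arguments of
#' [repairscan_config()]. Keys that are not recognised are rejected (with
#' the offending key named) rather than silently ignored, so typos cannot
#' leak default thresholds into a run.
#'
#' @param path Path to a YAML file.
#' @return A `repairscan_config` list; unspecified keys keep their defaults.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(repairscan_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(repairscan_config, raw)
}

#' @export
print.repairscan_config <- function(x, ...) {
  cat("<repairscan_config>\n")
  for (key in names(x)) {
    cat(sprintf("  %-22s %s\n", key, if (is.null(x[[key]])) "NULL" else format(x[[key]])))
  }
  invisible(x)
}
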