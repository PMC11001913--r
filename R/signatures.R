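#' Cosine similarity between two vectors
#'
#' `u . v / (|u| |v|)`, clipped into `[-1, 1]`. Used as the QC metric
#' between a mutation catalog and its reconstruction from fitted
#' signature exposures.
#'
#' @param u,v Numeric vectors of equal length, each with at least one
#'   non-zero entry.
#' @return A real number in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity undefined for a zero vector")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Refit signature exposures to a mutation catalog
#'
#' Solves the non-negative least-squares problem
#' `min ||catalog - P e||_2, e >= 0` against the reference signature
#' matrix `P`, then iteratively prunes signatures whose exposure
#' proportion (exposure / total catalog count) falls below `prune` and
#' re-runs the fit on the survivors until the active set is stable
#' (the deconstructSigs refitting convention, 0.06 by default). The
#' reconstruction `P e` is compared to the original catalog by cosine
#' similarity as the quality-control metric; catalogs with fewer than
#' `min_snv_warn` total mutations are flagged as low-count.
#'
#' @param catalog A `mutation_catalog` with positive total count.
#' @param reference A signature matrix on the same channel set (see
#'   [as_signature_matrix()]).
#' @param prune Minimum retained proportion (default 0.06); signatures
#'   below it are zeroed. If every signature falls below the threshold
#'   the single largest is kept.
#' @param min_snv_warn Low-count warning threshold (default 20).
#' @return An object of class `exposure_fit`: a list with `sample_id`,
#'   `channel_set`, `exposures` (named, count scale, zeros for pruned),
#'   `proportions`, `reconstruction_cosine`, `pruned` (names zeroed by
#'   the threshold), `total_count`, `low_counts`, `catalog`,
#'   `reconstruction`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' ref <- synthetic_signature_matrix("SBS96")
#' cat96 <- simulate_catalog(ref, c(30, 70, rep(0, 6)), noise = "none")
#' glance(fit_exposures(cat96, ref))
#' @export
fit_exposures <- function(catalog, reference, prune = 0.06, min_snv_warn = 20) {
  cat_set <- attr(catalog, "channel_set")
  ref_set <- attr(reference, "channel_set")
  if (!identical(cat_set, ref_set)) {
    abort(paste0("catalog channel set (", cat_set,
                 ") does not match reference (", ref_set, ")"))
  }
  m <- catalog_counts(catalog)
  if (!identical(names(m), rownames(reference))) {
    abort("catalog channels do not match reference rows")
  }
  total <- sum(m)
  if (total <= 0) abort("catalog has zero total count; nothing to fit")

  sigs <- colnames(reference)
  active <- sigs
  repeat {
    sol <- pracma::lsqnonneg(reference[, active, drop = FALSE], as.numeric(m))
    e <- setNames(sol$x, active)
    prop <- e / total
    keep <- names(prop)[prop >= prune]
    if (length(keep) == 0) keep <- names(which.max(prop))
    if (setequal(keep, active)) break
    active <- keep
  }

  exposures <- setNames(rep(0, length(sigs)), sigs)
  exposures[active] <- e
  pruned <- setdiff(sigs, active)
  recon <- as.vector(reference %*% exposures)
  fit <- structure(list(
    sample_id = attr(catalog, "sample_id"),
    channel_set = cat_set,
    exposures = exposures,
    proportions = exposures / total,
    reconstruction_cosine = cosine_similarity(as.numeric(m), recon),
    pruned = pruned,
    total_count = total,
    low_counts = total < min_snv_warn,
    catalog = as.numeric(m),
    reconstruction = recon
  ), class = "exposure_fit")
  if (fit$low_counts) {
    warn(sprintf("catalog for %s has only %s mutations (< %d); exposures are unstable",
                 fit$sample_id, format(total), min_snv_warn))
  }
  fit
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("<exposure_fit> %s (%s), %s mutations\n",
              x$sample_id, x$channel_set, format(x$total_count)))
  nz <- x$exposures[x$exposures > 0]
  for (s in names(nz)) {
    cat(sprintf("  %-8s %10.2f  (%.3f)\n", s, nz[[s]], x$proportions[[s]]))
  }
  cat(sprintf("  reconstruction cosine: %.6f\n", x$reconstruction_cosine))
  invisible(x)
}

#' @rdname fit_exposures
#' @param x An `exposure_fit`.
#' @param ... Unused.
#' @method tidy exposure_fit
#' @export
tidy.exposure_fit <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    signature = names(x$exposures),
    exposure = unname(x$exposures),
    proportion = unname(x$proportions),
    pruned = names(x$exposures) %in% x$pruned)
}

#' @rdname fit_exposures
#' @method glance exposure_fit
#' @export
glance.exposure_fit <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    channel_set = x$channel_set,
    total_count = x$total_count,
    n_active = sum(x$exposures > 0),
    n_pruned = length(x$pruned),
    reconstruction_cosine = x$reconstruction_cosine,
    low_counts = x$low_counts)
}

#' Is the ID6 deletion signature present?
#'
#' The short-deletion signature ID6 is an HR-deficiency indicator; its
#' presence is called as a strictly positive fitted exposure
#' ("ID6 signature > 0").
#'
#' @param id_fit An `exposure_fit` on the ID83 channel set containing an
#'   ID6 column.
#' @return `TRUE` if the fitted ID6 exposure is positive.
#' @export
id6_positive <- function(id_fit) {
  if (!"ID6" %in% names(id_fit$exposures)) {
    abort("fitted reference has no ID6 signature")
  }
  unname(id_fit$exposures[["ID6"]] > 0)
}

#' NER composite score
#'
#' A composite nucleotide-excision-repair deficiency score driven by the
#' signatures reported to track NER loss: SBS5 (substitutions) and ID8
#' (indels). The published model's exact trained combination is not
#' restated here; the implemented form is a weighted mean of the
#' configured signatures' fitted proportions (in `[0, 1]`), with the
#' published decision threshold (score >= 0.7 calls NER deficiency)
#' applied to it. Both the component set and the weights are fully
#' configurable.
#'
#' @param sbs_fit An `exposure_fit` on SBS96.
#' @param id_fit An `exposure_fit` on ID83.
#' @param weights Named non-negative weights over component signatures
#'   (default `c(SBS5 = 1, ID8 = 1)`); each name must exist in one of
#'   the two fits.
#' @param cutoff Decision threshold, inclusive (default 0.7).
#' @return A one-row tibble: `sample_id`, `score`, `ner_deficient`, and a
#'   `components` list-column holding the named proportions used.
#' @export
ner_composite_score <- function(sbs_fit, id_fit,
                                weights = c(SBS5 = 1, ID8 = 1),
                                cutoff = 0.7) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    abort("weights must be a named vector of signature names")
  }
  if (any(weights < 0)) abort("weights must be non-negative")
  comp <- vapply(names(weights), function(sig) {
    if (sig %in% names(sbs_fit$proportions)) {
      sbs_fit$proportions[[sig]]
    } else if (sig %in% names(id_fit$proportions)) {
      id_fit$proportions[[sig]]
    } else {
      abort(paste0("component signature '", sig,
                   "' absent from both fitted references"))
    }
  }, numeric(1))
  score <- sum(weights * comp) / sum(weights)
  tibble::tibble(
    sample_id = sbs_fit$sample_id,
    score = score,
    ner_deficient = score >= cutoff,
    components = list(comp))
}
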