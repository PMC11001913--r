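#' Fisher exact enrichment test on a 2x2 table
#'
#' Exact hypergeometric test with the minimum-likelihood two-sided rule
#' (the p-value sums all tables whose probability does not exceed the
#' observed one) and the conditional maximum-likelihood odds ratio, as
#' used to test enrichment of HR-gene deficiency among HRD-high samples.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A one-row tibble: `odds_ratio` (conditional MLE; may be `Inf`
#'   with a zero margin cell), `p_two_sided`.
#' @examples
#' fisher_enrichment(matrix(c(12, 0, 89, 215), nrow = 2, byrow = TRUE))
#' @export
fisher_enrichment <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    abort("table entries must be non-negative integers")
  }
  ft <- stats::fisher.test(table)
  tibble::tibble(odds_ratio = unname(ft$estimate), p_two_sided = ft$p.value)
}

check_survival_records <- function(records) {
  missing <- setdiff(c("time", "event"), names(records))
  if (length(missing) > 0) {
    abort(paste0("survival records missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("no survival records")
  if (any(records$time <= 0)) abort("survival times must be positive")
  if (any(!records$event %in% c(0, 1))) abort("event must be 0 (censored) or 1 (event)")
  invisible(records)
}

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator of the survival function; the median is the
#' earliest event time at which the estimated survival drops to 0.5 or
#' below, and is `NA` when the curve never reaches 0.5.
#'
#' @param records Tibble with columns `time` (days, > 0) and `event`
#'   (1 = event, 0 = censored).
#' @return An object of class `km_fit` wrapping the [survival::survfit()]
#'   fit, with a `median` element; supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
km_estimate <- function(records) {
  check_survival_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(records))
  s <- summary(fit, censored = TRUE)
  below <- s$time[s$surv <= 0.5 & s$n.event > 0]
  med <- if (length(below) > 0) min(below) else NA_real_
  structure(list(fit = fit, median = med, n = nrow(records)), class = "km_fit")
}

#' @rdname km_estimate
#' @param x A `km_fit`.
#' @param ... Unused.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble::tibble(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                 n_censor = s$n.censor, survival = s$surv)
}

#' @rdname km_estimate
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(n = x$n, events = sum(x$fit$n.event), median = x$median)
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, events = %d, median = %s\n",
              x$n, sum(x$fit$n.event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic for the difference
#' in survival between two groups.
#'
#' @param records Tibble with columns `time`, `event`, `group` (exactly
#'   two non-empty levels).
#' @return A one-row tibble: `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(records) {
  check_survival_records(records)
  groups <- unique(records$group)
  if (length(groups) != 2 || any(table(records$group) == 0)) {
    abort("logrank_test needs exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = as.data.frame(records))
  tibble::tibble(chi_square = sd$chisq, df = 1,
                 p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for a binary group
#'
#' Partial-likelihood fit with Breslow tie handling; returns the hazard
#' ratio of the second group level relative to the first with its Wald
#' 95% confidence interval on the log scale. Complete separation (or any
#' other failure to converge to a finite estimate) is reported as an
#' error rather than an arbitrarily large hazard ratio.
#'
#' @inheritParams logrank_test
#' @return A one-row tibble: `hr`, `ci_lo`, `ci_hi`, `p`.
#' @export
cox_hazard_ratio <- function(records) {
  check_survival_records(records)
  groups <- sort(unique(records$group))
  if (length(groups) != 2) abort("cox_hazard_ratio needs exactly two groups")
  ev <- tapply(records$event, records$group, sum)
  if (sum(ev) < 2 || any(is.na(ev))) {
    abort("non-convergence: need events in the data (at least 2)")
  }
  df <- as.data.frame(records)
  df$group <- factor(df$group, levels = groups)
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ group, data = df,
                      ties = "breslow"),
      warning = function(w) {
        if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
          abort(paste0("non-convergence in Cox fit: ", conditionMessage(w)))
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) abort(paste0("non-convergence in Cox fit: ", conditionMessage(e))))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
    abort("non-convergence in Cox fit: estimate diverged (possible complete separation)")
  }
  z <- stats::qnorm(0.975)
  tibble::tibble(
    hr = exp(beta),
    ci_lo = exp(beta - z * se),
    ci_hi = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Iron-associated ferroptosis signature genes
#'
#' The 11 iron-metabolism ferroptosis regulators and markers whose mean
#' z-scored expression forms the ferroptosis signature score.
#' @export
ferroptosis_signature_genes <- c("ACO1", "CD44", "CISD1", "IREB2", "NCOA4",
                                 "NFS1", "PHKG2", "STEAP3", "TFRC", "ZFP36",
                                 "ZEB1")

#' Per-sample gene-signature score
#'
#' Each gene row is z-scored across samples; a sample's score is the mean
#' z-score over the signature genes present in the table. Genes missing
#' from the table are dropped with a warning (the intersection is used);
#' a gene with zero variance contributes a z-score of 0 rather than NaN,
#' with a warning, so degenerate rows cannot poison the cohort.
#'
#' @param expr Expression tibble: a `gene` column plus one numeric column
#'   per sample.
#' @param genes Character vector of signature genes.
#' @return A tibble with columns `sample_id`, `score`.
#' @export
signature_score <- function(expr, genes = ferroptosis_signature_genes) {
  if (!"gene" %in% names(expr)) abort("expression table needs a 'gene' column")
  present <- intersect(genes, expr$gene)
  if (length(present) == 0) {
    abort("none of the signature genes are present in the expression table")
  }
  if (length(present) < length(genes)) {
    warn(paste0("signature gene(s) missing from expression table: ",
                paste(setdiff(genes, present), collapse = ", ")))
  }
  mat <- as.matrix(expr[match(present, expr$gene), setdiff(names(expr), "gene")])
  rownames(mat) <- present
  z <- t(apply(mat, 1, function(row) {
    s <- stats::sd(row)
    if (!is.finite(s) || s == 0) {
      warn("constant gene row; z-scores set to 0")
      rep(0, length(row))
    } else {
      (row - mean(row)) / s
    }
  }))
  tibble::tibble(sample_id = colnames(mat), score = colMeans(z))
}

#' Tukey fence outlier filter
#'
#' Drops values above `Q3 + 1.5 IQR` or below `Q1 - 1.5 IQR`, with
#' quartiles computed by linear interpolation between order statistics
#' (R quantile type 7). Idempotent on its own output.
#'
#' @param values Numeric vector with at least 4 values.
#' @return The retained values, in input order.
#' @examples
#' tukey_filter(c(1, 2, 3, 4, 100))
#' @export
tukey_filter <- function(values) {
  if (length(values) < 4) abort("tukey_filter needs at least 4 values")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
}

#' Stratify samples into score extremes
#'
#' Assigns the top `fraction` of samples (by score) to the "high" stratum
#' and the bottom `fraction` to "low", with `k = round-half-up(fraction
#' * n)` per stratum (this reproduces n = 131 per group from 327 samples
#' at 40%) and the remainder "middle". Boundary ties are broken by
#' stable input order.
#'
#' @param scores Tibble with columns `sample_id` and `score`
#'   (outlier-filtered upstream, e.g. via [tukey_filter()]).
#' @param fraction Fraction per extreme, in `(0, 0.5]`.
#' @return The input tibble with an added `stratum` column
#'   (`"high"`/`"low"`/`"middle"`).
#' @export
stratify_extremes <- function(scores, fraction = 0.4) {
  if (fraction <= 0 || fraction > 0.5) abort("fraction must lie in (0, 0.5]")
  n <- nrow(scores)
  if (n == 0) abort("no scores to stratify")
  if (length(unique(scores$score)) == 1) {
    warn("all scores tied; stratification is order-driven")
  }
  k <- min(floor(fraction * n + 0.5), floor(n / 2))
  ord <- order(scores$score)  # stable: ties keep input order
  stratum <- rep("middle", n)
  stratum[ord[seq_len(k)]] <- "low"
  stratum[ord[seq(n - k + 1, n)]] <- "high"
  out <- scores
  out$stratum <- stratum
  out
}

#' One-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Tests for a location shift of `b` relative to `a`:
#' `alternative = "greater"` asks whether `b` is shifted above `a`.
#' The p-value is exact (by enumeration) when the combined sample size is
#' at most 12 and there are no ties, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @param alternative `"greater"` (b above a) or `"less"`.
#' @return The one-tailed p-value.
#' @examples
#' mann_whitney_one_tailed(c(1, 2, 3), c(4, 5, 6), "greater")  # 0.05
#' @export
mann_whitney_one_tailed <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  exact <- (length(a) + length(b)) <= 12 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(b, a, alternative = alternative, exact = exact,
                       correct = TRUE))
  unname(wt$p.value)
}

#' Drug-response contrast between HRD-score quartiles
#'
#' Splits samples into a high group (HRD score at or above the third
#' quartile) and a low group (at or below the first quartile), discards
#' the middle half, and compares the response values of the two extremes
#' with a two-sided Mann-Whitney test. Quartiles use linear interpolation
#' between order statistics (type 7).
#'
#' @param data Tibble with columns `sample_id`, `hrd` (HRD totals) and
#'   `response` (e.g. a drug-sensitivity readout); at least 8 rows.
#' @return A list with `assignment` (the input plus a `group` column:
#'   `"high"`/`"low"`/`"middle"`) and `p` (Mann-Whitney p-value).
#' @export
compare_by_hrd_quartiles <- function(data) {
  missing <- setdiff(c("hrd", "response"), names(data))
  if (length(missing) > 0) {
    abort(paste0("data missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 8) abort("need at least 8 samples for a quartile split")
  q <- quantile(data$hrd, c(0.25, 0.75), type = 7, names = FALSE)
  group <- dplyr::case_when(
    data$hrd >= q[2] ~ "high",
    data$hrd <= q[1] ~ "low",
    TRUE ~ "middle")
  hi <- data$response[group == "high"]
  lo <- data$response[group == "low"]
  p <- suppressWarnings(
    stats::wilcox.test(hi, lo, alternative = "two.sided")$p.value)
  out <- data
  out$group <- group
  list(assignment = out, p = unname(p))
}
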