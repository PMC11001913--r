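test_that("fisher enrichment matches hypergeometric enumeration", {
  flat <- fisher_enrichment(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$odds_ratio, 1.0, tolerance = 1e-6)
  expect_equal(flat$p_two_sided, 1.0)

  diag2 <- fisher_enrichment(matrix(c(1, 0, 0, 1), 2))
  expect_equal(diag2$p_two_sided, 1.0)  # only 2 tables, cannot reject

  tab <- matrix(c(12, 0, 89, 215), nrow = 2, byrow = TRUE)
  res <- fisher_enrichment(tab)
  expect_lt(res$p_two_sided, 1e-5)
  expect_equal(res$p_two_sided, oracle_fisher_p(tab), tolerance = 1e-9)

  set.seed(3)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_enrichment(t2)$p_two_sided, oracle_fisher_p(t2),
                 tolerance = 1e-9)
  }
  expect_error(fisher_enrichment(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Kaplan-Meier estimate reproduces hand product-limit results", {
  rec <- tibble::tibble(time = c(1, 2, 3), event = 1)
  km <- km_estimate(rec)
  expect_equal(tidy(km)$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$median, 2)

  cens <- tibble::tibble(time = c(5, 6, 7), event = 0)
  expect_true(is.na(km_estimate(cens)$median))
  expect_true(all(tidy(km_estimate(cens))$survival == 1))

  single <- km_estimate(tibble::tibble(time = 5, event = 1))
  expect_equal(single$median, 5)
  expect_equal(tidy(single)$survival, 0)

  # no censoring: KM equals the empirical survival function
  set.seed(8)
  times <- round(rexp(40, 0.01) + 1)
  km2 <- tidy(km_estimate(tibble::tibble(time = times, event = 1)))
  emp <- vapply(km2$time, function(t) mean(times > t), numeric(1))
  expect_equal(km2$survival, emp, tolerance = 1e-12)
  expect_error(km_estimate(tibble::tibble(time = numeric(0), event = numeric(0))),
               "no survival records")
})

test_that("log-rank is symmetric in group labels and null on identical groups", {
  rec <- tibble::tibble(
    time = c(1, 2, 3, 4, 1, 2, 3, 4), event = 1,
    group = rep(c("A", "B"), each = 4))
  lr <- logrank_test(rec)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  surv <- simulate_survival(60, 2.5, seed = 12)
  lr1 <- logrank_test(surv)
  swapped <- dplyr::mutate(surv, group = ifelse(group == "A", "B", "A"))
  expect_equal(logrank_test(swapped)$chi_square, lr1$chi_square, tolerance = 1e-12)
  expect_error(logrank_test(dplyr::filter(surv, group == "A")), "two")
})

test_that("Cox hazard ratio inverts under label swap and flags separation", {
  surv <- simulate_survival(150, 2, seed = 5)
  hr <- cox_hazard_ratio(surv)
  swapped <- dplyr::mutate(surv, group = ifelse(group == "A", "B", "A"))
  hr_sw <- cox_hazard_ratio(swapped)
  expect_equal(hr_sw$hr, 1 / hr$hr, tolerance = 1e-9)
  expect_true(hr$ci_lo < hr$hr && hr$hr < hr$ci_hi)

  # single event -> refuse to report
  one_ev <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1, 0, 0, 0),
                           group = c("A", "A", "B", "B"))
  expect_error(cox_hazard_ratio(one_ev), "non-convergence")

  # complete separation: all A events precede all B observation
  sep <- tibble::tibble(time = c(1, 2, 3, 100, 101, 102),
                        event = c(1, 1, 1, 0, 0, 0),
                        group = rep(c("A", "B"), each = 3))
  expect_error(cox_hazard_ratio(sep), "non-convergence")
})

test_that("signature scores are mean z-scores with degenerate-row protection", {
  expr <- tibble::tibble(gene = c("G1", "G2"),
                         s1 = c(1, 1), s2 = c(1, 1), s3 = c(1, 1))
  w <- capture_warnings(sc <- signature_score(expr, c("G1", "G2")))
  expect_match(w, "constant", all = TRUE)
  expect_true(all(sc$score == 0))

  sim <- simulate_expression(50, shifted_fraction = 0, seed = 2)
  expr2 <- sim$expression
  # shift one sample up 2 SD on every signature gene -> top score
  idx <- expr2$gene %in% ferroptosis_signature_genes
  expr2$s0001[idx] <- expr2$s0001[idx] + 2
  sc2 <- signature_score(expr2)
  expect_equal(sc2$sample_id[which.max(sc2$score)], "s0001")

  # adding a constant to one gene row does not change scores
  expr3 <- sim$expression
  expr3[expr3$gene == "CD44", -1] <- expr3[expr3$gene == "CD44", -1] + 100
  expect_equal(signature_score(expr3)$score, signature_score(sim$expression)$score,
               tolerance = 1e-12)

  expect_warning(sub <- signature_score(sim$expression, c("CD44", "NOPE")), "missing")
  expect_equal(nrow(sub), 50)
  expect_error(signature_score(sim$expression, c("NOPE")), "none of the signature genes")
})

test_that("tukey fences drop outliers under the interpolated quartiles", {
  expect_equal(tukey_filter(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  expect_equal(tukey_filter(c(1, 2, 3, 4)), c(1, 2, 3, 4))
  expect_equal(tukey_filter(rep(7, 6)), rep(7, 6))
  once <- tukey_filter(c(rnorm(50), 25, -25))
  expect_equal(tukey_filter(once), once)
  expect_error(tukey_filter(c(1, 2, 3)), "at least 4")
})

test_that("extreme stratification sizes groups by round-half-up", {
  scores <- tibble::tibble(sample_id = sprintf("s%03d", 1:327),
                           score = rnorm(327))
  st <- stratify_extremes(scores, 0.4)
  expect_equal(sum(st$stratum == "high"), 131)
  expect_equal(sum(st$stratum == "low"), 131)

  st10 <- stratify_extremes(
    tibble::tibble(sample_id = letters[1:10], score = 1:10), 0.4)
  expect_equal(st10$stratum, c(rep("low", 4), rep("middle", 2), rep("high", 4)))
  expect_error(stratify_extremes(scores, 0.6), "fraction")
})

test_that("one-tailed Mann-Whitney is exact for small samples", {
  expect_equal(mann_whitney_one_tailed(c(1, 2, 3), c(4, 5, 6), "greater"), 0.05)
  x <- c(3, 1, 4, 1.5, 9)
  expect_gte(mann_whitney_one_tailed(x, x, "greater"), 0.5)
  expect_gte(mann_whitney_one_tailed(x, x, "less"), 0.5)
  expect_error(mann_whitney_one_tailed(numeric(0), 1), "non-empty")
})

test_that("HRD-quartile contrast splits extremes and detects association", {
  d8 <- tibble::tibble(sample_id = letters[1:8], hrd = 1:8, response = rnorm(8))
  res <- expect_silent(compare_by_hrd_quartiles(d8))
  expect_setequal(d8$sample_id[res$assignment$group == "high"], c("g", "h"))
  expect_setequal(d8$sample_id[res$assignment$group == "low"], c("a", "b"))

  d40 <- tibble::tibble(sample_id = sprintf("c%02d", 1:40), hrd = 1:40,
                        response = -(1:40))
  expect_lt(compare_by_hrd_quartiles(d40)$p, 0.01)
  expect_error(compare_by_hrd_quartiles(d8[1:5, ]), "at least 8")
})

test_that("survival plots and summaries are well-formed", {
  surv <- simulate_survival(40, 2, seed = 6)
  km <- km_estimate(surv)
  expect_s3_class(autoplot(km), "ggplot")
  gl <- glance(km)
  expect_equal(gl$n, 80)
  g <- toy_genome()
  sc <- hrd_score(simulate_scar_profile(1, 1, 0, g, seed = 2)$profile, g)
  expect_s3_class(plot_hrd_scores(sc), "ggplot")
  expect_s3_class(plot_segment_profile(simulate_random_profile(g, seed = 1)), "ggplot")
})
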