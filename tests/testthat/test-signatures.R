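test_that("cosine similarity matches hand computations and rejects zero vectors", {
  u <- c(0.3, 1.4, 0.05)
  expect_equal(cosine_similarity(u, u), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("noiseless mixtures are recovered exactly with cosine 1", {
  for (cs in c("SBS96", "ID83", "SV32")) {
    ref <- load_reference_signatures(cs)
    truth <- rep(0, ncol(ref))
    truth[1] <- 30; truth[2] <- 70
    fit <- fit_exposures(simulate_catalog(ref, truth, "none"), ref)
    expect_equal(unname(fit$exposures), truth, tolerance = 1e-6)
    expect_equal(fit$reconstruction_cosine, 1.0, tolerance = 1e-9)
  }
})

test_that("pruning zeroes sub-threshold signatures and refits the survivors", {
  ref <- load_reference_signatures("SBS96")
  pure <- rep(0, ncol(ref)); pure[1] <- 100
  fit <- fit_exposures(simulate_catalog(ref, pure, "none"), ref)
  expect_equal(unname(fit$exposures[1]), 100, tolerance = 1e-6)
  expect_true(all(fit$exposures[-1] == 0))

  # a 4% contribution sits below the 0.06 default and must be pruned
  small <- rep(0, ncol(ref)); small[1] <- 960; small[2] <- 40
  fit2 <- fit_exposures(simulate_catalog(ref, small, "none"), ref)
  expect_true(colnames(ref)[2] %in% fit2$pruned)
  expect_equal(unname(fit2$exposures[2]), 0)

  expect_error(
    fit_exposures(mutation_catalog(rep(0, 96), "SBS96"), ref), "zero total")
  id_ref <- load_reference_signatures("ID83")
  expect_error(
    fit_exposures(mutation_catalog(rep(1, 96), "SBS96"), id_ref), "channel set")
})

test_that("exposures are scale-equivariant; proportions and cosine are not", {
  ref <- load_reference_signatures("SBS96")
  mix <- c(200, 300, 500, rep(0, ncol(ref) - 3))
  f1 <- fit_exposures(simulate_catalog(ref, mix, "none"), ref)
  f5 <- fit_exposures(simulate_catalog(ref, 5 * mix, "none"), ref)
  expect_equal(unname(f5$exposures), unname(5 * f1$exposures), tolerance = 1e-6)
  expect_equal(f5$proportions, f1$proportions, tolerance = 1e-9)
  expect_equal(f5$reconstruction_cosine, f1$reconstruction_cosine, tolerance = 1e-12)
})

test_that("fit matches an independent projected-gradient NNLS and passes KKT", {
  ref <- load_reference_signatures("SBS96")
  truth <- c(2000, 0, 1500, 1000, rep(0, 4)) * 5000 / 4500
  cat_noisy <- simulate_catalog(ref, truth, "poisson", seed = 17)
  fit <- fit_exposures(cat_noisy, ref, prune = 0)  # pure NNLS comparison
  oracle <- oracle_nnls(unclass(ref)[, ], cat_noisy$count)
  expect_equal(unname(fit$exposures), oracle, tolerance = 1e-4)

  # KKT: gradient vanishes on the active set, is non-negative off it
  g <- 2 * as.vector(crossprod(ref, as.vector(ref %*% fit$exposures) - cat_noisy$count))
  scale <- 1 + sqrt(sum(cat_noisy$count^2))
  expect_true(all(abs(g[fit$exposures > 0]) <= 1e-8 * scale))
  expect_true(all(g[fit$exposures == 0] >= -1e-8 * scale))
})

test_that("noisy proportions are recovered within 0.03 for major signatures", {
  ref <- load_reference_signatures("SBS96")
  truth_prop <- c(0.4, 0.3, 0.2, 0.1, rep(0, 4))
  err <- matrix(NA_real_, nrow = 40, ncol = 4)
  for (s in 1:40) {
    cat_s <- simulate_catalog(ref, truth_prop * 5000, "poisson", seed = s)
    fit <- fit_exposures(cat_s, ref)
    err[s, ] <- abs(fit$proportions[1:4] - truth_prop[1:4])
  }
  expect_lt(mean(err), 0.03)
})

test_that("reconstruction cosine beats any single signature on mixtures", {
  ref <- load_reference_signatures("SBS96")
  mix <- c(300, 300, 400, rep(0, 5))
  cat_m <- simulate_catalog(ref, mix, "none")
  fit <- fit_exposures(cat_m, ref)
  singles <- apply(unclass(ref), 2, function(col) cosine_similarity(cat_m$count, col))
  expect_gte(fit$reconstruction_cosine, max(singles))
})

test_that("low-count catalogs attach a warning", {
  ref <- load_reference_signatures("SBS96")
  tiny <- simulate_catalog(ref, c(10, rep(0, 7)), "none")
  expect_warning(fit <- fit_exposures(tiny, ref), "unstable")
  expect_true(fit$low_counts)
})

test_that("tidy, glance and autoplot expose the exposure fit", {
  ref <- load_reference_signatures("ID83")
  fit <- fit_exposures(simulate_catalog(ref, c(50, 0, 30, 20), "none"), ref)
  td <- tidy(fit)
  expect_setequal(td$signature, colnames(ref))
  expect_equal(sum(td$exposure), 100, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$total_count, 100, tolerance = 1e-9)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_true(id6_positive(fit))
})

test_that("NER composite score averages SBS5 and ID8 proportions inclusively", {
  ref_sbs <- load_reference_signatures("SBS96")
  ref_id <- load_reference_signatures("ID83")
  # SBS5 at 80% of substitutions, ID8 at 80% of indels
  e_sbs <- setNames(rep(0, ncol(ref_sbs)), colnames(ref_sbs))
  e_sbs["SBS5"] <- 800; e_sbs["SBS1"] <- 200
  e_id <- setNames(rep(0, ncol(ref_id)), colnames(ref_id))
  e_id["ID8"] <- 80; e_id["ID1"] <- 20
  f_sbs <- fit_exposures(simulate_catalog(ref_sbs, e_sbs, "none"), ref_sbs)
  f_id <- fit_exposures(simulate_catalog(ref_id, e_id, "none"), ref_id)
  ner <- ner_composite_score(f_sbs, f_id)
  expect_equal(ner$score, 0.8, tolerance = 1e-6)
  expect_true(ner$ner_deficient)

  # zero drivers -> score 0, proficient
  e_sbs0 <- e_sbs; e_sbs0["SBS5"] <- 0; e_sbs0["SBS1"] <- 1000
  e_id0 <- e_id; e_id0["ID8"] <- 0; e_id0["ID1"] <- 100
  f_sbs0 <- fit_exposures(simulate_catalog(ref_sbs, e_sbs0, "none"), ref_sbs)
  f_id0 <- fit_exposures(simulate_catalog(ref_id, e_id0, "none"), ref_id)
  ner0 <- ner_composite_score(f_sbs0, f_id0)
  expect_equal(ner0$score, 0, tolerance = 1e-9)
  expect_false(ner0$ner_deficient)

  expect_error(ner_composite_score(f_sbs, f_id, weights = c(SBS99 = 1)),
               "absent")
})

test_that("a NER score of exactly 0.7 is called deficient (inclusive cutoff)", {
  ref_sbs <- load_reference_signatures("SBS96")
  ref_id <- load_reference_signatures("ID83")
  e_sbs <- setNames(rep(0, ncol(ref_sbs)), colnames(ref_sbs))
  e_sbs["SBS5"] <- 700; e_sbs["SBS1"] <- 300
  e_id <- setNames(rep(0, ncol(ref_id)), colnames(ref_id))
  e_id["ID8"] <- 70; e_id["ID1"] <- 30
  f_sbs <- fit_exposures(simulate_catalog(ref_sbs, e_sbs, "none"), ref_sbs)
  f_id <- fit_exposures(simulate_catalog(ref_id, e_id, "none"), ref_id)
  ner <- ner_composite_score(f_sbs, f_id)
  expect_equal(ner$score, 0.7, tolerance = 1e-9)
  expect_true(ner$ner_deficient)
})
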