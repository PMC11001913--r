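test_that("preprocessing merges, smooths across holes and splits at midpoints", {
  # abutting identical-state segments merge
  p <- manual_profile(list(
    list("chr1", 1, 2e7, 1, 1), list("chr1", 2e7 + 1, 4e7, 1, 1),
    list("chr1", 4e7 + 1, 1e8, 2, 1)))
  pp <- preprocess_segments(p, toy_genome())
  expect_equal(nrow(pp), 2)
  expect_equal(pp$end[1], 4e7)

  # short segment between identical flanks vanishes into one segment
  p <- manual_profile(list(
    list("chr1", 1, 2e7, 2, 1), list("chr1", 2e7 + 1, 2.2e7, 1, 1),
    list("chr1", 2.2e7 + 1, 4e7, 2, 1)))
  pp <- preprocess_segments(p, toy_genome())
  expect_equal(nrow(pp), 1)
  expect_equal(c(pp$start, pp$end, pp$a_copies, pp$b_copies), c(1, 4e7, 2, 1))

  # short segment between differing flanks: hole split at its midpoint
  p <- manual_profile(list(
    list("chr1", 1, 2e7, 2, 1), list("chr1", 2e7 + 1, 2.2e7, 1, 1),
    list("chr1", 2.2e7 + 1, 4e7, 3, 1)))
  pp <- preprocess_segments(p, toy_genome())
  expect_equal(nrow(pp), 2)
  expect_equal(pp$end[1], 2.1e7)
  expect_equal(pp$start[2], 2.1e7 + 1)
})

test_that("preprocessing is idempotent on random profiles", {
  g <- toy_genome()
  for (s in 1:20) {
    p <- simulate_random_profile(g, seed = s)
    once <- preprocess_segments(p, g)
    twice <- preprocess_segments(once, g)
    expect_equal(unclass(twice), unclass(once))
  }
})

test_that("HRD-LOH counts >15 Mb interstitial LOH runs only", {
  g <- toy_genome()
  balanced <- manual_profile(list(list("chr1", 1, 1e8, 1, 1)))
  expect_equal(score_hrd_loh(balanced, g), 0L)

  interstitial <- manual_profile(list(
    list("chr1", 1, 3e7, 1, 1), list("chr1", 3e7 + 1, 5e7, 1, 0),
    list("chr1", 5e7 + 1, 1e8, 1, 1)))
  expect_equal(score_hrd_loh(interstitial, g), 1L)

  # exactly 15 Mb is NOT "exceeding 15 Mb"
  at_cut <- manual_profile(list(
    list("chr1", 1, 3e7, 1, 1), list("chr1", 3e7 + 1, 4.5e7, 1, 0),
    list("chr1", 4.5e7 + 1, 1e8, 1, 1)))
  expect_equal(score_hrd_loh(at_cut, g), 0L)

  whole <- manual_profile(list(list("chr1", 1, 1e8, 1, 0)))
  expect_equal(score_hrd_loh(whole, g), 0L)

  # copy-neutral LOH (a=2, b=0) counts: the rule is allele-based
  cn_loh <- manual_profile(list(
    list("chr1", 1, 3e7, 1, 1), list("chr1", 3e7 + 1, 5e7, 2, 0),
    list("chr1", 5e7 + 1, 1e8, 1, 1)))
  expect_equal(score_hrd_loh(cn_loh, g), 1L)
})

test_that("LST requires >=10 Mb flanks on both sides within one arm", {
  g <- toy_genome()
  uniform <- manual_profile(list(list("chr1", 1, 1e8, 1, 1)))
  expect_equal(score_lst(uniform, g), 0L)

  # p-arm split 1-20 / 20-44 Mb: both flanks >= 10 Mb -> one break
  one_break <- manual_profile(list(
    list("chr1", 1, 2e7, 1, 1), list("chr1", 2e7 + 1, 4.4e7, 2, 1),
    list("chr1", 4.4e7 + 1, 1e8, 1, 1)))
  expect_equal(score_lst(one_break, g), 1L)

  # 12 Mb | 8 Mb flanks: the 8 Mb side fails the flank rule
  short_flank <- manual_profile(list(
    list("chr1", 1, 1.2e7, 1, 1), list("chr1", 1.2e7 + 1, 2e7, 2, 1),
    list("chr1", 2e7 + 1, 4.4e7, 1, 1), list("chr1", 4.4e7 + 1, 1e8, 1, 1)))
  expect_equal(score_lst(short_flank, g), 0L)  # the 8 Mb middle fails both junctions

  # breakpoints separated by the centromere are ignored (per-arm counting)
  cen_break <- manual_profile(list(
    list("chr1", 1, 4.9e7, 1, 1), list("chr1", 4.9e7 + 1, 1e8, 2, 1)))
  expect_equal(score_lst(cen_break, g), 0L)
})

test_that("TAI counts telomere-anchored imbalance not crossing the centromere", {
  g <- toy_genome()
  balanced <- manual_profile(list(list("chr1", 1, 1e8, 1, 1)))
  expect_equal(score_tai(balanced, g), 0L)

  q_tel <- manual_profile(list(
    list("chr1", 1, 7e7, 1, 1), list("chr1", 7e7 + 1, 1e8, 2, 1)))
  expect_equal(score_tai(q_tel, g), 1L)

  whole_ai <- manual_profile(list(list("chr1", 1, 1e8, 2, 1)))
  expect_equal(score_tai(whole_ai, g), 0L)  # crosses the centromere

  interstitial_ai <- manual_profile(list(
    list("chr1", 1, 2e7, 1, 1), list("chr1", 2e7 + 1, 4e7, 2, 1),
    list("chr1", 4e7 + 1, 1e8, 1, 1)))
  expect_equal(score_tai(interstitial_ai, g), 0L)

  # LOH reaching a telomere is also an allelic imbalance -> TAI counts it
  tel_loh <- manual_profile(list(
    list("chr1", 1, 2e7, 1, 0), list("chr1", 2e7 + 1, 1e8, 1, 1)))
  expect_equal(score_tai(tel_loh, g), 1L)
})

test_that("genomic LOH fraction is length-weighted and excludes whole chromosomes", {
  g <- toy_genome(1)
  balanced <- manual_profile(list(list("chr1", 1, 1e8, 1, 1)))
  expect_equal(genomic_loh_fraction(balanced, g), 0)

  p20 <- manual_profile(list(
    list("chr1", 1, 3e7, 1, 1), list("chr1", 3e7 + 1, 5e7, 1, 0),
    list("chr1", 5e7 + 1, 1e8, 1, 1)))
  expect_equal(genomic_loh_fraction(p20, g), 0.2)

  whole <- manual_profile(list(list("chr1", 1, 1e8, 1, 0)))
  expect_equal(genomic_loh_fraction(whole, g), 0)
  expect_error(genomic_loh_fraction(whole[0, ], g), "empty profile")
})

test_that("scores are invariant to segment and chromosome input order", {
  g <- toy_genome()
  sim <- simulate_scar_profile(2, 1, 1, g, seed = 13)
  p <- sim$profile
  shuffled <- as_segment_profile(p[sample(nrow(p)), ], annotation = g)
  expect_equal(hrd_score(shuffled, g), hrd_score(p, g))
})

test_that("production scorers agree with the naive transcription on random profiles", {
  g <- toy_genome()
  for (s in 1:60) {
    pp <- preprocess_segments(simulate_random_profile(g, seed = 1000 + s), g)
    prod <- c(score_hrd_loh(pp, g), score_lst(pp, g), score_tai(pp, g))
    expect_equal(unname(prod), unname(oracle_scars(pp, g)))
    ex <- scar_counts_exhaustive(pp, g)
    expect_equal(unname(prod), c(ex$hrd_loh, ex$lst, ex$tai))
  }
})

test_that("hrd_score assembles components, total, and both classifications", {
  g <- toy_genome()
  balanced <- manual_profile(list(
    list("chr1", 1, 1e8, 1, 1), list("chr2", 1, 1e8, 1, 1),
    list("chr3", 1, 1e8, 1, 1)))
  sc <- hrd_score(balanced, g)
  expect_equal(c(sc$hrd_loh, sc$lst, sc$tai, sc$total), c(0, 0, 0, 0))
  expect_equal(sc$hr_status, "HR-proficient")
  expect_equal(sc$loh_class, "LOH-low")

  sim <- simulate_scar_profile(2, 1, 1, g, seed = 21)
  sc <- hrd_score(sim$profile, g)
  expect_equal(sc$total, 4)
  expect_equal(sc[c("hrd_loh", "lst", "tai")],
               sim$truth[c("hrd_loh", "lst", "tai")])

  # multi-sample profiles score per sample
  multi <- as_segment_profile(dplyr::bind_rows(
    dplyr::mutate(as.data.frame(sim$profile), sample_id = "s1"),
    dplyr::mutate(as.data.frame(balanced), sample_id = "s2")), annotation = g)
  sc2 <- hrd_score(multi, g)
  expect_equal(nrow(sc2), 2)
  expect_equal(sc2$total, c(4, 0))
})

test_that("an HRD total of exactly 42 is called HR-deficient", {
  # 21 chromosomes x 2 arms, one planted LOH event per arm
  g <- make_toy_genome(21, 100)
  sim <- simulate_scar_profile(42, 0, 0, g, seed = 4)
  sc <- hrd_score(sim$profile, g)
  expect_equal(sc$total, 42)
  expect_equal(sc$hr_status, "HR-deficient")
  # one event fewer falls below the cut-off
  sim41 <- simulate_scar_profile(41, 0, 0, g, seed = 4)
  expect_equal(hrd_score(sim41$profile, g)$hr_status, "HR-proficient")
})

test_that("a LOH fraction of exactly 16% is classified LOH-high", {
  g <- toy_genome(1)
  p <- manual_profile(list(
    list("chr1", 1, 3e7, 1, 1), list("chr1", 3e7 + 1, 4.6e7, 1, 0),
    list("chr1", 4.6e7 + 1, 1e8, 1, 1)))
  sc <- hrd_score(p, g)
  expect_equal(sc$loh_fraction, 0.16)
  expect_equal(sc$loh_class, "LOH-high")
})
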