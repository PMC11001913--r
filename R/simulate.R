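#' Simulate an ASCN profile with planted scar events
#'
#' Builds a full-coverage, integer-ASCN segment profile on a toy genome
#' with a requested number of each scar event planted on distinct
#' chromosome arms, then *re-scores its own output* with the exhaustive
#' reference scorer ([scar_counts_exhaustive()]) and only returns profiles
#' whose recount equals the request. The returned truth is therefore
#' always an oracle recount of the emitted profile, never an echo of the
#' arguments. Event geometry is chosen so the definitions do not
#' interact:
#'
#' * LOH events are interstitial `a=1, b=0` runs of 16--20 Mb flanked by
#'   4 Mb balanced `a=2, b=2` buffers, so they never reach a telomere
#'   (no TAI) and never abut a >= 10 Mb flank pair (no LST);
#' * LST events are junctions between two 11 Mb imbalanced segments
#'   (`2:1` vs `3:1`), again buffered, interstitial and with `b >= 1`
#'   (no LOH, no TAI);
#' * TAI events are telomere-anchored `a=2, b=1` runs of 12--17 Mb ended
#'   by a 4 Mb balanced buffer (no LOH; the short buffer blocks any LST).
#'
#' @param n_loh,n_lst,n_tai Requested event counts (each >= 0); their sum
#'   must not exceed the number of chromosome arms.
#' @param annotation A `genome_annotation`, typically [make_toy_genome()].
#' @param seed Integer seed; output is a deterministic function of the
#'   arguments and the seed.
#' @param sample_id Sample label for the emitted profile.
#' @param config A [repairscan_config()] supplying the scoring thresholds
#'   used for the oracle recount.
#' @param max_attempts Placement retries before giving up.
#' @return A list with elements `profile` (a `segment_profile`) and
#'   `truth` (a one-row tibble with the oracle-recounted `hrd_loh`,
#'   `lst`, `tai` and their `total`).
#' @examples
#' genome <- make_toy_genome(3, 100)
#' sim <- simulate_scar_profile(2, 0, 0, genome, seed = 7)
#' sim$truth
#' @export
simulate_scar_profile <- function(n_loh, n_lst, n_tai, annotation,
                                  seed = 1, sample_id = "sim",
                                  config = repairscan_config(),
                                  max_attempts = 1000) {
  for (n in c(n_loh, n_lst, n_tai)) {
    if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
      abort("event counts must be non-negative integers")
    }
  }
  arms <- arm_table(annotation)
  n_events <- n_loh + n_lst + n_tai
  if (n_events > nrow(arms)) {
    abort(sprintf(
      "cannot place %d events on %d chromosome arms; enlarge the genome",
      n_events, nrow(arms)))
  }
  arm_len <- arms$end - arms$start + 1
  if (n_events > 0 && any(arm_len < 38e6)) {
    abort("chromosome arms too small to host planted events (need >= 38 Mb)")
  }

  result <- withr::with_seed(seed, {
    out <- NULL
    for (attempt in seq_len(max_attempts)) {
      slots <- sample(nrow(arms))
      kinds <- c(rep("loh", n_loh), rep("lst", n_lst), rep("tai", n_tai))
      events <- list()
      for (k in seq_along(kinds)) {
        arm <- arms[slots[k], ]
        events[[k]] <- plant_event(kinds[k], arm, annotation)
      }
      profile <- assemble_profile(events, annotation, sample_id)
      counts <- scar_counts_exhaustive(
        profile, annotation,
        loh_min_mb = config$loh_min_mb, flank_mb = config$lst_flank_mb,
        smooth_mb = config$lst_smooth_mb, tai_min_mb = config$tai_min_mb)
      if (counts$hrd_loh == n_loh && counts$lst == n_lst && counts$tai == n_tai) {
        out <- list(profile = profile, counts = counts)
        break
      }
    }
    out
  })
  if (is.null(result)) {
    abort(sprintf("event placement failed after %d attempts", max_attempts))
  }
  truth <- tibble::tibble(
    sample_id = sample_id,
    hrd_loh = result$counts$hrd_loh, lst = result$counts$lst,
    tai = result$counts$tai,
    total = result$counts$hrd_loh + result$counts$lst + result$counts$tai)
  list(profile = result$profile, truth = truth)
}

# One planted event on one arm; returns a tibble of non-background
# segments. Buffers are 4 Mb of balanced a=2,b=2 so junctions with the
# a=1,b=1 background never satisfy the 10 Mb LST flank rule.
plant_event <- function(kind, arm, annotation) {
  buf <- 4e6
  chrom <- arm$chrom
  chr_len <- annotation$length[annotation$chrom == chrom]
  telomere_at_start <- arm$start <= 1

  seg <- function(start, end, a, b) {
    tibble::tibble(chrom = chrom, start = start, end = end,
                   a_copies = a, b_copies = b)
  }

  if (kind == "tai") {
    run_len <- round(runif(1, 12e6, 17e6))
    if (telomere_at_start) {
      dplyr::bind_rows(
        seg(1, run_len, 2, 1),
        seg(run_len + 1, run_len + buf, 2, 2))
    } else {
      dplyr::bind_rows(
        seg(chr_len - run_len - buf + 1, chr_len - run_len, 2, 2),
        seg(chr_len - run_len + 1, chr_len, 2, 1))
    }
  } else {
    core_len <- if (kind == "loh") round(runif(1, 16e6, 20e6)) else 22e6
    block_len <- core_len + 2 * buf
    # keep >= 4 Mb of background on each side of the block within the arm
    margin <- 4e6
    lo <- arm$start + margin
    hi <- arm$end - margin - block_len
    start <- round(runif(1, lo, max(lo, hi)))
    if (kind == "loh") {
      dplyr::bind_rows(
        seg(start, start + buf - 1, 2, 2),
        seg(start + buf, start + buf + core_len - 1, 1, 0),
        seg(start + buf + core_len, start + block_len - 1, 2, 2))
    } else {
      half <- 11e6
      dplyr::bind_rows(
        seg(start, start + buf - 1, 2, 2),
        seg(start + buf, start + buf + half - 1, 2, 1),
        seg(start + buf + half, start + buf + 2 * half - 1, 3, 1),
        seg(start + buf + 2 * half, start + block_len - 1, 2, 2))
    }
  }
}

# Fill everything not occupied by events with balanced diploid background
# and return a canonical (merged, sorted) full-coverage profile.
assemble_profile <- function(events, annotation, sample_id) {
  ev <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                   a_copies = numeric(0), b_copies = numeric(0))
  rows <- list()
  for (i in seq_len(nrow(annotation))) {
    chrom <- annotation$chrom[i]
    chr_len <- annotation$length[i]
    chr_ev <- ev[ev$chrom == chrom, , drop = FALSE]
    chr_ev <- chr_ev[order(chr_ev$start), , drop = FALSE]
    pos <- 1
    for (j in seq_len(nrow(chr_ev))) {
      if (chr_ev$start[j] > pos) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = chrom, start = pos, end = chr_ev$start[j] - 1,
          a_copies = 1, b_copies = 1)
      }
      rows[[length(rows) + 1]] <- chr_ev[j, ]
      pos <- chr_ev$end[j] + 1
    }
    if (pos <= chr_len) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = chrom, start = pos, end = chr_len,
        a_copies = 1, b_copies = 1)
    }
  }
  df <- dplyr::bind_rows(rows)
  df$sample_id <- sample_id
  as_segment_profile(df, annotation = annotation)
}

#' Simulate a random segment profile
#'
#' Full-coverage profiles with random contiguous segmentation (segment
#' lengths 3--40 Mb) and random ASCN states, used for oracle-equivalence
#' property testing of the scar scorers. States are drawn from a small
#' set that exercises LOH, imbalance and balance.
#'
#' @param annotation A `genome_annotation`.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A `segment_profile`.
#' @export
simulate_random_profile <- function(annotation, seed = 1, sample_id = "rand") {
  states <- rbind(c(1, 1), c(2, 1), c(1, 0), c(2, 0), c(2, 2), c(3, 1), c(3, 2))
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(annotation))) {
      chrom <- annotation$chrom[i]
      chr_len <- annotation$length[i]
      pos <- 1
      while (pos <= chr_len) {
        len <- round(runif(1, 3e6, 4e7))
        end <- min(pos + len - 1, chr_len)
        st <- states[sample(nrow(states), 1), ]
        rows[[length(rows) + 1]] <- tibble::tibble(
          chrom = chrom, start = pos, end = end,
          a_copies = st[1], b_copies = st[2])
        pos <- end + 1
      }
    }
    df <- dplyr::bind_rows(rows)
    df$sample_id <- sample_id
    as_segment_profile(df, annotation = annotation)
  })
}

#' Simulate a mutation catalog from known exposures
#'
#' Draws a catalog as a non-negative mixture of reference signatures:
#' with `noise = "none"` the counts are exactly `reference %*% exposures`
#' (real-valued), so refitting must recover the exposures to numerical
#' precision; with `noise = "poisson"` each channel is an independent
#' Poisson draw with that mean.
#'
#' @param reference A signature matrix (see [as_signature_matrix()]).
#' @param exposures Non-negative numeric vector, one entry per reference
#'   column (count scale).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed (used for Poisson noise).
#' @param sample_id Sample label.
#' @return A `mutation_catalog`.
#' @export
simulate_catalog <- function(reference, exposures, noise = c("none", "poisson"),
                             seed = 1, sample_id = "sim") {
  noise <- match.arg(noise)
  if (length(exposures) != ncol(reference)) {
    abort("exposures length must equal the number of reference signatures")
  }
  if (any(exposures < 0)) abort("exposures must be non-negative")
  mu <- as.vector(reference %*% exposures)
  counts <- if (noise == "none") mu else withr::with_seed(seed, rpois(length(mu), mu))
  mutation_catalog(setNames(counts, rownames(reference)),
                   attr(reference, "channel_set"), sample_id = sample_id)
}

somatic_filter_names <- c("TLOD", "NLOD", "NORMAL.DEPTH", "TUMOR.DEPTH",
                          "TUMOR.ALT", "NORMAL.ALT", "TUMOR.AF")

#' Simulate a variant table with controlled filter composition
#'
#' Emits `n_pass` somatic records that satisfy all seven hard filters
#' (with some fields placed exactly at the passing boundary) plus, for
#' each entry of `fail_spec`, records that violate exactly that one
#' filter with a boundary-adjacent value. All records are Pathogenic,
#' exonic and nonsynonymous so that filtering alone determines survival.
#'
#' @param n_pass Number of fully passing records.
#' @param fail_spec Named integer vector/list mapping a filter name (one
#'   of TLOD, NLOD, NORMAL.DEPTH, TUMOR.DEPTH, TUMOR.ALT, NORMAL.ALT,
#'   TUMOR.AF) to a count of single-filter failures.
#' @param seed Integer seed (jitters the passing margins).
#' @param sample_id,gene Labels for the emitted records.
#' @return A variant tibble (see [as_variant_table()]).
#' @export
simulate_variants <- function(n_pass, fail_spec = list(), seed = 1,
                              sample_id = "sim", gene = "GENE1") {
  unknown <- setdiff(names(fail_spec), somatic_filter_names)
  if (length(unknown) > 0) {
    abort(paste0("unknown filter name(s): ", paste(unknown, collapse = ", ")))
  }
  withr::with_seed(seed, {
    rows <- list()
    passing_row <- function(key) {
      tumor_depth <- 20 + sample(0:80, 1)
      tumor_alt <- min(tumor_depth, 5 + sample(0:10, 1))
      tibble::tibble(
        sample_id = sample_id, gene = gene, origin = "somatic",
        tlod = 6 + runif(1, 0, 20), nlod = 3 + runif(1, 0, 10),
        normal_depth = 15 + sample(0:40, 1), tumor_depth = tumor_depth,
        tumor_alt = tumor_alt, normal_alt = 0,
        tumor_af = min(1, 0.05 + runif(1, 0, 0.5)),
        pathogenicity = "Pathogenic", is_exonic_nonsynonymous = TRUE,
        variant_key = key)
    }
    for (i in seq_len(n_pass)) {
      r <- passing_row(sprintf("pass_%03d", i))
      # keep the first passing record exactly on every boundary
      if (i == 1) {
        r$tlod <- 6; r$nlod <- 3; r$normal_depth <- 15
        r$tumor_depth <- 20; r$tumor_alt <- 5; r$tumor_af <- 0.05
      }
      rows[[length(rows) + 1]] <- r
    }
    for (f in names(fail_spec)) {
      for (i in seq_len(fail_spec[[f]])) {
        r <- passing_row(sprintf("fail_%s_%03d", f, i))
        if (f == "TLOD") r$tlod <- 5.99
        if (f == "NLOD") r$nlod <- 2.99
        if (f == "NORMAL.DEPTH") r$normal_depth <- 14
        if (f == "TUMOR.DEPTH") r$tumor_depth <- 19
        if (f == "TUMOR.ALT") r$tumor_alt <- 4
        if (f == "NORMAL.ALT") {r$normal_alt <- 1; r$normal_depth <- max(r$normal_depth, 15)}
        if (f == "TUMOR.AF") r$tumor_af <- 0.049
        r$tumor_alt <- min(r$tumor_alt, r$tumor_depth)
        rows[[length(rows) + 1]] <- r
      }
    }
    if (length(rows) == 0) return(as_variant_table(tibble::tibble()))
    as_variant_table(dplyr::bind_rows(rows))
  })
}

#' Simulate two-group survival data with a specified hazard ratio
#'
#' Exponential event times: group "A" at `baseline_rate` events/day,
#' group "B" at `baseline_rate * hazard_ratio` (so `hazard_ratio > 1`
#' means group B fares worse), with independent exponential censoring at
#' `censor_rate`. The defaults emulate a platinum-treated
#' gastroesophageal cohort: baseline median survival 1015 days, hazard
#' ratio 2.43 for the comparison group, and roughly one fifth of
#' follow-up censored.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param hazard_ratio Positive real; hazard multiplier for group B.
#' @param baseline_rate Events per day in group A.
#' @param censor_rate Censoring intensity (events per day); 0 disables
#'   censoring.
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `time` (days), `event`
#'   (1 = event, 0 = censored), `group` ("A"/"B").
#' @export
simulate_survival <- function(n_per_group = 100, hazard_ratio = 2.43,
                              baseline_rate = log(2) / 1015,
                              censor_rate = 2e-4, seed = 1) {
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0) {
    abort("hazard_ratio must be positive")
  }
  if (n_per_group < 2) abort("n_per_group must be at least 2")
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate must lie in [0, 1)")
  withr::with_seed(seed, {
    rate <- rep(c(baseline_rate, baseline_rate * hazard_ratio), each = n_per_group)
    t_event <- rexp(2 * n_per_group, rate)
    t_cens <- if (censor_rate > 0) rexp(2 * n_per_group, censor_rate) else rep(Inf, 2 * n_per_group)
    tibble::tibble(
      sample_id = sprintf("s%04d", seq_len(2 * n_per_group)),
      time = pmax(pmin(t_event, t_cens), 1e-8),
      event = as.integer(t_event <= t_cens),
      group = rep(c("A", "B"), each = n_per_group))
  })
}

#' Simulate an expression table with a planted signature shift
#'
#' Standard-normal background expression (genes x samples) with a chosen
#' fraction of samples shifted upward on every signature gene by
#' `shift_sd_units` standard deviations. Defaults emulate the
#' ferroptosis-signature analysis: 327 samples, the 11 iron-associated
#' signature genes, a 40% affected fraction and a 2 SD planted effect.
#'
#' @param n_samples Number of samples.
#' @param genes Character vector of gene names (the planted signature);
#'   must be non-empty. Twenty unrelated background genes are added.
#' @param shifted_fraction Fraction of samples shifted, in `[0, 1]`.
#' @param shift_sd_units Size of the planted shift in SD units.
#' @param seed Integer seed.
#' @return A list with `expression` (tibble: `gene` column + one column
#'   per sample) and `shifted` (character vector of shifted sample ids).
#' @export
simulate_expression <- function(n_samples = 327,
                                genes = ferroptosis_signature_genes,
                                shifted_fraction = 0.4,
                                shift_sd_units = 2, seed = 1) {
  if (length(genes) == 0) abort("genes must be a non-empty character vector")
  if (shifted_fraction < 0 || shifted_fraction > 1) {
    abort("shifted_fraction must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    background <- sprintf("BG%02d", 1:20)
    all_genes <- c(genes, background)
    mat <- matrix(rnorm(length(all_genes) * n_samples),
                  nrow = length(all_genes),
                  dimnames = list(all_genes, sprintf("s%04d", seq_len(n_samples))))
    n_shift <- round(shifted_fraction * n_samples)
    shifted <- sample(colnames(mat), n_shift)
    mat[genes, shifted] <- mat[genes, shifted] + shift_sd_units
    expr <- dplyr::bind_cols(tibble::tibble(gene = rownames(mat)),
                             tibble::as_tibble(mat))
    list(expression = expr, shifted = shifted)
  })
}
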