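#' Genomic scar scores
#'
#' The three genomic scar components quantify the chromosomal damage left
#' behind by defective homologous recombination:
#'
#' * **HRD-LOH** -- the number of loss-of-heterozygosity regions
#'   (minor-allele copy number zero) exceeding 15 Mb but smaller than the
#'   whole chromosome;
#' * **LST** (large-scale state transitions) -- the number of chromosomal
#'   breaks between adjacent copy-number regions of at least 10 Mb each,
#'   separated by at most 3 Mb, counted per chromosome arm;
#' * **TAI** (telomeric allelic imbalance) -- the number of
#'   allelic-imbalance regions (`a_copies != b_copies`) that extend to a
#'   telomeric chromosome end without crossing the centromere.
#'
#' Their sum is the HRD score; a total of at least 42 calls the sample
#' HR-deficient. [hrd_score()] computes all components, the total, the
#' HR status, the genomic LOH fraction and the LOH-high/low class in one
#' pass; the `score_*` functions expose the individual components.
#'
#' @param profile A `segment_profile` (single sample for the `score_*`
#'   functions; [hrd_score()] accepts multi-sample profiles).
#' @param annotation A `genome_annotation` covering every chromosome in
#'   the profile.
#' @param min_mb Minimum run size in Mb: strict lower bound for HRD-LOH
#'   (default 15), inclusive lower bound for TAI (default 0).
#' @param smooth_mb Smoothing / gap-tolerance scale in Mb (default 3).
#' @param flank_mb Minimum flank size in Mb for an LST junction
#'   (default 10).
#' @param config A [repairscan_config()] supplying all thresholds.
#' @return [hrd_score()] returns a tibble with one row per sample and
#'   columns `sample_id`, `hrd_loh`, `lst`, `tai`, `total`, `hr_status`,
#'   `loh_fraction`, `loh_class`; the `score_*` functions return a single
#'   integer.
#' @examples
#' genome <- make_toy_genome(3, 100)
#' sim <- simulate_scar_profile(2, 1, 1, genome, seed = 7)
#' hrd_score(sim$profile, genome)
#' @name scar_scores
NULL

require_single_sample <- function(profile) {
  ids <- unique(profile$sample_id)
  if (length(ids) > 1) abort("expected a single-sample profile")
  invisible(ids)
}

check_profile_chroms <- function(profile, annotation) {
  unknown <- setdiff(unique(profile$chrom), annotation$chrom)
  if (length(unknown) > 0) {
    abort(paste0("profile chromosome(s) absent from annotation: ",
                 paste(unknown, collapse = ", ")))
  }
}

# Maximal runs of segments satisfying `flag`, merging across gaps up to
# smooth_bp. Returns per-run span and covered bp for one chromosome.
segment_runs <- function(segs, flag, smooth_bp) {
  if (nrow(segs) == 0 || !any(flag)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0), covered = numeric(0)))
  }
  gap_prev <- segs$start - dplyr::lag(segs$end, default = segs$start[1] - 1) - 1
  new_run <- !flag |
    !dplyr::lag(flag, default = FALSE) |
    gap_prev > smooth_bp
  run_id <- cumsum(new_run)
  segs |>
    dplyr::mutate(.flag = flag, .run = run_id,
                  .len = .data$end - .data$start + 1) |>
    dplyr::filter(.data$.flag) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     covered = sum(.data$.len), .groups = "drop") |>
    dplyr::select("start", "end", "covered")
}

#' @rdname scar_scores
#' @export
score_hrd_loh <- function(profile, annotation, min_mb = 15, smooth_mb = 3) {
  require_single_sample(profile)
  check_profile_chroms(profile, annotation)
  smooth_bp <- smooth_mb * 1e6
  total <- 0L
  for (chr in unique(profile$chrom)) {
    segs <- profile[profile$chrom == chr, ]
    chr_len <- annotation$length[annotation$chrom == chr]
    runs <- segment_runs(segs, segs$b_copies == 0, smooth_bp)
    if (nrow(runs) == 0) next
    qual <- (runs$end - runs$start + 1) > min_mb * 1e6 &
      !(runs$start <= 1 & runs$end >= chr_len)
    total <- total + sum(qual)
  }
  as.integer(total)
}

#' @rdname scar_scores
#' @export
score_tai <- function(profile, annotation, min_mb = 0, smooth_mb = 3) {
  require_single_sample(profile)
  check_profile_chroms(profile, annotation)
  smooth_bp <- smooth_mb * 1e6
  total <- 0L
  for (chr in unique(profile$chrom)) {
    segs <- profile[profile$chrom == chr, ]
    ann <- annotation[annotation$chrom == chr, ]
    runs <- segment_runs(segs, segs$a_copies != segs$b_copies, smooth_bp)
    if (nrow(runs) == 0) next
    telomeric <- runs$start <= 1 | runs$end >= ann$length
    crosses_cen <- runs$start < ann$cen_start & runs$end > ann$cen_end
    qual <- telomeric & !crosses_cen & (runs$end - runs$start + 1) >= min_mb * 1e6
    total <- total + sum(qual)
  }
  as.integer(total)
}

#' @rdname scar_scores
#' @export
score_lst <- function(profile, annotation, flank_mb = 10, smooth_mb = 3) {
  require_single_sample(profile)
  check_profile_chroms(profile, annotation)
  pp <- preprocess_segments(profile, smooth_mb = smooth_mb)
  smooth_bp <- smooth_mb * 1e6
  flank_bp <- flank_mb * 1e6
  arms <- arm_table(annotation)
  total <- 0L
  for (i in seq_len(nrow(arms))) {
    segs <- clip_to_interval(pp[pp$chrom == arms$chrom[i], ],
                             arms$start[i], arms$end[i])
    segs <- merge_identical_adjacent(segs, smooth_bp)
    if (nrow(segs) < 2) next
    len <- segs$end - segs$start + 1
    for (j in seq_len(nrow(segs) - 1)) {
      differs <- segs$a_copies[j] != segs$a_copies[j + 1] ||
        segs$b_copies[j] != segs$b_copies[j + 1]
      gap <- segs$start[j + 1] - segs$end[j] - 1
      if (differs && gap <= smooth_bp &&
          len[j] >= flank_bp && len[j + 1] >= flank_bp) {
        total <- total + 1L
      }
    }
  }
  total
}

clip_to_interval <- function(segs, lo, hi) {
  segs <- segs[segs$end >= lo & segs$start <= hi, , drop = FALSE]
  if (nrow(segs) == 0) return(segs)
  segs$start <- pmax(segs$start, lo)
  segs$end <- pmin(segs$end, hi)
  segs
}

merge_identical_adjacent <- function(segs, smooth_bp) {
  if (nrow(segs) < 2) return(segs)
  segs <- segs[order(segs$start), , drop = FALSE]
  i <- 1
  while (i < nrow(segs)) {
    gap <- segs$start[i + 1] - segs$end[i] - 1
    if (gap <= smooth_bp &&
        segs$a_copies[i] == segs$a_copies[i + 1] &&
        segs$b_copies[i] == segs$b_copies[i + 1]) {
      segs$end[i] <- segs$end[i + 1]
      segs <- segs[-(i + 1), , drop = FALSE]
    } else {
      i <- i + 1
    }
  }
  segs
}

#' Genomic LOH fraction
#'
#' Fraction of the profiled genome lying in LOH (minor-allele copy number
#' zero), excluding whole-chromosome LOH runs, as a length-based proxy for
#' the "fraction of examined loci under LOH" used by commercial LOH
#' assays. A fraction of at least 16% classifies the sample LOH-high.
#'
#' @inheritParams scar_scores
#' @return A real number in `[0, 1]`.
#' @export
genomic_loh_fraction <- function(profile, annotation, smooth_mb = 3) {
  require_single_sample(profile)
  check_profile_chroms(profile, annotation)
  if (nrow(profile) == 0) abort("empty profile: cannot compute LOH fraction")
  smooth_bp <- smooth_mb * 1e6
  covered <- sum(profile$end - profile$start + 1)
  if (covered <= 0) abort("profile covers no base pairs")
  loh_bp <- 0
  for (chr in unique(profile$chrom)) {
    segs <- profile[profile$chrom == chr, ]
    chr_len <- annotation$length[annotation$chrom == chr]
    runs <- segment_runs(segs, segs$b_copies == 0, smooth_bp)
    if (nrow(runs) == 0) next
    keep <- !(runs$start <= 1 & runs$end >= chr_len)
    loh_bp <- loh_bp + sum(runs$covered[keep])
  }
  loh_bp / covered
}

#' @rdname scar_scores
#' @export
hrd_score <- function(profile, annotation, config = repairscan_config()) {
  check_profile_chroms(profile, annotation)
  samples <- split(unclass_tbl(profile), profile$sample_id)
  rows <- lapply(samples, function(df) {
    p <- as_segment_profile(df, annotation = annotation)
    pp <- preprocess_segments(p, annotation, smooth_mb = config$lst_smooth_mb)
    hrd_loh <- score_hrd_loh(pp, annotation, min_mb = config$loh_min_mb,
                             smooth_mb = config$lst_smooth_mb)
    lst <- score_lst(pp, annotation, flank_mb = config$lst_flank_mb,
                     smooth_mb = config$lst_smooth_mb)
    tai <- score_tai(pp, annotation, min_mb = config$tai_min_mb,
                     smooth_mb = config$lst_smooth_mb)
    frac <- genomic_loh_fraction(pp, annotation, smooth_mb = config$lst_smooth_mb)
    total <- hrd_loh + lst + tai
    tibble::tibble(
      sample_id = df$sample_id[1],
      hrd_loh = hrd_loh, lst = lst, tai = tai, total = total,
      hr_status = ifelse(total >= config$hrd_cutoff, "HR-deficient", "HR-proficient"),
      loh_fraction = frac,
      loh_class = ifelse(frac >= config$loh_fraction_cutoff, "LOH-high", "LOH-low")
    )
  })
  dplyr::bind_rows(rows)
}

#' Exhaustive reference scorer for the scar components
#'
#' A deliberately naive transcription of the three scar definitions,
#' written as explicit scans over every candidate run and junction. It is
#' the ground-truth scorer the synthetic-profile generator re-scores its
#' output with, and the reference the vectorised production scorers are
#' compared against in the tests. Expects a preprocessed (smoothed)
#' profile, like the production scorers.
#'
#' @inheritParams scar_scores
#' @param loh_min_mb,flank_mb,tai_min_mb,smooth_mb Thresholds as in the
#'   individual scorers.
#' @return A list with integer elements `hrd_loh`, `lst`, `tai`.
#' @export
scar_counts_exhaustive <- function(profile, annotation,
                                   loh_min_mb = 15, flank_mb = 10,
                                   smooth_mb = 3, tai_min_mb = 0) {
  require_single_sample(profile)
  check_profile_chroms(profile, annotation)
  smooth_bp <- smooth_mb * 1e6
  hrd_loh <- 0L; lst <- 0L; tai <- 0L

  for (chr in unique(profile$chrom)) {
    segs <- profile[profile$chrom == chr, ]
    segs <- segs[order(segs$start), ]
    ann <- annotation[annotation$chrom == chr, ]
    n <- nrow(segs)
    linked <- function(i, j) {
      # segments i..j form one contiguous block (gaps <= smooth_bp)
      if (i == j) return(TRUE)
      all(segs$start[(i + 1):j] - segs$end[i:(j - 1)] - 1 <= smooth_bp)
    }

    # --- HRD-LOH: every maximal contiguous block of b == 0 segments ---
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!all(segs$b_copies[i:j] == 0)) next
        if (!linked(i, j)) next
        maximal_left <- i == 1 || segs$b_copies[i - 1] != 0 ||
          segs$start[i] - segs$end[i - 1] - 1 > smooth_bp
        maximal_right <- j == n || segs$b_copies[j + 1] != 0 ||
          segs$start[j + 1] - segs$end[j] - 1 > smooth_bp
        if (!maximal_left || !maximal_right) next
        run_len <- segs$end[j] - segs$start[i] + 1
        whole <- segs$start[i] <= 1 && segs$end[j] >= ann$length
        if (run_len > loh_min_mb * 1e6 && !whole) hrd_loh <- hrd_loh + 1L
      }
    }

    # --- TAI: maximal allelic-imbalance blocks anchored at a telomere ---
    imb <- segs$a_copies != segs$b_copies
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!all(imb[i:j])) next
        if (!linked(i, j)) next
        maximal_left <- i == 1 || !imb[i - 1] ||
          segs$start[i] - segs$end[i - 1] - 1 > smooth_bp
        maximal_right <- j == n || !imb[j + 1] ||
          segs$start[j + 1] - segs$end[j] - 1 > smooth_bp
        if (!maximal_left || !maximal_right) next
        run_start <- segs$start[i]; run_end <- segs$end[j]
        at_telomere <- run_start <= 1 || run_end >= ann$length
        crosses <- run_start < ann$cen_start && run_end > ann$cen_end
        long_enough <- run_end - run_start + 1 >= tai_min_mb * 1e6
        if (at_telomere && !crosses && long_enough) tai <- tai + 1L
      }
    }

    # --- LST: junctions between >= flank_mb state blocks within an arm ---
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") 1 else ann$cen_end + 1
      hi <- if (arm == "p") ann$cen_start - 1 else ann$length
      a <- clip_to_interval(segs, lo, hi)
      a <- merge_identical_adjacent(a, smooth_bp)
      if (nrow(a) < 2) next
      for (j in seq_len(nrow(a) - 1)) {
        same_state <- a$a_copies[j] == a$a_copies[j + 1] &&
          a$b_copies[j] == a$b_copies[j + 1]
        gap <- a$start[j + 1] - a$end[j] - 1
        left_len <- a$end[j] - a$start[j] + 1
        right_len <- a$end[j + 1] - a$start[j + 1] + 1
        if (!same_state && gap <= smooth_bp &&
            left_len >= flank_mb * 1e6 && right_len >= flank_mb * 1e6) {
          lst <- lst + 1L
        }
      }
    }
  }
  list(hrd_loh = hrd_loh, lst = lst, tai = tai)
}
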