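# Independent reference implementations used to check the production code.
# These are deliberately naive and share no helpers with the package.

# --- scar scores: a straight transcription of the three definitions ------
# Operates on a smoothed single-sample profile (data frame with chrom,
# start, end, a_copies, b_copies). Gaps of at most smooth_mb do not break
# a run, matching the documented adjacency convention.
oracle_scars <- function(profile, annotation, loh_min_mb = 15, flank_mb = 10,
                         smooth_mb = 3, tai_min_mb = 0) {
  hrd_loh <- 0; lst <- 0; tai <- 0
  for (chr in unique(profile$chrom)) {
    p <- profile[profile$chrom == chr, ]
    p <- p[order(p$start), ]
    ann <- annotation[annotation$chrom == chr, ]
    n <- nrow(p)
    gap_ok <- function(i) p$start[i + 1] - p$end[i] - 1 <= smooth_mb * 1e6

    # maximal runs of an indicator, walking segment by segment
    runs <- function(flag) {
      out <- list()
      i <- 1
      while (i <= n) {
        if (!flag[i]) { i <- i + 1; next }
        j <- i
        while (j < n && flag[j + 1] && gap_ok(j)) j <- j + 1
        out[[length(out) + 1]] <- c(p$start[i], p$end[j])
        i <- j + 1
      }
      out
    }

    # (1) LOH regions exceeding loh_min_mb but less than the whole chromosome
    for (r in runs(p$b_copies == 0)) {
      if (r[2] - r[1] + 1 > loh_min_mb * 1e6 && !(r[1] <= 1 && r[2] >= ann$length)) {
        hrd_loh <- hrd_loh + 1
      }
    }

    # (3) allelic imbalance extending to the telomeric end, not crossing
    # the centromere
    for (r in runs(p$a_copies != p$b_copies)) {
      touches_telomere <- r[1] <= 1 || r[2] >= ann$length
      crosses_cen <- r[1] < ann$cen_start && r[2] > ann$cen_end
      if (touches_telomere && !crosses_cen && r[2] - r[1] + 1 >= tai_min_mb * 1e6) {
        tai <- tai + 1
      }
    }

    # (2) breaks between adjacent regions of at least flank_mb, at most
    # smooth_mb apart, within one chromosome arm
    for (arm_bounds in list(c(1, ann$cen_start - 1), c(ann$cen_end + 1, ann$length))) {
      a <- p[p$end >= arm_bounds[1] & p$start <= arm_bounds[2], ]
      if (nrow(a) == 0) next
      a$start <- pmax(a$start, arm_bounds[1])
      a$end <- pmin(a$end, arm_bounds[2])
      # coalesce same-state neighbours so flank lengths are maximal
      k <- 1
      while (k < nrow(a)) {
        if (a$a_copies[k] == a$a_copies[k + 1] && a$b_copies[k] == a$b_copies[k + 1] &&
            a$start[k + 1] - a$end[k] - 1 <= smooth_mb * 1e6) {
          a$end[k] <- a$end[k + 1]
          a <- a[-(k + 1), ]
        } else k <- k + 1
      }
      if (nrow(a) < 2) next
      for (k in seq_len(nrow(a) - 1)) {
        state_differs <- a$a_copies[k] != a$a_copies[k + 1] ||
          a$b_copies[k] != a$b_copies[k + 1]
        if (state_differs &&
            a$start[k + 1] - a$end[k] - 1 <= smooth_mb * 1e6 &&
            a$end[k] - a$start[k] + 1 >= flank_mb * 1e6 &&
            a$end[k + 1] - a$start[k + 1] + 1 >= flank_mb * 1e6) {
          lst <- lst + 1
        }
      }
    }
  }
  c(hrd_loh = hrd_loh, lst = lst, tai = tai)
}

# --- NNLS by projected gradient, run to a tight tolerance ----------------
oracle_nnls <- function(P, m, tol = 1e-10, maxit = 500000) {
  PtP <- crossprod(P)
  Ptm <- crossprod(P, m)
  step <- 1 / (2 * max(eigen(PtP, symmetric = TRUE, only.values = TRUE)$values))
  e <- rep(0, ncol(P))
  for (it in seq_len(maxit)) {
    g <- 2 * (PtP %*% e - Ptm)
    e_new <- pmax(0, e - step * g)
    if (max(abs(e_new - e)) < tol) { e <- e_new; break }
    e <- e_new
  }
  as.vector(e)
}

# --- two-sided Fisher p by direct hypergeometric enumeration -------------
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

toy_genome <- function(n_chrom = 3) repairscan::make_toy_genome(n_chrom, 100)

manual_profile <- function(rows, sample_id = "manual") {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]), end = as.numeric(r[[3]]),
               a_copies = as.numeric(r[[4]]), b_copies = as.numeric(r[[5]]))
  }))
  repairscan::as_segment_profile(df, sample_id = sample_id)
}

passing_somatic_variant <- function(key = "v1", gene = "BRCA2", ...) {
  row <- tibble::tibble(
    sample_id = "s1", gene = gene, origin = "somatic",
    tlod = 10, nlod = 5, normal_depth = 30, tumor_depth = 50,
    tumor_alt = 8, normal_alt = 0, tumor_af = 0.16,
    pathogenicity = "Pathogenic", is_exonic_nonsynonymous = TRUE,
    variant_key = key)
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}
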