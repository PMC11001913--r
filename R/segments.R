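#' Allele-specific copy-number segment profiles
#'
#' A segment profile is a tibble with columns `sample_id`, `chrom`,
#' `start`, `end`, `a_copies`, `b_copies`: ordered, non-overlapping
#' allele-specific copy-number (ASCN) segments, coordinates 1-based
#' inclusive, so a segment's length is `end - start + 1`. On validation
#' rows with `b_copies > a_copies` are swapped so that `a_copies` is
#' always the major allele: the A/B labels carry no phase meaning, and
#' every downstream rule only looks at the minor allele (`b_copies == 0`
#' is LOH) or at imbalance (`a_copies != b_copies`).
#'
#' @param df A data frame with columns `chrom`, `start`, `end` and either
#'   `a_copies`/`b_copies` or `A`/`B`; an optional `sample_id` column.
#' @param annotation Optional `genome_annotation`; when given, segments
#'   must fall inside annotated chromosomes.
#' @param sample_id Sample label used when `df` has no `sample_id` column.
#' @return A validated `segment_profile` tibble, sorted by chromosome and
#'   start, with `a_copies >= b_copies` on every row.
#' @export
as_segment_profile <- function(df, annotation = NULL, sample_id = "sample") {
  df <- tibble::as_tibble(df)
  if (!"a_copies" %in% names(df) && "A" %in% names(df)) {
    df <- dplyr::rename(df, a_copies = "A", b_copies = "B")
  }
  required <- c("chrom", "start", "end", "a_copies", "b_copies")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("segment table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"sample_id" %in% names(df)) df$sample_id <- sample_id
  df <- df[c("sample_id", required)]
  df$chrom <- as.character(df$chrom)
  for (col in c("start", "end", "a_copies", "b_copies")) df[[col]] <- as.numeric(df[[col]])

  if (any(df$a_copies < 0 | df$b_copies < 0)) {
    abort("negative copy numbers in segment table")
  }
  if (any(df$end < df$start)) abort("segment with end < start")

  swap <- df$b_copies > df$a_copies
  if (any(swap)) {
    tmp <- df$a_copies[swap]
    df$a_copies[swap] <- df$b_copies[swap]
    df$b_copies[swap] <- tmp
  }

  df <- dplyr::arrange(df, .data$sample_id, .data$chrom, .data$start)
  check_no_overlap(df)

  if (!is.null(annotation)) {
    unknown <- setdiff(unique(df$chrom), annotation$chrom)
    if (length(unknown) > 0) {
      abort(paste0("segments on chromosome(s) absent from annotation: ",
                   paste(unknown, collapse = ", ")))
    }
    joined <- dplyr::left_join(df, annotation, by = "chrom")
    if (any(joined$start < 1 | joined$end > joined$length)) {
      abort("segment outside annotated chromosome bounds")
    }
  }
  class(df) <- c("segment_profile", class(tibble::tibble()))
  df
}

check_no_overlap <- function(df) {
  grp <- split(df, paste(df$sample_id, df$chrom))
  for (g in grp) {
    if (nrow(g) < 2) next
    prev_end <- g$end[-nrow(g)]
    next_start <- g$start[-1]
    bad <- which(next_start <= prev_end)
    if (length(bad) > 0) {
      i <- bad[1]
      abort(sprintf(
        "overlapping segments on %s: [%s-%s] and [%s-%s]",
        g$chrom[1], format(g$start[i], scientific = FALSE),
        format(g$end[i], scientific = FALSE),
        format(g$start[i + 1], scientific = FALSE),
        format(g$end[i + 1], scientific = FALSE)))
    }
  }
  invisible(df)
}

#' Read an ASCN segment profile from a SEG-style TSV
#'
#' Expects columns `chrom`, `start`, `end` and `A`, `B` (or
#' `a_copies`/`b_copies`), 1-based inclusive coordinates, plus an optional
#' `sample_id` column.
#'
#' @inheritParams as_segment_profile
#' @param path Path to the TSV file.
#' @return A `segment_profile` tibble.
#' @export
read_segments <- function(path, annotation = NULL, sample_id = "sample") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_segment_profile(df, annotation = annotation, sample_id = sample_id)
}

#' Write a segment profile to a SEG-style TSV
#' @param profile A `segment_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profile, path) {
  readr::write_tsv(unclass_tbl(profile), path)
  invisible(path)
}

#' Smooth and canonicalise a segment profile
#'
#' Prepares a profile for scar scoring, per sample and chromosome:
#' * adjacent segments with identical `(a_copies, b_copies)` separated by
#'   at most `smooth_mb` are merged into one;
#' * segments shorter than `smooth_mb` are removed -- if the segments
#'   flanking the hole share the same ASCN state they are merged across
#'   it, otherwise the hole is split at its midpoint between the two
#'   differing neighbours;
#' * a short segment with no neighbour within `smooth_mb` is kept, so
#'   isolated coverage is never silently deleted.
#'
#' The operation is idempotent, and is the smoothing implied by the LST
#' definition's tolerance of up to 3 Mb between adjacent regions.
#'
#' @param profile A `segment_profile`.
#' @param annotation Optional `genome_annotation` used for validation.
#' @param smooth_mb Smoothing scale in Mb (default 3).
#' @return A `segment_profile`, sorted and non-overlapping.
#' @export
preprocess_segments <- function(profile, annotation = NULL, smooth_mb = 3) {
  smooth_bp <- smooth_mb * 1e6
  pieces <- split(unclass_tbl(profile), paste(profile$sample_id, profile$chrom))
  out <- lapply(pieces, smooth_chrom_segments, smooth_bp = smooth_bp)
  res <- dplyr::bind_rows(out)
  as_segment_profile(res, annotation = annotation)
}

smooth_chrom_segments <- function(segs, smooth_bp) {
  segs <- segs[order(segs$start), , drop = FALSE]
  keep_short <- rep(FALSE, nrow(segs))
  repeat {
    changed <- FALSE
    # merge identical-state neighbours within reach
    i <- 1
    while (i < nrow(segs)) {
      gap <- segs$start[i + 1] - segs$end[i] - 1
      if (gap <= smooth_bp &&
          segs$a_copies[i] == segs$a_copies[i + 1] &&
          segs$b_copies[i] == segs$b_copies[i + 1]) {
        segs$end[i] <- segs$end[i + 1]
        keep_short[i] <- keep_short[i] && keep_short[i + 1]
        segs <- segs[-(i + 1), , drop = FALSE]
        keep_short <- keep_short[-(i + 1)]
        changed <- TRUE
      } else {
        i <- i + 1
      }
    }
    # drop one short segment and close the hole
    short <- which(segs$end - segs$start + 1 < smooth_bp & !keep_short)
    if (length(short) > 0) {
      j <- short[1]
      left <- j > 1 && (segs$start[j] - segs$end[j - 1] - 1) <= smooth_bp
      right <- j < nrow(segs) && (segs$start[j + 1] - segs$end[j] - 1) <= smooth_bp
      if (left && right) {
        lo <- segs$end[j - 1]
        hi <- segs$start[j + 1]
        mid <- floor((lo + hi) / 2)
        segs$end[j - 1] <- mid
        segs$start[j + 1] <- mid + 1
        segs <- segs[-j, , drop = FALSE]
        keep_short <- keep_short[-j]
        changed <- TRUE
      } else if (left) {
        segs$end[j - 1] <- segs$end[j]
        segs <- segs[-j, , drop = FALSE]
        keep_short <- keep_short[-j]
        changed <- TRUE
      } else if (right) {
        segs$start[j + 1] <- segs$start[j]
        segs <- segs[-j, , drop = FALSE]
        keep_short <- keep_short[-j]
        changed <- TRUE
      } else {
        keep_short[j] <- TRUE
      }
    }
    if (!changed && !any(segs$end - segs$start + 1 < smooth_bp & !keep_short)) break
  }
  segs
}

segment_lengths <- function(profile) profile$end - profile$start + 1
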