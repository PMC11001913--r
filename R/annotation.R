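#' Genome annotation: chromosome lengths and centromere intervals
#'
#' A genome annotation is a tibble with one row per chromosome and columns
#' `chrom`, `length`, `cen_start`, `cen_end` (all coordinates 1-based bp).
#' It defines the geometry the scar scores depend on: the p-arm is
#' `[1, cen_start)`, the q-arm is `(cen_end, length]`, and the two
#' telomeric ends are positions 1 and `length`. Telomeric allelic
#' imbalance needs the chromosome ends; LST counting needs the arms.
#'
#' @param df A data frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end`.
#' @return A validated `genome_annotation` tibble.
#' @export
as_genome_annotation <- function(df) {
  required <- c("chrom", "length", "cen_start", "cen_end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing column(s): ", paste(missing, collapse = ", ")))
  }
  ann <- tibble::as_tibble(df[required])
  ann$chrom <- as.character(ann$chrom)
  for (col in c("length", "cen_start", "cen_end")) ann[[col]] <- as.numeric(ann[[col]])

  dup <- ann$chrom[duplicated(ann$chrom)]
  if (length(dup) > 0) {
    abort(paste0("duplicate chromosome name(s) in annotation: ", paste(unique(dup), collapse = ", ")))
  }
  bad <- ann$chrom[!(ann$cen_start >= 1 & ann$cen_start < ann$cen_end & ann$cen_end <= ann$length)]
  if (length(bad) > 0) {
    abort(paste0("centromere interval outside chromosome for: ", paste(bad, collapse = ", ")))
  }
  if (any(ann$length <= 0)) abort("chromosome lengths must be positive")
  class(ann) <- c("genome_annotation", class(tibble::tibble()))
  ann
}

#' Read a genome annotation from a TSV file
#'
#' Expects columns `chrom`, `length`, `cen_start`, `cen_end`.
#'
#' @param path Path to a tab-separated file.
#' @return A `genome_annotation` tibble.
#' @export
read_genome_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_genome_annotation(df)
}

#' Write a genome annotation to a TSV file
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_annotation <- function(annotation, path) {
  readr::write_tsv(tibble::as_tibble(unclass_tbl(annotation)), path)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- class(tibble::tibble())
  x
}

#' Build a toy genome annotation
#'
#' Equal-length chromosomes with the centromere occupying the central
#' 45--55% of each chromosome. Used by the synthetic-data generators and
#' in tests; small enough that exhaustive re-scoring is instantaneous.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param length_mb Chromosome length in Mb.
#' @return A `genome_annotation` tibble.
#' @examples
#' make_toy_genome(3, 100)
#' @export
make_toy_genome <- function(n_chrom = 3, length_mb = 100) {
  if (!is.numeric(n_chrom) || length(n_chrom) != 1 || n_chrom < 1) {
    abort("n_chrom must be an integer >= 1")
  }
  len <- length_mb * 1e6
  as_genome_annotation(tibble::tibble(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = len,
    cen_start = round(0.45 * len),
    cen_end = round(0.55 * len)
  ))
}

#' Chromosome arms implied by an annotation
#'
#' @param annotation A `genome_annotation`.
#' @return A tibble with columns `chrom`, `arm` ("p"/"q"), `start`, `end`.
#' @export
arm_table <- function(annotation) {
  dplyr::bind_rows(
    tibble::tibble(chrom = annotation$chrom, arm = "p",
                   start = 1, end = annotation$cen_start - 1),
    tibble::tibble(chrom = annotation$chrom, arm = "q",
                   start = annotation$cen_end + 1, end = annotation$length)
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}
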