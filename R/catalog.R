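#' Mutation catalogs
#'
#' A mutation catalog is a tibble with columns `channel` and `count`
#' holding per-channel non-negative mutation counts for one sample, with
#' attributes `channel_set` and `sample_id`. Channels are stored in the
#' canonical order of the declared channel set (see [sbs96_channels()]).
#'
#' @param counts Numeric vector of non-negative counts, one per channel,
#'   either in canonical order or named by channel label.
#' @param channel_set One of `"SBS96"`, `"ID83"`, `"SV32"`.
#' @param sample_id Sample label.
#' @return A `mutation_catalog` tibble.
#' @export
mutation_catalog <- function(counts, channel_set, sample_id = "sample") {
  channel_set <- match_channel_set(channel_set)
  labels <- channel_labels(channel_set)
  if (length(counts) != length(labels)) {
    abort(sprintf("expected %d channels, found %d", length(labels), length(counts)))
  }
  if (!is.null(names(counts))) {
    missing <- setdiff(labels, names(counts))
    if (length(missing) > 0) {
      abort(paste0("catalog channel labels do not match ", channel_set,
                   "; missing e.g. ", missing[1]))
    }
    counts <- counts[labels]
  }
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("catalog counts must be finite and non-negative")
  }
  out <- tibble::tibble(channel = labels, count = counts)
  attr(out, "channel_set") <- channel_set
  attr(out, "sample_id") <- sample_id
  class(out) <- c("mutation_catalog", class(tibble::tibble()))
  out
}

#' Read a mutation catalog from a `channel<TAB>count` TSV
#'
#' Rows may appear in any order; they are matched to the canonical channel
#' order of `channel_set` by label. A wrong number of rows is a format
#' error stating expected and found counts.
#'
#' @param path Path to the TSV file.
#' @inheritParams mutation_catalog
#' @return A `mutation_catalog` tibble.
#' @export
read_catalog <- function(path, channel_set, sample_id = "sample") {
  channel_set <- match_channel_set(channel_set)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("channel", "count"), names(df))
  if (length(missing) > 0) {
    abort(paste0("catalog file is missing column(s): ", paste(missing, collapse = ", ")))
  }
  mutation_catalog(setNames(df$count, df$channel), channel_set, sample_id = sample_id)
}

#' Write a mutation catalog to TSV
#' @param catalog A `mutation_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(unclass_tbl(catalog)[c("channel", "count")], path)
  invisible(path)
}

catalog_counts <- function(catalog) setNames(catalog$count, catalog$channel)

#' Read a reference signature matrix from TSV
#'
#' The file holds channel labels in the first column (named `channel`) and
#' one column per signature. Columns are normalised to sum to one at load
#' time, so references may be supplied either as probabilities or as raw
#' channel weights; rows are reordered to the canonical channel order.
#'
#' @param path Path to the TSV file.
#' @param channel_set One of `"SBS96"`, `"ID83"`, `"SV32"`.
#' @return A numeric matrix (channels x signatures) with `channel_set`
#'   attribute; every column sums to 1.
#' @export
read_signature_matrix <- function(path, channel_set) {
  channel_set <- match_channel_set(channel_set)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"channel" %in% names(df)) abort("signature matrix file must have a 'channel' column")
  labels <- channel_labels(channel_set)
  if (nrow(df) != length(labels) || length(setdiff(labels, df$channel)) > 0) {
    abort(paste0("signature matrix rows do not match the ", channel_set, " channel set"))
  }
  mat <- as.matrix(df[match(labels, df$channel), setdiff(names(df), "channel"), drop = FALSE])
  rownames(mat) <- labels
  as_signature_matrix(mat, channel_set)
}

#' Validate and normalise a signature matrix
#'
#' @param mat Non-negative numeric matrix, channels (rows) x signatures
#'   (columns); rownames must match the channel set.
#' @inheritParams read_signature_matrix
#' @return The column-normalised matrix with a `channel_set` attribute.
#' @export
as_signature_matrix <- function(mat, channel_set) {
  channel_set <- match_channel_set(channel_set)
  labels <- channel_labels(channel_set)
  if (is.null(rownames(mat)) || !identical(sort(rownames(mat)), sort(labels))) {
    abort(paste0("signature matrix rownames must be the ", channel_set, " channel labels"))
  }
  mat <- mat[labels, , drop = FALSE]
  if (any(mat < 0) || any(!is.finite(mat))) abort("signature matrix entries must be finite and non-negative")
  csum <- colSums(mat)
  if (any(csum <= 0)) abort("signature matrix has an all-zero column")
  mat <- sweep(mat, 2, csum, "/")
  attr(mat, "channel_set") <- channel_set
  mat
}

#' Write a signature matrix to TSV
#' @param mat A signature matrix (see [as_signature_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(mat, path) {
  df <- tibble::as_tibble(mat)
  df <- dplyr::bind_cols(tibble::tibble(channel = rownames(mat)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Synthetic reference signature matrix
#'
#' Generates a deterministic, synthetic stand-in for a reference signature
#' matrix: sparse, near-orthogonal non-negative channel profiles drawn
#' from a Gamma distribution and column-normalised. These are NOT the
#' COSMIC signatures -- they share only their shape (channels x
#' signatures, columns summing to one) and their default naming, so the
#' refitting code paths can be exercised end-to-end; supply a real COSMIC
#' TSV via [read_signature_matrix()] for production use.
#'
#' @inheritParams read_signature_matrix
#' @param signatures Character vector of signature names; defaults to a
#'   small COSMIC-style panel per channel set (including SBS3, ID6, ID8).
#' @param seed Integer seed; the same seed always yields the same matrix.
#' @return A signature matrix (see [as_signature_matrix()]).
#' @export
synthetic_signature_matrix <- function(channel_set,
                                       signatures = NULL,
                                       seed = 20240408) {
  channel_set <- match_channel_set(channel_set)
  if (is.null(signatures)) {
    signatures <- switch(channel_set,
      SBS96 = c("SBS1", "SBS2", "SBS3", "SBS5", "SBS13", "SBS17b", "SBS18", "SBS40"),
      ID83 = c("ID1", "ID2", "ID6", "ID8"),
      SV32 = paste0("RS", 1:6)
    )
  }
  labels <- channel_labels(channel_set)
  mat <- withr::with_seed(seed, {
    m <- matrix(stats::rgamma(length(labels) * length(signatures), shape = 0.3, rate = 1),
                nrow = length(labels))
    m
  })
  rownames(mat) <- labels
  colnames(mat) <- signatures
  as_signature_matrix(mat, channel_set)
}

#' Load the signature references shipped with the package
#'
#' Returns the synthetic fixture matrix stored under `inst/extdata`
#' (`synthetic_<set>_signatures.tsv`); see [synthetic_signature_matrix()]
#' for what these are and are not.
#'
#' @inheritParams read_signature_matrix
#' @return A signature matrix.
#' @export
load_reference_signatures <- function(channel_set) {
  channel_set <- match_channel_set(channel_set)
  fname <- paste0("synthetic_", tolower(channel_set), "_signatures.tsv")
  path <- system.file("extdata", fname, package = "repairscan")
  if (path == "") abort(paste0("fixture not found: ", fname))
  read_signature_matrix(path, channel_set)
}
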