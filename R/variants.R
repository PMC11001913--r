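variant_columns <- c("sample_id", "gene", "origin", "tlod", "nlod",
                     "normal_depth", "tumor_depth", "tumor_alt", "normal_alt",
                     "tumor_af", "pathogenicity", "is_exonic_nonsynonymous",
                     "variant_key")

pathogenicity_levels <- c("Benign", "Likely Benign", "Uncertain significance",
                          "Likely Pathogenic", "Pathogenic")

#' Validate a variant table
#'
#' Variant records carry the MuTect2-style evidence fields the somatic
#' hard filters act on (`tlod`, `nlod`, depths, alt counts, `tumor_af`),
#' an `origin` (`"germline"` or `"somatic"`), the five-level
#' pathogenicity class, an exonic-nonsynonymous flag and a `variant_key`
#' uniquely identifying the nucleotide change (used to distinguish
#' homozygous from compound-heterozygous genotypes).
#'
#' @param df A data frame with (a subset of) the variant columns; missing
#'   `pathogenicity` defaults to "Uncertain significance" with a warning,
#'   missing `origin` defaults to "somatic".
#' @return A validated variant tibble.
#' @export
as_variant_table <- function(df) {
  df <- tibble::as_tibble(df)
  aliases <- c(TLOD = "tlod", NLOD = "nlod", "NORMAL.DEPTH" = "normal_depth",
               "TUMOR.DEPTH" = "tumor_depth", "TUMOR.ALT" = "tumor_alt",
               "NORMAL.ALT" = "normal_alt", "TUMOR.AF" = "tumor_af")
  for (alias in names(aliases)) {
    if (alias %in% names(df) && !aliases[[alias]] %in% names(df)) {
      names(df)[names(df) == alias] <- aliases[[alias]]
    }
  }
  if (nrow(df) == 0) {
    return(tibble::tibble(
      sample_id = character(0), gene = character(0), origin = character(0),
      tlod = numeric(0), nlod = numeric(0), normal_depth = numeric(0),
      tumor_depth = numeric(0), tumor_alt = numeric(0), normal_alt = numeric(0),
      tumor_af = numeric(0), pathogenicity = character(0),
      is_exonic_nonsynonymous = logical(0), variant_key = character(0)))
  }
  if (!"pathogenicity" %in% names(df)) {
    warn("variant table has no pathogenicity column; defaulting to 'Uncertain significance'")
    df$pathogenicity <- "Uncertain significance"
  }
  if (!"origin" %in% names(df)) df$origin <- "somatic"
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample"
  if (!"is_exonic_nonsynonymous" %in% names(df)) df$is_exonic_nonsynonymous <- TRUE
  if (!"variant_key" %in% names(df)) {
    abort("variant table is missing a variant_key column")
  }
  missing <- setdiff(variant_columns, names(df))
  if (length(missing) > 0) {
    abort(paste0("variant table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- df[variant_columns]
  num_cols <- c("tlod", "nlod", "normal_depth", "tumor_depth", "tumor_alt",
                "normal_alt", "tumor_af")
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  df$is_exonic_nonsynonymous <- as.logical(df$is_exonic_nonsynonymous)

  bad <- !df$origin %in% c("germline", "somatic")
  if (any(bad)) abort("variant origin must be 'germline' or 'somatic'")
  bad <- !df$pathogenicity %in% pathogenicity_levels
  if (any(bad)) {
    abort(paste0("unknown pathogenicity class: ",
                 paste(unique(df$pathogenicity[bad]), collapse = ", ")))
  }
  counts <- df[c("normal_depth", "tumor_depth", "tumor_alt", "normal_alt")]
  if (any(unlist(counts) < 0, na.rm = TRUE)) abort("negative read counts in variant table")
  if (any(df$tumor_alt > df$tumor_depth, na.rm = TRUE)) {
    abort("tumor_alt exceeds tumor_depth")
  }
  if (any(df$normal_alt > df$normal_depth, na.rm = TRUE)) {
    abort("normal_alt exceeds normal_depth")
  }
  if (any(df$tumor_af < 0 | df$tumor_af > 1, na.rm = TRUE)) {
    abort("tumor_af must lie in [0, 1]")
  }
  df
}

#' Read variants from a TSV or a minimal VCF
#'
#' Files ending in `.vcf` are parsed as minimal single-pair VCFs: `TLOD`,
#' `NLOD`, `GENE`, `ORIGIN`, `PATHOGENICITY` and `EXONIC_NONSYN` are read
#' from INFO, read depths and allele fractions from the `DP`/`AD`/`AF`
#' FORMAT fields of the `NORMAL` and `TUMOR` sample columns, and
#' `variant_key` is `CHROM:POS:REF:ALT`. Anything else is read as a TSV
#' with the variant columns (MuTect2-style uppercase aliases such as
#' `TLOD`, `TUMOR.AF` are accepted). A file with a header but no data
#' rows yields an empty table, not an error.
#'
#' @param path Path to the file.
#' @param sample_id Sample label used when the file carries none.
#' @return A validated variant tibble (see [as_variant_table()]).
#' @export
read_variants <- function(path, sample_id = "sample") {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    read_variants_vcf(path, sample_id)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    as_variant_table(df)
  }
}

read_variants_vcf <- function(path, sample_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0) return(as_variant_table(tibble::tibble()))
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))

  info_num <- function(key) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = key, as.numeric = TRUE))
    if (is.null(v)) rep(NA_real_, n) else as.vector(unname(v))
  }
  info_chr <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n) else as.vector(unname(v))
  }
  tlod <- info_num("TLOD")
  nlod <- info_num("NLOD")
  for (field in c("TLOD", "NLOD")) {
    v <- if (field == "TLOD") tlod else nlod
    if (any(is.na(v))) {
      abort(sprintf("VCF record %d lacks required INFO field %s",
                    which(is.na(v))[1], field))
    }
  }
  gt_field <- function(element, col) {
    m <- vcfR::extract.gt(vcf, element = element)
    if (is.null(m) || !col %in% colnames(m)) {
      abort(paste0("VCF lacks FORMAT field ", element, " for sample ", col))
    }
    m[, col]
  }
  parse_ad_alt <- function(x) as.numeric(vapply(strsplit(x, ","), function(p) p[2], ""))
  normal_dp <- as.numeric(gt_field("DP", "NORMAL"))
  tumor_dp <- as.numeric(gt_field("DP", "TUMOR"))
  normal_alt <- parse_ad_alt(gt_field("AD", "NORMAL"))
  tumor_alt <- parse_ad_alt(gt_field("AD", "TUMOR"))
  tumor_af <- as.numeric(gt_field("AF", "TUMOR"))

  path_class <- info_chr("PATHOGENICITY")
  if (all(is.na(path_class))) path_class <- NULL
  exonic <- info_chr("EXONIC_NONSYN")
  origin <- info_chr("ORIGIN")

  df <- tibble::tibble(
    sample_id = sample_id,
    gene = info_chr("GENE"),
    origin = ifelse(is.na(origin), "somatic", origin),
    tlod = tlod, nlod = nlod,
    normal_depth = normal_dp, tumor_depth = tumor_dp,
    tumor_alt = tumor_alt, normal_alt = normal_alt,
    tumor_af = tumor_af,
    is_exonic_nonsynonymous = is.na(exonic) | exonic %in% c("1", "TRUE", "yes"),
    variant_key = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
  )
  if (!is.null(path_class)) df$pathogenicity <- gsub("_", " ", path_class)
  as_variant_table(df)
}

#' Write a variant table to TSV
#' @param variants A variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}
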