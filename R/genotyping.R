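#' Apply the somatic hard filters
#'
#' Somatic records must satisfy all seven published hard filters, every
#' inequality inclusive and `NORMAL.ALT` a strict equality:
#' `TLOD >= 6`, `NLOD >= 3`, `NORMAL.DEPTH >= 15`, `TUMOR.DEPTH >= 20`,
#' `TUMOR.ALT >= 5`, `NORMAL.ALT == 0`, `TUMOR.AF >= 0.05`.
#' Germline records are MuTect2-tumor-only evidence-free and bypass these
#' somatic-specific filters. Each rejected record carries the full list
#' of filters it violates.
#'
#' @param variants A variant tibble (see [as_variant_table()]).
#' @param config A [repairscan_config()] (reserved for future tunables;
#'   the seven thresholds are the published constants).
#' @return A list with elements `retained` (variant tibble) and
#'   `rejected` (variant tibble with an extra `fail_reasons` character
#'   column, filters separated by `";"`).
#' @examples
#' v <- simulate_variants(3, list(TUMOR.AF = 2), seed = 1)
#' apply_variant_filters(v)$retained
#' @export
apply_variant_filters <- function(variants, config = repairscan_config()) {
  variants <- as_variant_table(variants)
  if (nrow(variants) == 0) {
    rejected <- variants
    rejected$fail_reasons <- character(0)
    return(list(retained = variants, rejected = rejected))
  }
  somatic <- variants$origin == "somatic"
  req <- c("tlod", "nlod", "normal_depth", "tumor_depth", "tumor_alt",
           "normal_alt", "tumor_af")
  for (col in req) {
    if (any(somatic & is.na(variants[[col]]))) {
      abort(paste0("somatic record with missing ", col,
                   " (variant_key ",
                   variants$variant_key[which(somatic & is.na(variants[[col]]))[1]], ")"))
    }
  }
  checks <- list(
    TLOD = variants$tlod >= 6,
    NLOD = variants$nlod >= 3,
    "NORMAL.DEPTH" = variants$normal_depth >= 15,
    "TUMOR.DEPTH" = variants$tumor_depth >= 20,
    "TUMOR.ALT" = variants$tumor_alt >= 5,
    "NORMAL.ALT" = variants$normal_alt == 0,
    "TUMOR.AF" = variants$tumor_af >= 0.05
  )
  fail_mat <- !do.call(cbind, checks)
  fail_mat[!somatic, ] <- FALSE  # germline records bypass the somatic filters
  n_fail <- rowSums(fail_mat)
  reasons <- apply(fail_mat, 1, function(r) paste(names(checks)[r], collapse = ";"))

  rejected <- variants[n_fail > 0, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$fail_reasons <- reasons[n_fail > 0]
  else rejected$fail_reasons <- character(0)
  list(retained = variants[n_fail == 0, , drop = FALSE], rejected = rejected)
}

#' Select deleterious variants
#'
#' Keeps exonic, non-synonymous variants classified "Pathogenic" or
#' "Likely Pathogenic"; everything else (benign, uncertain, synonymous,
#' non-exonic) is dropped. Apply after [apply_variant_filters()].
#'
#' @param variants A variant tibble.
#' @return The deleterious subset, possibly empty.
#' @export
select_deleterious <- function(variants) {
  variants <- as_variant_table(variants)
  dplyr::filter(variants,
                .data$is_exonic_nonsynonymous,
                .data$pathogenicity %in% c("Pathogenic", "Likely Pathogenic"))
}

#' Gene-level LOH from a segment profile
#'
#' An LOH event is registered for a gene when any segment overlapping the
#' gene interval by at least one base pair has minor-allele copy number
#' zero (after major/minor normalisation, "either the A or B allele at
#' zero" is exactly `b_copies == 0`). Partial overlap counts: a deletion
#' clipping the gene still inactivates the allele.
#'
#' @param profile A single-sample `segment_profile`.
#' @param chrom,start,end Gene interval (1-based inclusive).
#' @return `TRUE`/`FALSE`; a gene on a chromosome the profile does not
#'   cover yields a coverage warning and `FALSE`.
#' @export
detect_gene_loh <- function(profile, chrom, start, end) {
  require_single_sample(profile)
  segs <- profile[profile$chrom == chrom, , drop = FALSE]
  if (nrow(segs) == 0) {
    warn(paste0("no segment coverage on ", chrom, "; returning loh = FALSE"))
    return(FALSE)
  }
  any(segs$b_copies == 0 & segs$end >= start & segs$start <= end)
}

hr_deficient_genotypes <- c("HetMutantLOH", "HomozygousMutant", "CompoundHetMutant")

#' Assign the six-class genotype for one sample-gene pair
#'
#' The published classes, keyed by the deleterious variant count and the
#' gene-level LOH flag:
#' no variant -> `WildType` / `WildTypeLOH`; one variant ->
#' `HetMutant` / `HetMutantLOH`; two or more records sharing a single
#' `variant_key` (the same change on both alleles) ->
#' `HomozygousMutant`; two or more distinct keys -> `CompoundHetMutant`.
#' A gene is HR-deficient exactly when both alleles are disabled:
#' genotype in `{HetMutantLOH, HomozygousMutant, CompoundHetMutant}`.
#' Phasing is not inferred; distinct deleterious variants are assumed to
#' lie in trans (flagged in the `phase_assumed` column).
#'
#' @param deleterious Variant tibble for one sample-gene pair (possibly
#'   zero rows), already filtered and restricted to deleterious records.
#' @param loh Logical gene-level LOH flag (see [detect_gene_loh()]).
#' @param sample_id,gene Labels used when `deleterious` is empty.
#' @return A one-row tibble: `sample_id`, `gene`, `genotype`,
#'   `n_deleterious`, `deleterious_variants` (`";"`-separated keys),
#'   `loh`, `hr_deficient`, `phase_assumed`.
#' @export
assign_genotype <- function(deleterious, loh, sample_id = NULL, gene = NULL) {
  deleterious <- as_variant_table(deleterious)
  if (nrow(deleterious) > 0) {
    sample_id <- sample_id %||% deleterious$sample_id[1]
    gene <- gene %||% deleterious$gene[1]
  } else {
    sample_id <- sample_id %||% "sample"
    gene <- gene %||% "gene"
  }
  keys <- deleterious$variant_key
  n_records <- length(keys)
  n_distinct <- length(unique(keys))
  genotype <- if (n_records == 0) {
    if (loh) "WildTypeLOH" else "WildType"
  } else if (n_records == 1) {
    if (loh) "HetMutantLOH" else "HetMutant"
  } else if (n_distinct == 1) {
    "HomozygousMutant"
  } else {
    "CompoundHetMutant"
  }
  tibble::tibble(
    sample_id = sample_id, gene = gene, genotype = genotype,
    n_deleterious = n_records,
    deleterious_variants = paste(unique(keys), collapse = ";"),
    loh = loh,
    hr_deficient = genotype %in% hr_deficient_genotypes,
    phase_assumed = genotype == "CompoundHetMutant")
}

#' Genotype a panel of genes for one sample
#'
#' End-to-end wrapper: hard-filters the variants, keeps the deleterious
#' ones, looks up gene-level LOH in the segment profile, and assigns the
#' six-class genotype per gene with the biallelic HR-deficiency flag.
#'
#' @param variants A variant tibble for one sample.
#' @param profile A single-sample `segment_profile` for the same sample.
#' @param genes Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @param config A [repairscan_config()].
#' @return A tibble with one [assign_genotype()] row per gene.
#' @export
call_genotypes <- function(variants, profile, genes, config = repairscan_config()) {
  filtered <- apply_variant_filters(variants, config)
  deleterious <- select_deleterious(filtered$retained)
  sample_id <- unique(c(variants$sample_id, profile$sample_id))[1]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    loh <- detect_gene_loh(profile, g$chrom, g$start, g$end)
    dels <- deleterious[deleterious$gene == g$gene, , drop = FALSE]
    assign_genotype(dels, loh, sample_id = sample_id, gene = g$gene)
  })
  dplyr::bind_rows(rows)
}

#' Promoter methylation call from probe beta values
#'
#' The gene-level promoter methylation summary is the median beta value
#' over promoter-associated probes; the gene is called methylated when
#' that median reaches the configurable threshold (default 0.2).
#'
#' @param beta_values Numeric vector of probe beta values in `[0, 1]`.
#' @param threshold Methylation call threshold (inclusive).
#' @param sample_id,gene Labels.
#' @return A one-row tibble: `sample_id`, `gene`, `promoter_beta_median`,
#'   `methylated`.
#' @export
promoter_methylation_status <- function(beta_values, threshold = 0.2,
                                        sample_id = "sample", gene = "gene") {
  if (length(beta_values) == 0) abort("beta_values must contain at least one probe")
  if (any(!is.finite(beta_values)) || any(beta_values < 0 | beta_values > 1)) {
    abort("beta values must lie in [0, 1]")
  }
  med <- median(beta_values)
  tibble::tibble(sample_id = sample_id, gene = gene,
                 promoter_beta_median = med,
                 methylated = med >= threshold)
}
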