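#' Assign per-gene, per-line dose from deletion intervals
#'
#' A gene is one-dose in a deficiency line when its whole span lies inside
#' the line's deleted interval on the same arm, two-dose when it does not
#' overlap the deletion at all, and excluded (dose `NA`) when it partially
#' overlaps a deletion boundary — boundary genes cannot be assigned a dose
#' without risk of mislabeling. Intervals are 0-based half-open.
#'
#' @param genes gene annotation tibble (`gene_id`, `arm`, `start`, `end`).
#' @param dfs deficiency definitions (`line_id`, `arm`, `start`, `end`).
#' @return tibble with one row per (gene, line): `gene_id`, `line_id`,
#'   `dose` (integer 1, 2 or `NA` for excluded).
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", arm = "2L", start = 120, end = 180)
#' dfs <- tibble::tibble(line_id = "Df-A", arm = "2L", start = 100, end = 200)
#' assign_dose(genes, dfs)
#' @export
assign_dose <- function(genes, dfs) {
  genes <- validate_gene_annotation(genes)
  if (anyDuplicated(dfs$line_id)) abort("one deletion interval per line_id")
  grid <- tidyr::expand_grid(gene_id = genes$gene_id, line_id = dfs$line_id)
  grid |>
    dplyr::left_join(dplyr::select(genes, "gene_id", "arm", "start", "end"),
                     by = "gene_id") |>
    dplyr::left_join(dplyr::select(dfs, "line_id", df_arm = "arm",
                                   df_start = "start", df_end = "end"),
                     by = "line_id") |>
    dplyr::mutate(
      overlaps = .data$arm == .data$df_arm &
        .data$start < .data$df_end & .data$df_start < .data$end,
      contained = .data$overlaps &
        .data$start >= .data$df_start & .data$end <= .data$df_end,
      dose = dplyr::case_when(
        contained ~ 1L,
        !overlaps ~ 2L,
        TRUE ~ NA_integer_
      )
    ) |>
    dplyr::select("gene_id", "line_id", "dose") |>
    dplyr::arrange(.data$gene_id, .data$line_id)
}

#' Derive an expression cutoff from intergenic background signal
#'
#' Genes are called expressed only above the background seen in intergenic
#' regions. The default cutoff is the 95th percentile of the intergenic
#' signal distribution (linear interpolation). Because the phrase "median of
#' the top 95 percentile" admits a second reading, `method =
#' "top_tail_median"` instead returns the median of the values at or above
#' that percentile. `fixed_cutoff()` gives the published whole-fly reference
#' value for use with real cohorts.
#'
#' @param intergenic_fpkm non-empty numeric vector of non-negative
#'   intergenic FPKM signals.
#' @param percentile percentile in (0, 100\].
#' @param method `"percentile"` (default) or `"top_tail_median"`.
#' @return a single numeric cutoff on the linear FPKM scale.
#' @examples
#' derive_cutoff(seq(0.01, 1, by = 0.01)) # ~0.9505
#' @export
derive_cutoff <- function(intergenic_fpkm, percentile = 95,
                          method = c("percentile", "top_tail_median")) {
  method <- match.arg(method)
  if (length(intergenic_fpkm) == 0) abort("intergenic signal vector is empty")
  if (anyNA(intergenic_fpkm) || any(intergenic_fpkm < 0)) {
    abort("intergenic signals must be non-negative and non-missing")
  }
  if (percentile <= 0 || percentile > 100) abort("percentile must be in (0, 100]")
  q <- unname(quantile(intergenic_fpkm, percentile / 100, type = 7))
  if (method == "percentile") q else median(intergenic_fpkm[intergenic_fpkm >= q])
}

#' Published whole-fly FPKM expression cutoff
#'
#' The reference cutoff applied to the 99-line whole-fly cohort
#' (FPKM >= 0.6829118 in every replicate), for use when analysing real data
#' with the original threshold rather than re-deriving it.
#'
#' @return a single numeric value.
#' @export
fixed_cutoff <- function() 0.6829118

#' Genes expressed above cutoff in every sample of a set
#'
#' Variability statistics are only computed for genes expressed in all
#' replicates being compared: a gene is retained when its FPKM is at or
#' above the cutoff in every named sample.
#'
#' @param expr long expression tibble (`gene_id`, `sample_id`, `fpkm`).
#' @param sample_ids character vector of sample ids forming the comparison
#'   group (e.g. the two replicates of one line/sex).
#' @param cutoff numeric cutoff on the linear FPKM scale.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(expr, sample_ids, cutoff) {
  unknown <- setdiff(sample_ids, unique(expr$sample_id))
  if (length(unknown) > 0) {
    abort(paste0("unknown sample(s): ", paste(unknown, collapse = ", ")))
  }
  expr |>
    dplyr::filter(.data$sample_id %in% sample_ids) |>
    dplyr::summarise(keep = dplyr::n() == length(sample_ids) &&
                       all(.data$fpkm >= cutoff),
                     .by = "gene_id") |>
    dplyr::filter(.data$keep) |>
    dplyr::pull("gene_id")
}
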