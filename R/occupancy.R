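#' Flag genes overlapping occupancy peaks
#'
#' A gene is occupancy-flagged when its span overlaps at least one peak
#' interval by at least one base pair on the same arm. Both gene and peak
#' coordinates are 0-based half-open, so a peak starting exactly at a
#' gene's end does not overlap it.
#'
#' @param genes gene annotation tibble.
#' @param peaks peak tibble from [read_intervals()] (`arm`, `start`, `end`).
#' @return tibble `gene_id`, `occupied` (logical), one row per gene.
#' @export
flag_occupancy <- function(genes, peaks) {
  hits <- dplyr::inner_join(
    dplyr::select(genes, "gene_id", "arm", "start", "end"),
    dplyr::select(peaks, "arm", p_start = "start", p_end = "end"),
    by = dplyr::join_by("arm", "start" < "p_end", "end" > "p_start")
  )
  tibble::tibble(gene_id = genes$gene_id,
                 occupied = genes$gene_id %in% hits$gene_id)
}

#' Flag housekeeping genes from tissue-specificity scores
#'
#' Housekeeping genes are called as those with tau strictly below the given
#' percentile (default 5th, linear interpolation) of the tau distribution
#' over genes with a tau score. Low tau means broad, tissue-unspecific
#' expression. Genes without tau get `NA` and are excluded from
#' tau-stratified analyses only.
#'
#' @param genes gene annotation tibble with a `tau` column.
#' @param percentile percentile in (0, 100).
#' @return tibble `gene_id`, `housekeeping` (logical or `NA`).
#' @export
housekeeping_flag <- function(genes, percentile = 5) {
  if (!"tau" %in% names(genes) || all(is.na(genes$tau))) {
    abort("no tau scores available")
  }
  thr <- unname(quantile(genes$tau, percentile / 100, na.rm = TRUE, type = 7))
  tibble::tibble(gene_id = genes$gene_id,
                 housekeeping = ifelse(is.na(genes$tau), NA,
                                       genes$tau < thr))
}

#' Per-gene coefficient of variation across two-dose lines
#'
#' Uses the deletion cohort's many lines as pseudo-replicates: for each
#' gene and condition, the CV of expression across the lines in which the
#' gene is two-dose and passes the expression cutoff in every replicate.
#' Genes on the arm carrying the deletions (default 2L) are excluded
#' because they are one-dose somewhere; genes with fewer than `min_lines`
#' usable lines are dropped with a warning.
#'
#' @param expr long expression tibble.
#' @param dose dose table from [assign_dose()].
#' @param genes gene annotation (for the arm exclusion).
#' @param cutoff linear-FPKM expression cutoff.
#' @param exclude_arm arm to exclude entirely (default `"2L"`).
#' @param min_lines minimum usable lines per gene (default 3).
#' @param per_line `"mean"` (default): CV over per-line replicate means;
#'   `"all_samples"`: CV over all individual samples.
#' @return tibble: `gene_id`, `sex`, `sex_transformed`, `tissue`, `cv`,
#'   `n_lines`.
#' @export
gene_cv_table <- function(expr, dose, genes, cutoff, exclude_arm = "2L",
                          min_lines = 3, per_line = c("mean", "all_samples")) {
  per_line <- match.arg(per_line)
  keep_genes <- genes$gene_id[!genes$arm %in% exclude_arm]
  usable <- replicate_stats(dplyr::filter(expr, .data$gene_id %in% keep_genes),
                            cutoff) |>
    dplyr::left_join(dose, by = c("gene_id", "line_id")) |>
    dplyr::filter(.data$dose == 2L, .data$all_expressed)
  if (per_line == "mean") {
    per_unit <- usable |>
      dplyr::mutate(value = .data$line_mean) |>
      dplyr::select("gene_id", "line_id", "sex", "sex_transformed",
                    "tissue", "value")
  } else {
    per_unit <- usable |>
      dplyr::select("gene_id", "line_id", "sex", "sex_transformed",
                    "tissue") |>
      dplyr::inner_join(expr, by = c("gene_id", "line_id", "sex",
                                     "sex_transformed", "tissue")) |>
      dplyr::mutate(value = .data$fpkm) |>
      dplyr::select("gene_id", "line_id", "sex", "sex_transformed",
                    "tissue", "value")
  }
  out <- per_unit |>
    dplyr::summarise(
      n_lines = dplyr::n_distinct(.data$line_id),
      cv = if (dplyr::n_distinct(.data$line_id) >= min_lines)
        cv(.data$value) else NA_real_,
      .by = c("gene_id", "sex", "sex_transformed", "tissue")
    )
  n_drop <- sum(is.na(out$cv))
  if (n_drop > 0) {
    warn(paste0(n_drop, " gene/condition record(s) with fewer than ",
                min_lines, " usable lines; dropped"))
  }
  dplyr::filter(out, !is.na(.data$cv))
}

#' Rank-sum comparison of CV between flagged and unflagged genes, by stratum
#'
#' Within each stratum (e.g. X-linked vs autosomal, housekeeping vs not,
#' EBox present vs absent, NSL-activated vs not) and condition, compares
#' the CV of occupancy-flagged genes against unflagged genes with a
#' Wilcoxon rank-sum test. Genes with a missing flag or stratum label are
#' excluded from that comparison only; a stratum with an empty side is
#' reported but not tested.
#'
#' @param cv_records tibble from [gene_cv_table()].
#' @param flags tibble `gene_id`, `flag` (logical) — e.g. MOF occupancy
#'   from [flag_occupancy()], renamed to `flag`.
#' @param strata optional tibble `gene_id`, `stratum` (character/factor);
#'   when omitted a single stratum `"all"` is used.
#' @param by condition columns to stratify by (default sex and tissue).
#' @return tibble with one row per (condition, stratum): sizes, medians,
#'   statistic, p-value (`NA` when one side is empty).
#' @export
stratified_compare <- function(cv_records, flags, strata = NULL,
                               by = c("sex", "tissue")) {
  if (is.null(strata)) {
    strata <- tibble::tibble(gene_id = unique(cv_records$gene_id),
                             stratum = "all")
  }
  dat <- cv_records |>
    dplyr::inner_join(flags, by = "gene_id") |>
    dplyr::inner_join(strata, by = "gene_id") |>
    dplyr::filter(!is.na(.data$flag), !is.na(.data$stratum))
  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "stratum")))) |>
    dplyr::group_modify(function(df, key) {
      a <- df$cv[df$flag]
      b <- df$cv[!df$flag]
      if (length(a) == 0 || length(b) == 0) {
        return(tibble::tibble(
          label_a = "flagged", label_b = "unflagged",
          n_a = length(a), n_b = length(b),
          median_a = if (length(a)) median(a) else NA_real_,
          median_b = if (length(b)) median(b) else NA_real_,
          statistic = NA_real_, p_value = NA_real_,
          test = "wilcoxon_rank_sum"
        ))
      }
      compare_groups(a, b, "flagged", "unflagged")
    }) |>
    dplyr::ungroup()
}
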