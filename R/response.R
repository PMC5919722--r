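#' Fold change of one-dose genes against pooled two-dose controls
#'
#' For every gene that is one-dose in a given line, the linear fold change
#' is the mean FPKM over that line's replicates divided by the mean FPKM
#' over the pooled replicates of all same-condition lines where the gene is
#' two-dose. With no dosage compensation a heterozygous deletion halves
#' expression, so fc = 0.5 is the no-response baseline. Genes must pass the
#' expression cutoff in all numerator replicates and in the two-dose pool on
#' a per-line basis (lines failing the cutoff are left out of the pool);
#' genes with no usable two-dose line are dropped with a warning.
#'
#' @param expr long expression tibble.
#' @param dose dose table from [assign_dose()].
#' @param cutoff linear-FPKM expression cutoff.
#' @return tibble: `gene_id`, `line_id`, `sex`, `sex_transformed`, `tissue`,
#'   `fc`, `log2fc`.
#' @export
fold_change <- function(expr, dose, cutoff) {
  per_line <- replicate_stats(expr, cutoff) |>
    dplyr::left_join(dose, by = c("gene_id", "line_id"))
  one <- dplyr::filter(per_line, .data$dose == 1L, .data$all_expressed)
  controls <- per_line |>
    dplyr::filter(.data$dose == 2L, .data$all_expressed) |>
    dplyr::summarise(
      control_mean = mean(.data$line_mean),
      n_control_lines = dplyr::n(),
      .by = c("gene_id", "sex", "sex_transformed", "tissue")
    )
  out <- dplyr::inner_join(one, controls,
                           by = c("gene_id", "sex", "sex_transformed", "tissue"))
  n_dropped <- nrow(one) - nrow(out)
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " one-dose measurement(s) without a usable ",
                "two-dose control pool; dropped"))
  }
  out |>
    dplyr::filter(.data$control_mean > 0) |>
    dplyr::mutate(fc = .data$line_mean / .data$control_mean,
                  log2fc = log2(.data$fc)) |>
    dplyr::select("gene_id", "line_id", "sex", "sex_transformed", "tissue",
                  "fc", "log2fc")
}

#' Dosage-response magnitude of a fold change
#'
#' The dosage response measures how far a one-dose gene deviates from the
#' twofold-reduction baseline, in absolute log2 units:
#' `response_raw = |log2(fc) + 1|`. Halving (fc = 0.5, no compensation)
#' scores 0; full compensation (fc = 1) and twofold anticompensation
#' (fc = 0.25) both score 1. For binning, rounding to the closest integer
#' (half-to-even) is applied to `log2(fc)` before the shift:
#' `response_bin = |round(log2(fc)) + 1|`. `formula = "literal"` exposes the
#' alternative reading `|log2(fc + 1)|`, which does not satisfy the halving
#' baseline and is provided for comparison only.
#'
#' @param fc positive numeric vector of linear fold changes (Df/+ vs
#'   control).
#' @param formula `"shifted"` (default) or `"literal"`.
#' @return tibble: `fc`, `response_raw` (continuous magnitude),
#'   `response_bin` (non-negative integer).
#' @examples
#' response_score(c(0.5, 1, 0.25))
#' @export
response_score <- function(fc, formula = c("shifted", "literal")) {
  formula <- match.arg(formula)
  if (any(fc <= 0)) abort("fold changes must be positive")
  if (formula == "shifted") {
    l2 <- log2(fc)
    raw <- abs(l2 + 1)
    bin <- as.integer(abs(round(l2) + 1)) # round() is half-to-even
  } else {
    raw <- abs(log2(fc + 1))
    bin <- as.integer(abs(round(log2(fc + 1))))
  }
  tibble::tibble(fc = fc, response_raw = raw, response_bin = bin)
}

#' Score dosage responses for a fold-change table
#'
#' @param fcs fold-change tibble from [fold_change()].
#' @param formula passed to [response_score()].
#' @return `fcs` with `response_raw` and `response_bin` columns added.
#' @export
response_table <- function(fcs, formula = c("shifted", "literal")) {
  sc <- response_score(fcs$fc, formula = match.arg(formula))
  dplyr::bind_cols(fcs, sc[c("response_raw", "response_bin")])
}

#' Delta distributions across dosage-response bins
#'
#' Joins dosage-response records with delta records on (gene, line,
#' condition), pools bins at or above `max_bin_pool`, and reports per-bin
#' delta summaries together with rank-sum tests between adjacent bins. A
#' monotone increase of median delta across bins indicates that genes
#' responding to dose reduction most strongly are also the most variable.
#'
#' @param responses response tibble from [response_table()].
#' @param deltas delta tibble from [delta_table()].
#' @param max_bin_pool bins >= this value are pooled (default 2).
#' @return list of class `dosevar_response_bins` with elements `bins`
#'   (per-bin n and median delta) and `tests` (adjacent-bin comparisons),
#'   both tibbles carrying the condition columns.
#' @export
bin_vs_delta <- function(responses, deltas, max_bin_pool = 2) {
  joined <- dplyr::inner_join(
    responses, deltas,
    by = c("gene_id", "line_id", "sex", "sex_transformed", "tissue")
  ) |>
    dplyr::mutate(bin = pmin(.data$response_bin, max_bin_pool),
                  bin_label = ifelse(.data$bin >= max_bin_pool,
                                     paste0(">=", max_bin_pool),
                                     as.character(.data$bin)))
  bins <- joined |>
    dplyr::summarise(n = dplyr::n(), median_delta = median(.data$delta),
                     .by = c("sex", "sex_transformed", "tissue",
                             "bin", "bin_label")) |>
    dplyr::arrange(.data$sex, .data$tissue, .data$bin)
  tests <- joined |>
    dplyr::group_by(.data$sex, .data$sex_transformed, .data$tissue) |>
    dplyr::group_modify(function(df, key) {
      present <- sort(unique(df$bin))
      if (length(present) < 2) return(tibble::tibble())
      purrr::map_dfr(seq_len(length(present) - 1), function(i) {
        a <- df$delta[df$bin == present[i]]
        b <- df$delta[df$bin == present[i + 1]]
        compare_groups(a, b,
                       unique(df$bin_label[df$bin == present[i]]),
                       unique(df$bin_label[df$bin == present[i + 1]]))
      })
    }) |>
    dplyr::ungroup()
  structure(list(bins = bins, tests = tests, data = joined),
            class = "dosevar_response_bins")
}

#' @export
print.dosevar_response_bins <- function(x, ...) {
  cat("Delta by dosage-response bin\n")
  print(x$bins)
  if (nrow(x$tests) > 0) {
    cat("Adjacent-bin rank-sum tests\n")
    print(x$tests)
  }
  invisible(x)
}
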