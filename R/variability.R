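#' Replicate-pair expression variability statistic
#'
#' The scale-free variability of a pair of expression measurements:
#' \eqn{\delta = 2 |F_1 - F_2| / (F_1 + F_2)}. It lies in \[0, 2\], is 0 for
#' identical replicates, and for a pair equals exactly twice the
#' population-convention coefficient of variation ([cv()]). Because it is
#' built from only two replicates it is a group-level instrument: pools of
#' delta values are compared between gene groups, it is not a per-gene noise
#' estimate.
#'
#' @param f1,f2 numeric vectors of paired FPKM values; both must be
#'   positive (in practice, at or above the expression cutoff).
#' @return numeric vector of delta values in \[0, 2\].
#' @examples
#' delta(3, 1)    # 1
#' delta(8, 4)    # 2/3, exactly 2 * cv(c(8, 4))
#' @export
delta <- function(f1, f2) {
  if (any(f1 + f2 <= 0)) abort("delta requires f1 + f2 > 0")
  2 * abs(f1 - f2) / (f1 + f2)
}

#' Mean pairwise delta over two or more replicates
#'
#' For triplicate designs, variability is the mean of the delta values of
#' all unordered replicate pairs; for `n = 2` this reduces to [delta()].
#'
#' @param replicates numeric vector of at least two positive FPKM values.
#' @return a single numeric value.
#' @examples
#' delta_multi(c(4, 4, 8)) # mean(0, 2/3, 2/3) = 4/9
#' @export
delta_multi <- function(replicates) {
  n <- length(replicates)
  if (n < 2) abort("delta_multi needs at least two replicates")
  pairs <- utils::combn(n, 2)
  mean(delta(replicates[pairs[1, ]], replicates[pairs[2, ]]))
}

#' Coefficient of variation
#'
#' Standard deviation divided by mean. The default population convention
#' (divisor n) makes the pairwise identity `delta = 2 * cv` exact; the
#' sample convention (divisor n - 1) is available for comparison with other
#' tools.
#'
#' @param values non-empty numeric vector with positive mean.
#' @param convention `"population"` (divisor n, default) or `"sample"`.
#' @return a single non-negative numeric value.
#' @examples
#' cv(c(4, 8)) # 1/3
#' @export
cv <- function(values, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (length(values) == 0) abort("cv of an empty vector is undefined")
  m <- mean(values)
  if (m <= 0) abort("cv requires a positive mean")
  s <- sd(values)
  if (convention == "population") {
    n <- length(values)
    s <- s * sqrt((n - 1) / n)
  }
  if (is.na(s)) s <- 0 # single value
  s / m
}

#' Per-(gene, line, condition) delta table
#'
#' Computes the replicate variability statistic for every gene in every
#' line and condition (sex, sex-transformed status, tissue) where the gene
#' passes the expression cutoff in all replicates. Dose labels from
#' [assign_dose()] are joined in so that one-dose and two-dose pools can be
#' compared directly.
#'
#' @param expr long expression tibble from [read_expression()] or
#'   [generate_cohort()].
#' @param dose dose table from [assign_dose()].
#' @param cutoff linear-FPKM expression cutoff; genes below it in any
#'   replicate of a (line, condition) group are dropped from that group.
#' @param min_replicates minimum replicates required per group.
#' @return tibble: `gene_id`, `line_id`, `sex`, `sex_transformed`, `tissue`,
#'   `n_replicates`, `delta`, `dose`.
#' @export
delta_table <- function(expr, dose, cutoff, min_replicates = 2) {
  if (min_replicates < 2) abort("delta needs at least two replicates")
  out <- replicate_stats(expr, cutoff) |>
    dplyr::filter(.data$n_replicates >= min_replicates,
                  .data$all_expressed) |>
    dplyr::select("gene_id", "line_id", "sex", "sex_transformed", "tissue",
                  "n_replicates", "delta")
  dplyr::left_join(out, dose, by = c("gene_id", "line_id"))
}

#' Wilcoxon rank-sum comparison of two value pools
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test: exact enumeration for
#' small untied samples (both n <= 50), normal approximation with tie
#' correction otherwise — the procedure used for every group contrast in the
#' package (dose groups, response bins, occupancy strata).
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @param label_a,label_b group labels carried into the output.
#' @return one-row tibble: `label_a`, `label_b`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `statistic` (Mann-Whitney U of group a), `p_value`, `test`.
#' @export
compare_groups <- function(values_a, values_b,
                           label_a = "a", label_b = "b") {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both groups must be non-empty")
  }
  ht <- suppressWarnings(wilcox.test(values_a, values_b, exact = NULL,
                                     correct = TRUE))
  tibble::tibble(
    label_a = label_a, label_b = label_b,
    n_a = length(values_a), n_b = length(values_b),
    median_a = median(values_a), median_b = median(values_b),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    test = "wilcoxon_rank_sum"
  )
}

#' Compare delta pools split by a grouping column
#'
#' Convenience wrapper running [compare_groups()] between the two levels of
#' a grouping column of a delta table (e.g. `dose`, `sex`), optionally
#' within conditions.
#'
#' @param records tibble holding the values and grouping column.
#' @param value name of the value column (default `"delta"`).
#' @param group name of the two-level grouping column.
#' @param by optional character vector of condition columns to stratify by.
#' @return tibble with one comparison row per condition.
#' @export
compare_by <- function(records, group, value = "delta", by = character()) {
  levels <- sort(unique(records[[group]]))
  if (length(levels) != 2) abort("grouping column must have exactly two levels")
  run1 <- function(df) {
    a <- df[[value]][df[[group]] == levels[1]]
    b <- df[[value]][df[[group]] == levels[2]]
    compare_groups(a, b, as.character(levels[1]), as.character(levels[2]))
  }
  if (length(by) == 0) return(run1(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ run1(.x)) |>
    dplyr::ungroup()
}

#' Observed one-dose median delta against a resampled two-dose null
#'
#' Pools delta over all one-dose (gene, deleting-line) measurements and
#' compares its median with a null distribution built from the same genes
#' when they are two-dose. Under the default `"gene_resample"` scheme each
#' null draw re-assigns every one-dose gene to a uniformly chosen line in
#' which it is two-dose and records the pooled median; `"per_line"` instead
#' yields one null median per non-deleting line (the pooled deltas of the
#' one-dose gene set measured two-dose in that line). Genes never measured
#' two-dose elsewhere are dropped with a warning.
#'
#' The empirical p-value uses the add-one rule
#' `(1 + #\{null >= observed\}) / (B + 1)` so it is never zero.
#'
#' @param deltas delta table from [delta_table()] (must carry `dose`),
#'   already restricted to one condition (sex/tissue).
#' @param B number of null resamples (gene_resample scheme).
#' @param seed RNG seed.
#' @param scheme `"gene_resample"` or `"per_line"`.
#' @return object of class `dosevar_median_null`; see [tidy()] and
#'   [glance()] methods.
#' @export
median_null <- function(deltas, B = 999, seed = 1,
                        scheme = c("gene_resample", "per_line")) {
  scheme <- match.arg(scheme)
  if (!"dose" %in% names(deltas)) abort("delta table must carry a dose column")
  one <- dplyr::filter(deltas, .data$dose == 1L)
  two <- dplyr::filter(deltas, .data$dose == 2L)
  if (nrow(one) == 0) abort("no one-dose measurements in the delta table")
  usable <- one$gene_id %in% two$gene_id
  if (!all(usable)) {
    warn(paste0(sum(!usable),
                " one-dose gene(s) never measured two-dose elsewhere; dropped"))
    one <- one[usable, , drop = FALSE]
  }
  observed <- median(one$delta)
  two_by_gene <- split(two$delta, two$gene_id)[unique(one$gene_id)]
  withr_seed(seed)
  if (scheme == "gene_resample") {
    counts <- table(one$gene_id)[names(two_by_gene)]
    null_medians <- vapply(seq_len(B), function(i) {
      draws <- unlist(mapply(function(v, k) v[sample.int(length(v), k, replace = TRUE)],
                             two_by_gene, as.integer(counts), SIMPLIFY = FALSE),
                      use.names = FALSE)
      median(draws)
    }, numeric(1))
  } else {
    pool_lines <- setdiff(unique(two$line_id), unique(one$line_id))
    gene_set <- unique(one$gene_id)
    null_medians <- two |>
      dplyr::filter(.data$line_id %in% pool_lines,
                    .data$gene_id %in% gene_set) |>
      dplyr::summarise(m = median(.data$delta), .by = "line_id") |>
      dplyr::pull("m")
    B <- length(null_medians)
  }
  structure(
    list(observed_median = observed, null_medians = null_medians,
         empirical_p = (1 + sum(null_medians >= observed)) / (B + 1),
         B = B, seed = seed, scheme = scheme, n_pool = nrow(one)),
    class = "dosevar_median_null"
  )
}

# seed scoping without adding a dependency on withr
withr_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' @export
print.dosevar_median_null <- function(x, ...) {
  cat("Median-vs-null comparison (", x$scheme, " scheme)\n", sep = "")
  cat("  one-dose pool size : ", x$n_pool, "\n", sep = "")
  cat("  observed median    : ", format(x$observed_median, digits = 4), "\n", sep = "")
  cat("  null draws (B)     : ", x$B, "\n", sep = "")
  cat("  empirical p        : ", format(x$empirical_p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn median_null one row per null draw (`draw`, `null_median`).
#' @param x a `dosevar_median_null` object.
#' @param ... unused.
#' @export
tidy.dosevar_median_null <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null_medians), null_median = x$null_medians)
}

#' @describeIn median_null one-row summary (observed median, B, empirical p).
#' @export
glance.dosevar_median_null <- function(x, ...) {
  tibble::tibble(observed_median = x$observed_median, B = x$B,
                 empirical_p = x$empirical_p, n_pool = x$n_pool,
                 scheme = x$scheme, seed = x$seed)
}
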