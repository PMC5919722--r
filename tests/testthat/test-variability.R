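test_that("delta matches hand evaluations and its pairwise identity with CV", {
  expect_equal(delta(10, 10), 0)
  expect_equal(delta(3, 1), 1)
  expect_equal(delta(8, 4), 2 / 3)
  expect_equal(cv(c(8, 4)), 1 / 3)
  expect_equal(delta(8, 4) / cv(c(8, 4)), 2)
  expect_error(delta(0, 0), "f1 \\+ f2")

  set.seed(11)
  f1 <- rlnorm(1e4, 1, 1)
  f2 <- rlnorm(1e4, 1, 1)
  d <- delta(f1, f2)
  expect_true(all(d >= 0 & d < 2))
  two_cv <- vapply(seq_along(f1), function(i) 2 * cv(c(f1[i], f2[i])),
                   numeric(1))
  expect_equal(d, two_cv, tolerance = 1e-12)
})

test_that("multi-replicate delta averages all unordered pairs", {
  expect_equal(delta_multi(c(5, 5, 5)), 0)
  expect_equal(delta_multi(c(4, 4, 8)), mean(c(0, 2 / 3, 2 / 3)))
  expect_equal(delta_multi(c(7, 3)), delta(7, 3))
  expect_error(delta_multi(4), "two replicates")
})

test_that("cv follows the population convention and is scale invariant", {
  expect_equal(cv(rep(2.5, 6)), 0)
  expect_equal(cv(c(4, 8)), 1 / 3)
  expect_equal(cv(c(4, 8), convention = "sample"), sd(c(4, 8)) / 6)
  x <- rlnorm(50, 2, 0.6)
  expect_equal(cv(3.7 * x), cv(x))
  expect_error(cv(c(-5, 1)), "positive mean")
})

test_that("rank-sum comparison matches exact and permutation references", {
  same <- compare_groups(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_gt(same$p_value, 0.9)

  small <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(small$p_value, 0.1) # exact: 2/choose(6,3)
  expect_equal(small$statistic, 0)

  set.seed(21)
  a <- rnorm(18)
  b <- rnorm(22, 0.4)
  p_perm <- permutation_p(a, b, n_perm = 1e4)
  p_pkg <- compare_groups(a, b)$p_value
  expect_lt(abs(p_pkg - p_perm), 0.02)

  # planted shift at n = 500 is detected
  big <- compare_groups(rnorm(500), rnorm(500, 0.3))
  expect_lt(big$p_value, 0.01)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("delta table filters on cutoff and joins dose labels", {
  genes <- c("hi", "lo", "borderline")
  expr <- toy_expression(
    genes,
    list(L1_F_1 = c(8, 0.1, 1.0), L1_F_2 = c(4, 0.2, 0.5),
         L2_F_1 = c(6, 0.3, 2.0), L2_F_2 = c(6, 0.1, 2.0))
  )
  dose <- tibble::tibble(gene_id = rep(genes, 2),
                         line_id = rep(c("L1", "L2"), each = 3),
                         dose = c(1L, 2L, 2L, 2L, 2L, 2L))
  dt <- delta_table(expr, dose, cutoff = 0.68)
  expect_equal(sort(unique(dt$gene_id)), c("borderline", "hi"))
  # borderline passes only in L2
  expect_equal(dt$line_id[dt$gene_id == "borderline"], "L2")
  expect_equal(dt$delta[dt$gene_id == "hi" & dt$line_id == "L1"], 2 / 3)
  expect_equal(dt$delta[dt$gene_id == "hi" & dt$line_id == "L2"], 0)
  expect_equal(dt$dose[dt$gene_id == "hi" & dt$line_id == "L1"], 1L)
  # triplicates: mean pairwise delta, all three must pass
  expr3 <- toy_expression("g", list(L1_F_1 = 4, L1_F_2 = 4, L1_F_3 = 8))
  dt3 <- delta_table(expr3, tibble::tibble(gene_id = "g", line_id = "L1",
                                           dose = 2L), cutoff = 0.5)
  expect_equal(dt3$delta, delta_multi(c(4, 4, 8)))
  expect_equal(dt3$n_replicates, 3L)
})

test_that("median null resampling has the documented contract", {
  cfg <- small_config(seed = 5)
  co <- generate_cohort(cfg)
  genes <- dplyr::filter(co$genes, !is_spike_in)
  dose <- assign_dose(genes, co$dfs)
  cutoff <- derive_cutoff(co$intergenic)
  deltas <- delta_table(
    dplyr::filter(co$expression, gene_id %in% genes$gene_id), dose, cutoff
  ) |>
    dplyr::filter(sex == "F", dose %in% c(1L, 2L))

  r1 <- median_null(deltas, B = 1, seed = 9)
  expect_length(r1$null_medians, 1)
  expect_true(r1$empirical_p %in% c(0.5, 1))

  r <- median_null(deltas, B = 199, seed = 9)
  expect_length(r$null_medians, 199)
  expect_gt(r$empirical_p, 0)
  expect_lte(r$empirical_p, 1)
  # planted one-dose inflation: observed median clears the null
  expect_equal(r$empirical_p, 1 / 200)
  expect_gt(r$observed_median, median(r$null_medians))
  # determinism and tidier shapes
  r2 <- median_null(deltas, B = 199, seed = 9)
  expect_equal(r2$null_medians, r$null_medians)
  expect_equal(nrow(tidy(r)), 199)
  expect_equal(glance(r)$empirical_p, r$empirical_p)

  per_line <- median_null(deltas, seed = 9, scheme = "per_line")
  expect_equal(length(per_line$null_medians), per_line$B)
})
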