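test_that("peak overlap flags agree with a brute-force oracle", {
  genes <- tibble::tibble(gene_id = c("a", "b"), arm = "2L",
                          start = c(100, 100), end = c(200, 200))
  peaks <- tibble::tibble(arm = "2L", start = c(150, 200), end = c(300, 300))
  fl <- flag_occupancy(genes, peaks[1, ])
  expect_true(fl$occupied[fl$gene_id == "a"])
  # half-open adjacency: peak starting at the gene end does not overlap
  fl2 <- flag_occupancy(genes, peaks[2, ])
  expect_false(any(fl2$occupied))

  set.seed(33)
  rgenes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    arm = sample(c("2L", "X", "3R"), 40, replace = TRUE),
    start = sample.int(5000, 40)
  ) |> dplyr::mutate(end = start + sample.int(400, 40))
  rpeaks <- tibble::tibble(
    arm = sample(c("2L", "X", "3R"), 15, replace = TRUE),
    start = sample.int(5000, 15)
  ) |> dplyr::mutate(end = start + sample.int(600, 15))
  expect_equal(flag_occupancy(rgenes, rpeaks)$occupied,
               overlap_oracle(rgenes, rpeaks))
})

test_that("housekeeping call uses a strict percentile threshold on tau", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), arm = "2R",
                          start = 1:100 * 10, end = 1:100 * 10 + 5,
                          tau = (1:100) / 100)
  hk <- housekeeping_flag(genes)
  expect_equal(sum(hk$housekeeping), 5)
  expect_true(all(hk$housekeeping[1:5]))

  same <- dplyr::mutate(genes, tau = 0.4)
  expect_equal(sum(housekeeping_flag(same)$housekeeping), 0) # strict <

  missing <- dplyr::mutate(genes, tau = replace(tau, 1:10, NA))
  hk2 <- housekeeping_flag(missing)
  expect_true(all(is.na(hk2$housekeeping[1:10])))
  expect_error(housekeeping_flag(dplyr::mutate(genes, tau = NA_real_)),
               "tau")
})

test_that("line-wise CV table respects exclusions and line minima", {
  genes <- tibble::tibble(
    gene_id = c("const", "varies", "few", "on2L"),
    arm = c("2R", "2R", "2R", "2L"),
    start = c(0, 100, 200, 0), end = c(50, 150, 250, 50)
  )
  lines <- sprintf("L%d", 1:4)
  expr <- purrr::map_dfr(seq_along(lines), function(i) {
    toy_expression(genes$gene_id, setNames(
      list(c(5, c(2, 4, 8, 6)[i], 3, 3), c(5, c(2, 4, 8, 6)[i], 3, 3)),
      paste0(lines[i], c("_F_1", "_F_2"))))
  })
  dose <- tidyr::expand_grid(gene_id = genes$gene_id, line_id = lines) |>
    dplyr::mutate(dose = ifelse(gene_id == "few" & line_id != "L1", NA, 2L))
  cvt <- suppressWarnings(
    gene_cv_table(expr, dose, genes, cutoff = 0.5, exclude_arm = "2L")
  )
  expect_false("on2L" %in% cvt$gene_id)  # strict arm exclusion
  expect_false("few" %in% cvt$gene_id)   # < 3 usable lines
  expect_equal(cvt$cv[cvt$gene_id == "const"], 0)
  expect_equal(cvt$cv[cvt$gene_id == "varies"], cv(c(2, 4, 8, 6)))
  expect_equal(cvt$n_lines[cvt$gene_id == "varies"], 4L)

  # replicate/line ordering does not change the table
  cvt2 <- suppressWarnings(
    gene_cv_table(expr[sample.int(nrow(expr)), ], dose, genes,
                  cutoff = 0.5, exclude_arm = "2L")
  )
  expect_equal(dplyr::arrange(cvt2, gene_id), dplyr::arrange(cvt, gene_id))
})

test_that("stratified comparison handles strata, empties and degenerates", {
  set.seed(44)
  cvr <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:120),
    sex = "F", sex_transformed = FALSE, tissue = "whole",
    cv = c(rlnorm(60, -2, 0.3), rlnorm(60, -1.2, 0.3)),
    n_lines = 10L
  )
  flags <- tibble::tibble(gene_id = cvr$gene_id,
                          flag = rep(c(TRUE, FALSE), each = 60))
  out <- stratified_compare(cvr, flags)
  expect_equal(nrow(out), 1)
  expect_lt(out$p_value, 0.01)
  expect_lt(out$median_a, out$median_b) # flagged genes are quieter
  # degenerate single stratum equals an unstratified comparison
  direct <- compare_groups(cvr$cv[flags$flag], cvr$cv[!flags$flag])
  expect_equal(out$p_value, direct$p_value)

  # a stratum with an empty side is reported, not tested
  strata <- tibble::tibble(gene_id = cvr$gene_id,
                           stratum = rep(c("X", "auto"), times = c(60, 60)))
  out2 <- stratified_compare(cvr, flags, strata)
  expect_equal(nrow(out2), 2)
  expect_true(all(is.na(out2$p_value)))
  expect_equal(out2$n_b[out2$stratum == "X"], 0)
})
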