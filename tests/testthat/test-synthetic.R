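test_that("cohort generation is deterministic and structurally valid", {
  cfg <- small_config(seed = 2)
  co <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_equal(co$expression, co2$expression) # bit-identical under one seed
  expect_equal(co$truth, co2$truth)

  expect_equal(nrow(co$dfs), cfg$n_df_lines)
  expect_equal(nrow(co$samples),
               cfg$n_df_lines * length(cfg$sexes) * cfg$replicates)
  expect_equal(nrow(co$expression), nrow(co$genes) * nrow(co$samples))
  expect_true(all(co$expression$fpkm >= 0))

  # every Df deletes exactly genes_per_df fully-contained genes
  dose <- assign_dose(dplyr::filter(co$genes, !is_spike_in), co$dfs)
  per_line <- dose |>
    dplyr::summarise(n1 = sum(dose == 1L, na.rm = TRUE), .by = line_id)
  expect_true(all(per_line$n1 == cfg$genes_per_df))

  # a different seed changes the data
  co3 <- generate_cohort(small_config(seed = 3))
  expect_false(isTRUE(all.equal(co$expression$fpkm, co3$expression$fpkm)))

  # infeasible deletions are rejected up front
  expect_error(cohort_config(arms = c("2L" = 10), genes_per_df = 40),
               "exceeds")
})

test_that("spike-ins are quiet and flagged, not inferred from ids", {
  co <- generate_cohort(small_config(seed = 6))
  spikes <- co$genes$gene_id[co$genes$is_spike_in]
  expect_length(spikes, 4)
  sp <- dplyr::filter(co$expression, gene_id %in% spikes)
  gn <- dplyr::filter(co$expression, !gene_id %in% spikes)
  # technical noise of spike-ins is far below biological noise
  sp_cv <- sp |> dplyr::summarise(cv = cv(fpkm), .by = gene_id)
  expect_lt(max(sp_cv$cv), 0.15)
  gn_cv <- gn |> dplyr::summarise(cv = cv(fpkm), .by = gene_id)
  expect_gt(median(gn_cv$cv), median(sp_cv$cv))
})

test_that("intergenic background matches its analytic quantile", {
  cfg <- cohort_config(seed = 10)
  x <- generate_intergenic(cfg, n = 1e5)
  analytic <- qlnorm(0.95, cfg$intergenic_meanlog, cfg$intergenic_sdlog)
  expect_lt(abs(derive_cutoff(x) - analytic) / analytic, 0.02)
  expect_equal(generate_intergenic(cfg, n = 100),
               generate_intergenic(cfg, n = 100)) # seeded determinism
  # degenerate sd: the cutoff is the constant
  cfg0 <- cohort_config(intergenic_sdlog = 0, seed = 1)
  expect_equal(derive_cutoff(generate_intergenic(cfg0)),
               exp(cfg0$intergenic_meanlog))
})

test_that("planted one-dose inflation is detected; the null cohort is quiet", {
  co <- generate_cohort(small_config(seed = 8))
  genes <- dplyr::filter(co$genes, !is_spike_in)
  dose <- assign_dose(genes, co$dfs)
  cutoff <- derive_cutoff(co$intergenic)
  dt <- delta_table(dplyr::filter(co$expression, gene_id %in% genes$gene_id),
                    dose, cutoff) |>
    dplyr::filter(dose %in% c(1L, 2L))
  cmp <- compare_by(dt, group = "dose")
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$median_a, cmp$median_b)

  null_cfg <- small_config(seed = 8, alpha0 = 0, alpha1 = 0,
                           occ_shrink = 1, female_mult = 1)
  co0 <- generate_cohort(null_cfg)
  dt0 <- delta_table(
    dplyr::filter(co0$expression, gene_id %in% genes$gene_id),
    assign_dose(genes, co0$dfs), derive_cutoff(co0$intergenic)
  ) |>
    dplyr::filter(dose %in% c(1L, 2L))
  cmp0 <- compare_by(dt0, group = "dose")
  expect_gt(cmp0$p_value, 0.01)
  sex0 <- compare_by(dt0, group = "sex")
  expect_gt(sex0$p_value, 0.01)
})
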