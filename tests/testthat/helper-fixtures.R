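# Shared fixture builders: everything is generated in code at test time.

withr_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# A compact cohort configuration for unit tests (the full default config is
# exercised by the acceptance suite).
small_config <- function(seed = 1, ...) {
  cohort_config(arms = c("2L" = 120, "2R" = 60, "X" = 60),
                n_df_lines = 12, genes_per_df = 15,
                n_spike_ins = 4, n_intergenic = 300,
                seed = seed, ...)
}

# Tiny hand-built expression cohort: 2 lines x 2 sexes x 2 replicates.
toy_expression <- function(genes, fpkm_by_sample) {
  samples <- toy_samples(names(fpkm_by_sample))
  purrr::imap_dfr(fpkm_by_sample, function(vals, sid) {
    tibble::tibble(gene_id = genes, sample_id = sid, fpkm = vals)
  }) |>
    dplyr::inner_join(samples, by = "sample_id") |>
    dplyr::relocate("fpkm", .after = dplyr::last_col())
}

toy_samples <- function(sample_ids) {
  parts <- strsplit(sample_ids, "_")
  tibble::tibble(
    sample_id = sample_ids,
    line_id = vapply(parts, `[`, "", 1),
    sex = vapply(parts, `[`, "", 2),
    sex_transformed = FALSE,
    tissue = "whole",
    replicate = as.integer(vapply(parts, `[`, "", 3))
  )
}

# Independent brute-force interval-overlap oracle (0-based half-open).
overlap_oracle <- function(genes, peaks) {
  vapply(seq_len(nrow(genes)), function(i) {
    any(peaks$arm == genes$arm[i] &
          genes$start[i] < peaks$end &
          peaks$start < genes$end[i])
  }, logical(1))
}

# Monte-Carlo permutation oracle for the two-sided rank-sum test.
permutation_p <- function(a, b, n_perm = 1e4) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- sum(rank(pooled)[seq_len(na)])
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), na)
    sum(rank(pooled)[idx])
  }, numeric(1))
  mu <- na * (length(pooled) + 1) / 2
  (1 + sum(abs(perm - mu) >= abs(obs - mu))) / (n_perm + 1)
}
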