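# Vectorized per-(gene, line, condition) replicate summaries.
#
# Pivots replicates into columns so that replicate means, cutoff checks and
# pairwise delta values are computed with vectorized arithmetic instead of
# one R call per group (cohorts have hundreds of thousands of groups).
replicate_stats <- function(expr, cutoff) {
  wide <- expr |>
    dplyr::select("gene_id", "line_id", "sex", "sex_transformed", "tissue",
                  "replicate", "fpkm") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "fpkm",
                       names_prefix = "rep")
  repcols <- grep("^rep", names(wide), value = TRUE)
  mat <- as.matrix(wide[repcols])
  present <- !is.na(mat)
  n_rep <- rowSums(present)
  all_expressed <- rowSums(present & mat >= cutoff) == n_rep
  line_mean <- rowMeans(mat, na.rm = TRUE)
  # mean pairwise delta over the available replicates
  k <- ncol(mat)
  dsum <- numeric(nrow(mat))
  dcnt <- numeric(nrow(mat))
  if (k >= 2) {
    for (j in seq_len(k - 1)) {
      for (l in seq(j + 1, k)) {
        both <- present[, j] & present[, l]
        if (!any(both)) next
        d <- 2 * abs(mat[both, j] - mat[both, l]) /
          (mat[both, j] + mat[both, l])
        dsum[both] <- dsum[both] + d
        dcnt[both] <- dcnt[both] + 1
      }
    }
  }
  out <- wide[c("gene_id", "line_id", "sex", "sex_transformed", "tissue")]
  out$n_replicates <- as.integer(n_rep)
  out$all_expressed <- all_expressed
  out$line_mean <- line_mean
  out$delta <- ifelse(dcnt > 0, dsum / dcnt, NA_real_)
  out
}
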