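#' Configuration of a synthetic deletion cohort
#'
#' Describes the generative model of a DrosDel-style deficiency cohort:
#' each of `n_df_lines` lines deletes a contiguous block of `genes_per_df`
#' genes on `df_arm`, every line is profiled in both sexes with
#' `replicates` biological replicates, and expression is log-normal around
#' a gene-specific baseline. On the log2 scale,
#'
#' \deqn{\log_2 F_{g\ell r} = \log_2 B_g + d_{g\ell} + \epsilon_{line} +
#'   \epsilon_{rep}}
#'
#' with dose term \eqn{d = 0} for two-dose and \eqn{-1 + \rho_g} for
#' one-dose genes, where \eqn{\rho_g \sim N(0, \sigma_\rho)} is the
#' gene-specific dosage response (0 = exact halving, +1 = full
#' compensation). Both noise terms are scaled by a common dispersion
#' factor \eqn{\kappa}: one-dose measurements are inflated by
#' `1 + alpha0 + alpha1 * |rho_g|`, occupancy-flagged genes are shrunk by
#' `occ_shrink`, and female samples are inflated by `female_mult`. Under
#' compensation, male X genes keep dose term 0 and no inflation. Spike-ins
#' carry only technical noise `spike_sd`; intergenic background signals
#' are log-normal with known parameters so the derived expression cutoff
#' has an analytic reference value.
#'
#' @param arms named integer vector of gene counts per arm.
#' @param n_df_lines number of deficiency lines.
#' @param genes_per_df genes deleted per line (contiguous block).
#' @param df_arm arm carrying all deletions.
#' @param replicates biological replicates per line/sex (2 or 3).
#' @param sexes sexes profiled.
#' @param tissue tissue label for all samples.
#' @param baseline_log2_mean,baseline_log2_sd log2-FPKM baseline
#'   distribution across genes.
#' @param rep_sd replicate (biological) noise sd, log2 scale.
#' @param line_sd line-effect noise sd, log2 scale (shared by a line's
#'   replicates).
#' @param alpha0 one-dose dispersion inflation at zero response.
#' @param alpha1 additional inflation per unit |dosage response|.
#' @param sigma_rho sd of the gene-specific dosage response rho.
#' @param occ_fraction fraction of genes occupancy-flagged.
#' @param occ_shrink multiplicative dispersion shrink (< 1) for
#'   occupancy-flagged genes.
#' @param female_mult dispersion multiplier for female samples.
#' @param male_x_compensation if `TRUE`, male X-linked genes are fully
#'   dose-compensated (dose term 0, no one-dose inflation).
#' @param n_spike_ins number of spike-in controls.
#' @param spike_sd technical noise sd of spike-ins, log2 scale.
#' @param n_intergenic number of intergenic background signals.
#' @param intergenic_meanlog,intergenic_sdlog natural-log parameters of
#'   the intergenic log-normal distribution.
#' @param ebox_fraction,nsl_fraction fractions of genes flagged with an
#'   EBox promoter motif / as NSL-activated.
#' @param seed RNG seed; the cohort is a deterministic function of the
#'   config.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(arms = c("2L" = 600, "2R" = 350, "3L" = 350,
                                   "3R" = 350, "4" = 30, "X" = 320),
                          n_df_lines = 99, genes_per_df = 40,
                          df_arm = "2L", replicates = 2,
                          sexes = c("F", "M"), tissue = "whole",
                          baseline_log2_mean = 3, baseline_log2_sd = 1.5,
                          rep_sd = 0.25, line_sd = 0.2,
                          alpha0 = 0.5, alpha1 = 0.6, sigma_rho = 0.8,
                          occ_fraction = 0.3, occ_shrink = 0.6,
                          female_mult = 1.3, male_x_compensation = TRUE,
                          n_spike_ins = 20, spike_sd = 0.05,
                          n_intergenic = 1000,
                          intergenic_meanlog = log(0.05),
                          intergenic_sdlog = 1.55,
                          ebox_fraction = 0.3, nsl_fraction = 0.2,
                          seed = 1) {
  cfg <- as.list(environment())
  if (!df_arm %in% names(arms)) abort("df_arm must be one of the arms")
  if (genes_per_df > arms[[df_arm]]) {
    abort("genes_per_df exceeds the number of genes on the deletion arm")
  }
  sds <- c(rep_sd, line_sd, sigma_rho, spike_sd, baseline_log2_sd)
  if (any(sds < 0)) abort("all standard deviations must be non-negative")
  if (occ_shrink <= 0 || occ_shrink > 1) abort("occ_shrink must be in (0, 1]")
  if (!replicates %in% c(2, 3)) abort("replicates must be 2 or 3")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic deletion cohort with planted ground truth
#'
#' Draws a full cohort — expression table, sample metadata, gene
#' annotation, deficiency intervals, occupancy peaks, intergenic
#' background — from the generative model described in [cohort_config()],
#' along with the per-gene truth (baseline, dosage response, dispersion
#' factors) needed to verify that the analysis pipeline recovers the
#' planted effects. Bit-identical for a fixed config.
#'
#' @param config a [cohort_config()].
#' @return list of class `dosevar_cohort`: `expression` (long tibble as
#'   from [read_expression()]), `genes`, `samples`, `dfs`, `peaks`,
#'   `truth`, `intergenic`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr_seed(config$seed)

  # --- gene annotation ----------------------------------------------------
  arms <- config$arms
  gene_arm <- rep(names(arms), times = arms)
  idx_on_arm <- unlist(lapply(arms, seq_len), use.names = FALSE)
  n_real <- sum(arms)
  gene_len <- 1500
  spacing <- 2000
  genes <- tibble::tibble(
    gene_id = sprintf("G%05d", seq_len(n_real)),
    arm = gene_arm,
    start = (idx_on_arm - 1) * spacing,
    end = (idx_on_arm - 1) * spacing + gene_len,
    tau = runif(n_real),
    ebox = runif(n_real) < config$ebox_fraction,
    nsl_activated = runif(n_real) < config$nsl_fraction,
    is_spike_in = FALSE
  )
  if (config$n_spike_ins > 0) {
    ns <- config$n_spike_ins
    spike_arm <- names(arms)[length(arms)] # parked beyond the last arm
    spikes <- tibble::tibble(
      gene_id = sprintf("SPIKE%03d", seq_len(ns)),
      arm = spike_arm,
      start = (arms[[spike_arm]] + seq_len(ns) - 1) * spacing,
      end = (arms[[spike_arm]] + seq_len(ns) - 1) * spacing + gene_len,
      tau = NA_real_, ebox = NA, nsl_activated = NA,
      is_spike_in = TRUE
    )
    genes <- dplyr::bind_rows(genes, spikes)
  }

  # --- deficiency lines: contiguous blocks on df_arm ----------------------
  arm_genes <- dplyr::filter(genes, .data$arm == config$df_arm)
  max_start <- nrow(arm_genes) - config$genes_per_df + 1
  block_start <- sample.int(max_start, config$n_df_lines, replace = TRUE)
  dfs <- tibble::tibble(
    line_id = sprintf("Df-%03d", seq_len(config$n_df_lines)),
    arm = config$df_arm,
    start = arm_genes$start[block_start],
    end = arm_genes$end[block_start + config$genes_per_df - 1]
  )
  deleted <- purrr::map2_dfr(dfs$line_id, seq_len(nrow(dfs)), function(l, i) {
    tibble::tibble(
      line_id = l,
      gene_id = arm_genes$gene_id[block_start[i] +
                                    seq_len(config$genes_per_df) - 1]
    )
  })

  # --- per-gene truth -----------------------------------------------------
  n_genes <- nrow(genes)
  baseline_log2 <- rnorm(n_genes, config$baseline_log2_mean,
                         config$baseline_log2_sd)
  if (config$n_spike_ins > 0) {
    spike_rows <- which(genes$is_spike_in)
    baseline_log2[spike_rows] <- seq(0, 8, length.out = length(spike_rows))
  }
  rho <- rnorm(n_genes, 0, config$sigma_rho)
  rho[genes$is_spike_in] <- 0
  occupied <- runif(n_genes) < config$occ_fraction
  occupied[genes$is_spike_in] <- FALSE
  truth <- tibble::tibble(
    gene_id = genes$gene_id,
    baseline_log2 = baseline_log2,
    rho = rho,
    occupied = occupied,
    one_dose_inflation = 1 + config$alpha0 + config$alpha1 * abs(rho),
    tau = genes$tau
  )

  # --- occupancy peaks ----------------------------------------------------
  occ_genes <- genes[occupied, ]
  peaks <- tibble::tibble(arm = occ_genes$arm,
                          start = occ_genes$start + 100,
                          end = occ_genes$end - 100)
  attr(peaks, "name") <- "MOF"

  # --- samples ------------------------------------------------------------
  samples <- tidyr::expand_grid(
    line_id = dfs$line_id,
    sex = config$sexes,
    replicate = seq_len(config$replicates)
  ) |>
    dplyr::mutate(sex_transformed = FALSE, tissue = config$tissue,
                  sample_id = paste(.data$line_id, .data$sex,
                                    .data$replicate, sep = "_")) |>
    dplyr::relocate("sample_id")

  # --- expression ---------------------------------------------------------
  grid <- tidyr::expand_grid(
    gene_id = genes$gene_id,
    sample_id = samples$sample_id
  ) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::left_join(
      dplyr::select(truth, "gene_id", "baseline_log2", "rho",
                    "occupied", "one_dose_inflation"),
      by = "gene_id") |>
    dplyr::left_join(
      tibble::tibble(gene_id = genes$gene_id, arm = genes$arm,
                     is_spike_in = genes$is_spike_in),
      by = "gene_id") |>
    dplyr::left_join(dplyr::mutate(deleted, df_one_dose = TRUE),
                     by = c("gene_id", "line_id")) |>
    dplyr::mutate(df_one_dose = !is.na(.data$df_one_dose))

  male_x <- grid$arm == "X" & grid$sex == "M" & !grid$is_spike_in
  dose_term <- ifelse(grid$df_one_dose, -1 + grid$rho, 0)
  if (config$male_x_compensation) {
    dose_term[male_x] <- dose_term[male_x] + 0 # fully compensated
  } else {
    dose_term[male_x] <- dose_term[male_x] - 1
  }
  kappa <- ifelse(grid$df_one_dose, grid$one_dose_inflation, 1) *
    ifelse(grid$occupied, config$occ_shrink, 1) *
    ifelse(grid$sex == "F", config$female_mult, 1)
  kappa[grid$is_spike_in] <- 0

  # line effect: one draw per (gene, line, sex), shared across replicates
  line_key <- paste(grid$gene_id, grid$line_id, grid$sex, sep = "\r")
  key_idx <- match(line_key, unique(line_key))
  line_draw <- rnorm(max(key_idx))
  eps_line <- line_draw[key_idx] * config$line_sd * kappa
  eps_rep <- rnorm(nrow(grid)) * config$rep_sd * kappa
  eps_tech <- ifelse(grid$is_spike_in, rnorm(nrow(grid)) * config$spike_sd, 0)

  log2f <- grid$baseline_log2 + dose_term + eps_line + eps_rep + eps_tech
  expression <- grid |>
    dplyr::mutate(fpkm = 2^log2f) |>
    dplyr::select("gene_id", "sample_id", "line_id", "sex",
                  "sex_transformed", "tissue", "replicate", "fpkm")

  intergenic <- generate_intergenic(config, seed = mix_seed(config$seed, 77))

  structure(
    list(expression = expression, genes = genes, samples = samples,
         dfs = dfs, peaks = peaks, truth = truth, intergenic = intergenic,
         config = config),
    class = "dosevar_cohort"
  )
}

#' @export
print.dosevar_cohort <- function(x, ...) {
  cat("Synthetic deletion cohort:",
      nrow(x$genes), "genes,",
      nrow(x$dfs), "Df lines,",
      nrow(x$samples), "samples (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Generate intergenic background signals
#'
#' Low, long-tailed background expression drawn from a log-normal
#' distribution with known parameters, so the expression cutoff derived
#' from them ([derive_cutoff()]) can be checked against the analytic
#' quantile `qlnorm(p, meanlog, sdlog)`.
#'
#' @param config a [cohort_config()] (uses `n_intergenic`,
#'   `intergenic_meanlog`, `intergenic_sdlog`).
#' @param seed RNG seed (defaults to the config seed).
#' @param n optional override of the number of draws.
#' @return numeric vector of background signal values.
#' @export
generate_intergenic <- function(config = cohort_config(),
                                seed = config$seed, n = NULL) {
  n <- n %||% config$n_intergenic
  if (n <= 0) abort("n_intergenic must be positive")
  withr_seed(seed)
  rlnorm(n, config$intergenic_meanlog, config$intergenic_sdlog)
}
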