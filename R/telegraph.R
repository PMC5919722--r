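#' Parameters of the two-state (telegraph) transcription model
#'
#' A gene switches spontaneously between a repressed and an active promoter
#' state with activation rate `k_on` and repression rate `k_off`; while
#' active it transcribes mRNA at rate `s_a`, and each mRNA molecule decays
#' at rate `delta_m`. One- and two-dose genes are modelled as one or two
#' independent copies feeding a common mRNA pool. All rates are per second.
#'
#' @param k_on activation rate (/s).
#' @param k_off repression rate (/s).
#' @param s_a transcription rate while active (/s).
#' @param delta_m per-molecule mRNA degradation rate (/s).
#' @param n_copies number of independent gene copies, 1 or 2.
#' @return validated list of class `telegraph_params`.
#' @examples
#' telegraph_params() # the reference one-dose regime
#' @export
telegraph_params <- function(k_on = 0.02, k_off = 0.02, s_a = 0.01,
                             delta_m = 0.008, n_copies = 1) {
  rates <- c(k_on = k_on, k_off = k_off, s_a = s_a, delta_m = delta_m)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort("all telegraph rates must be positive and finite")
  }
  if (!n_copies %in% c(1, 2)) abort("n_copies must be 1 or 2")
  structure(list(k_on = k_on, k_off = k_off, s_a = s_a,
                 delta_m = delta_m, n_copies = as.integer(n_copies)),
            class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat("Telegraph model: k_on=", x$k_on, "/s, k_off=", x$k_off,
      "/s, s_a=", x$s_a, "/s, delta_m=", x$delta_m, "/s, copies=",
      x$n_copies, "\n", sep = "")
  invisible(x)
}

#' Reference parameter regimes for the dose comparison
#'
#' Three parameter sets sharing the switching rates k_on = k_off = 0.02/s
#' (switching half-time 35 s) and degradation rate delta_m = 0.008/s:
#' a one-dose gene without compensation (s_a = 0.01/s), a one-dose gene
#' with twofold per-copy compensation (s_a = 0.02/s), and a two-dose gene
#' (two copies at s_a = 0.01/s), so compensated one-dose and two-dose
#' genes have equal mean expression. `degradation = "half_time_14min"`
#' swaps in delta_m = ln(2)/840 s, the rate implied by a 14-minute mRNA
#' half-life, for sensitivity checks (the two readings of the degradation
#' rate differ; 0.008/s is the rate of record).
#'
#' @param degradation `"rate"` (delta_m = 0.008/s, default) or
#'   `"half_time_14min"`.
#' @return named list of `telegraph_params`: `one_dose`,
#'   `one_dose_compensated`, `two_dose`.
#' @export
telegraph_presets <- function(degradation = c("rate", "half_time_14min")) {
  degradation <- match.arg(degradation)
  dm <- if (degradation == "rate") 0.008 else log(2) / (14 * 60)
  list(
    one_dose = telegraph_params(0.02, 0.02, 0.01, dm, 1),
    one_dose_compensated = telegraph_params(0.02, 0.02, 0.02, dm, 1),
    two_dose = telegraph_params(0.02, 0.02, 0.01, dm, 2)
  )
}

#' Closed-form stationary mean mRNA count
#'
#' At stationarity each copy is active with probability
#' k_on / (k_on + k_off) and contributes s_a / delta_m molecules per unit
#' activity, so the mean is
#' `n_copies * k_on / (k_on + k_off) * s_a / delta_m`. Used as the
#' independent oracle for the stochastic simulation.
#'
#' @param params `telegraph_params`.
#' @return a single numeric value.
#' @export
stationary_mean <- function(params) {
  params$n_copies * params$k_on / (params$k_on + params$k_off) *
    params$s_a / params$delta_m
}

#' Closed-form stationary Fano factor
#'
#' Variance-to-mean ratio of the stationary mRNA count:
#' `1 + s_a * k_off / ((k_on + k_off) * (k_on + k_off + delta_m))`.
#' Promoter switching inflates it above the Poisson value of 1; it is
#' independent of copy number because independent copies add both mean and
#' variance.
#'
#' @param params `telegraph_params`.
#' @return a single numeric value >= 1.
#' @export
fano_factor <- function(params) {
  ks <- params$k_on + params$k_off
  1 + params$s_a * params$k_off / (ks * (ks + params$delta_m))
}

#' Simulate one cell's mRNA trajectory
#'
#' Exact Gillespie simulation of the telegraph model starting from all
#' copies repressed and zero mRNA. Events are promoter activation and
#' repression, single-molecule transcription, and single-molecule decay.
#'
#' @param params `telegraph_params`.
#' @param t_end simulated time in seconds.
#' @param seed optional RNG seed for a reproducible trajectory.
#' @return tibble with one row per event (plus the initial state): `time`
#'   (s, strictly increasing), `mrna` (total count), `n_active` (active
#'   copies).
#' @export
simulate_cell <- function(params, t_end, seed = NULL) {
  stopifnot(inherits(params, "telegraph_params"))
  if (t_end <= 0) abort("t_end must be positive")
  if (!is.null(seed)) withr_seed(seed)
  r <- ssa_telegraph_cpp(params$k_on, params$k_off, params$s_a,
                         params$delta_m, params$n_copies, t_end, 0,
                         TRUE)
  tibble::tibble(time = r$times, mrna = r$counts, n_active = r$active)
}

#' Per-cell mRNA counts for an independent cell population
#'
#' Runs `n_cells` independent single-cell simulations and returns each
#' cell's state. `observe = "point"` reports the count at `t_obs`;
#' `observe = "time_average"` reports each cell's time-averaged count over
#' the window after burn-in, a lower-variance estimate of the same
#' stationary mean.
#'
#' @param params `telegraph_params`.
#' @param n_cells number of cells (>= 1).
#' @param t_obs observation time (s); should exceed the relaxation
#'   burn-in, by default `5 / delta_m`.
#' @param seed RNG seed.
#' @param observe `"point"` or `"time_average"`.
#' @param burn_in start of the averaging window for
#'   `observe = "time_average"` (default `5 / delta_m`).
#' @return numeric vector of length `n_cells`.
#' @export
sample_population <- function(params, n_cells, t_obs = 5 / params$delta_m,
                              seed = NULL,
                              observe = c("point", "time_average"),
                              burn_in = 5 / params$delta_m) {
  stopifnot(inherits(params, "telegraph_params"))
  observe <- match.arg(observe)
  if (n_cells < 1) abort("n_cells must be at least 1")
  if (!is.null(seed)) withr_seed(seed)
  if (observe == "point") {
    as.numeric(ssa_population_cpp(params$k_on, params$k_off, params$s_a,
                                  params$delta_m, params$n_copies,
                                  t_obs, n_cells))
  } else {
    if (t_obs <= burn_in) abort("time averaging needs t_obs > burn_in")
    as.numeric(ssa_population_timeavg_cpp(params$k_on, params$k_off,
                                          params$s_a, params$delta_m,
                                          params$n_copies, t_obs, burn_in,
                                          n_cells))
  }
}

#' Population-mean mRNA count at the observation time
#'
#' Average over `n_cells` independent cells, emulating an RNA-Seq-style
#' measurement of a cell population: intrinsic single-cell fluctuations
#' average out as the population grows.
#'
#' @inheritParams sample_population
#' @return a single numeric value.
#' @export
population_mean <- function(params, n_cells, t_obs = 5 / params$delta_m,
                            seed = NULL,
                            observe = c("point", "time_average")) {
  mean(sample_population(params, n_cells, t_obs, seed,
                         observe = match.arg(observe)))
}

# deterministic sub-seed derivation (counter-based; keeps values < 2^31)
mix_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i)) %% 2147483629)
}

#' Delta between two independent population measurements
#'
#' Two replicate measurements of the same population size are simulated
#' independently (fresh derived sub-seeds) and their mean counts compared
#' with the replicate-variability statistic [delta()]. As the population
#' grows, intrinsic noise averages out and delta shrinks toward zero.
#'
#' @inheritParams sample_population
#' @param seed seed from which the two replicate sub-seeds are derived.
#' @return a single numeric delta value.
#' @export
population_delta <- function(params, n_cells, t_obs = 5 / params$delta_m,
                             seed = 1,
                             observe = c("point", "time_average")) {
  observe <- match.arg(observe)
  # delta is undefined when both replicate means are zero, which happens
  # regularly for single cells at low expression; redraw with fresh
  # sub-seeds (bounded) before giving up
  for (try in seq_len(100)) {
    m1 <- population_mean(params, n_cells, t_obs,
                          mix_seed(seed, 2 * try - 1), observe)
    m2 <- population_mean(params, n_cells, t_obs,
                          mix_seed(seed, 2 * try), observe)
    if (m1 + m2 > 0) return(delta(m1, m2))
  }
  abort("both population means are zero; delta undefined")
}

#' Mean delta as a function of cell population size
#'
#' For each population size, repeats the two-replicate delta measurement
#' and reports the mean and standard deviation of delta. Averaging over N
#' independent cells shrinks intrinsic fluctuations by the central limit
#' theorem, so mean delta falls off as N^(-1/2).
#'
#' @param params `telegraph_params`.
#' @param sizes strictly increasing integer vector of population sizes.
#' @param repeats number of repeated delta measurements per size (>= 2).
#' @param t_obs observation time (s).
#' @param seed base seed; every (size, repeat) gets a derived sub-seed.
#' @param observe `"point"` or `"time_average"`.
#' @return tibble of class `dosevar_delta_curve`: `size`, `mean_delta`,
#'   `sd_delta`, `repeats`, `seed`.
#' @export
delta_vs_popsize <- function(params, sizes = c(1, 10, 100, 1000),
                             repeats = 25, t_obs = 5 / params$delta_m,
                             seed = 1,
                             observe = c("point", "time_average")) {
  observe <- match.arg(observe)
  if (repeats < 2) abort("repeats must be at least 2")
  if (is.unsorted(sizes, strictly = TRUE)) {
    abort("sizes must be strictly increasing")
  }
  rows <- purrr::map_dfr(seq_along(sizes), function(i) {
    ds <- vapply(seq_len(repeats), function(j) {
      population_delta(params, sizes[i], t_obs,
                       seed = mix_seed(mix_seed(seed, i), j),
                       observe = observe)
    }, numeric(1))
    tibble::tibble(size = sizes[i], mean_delta = mean(ds),
                   sd_delta = sd(ds), repeats = repeats, seed = seed)
  })
  class(rows) <- c("dosevar_delta_curve", class(rows))
  rows
}

#' Log-log scaling slope of a delta-vs-population-size curve
#'
#' Ordinary least-squares slope of log10(mean delta) on log10(size);
#' intrinsic-noise averaging predicts -1/2.
#'
#' @param curve tibble from [delta_vs_popsize()].
#' @return a single numeric slope.
#' @export
delta_curve_slope <- function(curve) {
  unname(stats::coef(stats::lm(log10(mean_delta) ~ log10(size),
                               data = curve))[2])
}
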