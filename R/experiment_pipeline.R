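#' Configuration of a regime-by-mean-by-contrast sweep
#'
#' The full profile covers mean excitatory conductances 0-100 uS/cm^2 and
#' contrasts 0.05-0.5 with 60 trials of 1 s per block, matching the study
#' conditions; the scaled profile (3 x 3 grid, 20 trials of 0.5 s) is a
#' fast variant for continuous testing.
#'
#' @param mu_e Grid of mean excitatory conductances, uS/cm^2.
#' @param contrast Grid of conductance contrasts.
#' @param inhibition_ratios Inhibition ratios defining the regimes
#'   (0 = excitation only, 1 = balanced conductance, 5 = balanced current).
#' @param trials Trials per frozen and per unfrozen block (>= 2).
#' @param duration Trial duration, ms.
#' @param dt Integration step, ms.
#' @param dt_bin Letter resolution for entropy estimation, ms.
#' @param K_schedule Word lengths for the direct method.
#' @param master_seed Master seed; all per-trial seeds derive from it.
#' @param profile `"full"` or `"scaled"`; presets overriding the grid,
#'   trial count and duration unless given explicitly.
#' @param params A [membrane_params()] object.
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(mu_e = NULL, contrast = NULL,
                         inhibition_ratios = c(0, 1, 5),
                         trials = NULL, duration = NULL, dt = 0.01,
                         dt_bin = 1,
                         K_schedule = c(2, 4, 6, 8, 12, 16, 24, 32, 48, 64),
                         master_seed = 1,
                         profile = c("full", "scaled"),
                         params = membrane_params()) {
  profile <- match.arg(profile)
  if (is.null(mu_e))
    mu_e <- if (profile == "full") c(0, 10, 20, 40, 60, 80, 100)
            else c(20, 60, 100)
  if (is.null(contrast))
    contrast <- if (profile == "full") c(0.05, 0.1, 0.25, 0.4, 0.5)
                else c(0.1, 0.25, 0.5)
  if (is.null(trials)) trials <- if (profile == "full") 60 else 20
  if (is.null(duration)) duration <- if (profile == "full") 1000 else 500
  if (length(mu_e) < 1 || length(contrast) < 1) stop("empty grid")
  if (trials < 2) stop("need >= 2 trials for noise entropy")
  structure(list(mu_e = mu_e, contrast = contrast,
                 inhibition_ratios = inhibition_ratios,
                 trials = trials, duration = duration, dt = dt,
                 dt_bin = dt_bin, K_schedule = K_schedule,
                 master_seed = as.integer(master_seed),
                 profile = profile, params = params),
            class = "sweep_config")
}

#' Stable seed derivation
#'
#' Deterministically mixes the master seed with a sequence of integer or
#' numeric labels (regime, mean, contrast, block, trial, ...) into a
#' 31-bit seed, so every trial has its own reproducible random stream and
#' grid points can be computed in any order.
#'
#' @param master_seed Integer master seed.
#' @param ... Numeric labels; non-integers are scaled by 1000 and rounded.
#' @return Integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, ...) {
  labels <- vapply(list(...), function(x) round(as.numeric(x) * 1000),
                   numeric(1))
  h <- as.numeric(master_seed) %% 2147483647
  for (k in c(labels, 0)) {
    # 69069 * 2^31 < 2^53: exact in double arithmetic
    h <- (h * 69069 + (k %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# Simulate one block of trials; returns spike trains and per-trial
# current integrals.
.run_block <- function(config, regime, frozen, block_id) {
  r <- regime$inhibition_ratio
  mu <- regime$excitatory$mean
  ct <- if (mu > 0) regime$excitatory$sd / mu else 0
  trains <- vector("list", config$trials)
  integ <- vector("list", config$trials)
  frozen_stim_seed <- derive_seed(config$master_seed, r, mu, ct, block_id, 0)
  for (j in seq_len(config$trials)) {
    stim_seed <- if (frozen) frozen_stim_seed
                 else derive_seed(config$master_seed, r, mu, ct, block_id, j)
    chan_seed <- derive_seed(config$master_seed, r, mu, ct, block_id + 100, j)
    tr <- integrate_compartment(config$params, regime,
                                duration = config$duration, dt = config$dt,
                                stimulus_seed = stim_seed,
                                channel_seed = chan_seed,
                                record_trace = FALSE)
    trains[[j]] <- tr$spike_times
    integ[[j]] <- tr
  }
  list(trains = trains, traces = integ)
}

#' Run all metrics at one grid point
#'
#' Simulates one unfrozen block (a fresh stimulus waveform per trial) and
#' one frozen block (one waveform, varying channel noise) of
#' `config$trials` trials each, then computes: mean firing rate and ISI CV
#' (unfrozen block), total and noise entropy rates, mutual information,
#' bits/spike, ATP consumption with its component partition (unfrozen
#' block), bits/ATP, and the mean net synaptic current.  Fully
#' deterministic given the config's master seed.
#'
#' @param config A [sweep_config()].
#' @param inhibition_ratio Regime inhibition ratio.
#' @param mu_e Mean excitatory conductance, uS/cm^2.
#' @param contrast Conductance contrast.
#' @return Object of class `grid_point_metrics` (a one-row data.frame with
#'   the full breakdown in attribute `detail`).
#' @export
run_grid_point <- function(config, inhibition_ratio, mu_e, contrast) {
  stopifnot(inherits(config, "sweep_config"))
  regime <- build_regime(mu_e, contrast, inhibition_ratio,
                         e_e = config$params$e_e, e_i = config$params$e_i)
  unfrozen <- .run_block(config, regime, frozen = FALSE, block_id = 1)
  frozen <- .run_block(config, regime, frozen = TRUE, block_id = 2)

  rate <- firing_rate(unfrozen$trains, config$duration)
  cv <- isi_cv(unfrozen$trains)
  info <- estimate_information(unfrozen$trains, frozen$trains,
                               config$duration, config$dt_bin,
                               config$K_schedule)
  energy <- energy_breakdown(unfrozen$traces)
  eff <- efficiency_metrics(info$mi_rate, rate, energy$atp_per_second)
  net_i <- net_current(unfrozen$traces)

  row <- data.frame(
    regime = regime$regime_label,
    inhibition_ratio = inhibition_ratio,
    mu_e = mu_e, contrast = contrast,
    rate = rate, cv = cv,
    H_total = info$total$rate, H_noise = info$noise$rate,
    mi_rate = info$mi_rate,
    bits_per_spike = eff$bits_per_spike,
    atp_per_second = energy$atp_per_second,
    bits_per_atp = eff$bits_per_atp,
    frac_ap = unname(energy$fractions["action_potential"]),
    frac_synaptic = unname(energy$fractions["synaptic"]),
    frac_leak = unname(energy$fractions["leak"]),
    net_current = net_i)
  attr(row, "detail") <- list(info = info, energy = energy)
  class(row) <- c("grid_point_metrics", class(row))
  row
}

#' Mean net synaptic current of a trial set
#'
#' Time- and trial-averaged sum of the excitatory and inhibitory synaptic
#' current densities (inward negative).  Approximately zero in the
#' balanced-current regime; increasingly inward with growing mean
#' excitation otherwise.
#'
#' @param traces List of `compartment_trace` objects.
#' @return Mean net synaptic current density, uA/cm^2.
#' @export
net_current <- function(traces) {
  if (inherits(traces, "compartment_trace")) traces <- list(traces)
  mean(vapply(traces, function(tr)
    (tr$integrals$i_exc + tr$integrals$i_inh) / tr$duration, numeric(1)))
}

#' Run the full regime x mean x contrast sweep
#'
#' @param config A [sweep_config()].
#' @param verbose Print progress lines.
#' @return Data frame with one [run_grid_point()] row per (regime, mu_e,
#'   contrast) combination.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  grid <- expand.grid(inhibition_ratio = config$inhibition_ratios,
                      mu_e = config$mu_e, contrast = config$contrast,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    if (verbose)
      message(sprintf("ratio %g, mu_e %g, contrast %g",
                      g$inhibition_ratio, g$mu_e, g$contrast))
    r <- run_grid_point(config, g$inhibition_ratio, g$mu_e, g$contrast)
    attr(r, "detail") <- NULL
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare synaptic regimes across the grid
#'
#' For each non-reference regime, matches grid points (mu_e, contrast)
#' against the reference regime (default excitation only) and reports
#' per-point ratios of rate, mutual information, bits/spike, ATP/s and
#' bits/ATP, plus the entropy fold-reductions reference/other for total
#' and noise entropy with their grid mean and median.
#'
#' @param metrics Data frame from [run_sweep()].
#' @param reference_ratio Inhibition ratio of the reference regime.
#' @return List keyed by regime with a `points` data.frame and `summary`
#'   (mean/median fold-changes).
#' @export
compare_regimes <- function(metrics, reference_ratio = 0) {
  ref <- metrics[metrics$inhibition_ratio == reference_ratio, ]
  if (nrow(ref) == 0) stop("reference regime absent from metrics")
  others <- setdiff(unique(metrics$inhibition_ratio), reference_ratio)
  out <- list()
  for (r in others) {
    m <- metrics[metrics$inhibition_ratio == r, ]
    key <- paste(m$mu_e, m$contrast)
    ref_m <- ref[match(key, paste(ref$mu_e, ref$contrast)), ]
    pts <- data.frame(
      mu_e = m$mu_e, contrast = m$contrast,
      rate_ratio = m$rate / ref_m$rate,
      mi_ratio = m$mi_rate / ref_m$mi_rate,
      bits_per_spike_ratio = m$bits_per_spike / ref_m$bits_per_spike,
      atp_ratio = m$atp_per_second / ref_m$atp_per_second,
      bits_per_atp_ratio = m$bits_per_atp / ref_m$bits_per_atp,
      total_entropy_fold = ref_m$H_total / m$H_total,
      noise_entropy_fold = ref_m$H_noise / m$H_noise)
    fin <- function(x) x[is.finite(x)]
    out[[sprintf("ratio_%g", r)]] <- list(
      inhibition_ratio = r,
      points = pts,
      summary = list(
        mean_total_entropy_fold = mean(fin(pts$total_entropy_fold)),
        mean_noise_entropy_fold = mean(fin(pts$noise_entropy_fold)),
        median_total_entropy_fold = median(fin(pts$total_entropy_fold)),
        median_noise_entropy_fold = median(fin(pts$noise_entropy_fold)),
        median_entropy_fold = median(fin(c(pts$total_entropy_fold,
                                           pts$noise_entropy_fold))),
        median_rate_ratio = median(fin(pts$rate_ratio)),
        median_mi_ratio = median(fin(pts$mi_ratio))))
  }
  out
}

#' Write / read a sweep configuration as YAML
#'
#' Keys: mu_e, contrast, inhibition_ratios, trials, duration_ms, dt_ms,
#' dt_bin_ms, word_lengths, master_seed, profile, and the membrane
#' parameter overrides under `membrane:`.
#'
#' @param config A [sweep_config()].
#' @param path File path.
#' @return `write_sweep_config` returns `path` invisibly;
#'   `read_sweep_config` returns a `sweep_config`.
#' @export
write_sweep_config <- function(config, path) {
  x <- list(mu_e = config$mu_e, contrast = config$contrast,
            inhibition_ratios = config$inhibition_ratios,
            trials = config$trials, duration_ms = config$duration,
            dt_ms = config$dt, dt_bin_ms = config$dt_bin,
            word_lengths = config$K_schedule,
            master_seed = config$master_seed, profile = config$profile,
            membrane = unclass(config$params))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sweep_config
#' @export
read_sweep_config <- function(path) {
  x <- yaml::read_yaml(path)
  params <- if (is.null(x$membrane)) membrane_params()
  else do.call(membrane_params,
               x$membrane[intersect(names(x$membrane),
                                    names(formals(membrane_params)))])
  sweep_config(mu_e = x$mu_e, contrast = x$contrast,
               inhibition_ratios = x$inhibition_ratios,
               trials = x$trials, duration = x$duration_ms, dt = x$dt_ms,
               dt_bin = x$dt_bin_ms, K_schedule = x$word_lengths,
               master_seed = x$master_seed,
               profile = if (is.null(x$profile)) "full" else x$profile,
               params = params)
}
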