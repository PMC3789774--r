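#' Membrane and channel parameters
#'
#' Parameter set for the 100 um^2 single compartment: capacitance, maximal
#' conductance densities and reversal potentials of the transient Na+,
#' delayed-rectifier K+ and (non-probabilistic) leak conductances, plus the
#' single-channel conductance and channel densities that define the finite
#' channel populations used by the Markov scheme.  Defaults are the
#' canonical squid-axon constants with a 20 pS unitary conductance; the
#' densities (60 Na+/um^2, 18 K+/um^2) are chosen so that
#' `gamma * density` reproduces the macroscopic maximal conductances
#' (120 and 36 mS/cm^2).
#'
#' @param area_um2 Compartment area, um^2. Default 100.
#' @param c_m Specific capacitance, uF/cm^2.
#' @param gbar_na,gbar_k,g_leak Maximal conductance densities, mS/cm^2.
#' @param e_na,e_k,e_leak Reversal potentials, mV.
#' @param e_e,e_i Synaptic reversal potentials, mV.
#' @param gamma_ps Single-channel conductance, pS.
#' @param na_density,k_density Channel densities, channels/um^2.
#' @param threshold Spike detection threshold, mV.
#' @param refractory Spike detection lockout, ms.
#' @return An object of class `membrane_params`; fields `n_na`, `n_k` hold
#'   the integer channel counts `round(density * area)`.
#' @examples
#' p <- membrane_params()
#' c(p$n_na, p$n_k)       # 6000 Na+ and 1800 K+ channels at 100 um^2
#' @export
membrane_params <- function(area_um2 = 100, c_m = 1,
                            gbar_na = 120, gbar_k = 36, g_leak = 0.3,
                            e_na = 50, e_k = -77, e_leak = -54.4,
                            e_e = 0, e_i = -75,
                            gamma_ps = 20,
                            na_density = 60, k_density = 18,
                            threshold = 0, refractory = 2) {
  n_na <- as.integer(round(na_density * area_um2))
  n_k <- as.integer(round(k_density * area_um2))
  if (n_na <= 0L || n_k <= 0L) stop("channel counts must be positive")
  structure(list(area_um2 = area_um2, c_m = c_m,
                 gbar_na = gbar_na, gbar_k = gbar_k, g_leak = g_leak,
                 e_na = e_na, e_k = e_k, e_leak = e_leak,
                 e_e = e_e, e_i = e_i,
                 gamma_ps = gamma_ps,
                 na_density = na_density, k_density = k_density,
                 n_na = n_na, n_k = n_k,
                 threshold = threshold, refractory = refractory),
            class = "membrane_params")
}

#' Hodgkin-Huxley voltage-dependent rate functions
#'
#' The six first-order gating rates (1/ms) of the squid-axon model in the
#' modern voltage convention (rest near -65 mV).  The removable
#' singularities of alpha_m (at -40 mV) and alpha_n (at -55 mV) are handled
#' by their analytic limits.
#'
#' @param v Membrane potential, mV (vectorized).
#' @return Data frame with columns `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`.
#' @export
hh_rate_functions <- function(v) {
  phi <- function(x) ifelse(abs(x) < 1e-6, 1 + x / 2, x / (1 - exp(-x)))
  data.frame(
    alpha_m = phi((v + 40) / 10),
    beta_m = 4 * exp(-(v + 65) / 18),
    alpha_h = 0.07 * exp(-(v + 65) / 20),
    beta_h = 1 / (1 + exp(-(v + 35) / 10)),
    alpha_n = 0.1 * phi((v + 55) / 10),
    beta_n = 0.125 * exp(-(v + 65) / 80))
}

#' Steady-state gating values
#'
#' @param v Membrane potential, mV (vectorized).
#' @return Data frame with `m_inf`, `h_inf`, `n_inf` and the corresponding
#'   time constants `tau_m`, `tau_h`, `tau_n` (ms).
#' @export
hh_steady_state <- function(v) {
  r <- hh_rate_functions(v)
  data.frame(
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
    tau_m = 1 / (r$alpha_m + r$beta_m),
    tau_h = 1 / (r$alpha_h + r$beta_h),
    tau_n = 1 / (r$alpha_n + r$beta_n))
}

#' Deterministic resting potential
#'
#' Solves for the voltage at which the total steady-state membrane current
#' (Na+, K+ and leak at their equilibrium gating values, no stimulus)
#' vanishes.
#'
#' @param params A [membrane_params()] object.
#' @return Resting potential, mV.
#' @export
resting_potential <- function(params = membrane_params()) {
  f <- function(v) {
    s <- hh_steady_state(v)
    params$gbar_na * s$m_inf^3 * s$h_inf * (v - params$e_na) +
      params$gbar_k * s$n_inf^4 * (v - params$e_k) +
      params$g_leak * (v - params$e_leak)
  }
  uniroot(f, c(-90, -45), tol = 1e-10)$root
}

#' One Markov step of the stochastic channel populations
#'
#' Advances the 8-state Na+ occupancy vector (states h*4 + m for m gates
#' open = 0..3 and h = 0 inactivated / 1 available; conducting state is
#' m3h1) and the 5-state K+ occupancy vector (open n-gates 0..4; conducting
#' state n4) by one step of length `dt` at voltage `v`.  For each occupied
#' state the numbers of channels leaving through each transition are drawn
#' multinomially with probabilities rate*dt; totals are conserved.  Errors
#' if any per-state total transition probability reaches 1 (reduce dt).
#'
#' @param na_counts Integer vector of length 8 (Na+ state occupancies).
#' @param k_counts Integer vector of length 5 (K+ state occupancies).
#' @param v Membrane potential, mV.
#' @param dt Step size, ms.
#' @return List with updated `na` and `k` occupancy vectors.
#' @export
markov_channel_step <- function(na_counts, k_counts, v, dt) {
  .markov_step_cpp(as.integer(na_counts), as.integer(k_counts), v, dt)
}

#' Sample channel-state occupancies from the steady state at a voltage
#'
#' @param v Membrane potential, mV.
#' @param params A [membrane_params()] object.
#' @return List with integer occupancy vectors `na` (8) and `k` (5).
#' @export
sample_channel_states <- function(v, params = membrane_params()) {
  .init_counts_cpp(v, params$n_na, params$n_k)
}

#' Integrate the stochastic compartment for one trial
#'
#' Forward-Euler integration (default 10 us step) of the current-balance
#' equation
#' \deqn{C \dot V = -[g_{Na}(V-E_{Na}) + g_K(V-E_K) + g_L(V-E_L)
#'       + g_e(V-E_e) + g_i(V-E_i)],}
#' with `g_Na = gamma N_open_Na / area` and `g_K = gamma N_open_K / area`
#' given by the Markov channel populations (or by deterministic gating in
#' the infinite-channel limit when `deterministic = TRUE`).  The synaptic
#' conductances are OU traces generated under `stimulus_seed`; channel
#' randomness is governed by `channel_seed`, so two runs sharing
#' `stimulus_seed` see the identical conductance waveform (frozen noise)
#' while their spike trains differ through channel noise.  The voltage is
#' initialized at the deterministic resting potential with channel states
#' sampled multinomially from the steady-state occupancies there.
#'
#' @param params A [membrane_params()] object.
#' @param stimulus A [build_regime()] stimulus, or `NULL` for no synaptic
#'   input.
#' @param duration Trial duration, ms. Default 1000.
#' @param dt Step size, ms. Default 0.01 (10 us).
#' @param stimulus_seed,channel_seed Integer seeds for the stimulus and
#'   channel random streams.
#' @param deterministic Use deterministic (expected open fraction) gating.
#' @param record_trace Keep the full voltage/current time series (about
#'   0.8 MB per recorded series per simulated second); spike times and
#'   current integrals are always returned.
#' @param clip_negative Floor synaptic conductances at 0 inside the
#'   membrane equation (default TRUE; negative conductances are
#'   unphysical).
#' @param g_e,g_i Optional precomputed conductance traces (uS/cm^2,
#'   sampled at `dt`), overriding generation from `stimulus`.
#' @return An object of class `compartment_trace`: spike times (ms),
#'   per-source current integrals (uA*ms/cm^2), trial duration, parameters,
#'   and when recorded the time grid plus voltage, per-source current and
#'   open-fraction series.
#' @examples
#' \donttest{
#' tr <- integrate_compartment(membrane_params(),
#'                             build_regime(60, 0.25, 0),
#'                             duration = 200, stimulus_seed = 1,
#'                             channel_seed = 2)
#' length(tr$spike_times)
#' }
#' @export
integrate_compartment <- function(params = membrane_params(),
                                  stimulus = NULL,
                                  duration = 1000, dt = 0.01,
                                  stimulus_seed = NULL, channel_seed = NULL,
                                  deterministic = FALSE,
                                  record_trace = TRUE,
                                  clip_negative = TRUE,
                                  g_e = NULL, g_i = NULL) {
  stopifnot(inherits(params, "membrane_params"))
  if (duration < dt) stop("duration must be >= dt")
  n <- round(duration / dt)

  if (is.null(g_e)) {
    if (!is.null(stimulus)) {
      stopifnot(inherits(stimulus, "regime_stimulus"))
      if (!is.null(stimulus_seed)) set.seed(stimulus_seed)
      g_e <- ou_trace(stimulus$excitatory, duration, dt)
      g_i <- if (!is.null(stimulus$inhibitory))
        ou_trace(stimulus$inhibitory, duration, dt)
    } else {
      g_e <- numeric(n)
    }
  }
  if (length(g_e) != n)
    stop("g_e length does not match duration/dt")
  if (is.null(g_i)) g_i <- numeric(0)

  v0 <- resting_potential(params)
  if (!is.null(channel_seed)) set.seed(channel_seed)
  res <- .sim_compartment_cpp(as.numeric(g_e), as.numeric(g_i), dt,
                              unclass(params), v0, deterministic,
                              record_trace, clip_negative,
                              params$threshold, params$refractory)
  out <- list(spike_times = res$spike_times,
              duration = res$duration,
              dt = dt,
              v_init = v0,
              v_final = res$v_final,
              integrals = res$integrals,
              params = params,
              stimulus = stimulus,
              deterministic = deterministic)
  if (record_trace) {
    out$time <- (seq_len(n) - 1) * dt
    out$voltage <- res$voltage
    out$i_na <- res$i_na
    out$i_k <- res$i_k
    out$i_leak <- res$i_leak
    out$i_exc <- res$i_exc
    out$i_inh <- res$i_inh
    out$p_open_na <- res$p_open_na
    out$p_open_k <- res$p_open_k
    out$g_e <- as.numeric(g_e)
    if (length(g_i)) out$g_i <- as.numeric(g_i)
  }
  class(out) <- "compartment_trace"
  out
}

#' @export
print.compartment_trace <- function(x, ...) {
  cat(sprintf(
    "Compartment trace: %.3g ms at dt = %g ms, %d spikes (%.3g spikes/s)%s\n",
    x$duration, x$dt, length(x$spike_times),
    1000 * length(x$spike_times) / x$duration,
    if (x$deterministic) " [deterministic gating]" else ""))
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a fixed threshold with a refractory lockout; spike
#' times are reported at the first sample at or above threshold.
#'
#' @param voltage Voltage samples, mV.
#' @param dt Sample interval, ms.
#' @param threshold Threshold, mV. Default 0 (unambiguous for full-height
#'   action potentials; insensitive to moderate changes).
#' @param refractory Lockout after each detected spike, ms. Default 2.
#' @return Numeric vector of spike times (ms).
#' @examples
#' v <- rep(-65, 1000); v[200:210] <- 30; v[600:610] <- 30
#' detect_spikes(v, dt = 0.1)
#' @export
detect_spikes <- function(voltage, dt, threshold = 0, refractory = 2) {
  above <- voltage >= threshold
  cross <- which(above[-1L] & !above[-length(above)]) # index before crossing
  times <- cross * dt                                  # first sample >= thr
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}
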