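#' Ornstein-Uhlenbeck synaptic conductance specification
#'
#' Describes one synaptic conductance stream in the diffusion approximation:
#' the summed effect of many weak, independently activated synapses is a
#' Gaussian (Ornstein-Uhlenbeck) conductance process with mean `mean`,
#' stationary standard deviation `sd`, correlation time `tau` and reversal
#' potential `e_rev`.
#'
#' @param mean Mean conductance density (uS/cm^2), >= 0.
#' @param sd Stationary standard deviation (uS/cm^2), >= 0.
#' @param tau Correlation (synaptic decay) time constant, ms. Default 3.3 ms.
#' @param e_rev Reversal potential, mV (0 for excitation, -75 for
#'   inhibition).
#' @return An object of class `ou_spec`.
#' @examples
#' ou_spec(mean = 20, sd = 10)          # contrast 0.5 excitatory stream
#' ou_spec(20, 2, e_rev = -75)          # inhibitory stream
#' @export
ou_spec <- function(mean, sd, tau = 3.3, e_rev = 0) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd),
            is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (mean < 0) stop("mean conductance must be >= 0")
  if (sd < 0) stop("sd must be >= 0")
  if (tau <= 0) stop("time constant must be > 0")
  structure(list(mean = mean, sd = sd, tau = tau, e_rev = e_rev),
            class = "ou_spec")
}

#' @export
print.ou_spec <- function(x, ...) {
  cat(sprintf(
    "OU conductance: mean %.4g uS/cm^2, sd %.4g uS/cm^2 (contrast %s), tau %.3g ms, E_rev %.4g mV\n",
    x$mean, x$sd, if (x$mean > 0) sprintf("%.3g", x$sd / x$mean) else "undefined",
    x$tau, x$e_rev))
  invisible(x)
}

#' Contrast of an OU conductance stream
#'
#' Contrast is sd/mean of the stationary conductance distribution; it is
#' undefined (NA) for a zero-mean stream.
#'
#' @param spec An [ou_spec()].
#' @return Dimensionless contrast, or `NA` when the mean is 0.
#' @export
ou_contrast <- function(spec) {
  if (spec$mean > 0) spec$sd / spec$mean else NA_real_
}

#' Map microscopic synaptic parameters to OU moments
#'
#' In the diffusion approximation, a population of synapses activated at
#' total Poisson rate `rate_hz` with unitary event amplitude `amplitude`
#' and exponential decay `tau_ms` produces an OU conductance with mean
#' \eqn{\mu = R A \tau}, standard deviation \eqn{\sigma = A \sqrt{R \tau / 2}}
#' and contrast \eqn{\sigma/\mu = 1/\sqrt{2 R \tau}} (with \eqn{\tau} in
#' seconds).  The contrast therefore depends only on the event rate and the
#' decay time constant, not on the unitary amplitude: raising contrast at
#' fixed tau means lowering the afferent event rate.
#'
#' @param rate_hz Total synaptic event rate R, Hz (> 0).
#' @param amplitude Unitary event amplitude A, uS/cm^2 (> 0).
#' @param tau_ms Decay time constant, ms (> 0). Default 3.3.
#' @return List with `mean`, `sd` (uS/cm^2) and `contrast`.
#' @examples
#' micro_to_ou(rate_hz = 1000, amplitude = 0.01, tau_ms = 3.3)
#' @export
micro_to_ou <- function(rate_hz, amplitude, tau_ms = 3.3) {
  if (rate_hz <= 0 || amplitude <= 0 || tau_ms <= 0)
    stop("rate, amplitude and time constant must all be positive")
  tau_s <- tau_ms / 1000
  list(mean = rate_hz * amplitude * tau_s,
       sd = amplitude * sqrt(rate_hz * tau_s / 2),
       contrast = 1 / sqrt(2 * rate_hz * tau_s))
}

#' Exact one-step update of an OU conductance
#'
#' The OU process has a Gaussian transition density, so it can be advanced
#' by the exact difference equation
#' \deqn{g' = \mu + (g - \mu) e^{-\Delta/\tau} +
#'       \sigma \sqrt{1 - e^{-2\Delta/\tau}}\, z,}
#' which is valid for any step size: the stationary moments do not depend
#' on `dt`.
#'
#' @param g_now Current conductance value (uS/cm^2).
#' @param spec An [ou_spec()].
#' @param dt Step size, ms (> 0).
#' @param z Standard-normal draw(s); vectorized over `g_now`/`z`.
#' @return Updated conductance value(s).
#' @export
ou_step <- function(g_now, spec, dt, z) {
  stopifnot(inherits(spec, "ou_spec"))
  if (any(dt <= 0)) stop("dt must be > 0")
  rho <- exp(-dt / spec$tau)
  spec$mean + (g_now - spec$mean) * rho + spec$sd * sqrt(1 - rho^2) * z
}

#' Generate an OU conductance trace
#'
#' Samples `round(duration/dt)` points of the OU process on a regular grid
#' using the exact update.  The initial value is drawn from the stationary
#' Gaussian (mean, sd), so the trace is stationary from the first sample
#' and no burn-in is needed.
#'
#' Negative excursions (possible when contrast is high) are kept by default
#' so that the raw trace has the exact stationary Gaussian moments; the
#' membrane integrator clips conductances at zero at the point of use.  Set
#' `clip_negative = TRUE` to floor the returned trace itself at 0.
#'
#' @param spec An [ou_spec()].
#' @param duration Trace duration, ms (>= dt).
#' @param dt Sample step, ms. Default 0.01 (10 us).
#' @param seed Optional integer seed; when supplied the trace is a pure
#'   function of (spec, duration, dt, seed).  When `NULL` the current RNG
#'   state is used.
#' @param clip_negative Floor the returned samples at 0.
#' @return Numeric vector of conductances (uS/cm^2) with attributes `dt`
#'   and `spec`.
#' @examples
#' g <- ou_trace(ou_spec(20, 2), duration = 100, dt = 0.01, seed = 1)
#' c(mean(g), sd(g))
#' @export
ou_trace <- function(spec, duration, dt = 0.01, seed = NULL,
                     clip_negative = FALSE) {
  stopifnot(inherits(spec, "ou_spec"))
  if (duration < dt) stop("duration must be >= dt")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  if (spec$sd == 0) {
    g <- rep(spec$mean, n)
  } else {
    rho <- exp(-dt / spec$tau)
    z <- rnorm(n)
    x0 <- spec$sd * z[1L]
    if (n > 1L) {
      w <- spec$sd * sqrt(1 - rho^2) * z[-1L]
      x <- stats::filter(w, rho, method = "recursive", init = x0)
      g <- spec$mean + c(x0, as.numeric(x))
    } else {
      g <- spec$mean + x0
    }
  }
  if (clip_negative) g <- pmax(g, 0)
  attr(g, "dt") <- dt
  attr(g, "spec") <- spec
  g
}

#' Build a synaptic input regime from (mean, contrast) coordinates
#'
#' The three canonical regimes are parameterized by the inhibition ratio
#' r = mu_i / mu_e: `r = 0` is excitation only, `r = 1` balanced
#' conductance (identical excitatory and inhibitory mean and sd), and
#' `r = 5` balanced current (inhibition five-fold stronger, so inward and
#' outward synaptic currents approximately cancel near -64 mV given the
#' reversal potentials 0 and -75 mV).  Excitatory and inhibitory streams
#' always share the same contrast, so sd_i = r * contrast * mu_e.
#' Intermediate ratios are allowed for inhibition sweeps.
#'
#' @param mu_e Mean excitatory conductance density, uS/cm^2 (>= 0).
#' @param contrast Dimensionless sd/mean of both streams (>= 0).
#' @param inhibition_ratio mu_i / mu_e (>= 0).
#' @param tau Synaptic time constant for both streams, ms. Default 3.3.
#' @param e_e,e_i Excitatory / inhibitory reversal potentials, mV.
#' @return An object of class `regime_stimulus` with fields `regime_label`,
#'   `inhibition_ratio`, `excitatory` (an `ou_spec`) and `inhibitory`
#'   (an `ou_spec` or `NULL` when the ratio is 0).
#' @examples
#' build_regime(mu_e = 20, contrast = 0.1, inhibition_ratio = 5)
#' @export
build_regime <- function(mu_e, contrast, inhibition_ratio, tau = 3.3,
                         e_e = 0, e_i = -75) {
  if (mu_e < 0) stop("mu_e must be >= 0")
  if (contrast < 0) stop("contrast must be >= 0")
  if (inhibition_ratio < 0) stop("inhibition_ratio must be >= 0")
  label <- if (inhibition_ratio == 0) "excitation_only"
  else if (inhibition_ratio == 1) "balanced_conductance"
  else if (inhibition_ratio == 5) "balanced_current"
  else "intermediate"
  exc <- ou_spec(mu_e, contrast * mu_e, tau = tau, e_rev = e_e)
  inh <- if (inhibition_ratio > 0)
    ou_spec(inhibition_ratio * mu_e, inhibition_ratio * contrast * mu_e,
            tau = tau, e_rev = e_i)
  structure(list(regime_label = label,
                 inhibition_ratio = inhibition_ratio,
                 excitatory = exc,
                 inhibitory = inh),
            class = "regime_stimulus")
}

#' @export
print.regime_stimulus <- function(x, ...) {
  cat(sprintf("Synaptic regime '%s' (inhibition ratio %g)\n",
              x$regime_label, x$inhibition_ratio))
  cat("  excitatory: "); print(x$excitatory)
  if (!is.null(x$inhibitory)) {
    cat("  inhibitory: "); print(x$inhibitory)
  }
  invisible(x)
}

#' Write / read a conductance trace as columnar text
#'
#' Plain TSV with a `#`-prefixed header recording the generating
#' specification, so a trace file is self-describing.
#'
#' @param g_e Excitatory trace from [ou_trace()].
#' @param path Output file path.
#' @param g_i Optional inhibitory trace on the same grid.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   data.frame with columns `time_ms`, `g_e` and optionally `g_i`, with the
#'   header lines in attribute `header`.
#' @export
write_trace <- function(g_e, path, g_i = NULL) {
  dt <- attr(g_e, "dt")
  spec <- attr(g_e, "spec")
  hdr <- c(sprintf("# dt_ms %.17g", dt),
           sprintf("# exc mean %.17g sd %.17g tau %.17g e_rev %.17g",
                   spec$mean, spec$sd, spec$tau, spec$e_rev))
  if (!is.null(g_i)) {
    si <- attr(g_i, "spec")
    hdr <- c(hdr, sprintf("# inh mean %.17g sd %.17g tau %.17g e_rev %.17g",
                          si$mean, si$sd, si$tau, si$e_rev))
  }
  df <- data.frame(time_ms = (seq_along(g_e) - 1) * dt,
                   g_e = as.numeric(g_e))
  if (!is.null(g_i)) df$g_i <- as.numeric(g_i)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- lines[startsWith(lines, "#")]
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  attr(df, "header") <- hdr
  df
}
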