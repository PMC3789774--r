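#' Decompose a conductance into Na+ and K+ permeable pools
#'
#' Taking Na+ and K+ as the two charge carriers, a conductance `g` with
#' reversal potential `e_rev` between E_K and E_Na is equivalent, at every
#' voltage, to parallel Na+ and K+ conductances `na_fraction * g` and
#' `k_fraction * g` with
#' \deqn{k = (E_{Na} - E_{rev}) / (E_{Na} - E_K), \quad na = 1 - k,}
#' since then \eqn{g_{Na}'(V-E_{Na}) + g_K'(V-E_K) = g (V-E_{rev})}
#' identically.  This makes the K+ flux through synaptic and leak
#' conductances, and hence the Na+/K+ pump load, well defined.
#'
#' @param e_rev Reversal potential of the conductance, mV; must lie in
#'   \[E_K, E_Na\].
#' @param e_na,e_k Na+ / K+ reversal potentials, mV.
#' @return List with `na_fraction` and `k_fraction` (summing to 1).
#' @examples
#' decompose_conductance(0)        # excitatory: k = 50/127
#' decompose_conductance(-75)      # inhibitory: k = 125/127
#' @export
decompose_conductance <- function(e_rev, e_na = 50, e_k = -77) {
  if (e_rev < e_k || e_rev > e_na)
    stop(sprintf("reversal potential %g mV outside [E_K, E_Na] = [%g, %g]; no valid Na/K decomposition",
                 e_rev, e_k, e_na))
  k <- (e_na - e_rev) / (e_na - e_k)
  list(na_fraction = 1 - k, k_fraction = k)
}

#' Per-source K+ charge moved during a trial
#'
#' The excitatory, inhibitory and leak conductances are split into Na+/K+
#' pools ([decompose_conductance()]); the K+ current through each source is
#' the current through its K+ pool, `k_fraction * g_source * (V - E_K)`,
#' and the delayed-rectifier K+ current is taken whole.  Each source's K+
#' current is integrated (net, outward positive) over the trial on the
#' integration grid and converted from a density integral to
#' whole-compartment charge via the membrane area.
#'
#' These time integrals are accumulated during integration, so this works
#' on traces simulated with `record_trace = FALSE`.
#'
#' @param trace A `compartment_trace` from [integrate_compartment()].
#' @return Named numeric vector of net K+ charge in coulombs (whole
#'   compartment): `delayed_rectifier`, `excitatory`, `inhibitory`,
#'   `leak`.
#' @export
potassium_charge <- function(trace) {
  stopifnot(inherits(trace, "compartment_trace"))
  ii <- trace$integrals
  # integrals are uA*ms/cm^2 = 1e-9 C/cm^2; times area in cm^2
  area_cm2 <- trace$params$area_um2 * 1e-8
  scale <- 1e-9 * area_cm2
  c(delayed_rectifier = ii$k_dr * scale,
    excitatory = ii$k_exc * scale,
    inhibitory = ii$k_inh * scale,
    leak = ii$k_leak * scale)
}

#' ATP molecules needed to pump back a K+ charge
#'
#' The Na+/K+ ATPase hydrolyses one ATP per 3 Na+ extruded and 2 K+
#' imported, so the ATP count is the number of K+ ions (charge times
#' N_A / F) divided by 2.
#'
#' @param q_k Net outward K+ charge, coulombs (>= 0).
#' @return Number of ATP molecules.
#' @examples
#' atp_from_charge(96485)   # one mole of charge -> N_A / 2 ATP
#' @export
atp_from_charge <- function(q_k) {
  if (any(q_k < 0))
    stop("negative K+ charge: pass net outward charge")
  ions <- q_k * 6.02214e23 / 96485
  ions / 2
}

#' Partition ATP consumption into functional components
#'
#' Maps the per-source ATP counts onto the action-potential (delayed
#' rectifier), synaptic (excitatory + inhibitory K+ pools) and leak
#' components.
#'
#' @param atp Named vector as produced by
#'   `atp_from_charge(potassium_charge(trace))`.
#' @return Object of class `energy_breakdown`: `total`, `components`
#'   (action_potential, synaptic, leak) and `fractions`.
#' @export
partition_energy <- function(atp) {
  need <- c("delayed_rectifier", "excitatory", "inhibitory", "leak")
  missing <- setdiff(need, names(atp))
  if (length(missing))
    stop("missing sources: ", paste(missing, collapse = ", "))
  comp <- c(action_potential = unname(atp["delayed_rectifier"]),
            synaptic = unname(atp["excitatory"] + atp["inhibitory"]),
            leak = unname(atp["leak"]))
  total <- sum(comp)
  structure(list(total = total, components = comp,
                 fractions = if (total > 0) comp / total else comp * NA_real_),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("ATP: %.4g molecules (AP %.1f%%, synaptic %.1f%%, leak %.1f%%)\n",
              x$total, 100 * x$fractions["action_potential"],
              100 * x$fractions["synaptic"], 100 * x$fractions["leak"]))
  invisible(x)
}

#' ATP consumption of one or more trials
#'
#' Full energy accounting for a trial (or averaged over a list of trials):
#' per-source K+ charge, pump stoichiometry, component partition, and the
#' consumption rate per second.
#'
#' @param traces A `compartment_trace` or a list of them (same duration).
#' @return An `energy_breakdown` with additional fields `atp_per_second`
#'   and `duration` (ms).
#' @export
energy_breakdown <- function(traces) {
  if (inherits(traces, "compartment_trace")) traces <- list(traces)
  q <- rowMeans(vapply(traces, potassium_charge, numeric(4)))
  q <- pmax(q, 0)  # a source with net inward K+ flux costs the pump nothing
  bd <- partition_energy(atp_from_charge(q))
  bd$duration <- traces[[1L]]$duration
  bd$atp_per_second <- bd$total / (bd$duration / 1000)
  bd
}

#' Coding and energy efficiency of a spike train
#'
#' Coding efficiency is the mutual information rate per spike (bits/spike);
#' energy efficiency is the mutual information rate per ATP molecule
#' consumed (bits/ATP).  Either is reported missing (`NA`) when its
#' denominator is zero.
#'
#' @param mi_rate Mutual information rate, bits/s.
#' @param spike_rate Mean firing rate, spikes/s.
#' @param atp_rate ATP consumption, molecules/s.
#' @return List with `bits_per_spike` and `bits_per_atp`.
#' @examples
#' efficiency_metrics(10, 5, 1e8)
#' @export
efficiency_metrics <- function(mi_rate, spike_rate, atp_rate) {
  list(bits_per_spike = if (spike_rate > 0) mi_rate / spike_rate else NA_real_,
       bits_per_atp = if (atp_rate > 0) mi_rate / atp_rate else NA_real_)
}
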