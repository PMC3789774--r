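#' Synthetic fixtures with known statistics
#'
#' Generates data whose entropy, ISI statistics or information content is
#' known in closed form, so the estimators can be validated without any
#' compartment simulation:
#'
#' * `bernoulli_letters` - i.i.d. Bernoulli(p) letter matrix
#'   (`trials x bins`); analytic entropy rate
#'   `-[p log2 p + (1-p) log2(1-p)] / dt_bin` bits/ms at every word length.
#' * `poisson_train` - homogeneous Poisson spike trains (`rate_hz` over
#'   `duration` ms, `trials` of them); exponential ISIs, so CV -> 1.
#' * `two_pattern_trials` - two fixed K-letter response patterns, one per
#'   stimulus; `unfrozen` trials alternate stimuli (total word entropy
#'   exactly 1 bit), `frozen` trials repeat stimulus A (noise entropy 0),
#'   so MI is exactly 1 bit per word.
#' * `deterministic_hh_trace` - deterministic-gating compartment response
#'   to a constant excitatory conductance (`g_e_const`, uS/cm^2), a
#'   noise-free spike-train fixture.
#'
#' @param kind One of `"bernoulli_letters"`, `"poisson_train"`,
#'   `"two_pattern_trials"`, `"deterministic_hh_trace"`.
#' @param params Named list of kind-specific parameters (see Details).
#' @param seed Integer seed.
#' @return Kind-specific fixture: a letter matrix, a list of spike trains,
#'   a list with `unfrozen`/`frozen` letter matrices and `mi_bits_per_word`,
#'   or a `compartment_trace`.
#' @examples
#' L <- synthetic_fixtures("bernoulli_letters",
#'                         list(p = 0.5, trials = 4, bins = 100), seed = 1)
#' dim(L)
#' @export
synthetic_fixtures <- function(kind, params = list(), seed = 1) {
  set.seed(seed)
  switch(kind,
    bernoulli_letters = {
      p <- params$p %||% 0.5
      trials <- params$trials %||% 60
      bins <- params$bins %||% 1000
      m <- matrix(as.integer(stats::runif(trials * bins) < p),
                  nrow = trials)
      attr(m, "entropy_rate_bits_per_ms") <-
        if (p %in% c(0, 1)) 0 else -(p * log2(p) + (1 - p) * log2(1 - p))
      m
    },
    poisson_train = {
      rate <- params$rate_hz %||% 20
      duration <- params$duration %||% 1000
      trials <- params$trials %||% 1
      lapply(seq_len(trials), function(i) {
        n <- stats::rpois(1, rate * duration / 1000)
        sort(stats::runif(n, 0, duration))
      })
    },
    two_pattern_trials = {
      K <- params$K %||% 8
      trials <- params$trials %||% 60
      pat_a <- rep(c(1L, 0L), length.out = K)
      pat_b <- rep(c(0L, 1L), length.out = K)
      stim <- rep(c("A", "B"), length.out = trials)
      unfrozen <- t(vapply(stim, function(s)
        if (s == "A") pat_a else pat_b, integer(K)))
      frozen <- matrix(rep(pat_a, trials), nrow = trials, byrow = TRUE)
      rownames(unfrozen) <- NULL
      list(unfrozen = unfrozen, frozen = frozen, stimulus = stim,
           mi_bits_per_word = 1)
    },
    deterministic_hh_trace = {
      g_const <- params$g_e_const %||% 100
      duration <- params$duration %||% 200
      p <- params$membrane %||% membrane_params()
      dt <- params$dt %||% 0.01
      n <- round(duration / dt)
      integrate_compartment(p, stimulus = NULL, duration = duration,
                            dt = dt, deterministic = TRUE,
                            g_e = rep(g_const, n))
    },
    stop("unknown fixture kind: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
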