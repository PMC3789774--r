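#' Bin a spike train into letters
#'
#' Discretizes a spike train at temporal resolution `dt_bin` (default 1 ms):
#' letter b is the number of spikes in \[b*dt_bin, (b+1)*dt_bin).  With a
#' 2 ms refractory period the letters are effectively binary.
#'
#' @param spikes Numeric vector of spike times, ms.
#' @param duration Trial duration, ms.
#' @param dt_bin Bin width, ms. Default 1.
#' @return Integer vector of length `round(duration/dt_bin)`.
#' @examples
#' binarize(c(0.5, 1.5, 7.2), duration = 10)
#' @export
binarize <- function(spikes, duration, dt_bin = 1) {
  if (dt_bin <= 0) stop("dt_bin must be > 0")
  nbins <- round(duration / dt_bin)
  if (length(spikes) == 0) return(integer(nbins))
  idx <- floor(spikes / dt_bin) + 1L
  idx <- idx[idx >= 1L & idx <= nbins]
  tabulate(idx, nbins)
}

#' Letter matrix from a set of spike trains
#'
#' @param trains List of spike-time vectors (one per trial), ms.
#' @param duration Trial duration, ms.
#' @param dt_bin Bin width, ms.
#' @return Integer matrix, trials x bins.
#' @export
letter_matrix <- function(trains, duration, dt_bin = 1) {
  t(vapply(trains, binarize, integer(round(duration / dt_bin)),
           duration = duration, dt_bin = dt_bin))
}

# Encode K-letter words as strings; rows of `m` are words.
.encode_words <- function(m) {
  if (ncol(m) == 1L) return(as.character(m[, 1L]))
  do.call(paste, c(as.data.frame(m), sep = "."))
}

# Naive plug-in entropy (bits) of a sample of words, with the sample size
# and occupied-word count needed for bias correction.
.word_entropy <- function(words) {
  counts <- tabulate(match(words, unique(words)))
  n <- length(words)
  p <- counts / n
  list(H = -sum(p * log2(p)), occupied = length(counts), n = n)
}

#' First-order sampling-bias correction for a plug-in entropy
#'
#' The naive (plug-in) entropy of a finite sample is biased downward; the
#' leading term of the bias is (occupied - 1) / (2 N ln 2) bits, where
#' `occupied` counts the distinct words observed and N the sample size.
#' The corrected entropy adds this term back.
#'
#' @param naive_entropy Plug-in entropy, bits.
#' @param occupied Number of distinct words observed.
#' @param samples Sample size N (> 0).
#' @return Corrected entropy, bits.
#' @examples
#' bias_correct(1, occupied = 2, samples = 100)  # adds 1/(200 ln 2)
#' @export
bias_correct <- function(naive_entropy, occupied, samples) {
  if (samples <= 0) stop("samples must be > 0")
  naive_entropy + (occupied - 1) / (2 * samples * log(2))
}

#' Total entropy rate of binned responses at one word length
#'
#' Words are consecutive non-overlapping K-letter blocks; the word
#' distribution P(W) is estimated by pooling all blocks over trials and
#' block start positions (the trials carry independent stimulus waveforms,
#' i.e. unfrozen noise, so every block samples the same stationary response
#' ensemble).  The entropy rate is H(P)/(K dt_bin) in bits/s.
#'
#' @param letters Integer matrix (trials x bins) from [letter_matrix()].
#' @param K Word length in letters.
#' @param dt_bin Letter duration, ms.
#' @param correct Apply the first-order bias correction ([bias_correct()]).
#' @return Entropy rate, bits/s, with attributes `H_word` (bits/word),
#'   `occupied` and `n_words`.
#' @export
total_entropy <- function(letters, K, dt_bin = 1, correct = FALSE) {
  if (!is.matrix(letters)) letters <- matrix(letters, nrow = 1L)
  nw <- floor(ncol(letters) / K)
  if (nw < 1L || nrow(letters) * nw < 1L)
    stop("not enough letters for word length K")
  block <- letters[, seq_len(nw * K), drop = FALSE]
  # reshape: all K-letter words from all trials
  words_mat <- matrix(t(block), ncol = K, byrow = TRUE)
  we <- .word_entropy(.encode_words(words_mat))
  H <- if (correct) bias_correct(we$H, we$occupied, we$n) else we$H
  structure(1000 * H / (K * dt_bin),
            H_word = H, occupied = we$occupied, n_words = we$n)
}

#' Noise entropy rate of frozen-noise responses at one word length
#'
#' For frozen noise (the identical stimulus waveform on every trial), the
#' word distribution at each block start time t, P(W|t), is estimated
#' across trials; its entropy H(t) measures trial-to-trial
#' irreproducibility at that time.  The noise entropy rate is the average
#' of H(t) over start times divided by the word duration.
#'
#' @inheritParams total_entropy
#' @return Entropy rate, bits/s, with attribute `H_word` (mean bits/word).
#' @export
noise_entropy <- function(letters, K, dt_bin = 1, correct = FALSE) {
  if (!is.matrix(letters) || nrow(letters) < 2L)
    stop("noise entropy needs >= 2 trials")
  nw <- floor(ncol(letters) / K)
  if (nw < 1L) stop("not enough letters for word length K")
  n_trials <- nrow(letters)
  H_t <- vapply(seq_len(nw), function(b) {
    w <- letters[, ((b - 1L) * K + 1L):(b * K), drop = FALSE]
    we <- .word_entropy(.encode_words(w))
    if (correct) bias_correct(we$H, we$occupied, we$n) else we$H
  }, numeric(1))
  H <- mean(H_t)
  structure(1000 * H / (K * dt_bin), H_word = H, n_start_times = nw)
}

#' Extrapolate entropy rates to infinite word length
#'
#' Plug-in entropy rates computed at finite word length K are biased; the
#' asymptotic rate is recovered by linear extrapolation of the rate against
#' 1/K.  Among all sets of four consecutive word lengths, the set whose
#' (1/K, rate) points have the smallest linear-fit residual sum of squares
#' ("the four most linear values") is selected, ties broken toward larger
#' K, and the fitted intercept at 1/K = 0 is returned, floored at 0.
#'
#' @param K Word lengths (>= 4 values, increasing).
#' @param rates Entropy rates (bits/s) at each K.
#' @return List: `rate` (bits/s at 1/K = 0), `K_used` (the four word
#'   lengths selected), `slope`, `rss`.
#' @examples
#' K <- c(2, 4, 6, 8, 12, 16)
#' extrapolate_entropy(K, 100 + 40 / K)$rate   # exactly 100
#' @export
extrapolate_entropy <- function(K, rates) {
  ok <- is.finite(rates)
  K <- K[ok]; rates <- rates[ok]
  if (length(K) < 4) stop("extrapolation needs >= 4 word lengths")
  o <- order(K)
  K <- K[o]; rates <- rates[o]
  inv <- 1 / K
  best <- NULL
  for (i in seq_len(length(K) - 3L)) {
    idx <- i:(i + 3L)
    fit <- lm(rates[idx] ~ inv[idx])
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss <= best$rss)  # <=: later (larger-K) windows win ties
      best <- list(rate = max(0, unname(coef(fit)[1L])),
                   K_used = K[idx],
                   slope = unname(coef(fit)[2L]),
                   rss = rss)
  }
  best
}

#' Mutual information rate from total and noise entropy rates
#'
#' MI = total - noise.  Small negative values can arise from estimator
#' noise; they are floored at 0 with a warning.
#'
#' @param total_rate,noise_rate Entropy rates, bits/s, estimated with the
#'   same letter resolution and word-length schedule.
#' @return Mutual information rate, bits/s.
#' @export
mutual_information <- function(total_rate, noise_rate) {
  mi <- as.numeric(total_rate) - as.numeric(noise_rate)
  if (mi < 0) {
    warning(sprintf(
      "negative mutual information (%.3g bits/s) floored at 0 (estimator noise)",
      mi))
    mi <- 0
  }
  mi
}

#' Direct-method entropy rate with bias correction and extrapolation
#'
#' Runs the full direct-method schedule on a set of spike trains: binning
#' at `dt_bin`, per-K naive and bias-corrected entropy rates over the word
#' lengths `K_schedule` (word lengths exceeding the available bins are
#' dropped), and extrapolation of the corrected rates to infinite word
#' length.
#'
#' @param trains List of spike-time vectors (ms), one per trial.  Unfrozen
#'   noise trials for `type = "total"`, frozen-noise trials for
#'   `type = "noise"`.
#' @param duration Trial duration, ms.
#' @param type `"total"` or `"noise"`.
#' @param dt_bin Letter resolution, ms. Default 1.
#' @param K_schedule Word lengths. Default c(2,4,6,8,12,16,24,32,48,64).
#' @return Object of class `entropy_estimate`: `rate` (extrapolated
#'   bits/s), `K`, `naive_rate`, `corrected_rate` (per-K, bits/s),
#'   `K_used` (extrapolation quadruple), `type`.
#' @export
estimate_entropy_rate <- function(trains, duration,
                                  type = c("total", "noise"),
                                  dt_bin = 1,
                                  K_schedule = c(2, 4, 6, 8, 12, 16, 24, 32, 48, 64)) {
  type <- match.arg(type)
  letters <- letter_matrix(trains, duration, dt_bin)
  K_schedule <- K_schedule[floor(ncol(letters) / K_schedule) >= 1L]
  est_fun <- if (type == "total") total_entropy else noise_entropy
  naive <- vapply(K_schedule, function(K)
    as.numeric(est_fun(letters, K, dt_bin, correct = FALSE)), numeric(1))
  corrected <- vapply(K_schedule, function(K)
    as.numeric(est_fun(letters, K, dt_bin, correct = TRUE)), numeric(1))
  ex <- extrapolate_entropy(K_schedule, corrected)
  structure(list(rate = ex$rate, K = K_schedule,
                 naive_rate = naive, corrected_rate = corrected,
                 K_used = ex$K_used, slope = ex$slope, type = type,
                 dt_bin = dt_bin, n_trials = length(trains)),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf(
    "%s entropy: %.4g bits/s (extrapolated from K = {%s}; %d trials, dt_bin %g ms)\n",
    x$type, x$rate, paste(x$K_used, collapse = ", "), x$n_trials, x$dt_bin))
  invisible(x)
}

#' Total entropy, noise entropy and mutual information of a response set
#'
#' Convenience wrapper combining [estimate_entropy_rate()] on the unfrozen
#' (total) and frozen (noise) trial blocks with [mutual_information()].
#'
#' @param unfrozen_trains Spike trains from unfrozen-noise trials (a fresh
#'   stimulus waveform per trial).
#' @param frozen_trains Spike trains from frozen-noise trials (identical
#'   stimulus waveform on every trial).
#' @param duration Trial duration, ms.
#' @inheritParams estimate_entropy_rate
#' @return List with `total`, `noise` (entropy_estimate objects) and
#'   `mi_rate` (bits/s).
#' @export
estimate_information <- function(unfrozen_trains, frozen_trains, duration,
                                 dt_bin = 1,
                                 K_schedule = c(2, 4, 6, 8, 12, 16, 24, 32, 48, 64)) {
  tot <- estimate_entropy_rate(unfrozen_trains, duration, "total",
                               dt_bin, K_schedule)
  noi <- estimate_entropy_rate(frozen_trains, duration, "noise",
                               dt_bin, K_schedule)
  list(total = tot, noise = noi,
       mi_rate = mutual_information(tot$rate, noi$rate))
}
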