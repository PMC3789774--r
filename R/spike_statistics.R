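#' Mean firing rate of one or more spike trains
#'
#' @param spikes Numeric vector of spike times (ms), or a list of such
#'   vectors (one per trial).
#' @param duration Trial duration, ms.
#' @return Mean rate in spikes/s (count/duration averaged across trials).
#' @examples
#' firing_rate(c(100, 400, 900), duration = 1000)   # 3 spikes/s
#' @export
firing_rate <- function(spikes, duration) {
  if (duration <= 0) stop("duration must be > 0")
  if (!is.list(spikes)) spikes <- list(spikes)
  counts <- vapply(spikes, length, integer(1))
  mean(counts) / (duration / 1000)
}

#' Coefficient of variation of the interspike-interval distribution
#'
#' ISIs are computed within each trial (never across trial boundaries) and
#' pooled across trials; the CV is the standard deviation of the pooled
#' ISIs divided by their mean.  Pooling stabilizes the estimate at low
#' firing rates where single trials contribute few intervals.
#'
#' @param spikes Spike-time vector (ms) or list of such vectors.
#' @return CV (dimensionless), or `NA` when fewer than 2 ISIs are
#'   available (undefined, reported as missing rather than zero).
#' @examples
#' isi_cv(seq(0, 1000, by = 50))   # perfectly periodic: 0
#' @export
isi_cv <- function(spikes) {
  if (!is.list(spikes)) spikes <- list(spikes)
  isis <- unlist(lapply(spikes, function(s) if (length(s) >= 2) diff(s)),
                 use.names = FALSE)
  if (length(isis) < 2) return(NA_real_)
  sd(isis) / mean(isis)
}

#' Write / read spike times as plain text
#'
#' One spike time (ms) per line, one file per trial.
#'
#' @param spikes Numeric vector of spike times (ms).
#' @param path File path.
#' @return `write_spike_times` returns `path` invisibly;
#'   `read_spike_times` returns a numeric vector.
#' @export
write_spike_times <- function(spikes, path) {
  writeLines(sprintf("%.17g", spikes), path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  as.numeric(lines)
}
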