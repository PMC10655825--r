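#' Repetitive TMS stimulation protocol
#'
#' Bookkeeping for a high-frequency rTMS protocol: pulse frequency, pulses
#' per train, inter-train interval, number of trains and intensity as a
#' percentage of the resting motor threshold (RMT). The study protocol is
#' 20 Hz, 40 pulses per train, 28 s inter-train interval, 45 trains at 110%
#' RMT.
#'
#' @param frequency_hz pulse frequency in Hz.
#' @param pulses_per_train pulses per train.
#' @param iti_seconds inter-train interval in seconds.
#' @param n_trains number of trains.
#' @param intensity_pct_rmt stimulation intensity, percent of RMT.
#' @return object of class `stim_protocol`.
#' @export
stim_protocol <- function(frequency_hz = 20, pulses_per_train = 40,
                          iti_seconds = 28, n_trains = 45,
                          intensity_pct_rmt = 110) {
  vals <- c(frequency_hz, pulses_per_train, iti_seconds, n_trains,
            intensity_pct_rmt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all stimulation protocol parameters must be strictly positive")
  structure(list(frequency_hz = frequency_hz,
                 pulses_per_train = pulses_per_train,
                 iti_seconds = iti_seconds, n_trains = n_trains,
                 intensity_pct_rmt = intensity_pct_rmt),
            class = "stim_protocol")
}

#' Total pulses and total duration of a protocol
#'
#' `total_pulses = pulses_per_train * n_trains`. The duration counts one
#' inter-train interval after every train, including the last, i.e.
#' `total_seconds = n_trains * (pulses_per_train / frequency_hz +
#' iti_seconds)`: with the study protocol this gives 1800 pulses in
#' 1350 s (22.5 min).
#'
#' @param p a `stim_protocol`.
#' @return list with `total_pulses` (integer) and `total_seconds`.
#' @export
protocol_totals <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  if (p$frequency_hz == 0) stop("zero stimulation frequency")
  list(total_pulses = as.integer(p$pulses_per_train * p$n_trains),
       total_seconds = p$n_trains *
         (p$pulses_per_train / p$frequency_hz + p$iti_seconds))
}

#' @export
print.stim_protocol <- function(x, ...) {
  tot <- protocol_totals(x)
  cat(sprintf(
    "stim_protocol: %g Hz, %g pulses/train, ITI %g s, %g trains @ %g%% RMT\n",
    x$frequency_hz, x$pulses_per_train, x$iti_seconds, x$n_trains,
    x$intensity_pct_rmt))
  cat(sprintf("  total: %d pulses, %.4g min\n", tot$total_pulses,
              tot$total_seconds / 60))
  invisible(x)
}
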