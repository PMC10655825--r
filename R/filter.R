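#' Zero-phase Butterworth low-pass filtering of a BOLD run
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase) to every unit series. Series are demeaned before filtering
#' and the mean is restored afterwards, so the DC component is preserved
#' exactly; edge transients are controlled by odd-reflection padding.
#'
#' @param run a `bold_run`.
#' @param cutoff_hz low-pass cutoff in Hz; must be below the Nyquist
#'   frequency `1 / (2 * tr_seconds)`. Default 0.08 Hz.
#' @param order filter order (default 4).
#' @return the filtered `bold_run`.
#' @export
lowpass_filter <- function(run, cutoff_hz = 0.08, order = 4) {
  stopifnot(inherits(run, "bold_run"))
  nyq <- 1 / (2 * run$tr_seconds)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %.3g Hz is not below Nyquist (%.3g Hz)",
                 cutoff_hz, nyq))
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  run$data <- filtfilt_matrix(run$data, bf$b, bf$a)
  run
}

# Zero-phase IIR filtering of matrix columns: odd-reflection padding,
# forward pass, time reversal, second pass, crop. Demean/re-add mean so a
# constant series is returned unchanged. Vectorised across columns (one
# recursion over frames), which is much faster than per-column filtfilt
# calls for many units.
filtfilt_matrix <- function(x, b, a) {
  x <- as.matrix(x)
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  npad <- min(n - 1L, max(3L * (length(a) - 1L), 24L))
  pad_fwd <- function(y) {
    top <- -y[(npad + 1L):2L, , drop = FALSE]           # odd reflection
    bot <- -y[(n - 1L):(n - npad), , drop = FALSE]
    rbind(sweep(top, 2, 2 * y[1L, ], FUN = function(u, v) u + v),
          y,
          sweep(bot, 2, 2 * y[n, ], FUN = function(u, v) u + v))
  }
  onepass <- function(y) {
    nb <- length(b); na <- length(a)
    m <- nrow(y)
    out <- matrix(0, m, ncol(y))
    for (t in seq_len(m)) {
      acc <- b[1L] * y[t, ]
      for (k in 2:nb) if (t - k + 1L >= 1L) acc <- acc + b[k] * y[t - k + 1L, ]
      for (k in 2:na) if (t - k + 1L >= 1L) acc <- acc - a[k] * out[t - k + 1L, ]
      out[t, ] <- acc / a[1L]
    }
    out
  }
  y <- pad_fwd(xc)
  y <- onepass(y)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- onepass(y)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- y[(npad + 1L):(npad + n), , drop = FALSE]
  sweep(y, 2, mu, "+")
}

# Lag-autocorrelation of white noise passed through the zero-phase filter,
# and the implied variance of a Fisher z estimate from n filtered frames.
# Used by the synthetic-cohort coupling design (closed-form measurement
# model); the Bartlett approximation var(z) ~ (1/n) * sum_tau rho(tau)^2.
filter_autocorr <- function(tr_seconds, cutoff_hz, order = 4, len = 2048L) {
  nyq <- 1 / (2 * tr_seconds)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  imp <- matrix(0, len, 1L); imp[len %/% 2L, 1L] <- 1
  g <- filtfilt_matrix(imp, bf$b, bf$a)[, 1L]
  r <- stats::convolve(g, g, type = "open")      # autocorrelation of g
  mid <- (length(r) + 1L) %/% 2L
  r <- r[mid:length(r)]
  r / r[1L]
}

fisher_z_var <- function(n_frames, tr_seconds, cutoff_hz, order = 4) {
  rho <- filter_autocorr(tr_seconds, cutoff_hz, order)
  tau <- seq_along(rho) - 1L
  keep <- tau < n_frames & abs(rho) > 1e-8
  s <- sum((1 - tau[keep] / n_frames) * rho[keep]^2)
  s2 <- sum((1 - tau[keep][-1] / n_frames) * rho[keep][-1]^2)
  (s + s2) / n_frames            # two-sided sum over negative + positive lags
}
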