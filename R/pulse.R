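# Cardiac pulse waveform template: a band-limited periodic shape with its
# power concentrated in the first harmonic of the cardiac cycle, emulating
# the ~1 Hz principal component seen in gated velocity waveforms.

.pulse_harmonics <- function(n_harmonics) {
  k <- seq_len(n_harmonics)
  # decreasing harmonic amplitudes give a fast systolic upstroke followed by
  # a slower diastolic decay; the phase offsets skew the peak early in the
  # cycle the way arterial-driven waveforms are skewed
  list(amp = 1 / k, phase = -pi / 2 + 0.45 * (k - 1))
}

# Raw (unnormalized) template evaluated at possibly fractional cardiac-phase
# positions tau (in samples, one cycle = n_phases samples).
.pulse_raw <- function(tau, n_phases, n_harmonics) {
  h <- .pulse_harmonics(n_harmonics)
  out <- numeric(length(tau))
  for (k in seq_len(n_harmonics)) {
    out <- out + h$amp[k] * cos(2 * pi * k * tau / n_phases + h$phase[k])
  }
  out
}

# Normalization constants computed on the integer sampling grid, so that the
# sampled template has mean 0 and peak-to-trough range 1.
.pulse_norm <- function(n_phases, n_harmonics) {
  s <- .pulse_raw(seq_len(n_phases) - 1, n_phases, n_harmonics)
  list(center = mean(s), scale = max(s) - min(s))
}

# Template evaluated at arbitrary (fractional) positions with the integer-grid
# normalization; used by the renderer to inject fractional-sample lags.
.pulse_eval <- function(tau, n_phases, n_harmonics) {
  nc <- .pulse_norm(n_phases, n_harmonics)
  (.pulse_raw(tau, n_phases, n_harmonics) - nc$center) / nc$scale
}

#' Unit-amplitude cardiac pulse template
#'
#' Builds a deterministic periodic waveform of one cardiac cycle, used by the
#' synthetic scene generator as the shape of injected flow pulsatility. The
#' returned sequence has zero mean, peak-to-trough range exactly 1, and all
#' spectral power in the first \code{n_harmonics} harmonics, with the first
#' harmonic dominant.
#'
#' @param n_phases number of cardiac phases per cycle (samples).
#' @param n_harmonics number of harmonics to include; must satisfy
#'   \code{n_phases >= 2 * n_harmonics + 1} so the shape is unaliased.
#' @return numeric vector of length \code{n_phases}.
#' @examples
#' w <- make_pulse_template(38, 3)
#' range(w)  # peak-to-trough span of 1
#' @export
make_pulse_template <- function(n_phases, n_harmonics = 3) {
  stopifnot(length(n_phases) == 1, length(n_harmonics) == 1)
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  if (n_phases < 2 * n_harmonics + 1) {
    stop("n_phases too small for ", n_harmonics, " harmonics (need >= ",
         2 * n_harmonics + 1, ")")
  }
  s <- .pulse_raw(seq_len(n_phases) - 1, n_phases, n_harmonics)
  s <- s - mean(s)
  s / (max(s) - min(s))
}
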