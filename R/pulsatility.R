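# Waveform characterization: Savitzky-Golay decomposition into pulsatile
# signal and residual noise, the PCNR detection statistic with Monte Carlo
# null calibration, pulsatility index, temporal lag versus the sinus
# reference, and a supplementary spectral check.

# cache of smoothing matrices keyed by (n, order, frame, boundary)
.sg_cache <- new.env(parent = emptyenv())

#' Savitzky-Golay smoothing matrix
#'
#' Returns the n x n linear operator implementing low-pass Savitzky-Golay
#' filtering of a length-n waveform. With \code{boundary = "edgefit"} the
#' first and last half-frames are smoothed with the asymmetric polynomial
#' fits of the classical filter (the behaviour of
#' \code{signal::sgolayfilt}); with \code{"circular"} the central kernel is
#' applied with wrap-around extension, treating the waveform as one
#' periodic cardiac cycle.
#'
#' @param n waveform length (>= frame).
#' @param order polynomial order; default 3.
#' @param frame odd frame length; default 15.
#' @param boundary \code{"edgefit"} (default) or \code{"circular"}.
#' @return n x n numeric matrix.
#' @export
sg_smoother <- function(n, order = 3, frame = 15,
                        boundary = c("edgefit", "circular")) {
  boundary <- match.arg(boundary)
  if (frame %% 2 != 1) stop("frame must be odd")
  if (n < frame) stop("waveform length must be >= frame (", frame, ")")
  key <- paste(n, order, frame, boundary, sep = "|")
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])
  S <- unclass(signal::sgolay(p = order, n = frame))
  hw <- (frame - 1) / 2
  M <- matrix(0, n, n)
  h <- S[hw + 1, ]
  if (boundary == "circular") {
    for (t in seq_len(n)) {
      idx <- ((t - 1 + (-hw:hw)) %% n) + 1
      M[t, idx] <- M[t, idx] + h
    }
  } else {
    for (t in (hw + 1):(n - hw)) M[t, (t - hw):(t + hw)] <- h
    for (r in seq_len(hw)) {
      M[r, seq_len(frame)] <- S[r, ]
      M[n - hw + r, (n - frame + 1):n] <- S[hw + 1 + r, ]
    }
  }
  .sg_cache[[key]] <- M
  M
}

#' Low-pass filter a velocity waveform
#'
#' Savitzky-Golay smoothing (third order, 15-timepoint frame by default)
#' separating the cardiac-locked pulsatile component from high-frequency
#' noise.
#'
#' @param w a \code{\link{velocity_waveform}} or numeric vector.
#' @inheritParams sg_smoother
#' @return numeric vector of filtered values.
#' @export
smooth_waveform <- function(w, order = 3, frame = 15,
                            boundary = c("edgefit", "circular")) {
  v <- .wave_values(w)
  as.numeric(sg_smoother(length(v), order, frame, match.arg(boundary)) %*% v)
}

#' Pulsatility contrast-to-noise ratio
#'
#' The PCNR statistic: the range of the low-pass-filtered waveform (delta v)
#' divided by the standard deviation of the residuals between unfiltered and
#' filtered timepoints, \code{sqrt(sum(res^2) / (N - 1))}. PCNR behaves like
#' a t-statistic for the presence of cardiac-locked flow variation and is
#' invariant to the scale and offset of the waveform. A zero residual with a
#' positive range yields \code{Inf} (unambiguous signal); a constant
#' waveform yields 0.
#'
#' @param w a \code{\link{velocity_waveform}} or numeric vector.
#' @inheritParams sg_smoother
#' @return list with \code{pcnr}, \code{delta_v} (cm/s), \code{res_sd}
#'   (cm/s).
#' @export
pcnr <- function(w, order = 3, frame = 15,
                 boundary = c("edgefit", "circular")) {
  v <- .wave_values(w)
  # PCNR is offset-invariant; filtering the mean-centered waveform makes the
  # degenerate constant case exact instead of 0/0 rounding noise
  v0 <- v - mean(v)
  f <- smooth_waveform(v0, order, frame, match.arg(boundary))
  delta_v <- max(f) - min(f)
  res_sd <- sqrt(sum((v0 - f)^2) / (length(v0) - 1))
  p <- if (res_sd == 0) {
    if (delta_v > 0) Inf else 0
  } else {
    delta_v / res_sd
  }
  list(pcnr = p, delta_v = delta_v, res_sd = res_sd)
}

#' Monte Carlo calibration of the PCNR null distribution
#'
#' Draws \code{n_reps} waveforms of i.i.d. standard Gaussian noise of length
#' \code{n_phases}, computes PCNR for each, and returns the empirical
#' (1 - alpha) quantile as the pulsatility detection threshold. PCNR is
#' exactly invariant to the noise SD (both numerator and denominator are
#' linear in the scale), so a unit-variance null suffices; the threshold is
#' also insensitive to \code{n_phases} over the gated-acquisition range.
#'
#' @param n_phases waveform length.
#' @param alpha tail probability; default 0.01.
#' @param n_reps Monte Carlo draws (>= 1000); default 1e5.
#' @param seed RNG seed for reproducibility.
#' @inheritParams sg_smoother
#' @return object of class \code{null_calibration} with elements
#'   \code{threshold}, \code{alpha}, \code{n_phases}, \code{n_reps},
#'   \code{seed}.
#' @export
calibrate_null <- function(n_phases, alpha = 0.01, n_reps = 1e5, seed = 1,
                           order = 3, frame = 15,
                           boundary = c("edgefit", "circular")) {
  stopifnot(n_reps >= 1000, alpha > 0, alpha < 1)
  boundary <- match.arg(boundary)
  vals <- with_seed(seed, {
    W <- matrix(rnorm(n_phases * n_reps), n_phases, n_reps)
    null_pcnr(W, order, frame, boundary)
  })
  structure(list(threshold = unname(quantile(vals, 1 - alpha)),
                 alpha = alpha, n_phases = n_phases, n_reps = n_reps,
                 seed = seed, order = order, frame = frame,
                 boundary = boundary),
            class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(
    "PCNR null calibration: threshold %.3f at alpha = %g (N = %d, %g reps)\n",
    x$threshold, x$alpha, x$n_phases, x$n_reps))
  invisible(x)
}

#' PCNR of many waveforms at once
#'
#' Vectorized PCNR over the columns of a matrix; used by the Monte Carlo
#' null calibration and the power/type-I simulations.
#'
#' @param W matrix with one waveform per column.
#' @inheritParams sg_smoother
#' @return numeric vector of PCNR values, one per column.
#' @export
null_pcnr <- function(W, order = 3, frame = 15,
                      boundary = c("edgefit", "circular")) {
  W <- as.matrix(W)
  N <- nrow(W)
  W <- sweep(W, 2, colMeans(W))  # offset-invariant, see pcnr()
  M <- sg_smoother(N, order, frame, match.arg(boundary))
  F <- M %*% W
  mx <- F[1, ]; mn <- F[1, ]
  for (t in 2:N) {
    mx <- pmax(mx, F[t, ])
    mn <- pmin(mn, F[t, ])
  }
  res_sd <- sqrt(colSums((W - F)^2) / (N - 1))
  dv <- mx - mn
  out <- ifelse(res_sd == 0, ifelse(dv > 0, Inf, 0), dv / res_sd)
  as.numeric(out)
}

#' Pulsatility index
#'
#' PI = delta v / mean(|v|): the range of the low-pass-filtered waveform
#' divided by the time-averaged absolute velocity of the unfiltered
#' waveform. Dimensionless; invariant under positive scaling.
#'
#' @param w a \code{\link{velocity_waveform}} or numeric vector.
#' @inheritParams sg_smoother
#' @return numeric PI value.
#' @export
pulsatility_index <- function(w, order = 3, frame = 15,
                              boundary = c("edgefit", "circular")) {
  v <- .wave_values(w)
  mabs <- mean(abs(v))
  if (mabs == 0) stop("mean absolute velocity is zero; PI undefined")
  pcnr(v, order, frame, match.arg(boundary))$delta_v / mabs
}

#' Temporal lag by peak circular cross-correlation
#'
#' Estimates the delay of waveform \code{w} relative to the reference
#' \code{ref} (normally the superior sagittal sinus) as the lag maximizing
#' the circular cross-correlation of the mean-subtracted unfiltered
#' waveforms. Positive lag means \code{w} is delayed. Lags are integer
#' cardiac phases in [-N/2, N/2); ties are broken toward the smallest
#' absolute lag, then toward positive lag. No sub-sample interpolation is
#' performed, so lag is quantized to the cardiac-phase duration.
#'
#' @param w,ref \code{\link{velocity_waveform}}s (or numeric vectors) with
#'   equal length and phase duration.
#' @return list with \code{lag_samples} (integer) and \code{lag_ms}.
#' @export
temporal_lag <- function(w, ref) {
  if (inherits(w, "velocity_waveform") &&
      inherits(ref, "velocity_waveform") &&
      !isTRUE(all.equal(w$phase_duration, ref$phase_duration))) {
    stop("waveforms have different phase durations")
  }
  pd <- if (inherits(w, "velocity_waveform")) w$phase_duration else NA_real_
  x <- .wave_values(w)
  y <- .wave_values(ref)
  N <- length(x)
  if (length(y) != N) stop("waveforms must have the same number of phases")
  xc <- x - mean(x)
  yc <- y - mean(y)
  if (all(xc == 0) || all(yc == 0)) {
    stop("zero-variance waveform; cross-correlation undefined")
  }
  lags <- (-floor(N / 2)):(ceiling(N / 2) - 1)
  r <- vapply(lags, function(l) {
    sum(xc * yc[((seq_len(N) - 1 - l) %% N) + 1])
  }, 0)
  mx <- max(r)
  # near-exact ties (symmetric waveforms) can differ by rounding noise
  cand <- lags[r >= mx - 1e-9 * max(1, abs(mx))]
  cand <- cand[order(abs(cand), cand < 0)]
  lag <- cand[1]
  list(lag_samples = as.integer(lag), lag_ms = lag * pd)
}

#' Amplitude spectrum of a waveform
#'
#' Discrete Fourier amplitude at integer frequencies (cycles per cardiac
#' cycle), used as a basic check that waveform power is concentrated at the
#' cardiac fundamental (~1 Hz) rather than at high frequencies.
#'
#' @param w a \code{\link{velocity_waveform}} or numeric vector (>= 2
#'   samples).
#' @return data frame with \code{frequency} (cycles/cycle, from 1) and
#'   \code{amplitude}; the dominant nonzero frequency is attached as
#'   attribute \code{"dominant"}.
#' @export
power_spectrum <- function(w) {
  v <- .wave_values(w)
  N <- length(v)
  if (N < 2) stop("need at least 2 cardiac phases")
  amp <- 2 * Mod(fft(v))[2:(floor(N / 2) + 1)] / N
  out <- data.frame(frequency = seq_len(floor(N / 2)), amplitude = amp)
  attr(out, "dominant") <- if (all(amp == 0)) NA_integer_ else
    out$frequency[which.max(amp)]
  out
}

#' Characterize one vessel waveform
#'
#' Combines the PCNR decision (against a Monte Carlo calibrated threshold),
#' pulsatility index, and temporal lag versus a reference waveform into one
#' result row.
#'
#' @param w a \code{\link{velocity_waveform}}.
#' @param calibration a \code{\link{calibrate_null}} result.
#' @param ref optional reference waveform for the lag.
#' @param compute_pi set FALSE for vessels whose speed exceeds venc
#'   (arteries, sinus), where wrapped phase makes mean velocity and PI
#'   unreliable.
#' @return one-row data frame: \code{pcnr}, \code{delta_v}, \code{res_sd},
#'   \code{pulsatile}, \code{pi}, \code{lag_samples}, \code{lag_ms},
#'   \code{mean_abs_speed}.
#' @export
characterize_pulsatility <- function(w, calibration, ref = NULL,
                                     compute_pi = TRUE) {
  stopifnot(inherits(calibration, "null_calibration"))
  p <- pcnr(w, calibration$order, calibration$frame, calibration$boundary)
  v <- .wave_values(w)
  mabs <- mean(abs(v))
  pi_val <- if (compute_pi && mabs > 0) p$delta_v / mabs else NA_real_
  lag <- if (!is.null(ref)) temporal_lag(w, ref) else
    list(lag_samples = NA_integer_, lag_ms = NA_real_)
  data.frame(pcnr = p$pcnr, delta_v = p$delta_v, res_sd = p$res_sd,
             pulsatile = p$pcnr > calibration$threshold, pi = pi_val,
             lag_samples = lag$lag_samples, lag_ms = lag$lag_ms,
             mean_abs_speed = mabs)
}

#' Per-vessel pulsatility results table
#'
#' Applies \code{\link{characterize_pulsatility}} to every cluster waveform,
#' joining in the cluster annotations. PI is not computed for arteries or
#' the sinus (phase wrapping at the venous venc corrupts their mean
#' velocity), and clusters annotated \code{"discard"} are dropped.
#'
#' @param waveforms named list of cluster waveforms (see
#'   \code{\link{extract_waveforms}}).
#' @param reference sinus reference waveform, or NULL to skip lags.
#' @param calibration a \code{\link{calibrate_null}} result.
#' @param clusters cluster annotation data frame (id, class_label,
#'   territory, size).
#' @return data frame with one row per retained vessel.
#' @export
vessel_pulsatility <- function(waveforms, reference, calibration, clusters) {
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cls <- clusters$class_label[i]
    if (is.na(cls) || cls == "discard") return(NULL)
    w <- waveforms[[as.character(clusters$id[i])]]
    res <- characterize_pulsatility(
      w, calibration, ref = reference,
      compute_pi = cls %in% c("small_vein", "surface_vein"))
    cbind(data.frame(cluster = clusters$id[i], class_label = cls,
                     territory = clusters$territory[i],
                     size = clusters$size[i]),
          res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
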