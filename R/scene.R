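# Synthetic cardiac-gated phase-contrast scene generator. Every downstream
# stage (segmentation, velocimetry, pulsatility, cohort statistics) is
# validated against the ground truth these scenes carry.

#' Vessel specification for a synthetic scene
#'
#' Describes one vessel cutting through the imaging slice: its footprint in
#' the 2D grid, vessel class, vascular territory, through-slice flow, and
#' injected pulsatility.
#'
#' @param center integer vector \code{c(row, col)}: position of the footprint
#'   origin in the grid.
#' @param footprint integer matrix (n x 2) of voxel offsets relative to
#'   \code{center}; must form an 8-connected set of 1-30 voxels. Helpers:
#'   \code{\link{square_footprint}}, \code{\link{random_footprint}}.
#' @param class_label one of \code{"artery"}, \code{"small_vein"},
#'   \code{"surface_vein"}, \code{"sinus"}.
#' @param territory vascular territory: \code{"ACA"}, \code{"L_MCA"},
#'   \code{"R_MCA"}, \code{"PCA"}, or \code{"none"}.
#' @param mean_speed signed cycle-mean through-slice speed in cm/s (negative
#'   encodes superior-to-inferior flow).
#' @param pulse_amplitude peak-to-trough amplitude of the injected pulse
#'   waveform in cm/s.
#' @param lag_ms delay of this vessel's pulse waveform relative to the scene
#'   reference waveform, in ms (may be fractional in samples).
#' @param volume_fraction partial-volume weight in [0, 1] applied to the
#'   vessel's velocity contribution in each footprint voxel.
#' @return object of class \code{vessel_spec}.
#' @export
vessel_spec <- function(center, footprint, class_label,
                        territory = "none", mean_speed = -1,
                        pulse_amplitude = 0.3, lag_ms = 0,
                        volume_fraction = 1) {
  class_label <- match.arg(class_label, .vessel_classes)
  territory <- match.arg(territory, c(.territories, "none"))
  footprint <- as.matrix(footprint)
  storage.mode(footprint) <- "integer"
  if (ncol(footprint) != 2) stop("footprint must be an n x 2 offset matrix")
  n <- nrow(footprint)
  if (n < 1 || n > 30) stop("footprint must have 1-30 voxels")
  if (anyDuplicated(footprint)) stop("footprint has duplicate voxels")
  if (!.is_8_connected(footprint)) stop("footprint voxels must be 8-connected")
  if (volume_fraction < 0 || volume_fraction > 1) {
    stop("volume_fraction must lie in [0, 1]")
  }
  structure(list(center = as.integer(center), footprint = footprint,
                 class_label = class_label, territory = territory,
                 mean_speed = mean_speed, pulse_amplitude = pulse_amplitude,
                 lag_ms = lag_ms, volume_fraction = volume_fraction),
            class = "vessel_spec")
}

# 8-connectivity check by flood fill over the offset set.
.is_8_connected <- function(offsets) {
  n <- nrow(offsets)
  if (n == 1) return(TRUE)
  key <- paste(offsets[, 1], offsets[, 2])
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    d <- pmax(abs(offsets[, 1] - offsets[i, 1]),
              abs(offsets[, 2] - offsets[i, 2]))
    nb <- which(d == 1L & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Square vessel footprint
#'
#' @param w side length in voxels.
#' @return integer offset matrix with \code{w^2} rows.
#' @export
square_footprint <- function(w) {
  as.matrix(expand.grid(0:(w - 1), 0:(w - 1)))
}

#' Random 8-connected vessel footprint
#'
#' Grows a connected blob of \code{n} voxels by repeatedly attaching a random
#' 8-neighbor of a random member voxel. Uses the current RNG stream.
#'
#' @param n number of voxels (1-30).
#' @return integer offset matrix with \code{n} rows.
#' @export
random_footprint <- function(n) {
  stopifnot(n >= 1, n <= 30)
  pts <- matrix(0L, 1, 2)
  while (nrow(pts) < n) {
    i <- sample.int(nrow(pts), 1)
    step <- cbind(sample(-1:1, 1), sample(-1:1, 1))
    cand <- pts[i, , drop = FALSE] + step
    if (all(step == 0L)) next
    if (!any(pts[, 1] == cand[1] & pts[, 2] == cand[2])) {
      pts <- rbind(pts, cand)
    }
  }
  dimnames(pts) <- NULL
  pts
}

#' Synthetic scene configuration
#'
#' Collects everything the renderer needs: grid and gating geometry,
#' velocity encoding, the vessel population, a smooth polynomial background
#' phase field, and noise levels. Defaults mirror the acquisition the
#' package targets: 38 cardiac phases of 23.1 ms (two 11.55 ms TRs) and
#' venc = 10 cm/s chosen for slow venous flow.
#'
#' @param vessels list of \code{\link{vessel_spec}} objects.
#' @param grid_size voxels per side of the square slice (>= 34, so the 17x17
#'   median-filter window fits).
#' @param n_phases cardiac phases per cycle (>= 15, so the Savitzky-Golay
#'   frame fits).
#' @param phase_duration duration of one cardiac phase in ms.
#' @param venc velocity-encoding value in cm/s; a through-slice speed of
#'   venc maps to a signal phase of pi radians, faster flow wraps.
#' @param background_coef up to 10 coefficients (radians) of a 2D polynomial
#'   of degree <= 3 in grid coordinates normalized to [-1, 1]; term order
#'   1, x, y, x^2, xy, y^2, x^3, x^2 y, x y^2, y^3.
#' @param noise_sd_phase additive Gaussian noise SD on the phase images
#'   (radians).
#' @param noise_sd_mag additive Gaussian noise SD on the magnitude images
#'   (arbitrary units).
#' @param mag_base background magnitude level (arbitrary units).
#' @param mag_gain magnitude contrast scale for vessel voxels.
#' @param n_harmonics harmonics in the pulse template.
#' @param gating_smooth odd width (samples) of a circular uniform smoothing
#'   kernel applied to the pulse template, emulating the temporal blurring
#'   of prospective gating under heart-rate variability; 1 disables it.
#' @param voxel_size in-plane voxel size in mm (metadata only).
#' @param seed RNG seed for the noise draws; identical configurations render
#'   bit-identical scenes.
#' @return object of class \code{scene_config}.
#' @export
scene_config <- function(vessels, grid_size = 64, n_phases = 38,
                         phase_duration = 23.1, venc = 10,
                         background_coef = numeric(10),
                         noise_sd_phase = 0.05, noise_sd_mag = 3,
                         mag_base = 30, mag_gain = 40,
                         n_harmonics = 3, gating_smooth = 1,
                         voxel_size = 0.6, seed = 1) {
  if (grid_size < 34) stop("grid_size must be >= 34 (median-filter window)")
  if (n_phases < 15) stop("n_phases must be >= 15 (Savitzky-Golay frame)")
  if (venc <= 0) stop("venc must be positive")
  if (gating_smooth < 1 || gating_smooth %% 2 != 1) {
    stop("gating_smooth must be an odd positive width")
  }
  if (length(background_coef) > 10) {
    stop("background_coef supports polynomial degree <= 3 (10 terms)")
  }
  stopifnot(is.list(vessels), length(vessels) >= 1)
  for (v in vessels) {
    if (!inherits(v, "vessel_spec")) stop("vessels must be vessel_spec objects")
    if (abs(v$mean_speed) + v$pulse_amplitude > venc &&
        !v$class_label %in% c("artery", "sinus")) {
      stop("only arteries and the sinus may exceed venc (phase wrapping)")
    }
  }
  structure(list(vessels = vessels, grid_size = as.integer(grid_size),
                 n_phases = as.integer(n_phases),
                 phase_duration = phase_duration, venc = venc,
                 background_coef = as.numeric(background_coef),
                 noise_sd_phase = noise_sd_phase,
                 noise_sd_mag = noise_sd_mag,
                 mag_base = mag_base, mag_gain = mag_gain,
                 n_harmonics = as.integer(n_harmonics),
                 gating_smooth = as.integer(gating_smooth),
                 voxel_size = voxel_size, seed = seed),
            class = "scene_config")
}

#' Cardiac-gated phase-contrast series
#'
#' Container for per-cardiac-phase magnitude and phase image stacks plus the
#' acquisition metadata needed to convert phase to velocity.
#'
#' @param magnitude 3D array (x, y, cardiac phase), non-negative.
#' @param phase 3D array (x, y, cardiac phase), radians in (-pi, pi].
#' @param venc velocity encoding, cm/s.
#' @param phase_duration ms per cardiac phase.
#' @param voxel_size in-plane voxel size, mm.
#' @return object of class \code{gated_pc_series}.
#' @export
gated_pc_series <- function(magnitude, phase, venc, phase_duration,
                            voxel_size = 0.6) {
  magnitude <- unclass(magnitude)
  phase <- unclass(phase)
  stopifnot(length(dim(magnitude)) == 3, identical(dim(magnitude), dim(phase)))
  if (min(magnitude) < 0) stop("magnitude must be non-negative")
  if (max(phase) > pi + 1e-9 || min(phase) <= -pi - 1e-9) {
    stop("phase must lie in (-pi, pi]")
  }
  if (venc <= 0) stop("venc must be positive")
  structure(list(magnitude = magnitude, phase = phase, venc = venc,
                 phase_duration = phase_duration,
                 n_phases = dim(phase)[3], voxel_size = voxel_size),
            class = "gated_pc_series")
}

#' @export
print.gated_pc_series <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf(
    "gated_pc_series: %d x %d slice, %d cardiac phases (%.1f ms each), venc %.3g cm/s\n",
    d[1], d[2], d[3], x$phase_duration, x$venc))
  invisible(x)
}

# Wrap phase into (-pi, pi].
wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

# Polynomial background field on normalized [-1,1]^2 coordinates.
.background_field <- function(grid_size, coef) {
  coef <- c(coef, numeric(10 - length(coef)))
  u <- if (grid_size > 1) (seq_len(grid_size) - (grid_size + 1) / 2) /
    ((grid_size - 1) / 2) else 0
  x <- matrix(u, grid_size, grid_size)        # varies along rows
  y <- matrix(u, grid_size, grid_size, byrow = TRUE)
  coef[1] + coef[2] * x + coef[3] * y + coef[4] * x^2 + coef[5] * x * y +
    coef[6] * y^2 + coef[7] * x^3 + coef[8] * x^2 * y +
    coef[9] * x * y^2 + coef[10] * y^3
}

#' Render a synthetic phase-contrast scene
#'
#' Generates the per-cardiac-phase magnitude and phase images for a vessel
#' population, together with the full ground truth. The phase image at voxel
#' v and cardiac phase t is
#' \code{wrap(background(v) + pi * velocity(v, t) / venc + noise)} with
#' \code{velocity(v, t) = volume_fraction * (mean_speed + pulse_amplitude *
#' template(t - lag))}; speeds beyond venc therefore wrap, as in the
#' acquisition. Magnitude is elevated in vessel voxels with a compressive
#' response in \code{volume_fraction * |velocity|} (saturating at venc), so
#' that all vessel classes are conspicuous above the mean + 2 SD threshold
#' at the default contrast.
#'
#' @param config a \code{\link{scene_config}}.
#' @return list with elements \code{series} (a
#'   \code{\link{gated_pc_series}}) and \code{truth} (class
#'   \code{scene_truth}: \code{label_image}, \code{class_table},
#'   \code{true_waveforms} one row per vessel, \code{true_lags} in ms).
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  G <- config$grid_size
  N <- config$n_phases
  npix <- G * G
  nv <- length(config$vessels)

  # voxel lists and overlap check
  vox <- vector("list", nv)
  for (i in seq_len(nv)) {
    v <- config$vessels[[i]]
    rr <- v$center[1] + v$footprint[, 1]
    cc <- v$center[2] + v$footprint[, 2]
    if (any(rr < 1 | rr > G | cc < 1 | cc > G)) {
      stop("vessel ", i, " extends outside the grid")
    }
    vox[[i]] <- (cc - 1L) * G + rr
  }
  allvox <- unlist(vox)
  if (anyDuplicated(allvox)) stop("vessel footprints overlap")

  # noiseless voxel velocities and truth waveforms
  tt <- seq_len(N) - 1
  vel <- matrix(0, npix, N)
  true_wave <- matrix(0, nv, N)
  for (i in seq_len(nv)) {
    v <- config$vessels[[i]]
    lag_samples <- v$lag_ms / config$phase_duration
    tmpl <- .pulse_eval(tt - lag_samples, N, config$n_harmonics)
    if (config$gating_smooth > 1) {
      tmpl <- .circ_smooth(tmpl, config$gating_smooth)
    }
    w <- v$volume_fraction * (v$mean_speed + v$pulse_amplitude * tmpl)
    true_wave[i, ] <- w
    vel[vox[[i]], ] <- matrix(w, length(vox[[i]]), N, byrow = TRUE)
  }

  bg <- as.vector(.background_field(G, config$background_coef))
  phase_clean <- bg + pi * vel / config$venc
  mag_clean <- config$mag_base + config$mag_gain *
    (pmin(abs(vel), config$venc) / config$venc)^(1 / 3)

  out <- with_seed(config$seed, {
    ph <- phase_clean
    mg <- mag_clean
    if (config$noise_sd_phase > 0) {
      ph <- ph + rnorm(npix * N, sd = config$noise_sd_phase)
    }
    if (config$noise_sd_mag > 0) {
      mg <- mg + rnorm(npix * N, sd = config$noise_sd_mag)
    }
    list(ph = wrap_phase(ph), mg = pmax(mg, 0))
  })

  series <- gated_pc_series(array(out$mg, c(G, G, N)),
                            array(out$ph, c(G, G, N)),
                            venc = config$venc,
                            phase_duration = config$phase_duration,
                            voxel_size = config$voxel_size)

  label <- matrix(0L, G, G)
  for (i in seq_len(nv)) label[vox[[i]]] <- i
  class_table <- data.frame(
    cluster = seq_len(nv),
    class_label = vapply(config$vessels, `[[`, "", "class_label"),
    territory = vapply(config$vessels, `[[`, "", "territory"),
    size = vapply(vox, length, 0L),
    mean_speed = vapply(config$vessels, `[[`, 0, "mean_speed"),
    pulse_amplitude = vapply(config$vessels, `[[`, 0, "pulse_amplitude"),
    lag_ms = vapply(config$vessels, `[[`, 0, "lag_ms"),
    volume_fraction = vapply(config$vessels, `[[`, 0, "volume_fraction"),
    stringsAsFactors = FALSE)
  truth <- structure(list(label_image = label, class_table = class_table,
                          true_waveforms = true_wave,
                          true_lags = class_table$lag_ms),
                     class = "scene_truth")
  list(series = series, truth = truth)
}

# circular uniform smoothing of a periodic sequence (prospective-gating blur)
.circ_smooth <- function(x, width) {
  n <- length(x)
  hw <- (width - 1) / 2
  out <- numeric(n)
  for (d in -hw:hw) out <- out + x[((seq_len(n) - 1 + d) %% n) + 1]
  out / width
}
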