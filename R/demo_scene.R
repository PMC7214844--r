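# Study-condition scene and cohort builders. The defaults here define the
# synthetic analogue of the acquisition the package targets: vein clusters of
# 1-30 voxels with slow (< 2 cm/s) superior-to-inferior flow, a bright
# sagittal-sinus blob and arteries whose speeds exceed venc (so their phase
# wraps), cardiac-locked pulse waveforms with a ~60 ms venous delay, a smooth
# background phase field, and additive Gaussian noise.

# territory from grid position: anterior third ACA, posterior third PCA,
# middle split left/right MCA
.territory_of <- function(center, grid_size) {
  r <- center[1]; c <- center[2]
  if (r < grid_size / 3) return("ACA")
  if (r > 2 * grid_size / 3) return("PCA")
  if (c <= grid_size / 2) "L_MCA" else "R_MCA"
}

# Rejection-sample non-overlapping vessel placements (1-voxel margin).
.place_vessels <- function(protos, grid_size, occupied = NULL) {
  if (is.null(occupied)) occupied <- matrix(FALSE, grid_size, grid_size)
  out <- vector("list", length(protos))
  for (i in seq_along(protos)) {
    p <- protos[[i]]
    fp <- p$footprint
    for (attempt in 1:200) {
      center <- c(sample(6:(grid_size - 6), 1), sample(6:(grid_size - 6), 1))
      rr <- center[1] + fp[, 1]
      cc <- center[2] + fp[, 2]
      if (any(rr < 3 | rr > grid_size - 2 | cc < 3 | cc > grid_size - 2)) next
      # check the footprint plus a 1-voxel dilation ring
      box <- cbind(rep(rr, each = 9) + rep(-1:1, times = 3 * length(rr)),
                   rep(cc, each = 9) + rep(rep(-1:1, each = 3), length(cc)))
      if (any(occupied[box])) next
      occupied[cbind(rr, cc)] <- TRUE
      p$center <- center
      if (is.na(p$territory)) p$territory <- .territory_of(center, grid_size)
      out[[i]] <- p
      break
    }
    if (is.null(out[[i]])) stop("could not place vessel ", i, "; grid too full")
  }
  out
}

#' Default synthetic scene mimicking one subject's acquisition
#'
#' Draws a vessel population with paper-like composition: small cortical
#' veins (1-8 voxels, 0.8-2 cm/s), larger surface veins (2-20 voxels,
#' 1-2.5 cm/s), arteries whose speed exceeds venc so that their phase wraps,
#' and a superior sagittal sinus blob near the posterior edge serving as the
#' timing reference (lag 0). Veins are delayed by \code{vein_lag_ms} (plus
#' per-vessel jitter) relative to the sinus; arteries by
#' \code{artery_lag_ms}.
#'
#' @param seed RNG seed controlling both the vessel draw and the rendered
#'   noise.
#' @param n_small_veins,n_surface_veins,n_arteries vessel counts.
#' @param vein_lag_ms,artery_lag_ms mean injected lags (ms).
#' @param grid_size,n_phases,noise_sd_phase passed to
#'   \code{\link{scene_config}}.
#' @param ... further arguments forwarded to \code{\link{scene_config}}.
#' @return a \code{\link{scene_config}}.
#' @export
demo_scene_config <- function(seed = 1, n_small_veins = 8,
                              n_surface_veins = 4, n_arteries = 3,
                              vein_lag_ms = 60, artery_lag_ms = 0,
                              grid_size = 64, n_phases = 38,
                              noise_sd_phase = 0.05, ...) {
  with_seed(seed, {
    protos <- list()
    # sinus: 20+ voxel blob, posterior, flow faster than venc (wraps);
    # redraw until compact enough to sit near the posterior edge
    repeat {
      sinus_fp <- random_footprint(22)
      if (max(abs(sinus_fp)) <= 7) break
    }
    protos[[1]] <- list(
      footprint = sinus_fp, class_label = "sinus", territory = "none",
      mean_speed = -12, pulse_amplitude = 2.5, lag_ms = 0,
      volume_fraction = 1)
    for (i in seq_len(n_arteries)) {
      protos[[length(protos) + 1]] <- list(
        footprint = random_footprint(sample(2:8, 1)),
        class_label = "artery", territory = NA,
        mean_speed = runif(1, 11, 15),
        pulse_amplitude = runif(1, 2, 4),
        lag_ms = artery_lag_ms + rnorm(1, sd = 10),
        volume_fraction = 1)
    }
    for (i in seq_len(n_surface_veins)) {
      speed <- runif(1, 1, 2.5)
      protos[[length(protos) + 1]] <- list(
        footprint = random_footprint(sample(2:20, 1)),
        class_label = "surface_vein", territory = NA,
        mean_speed = -speed, pulse_amplitude = 0.3 * speed,
        lag_ms = vein_lag_ms + rnorm(1, sd = 10),
        volume_fraction = runif(1, 0.8, 1))
    }
    for (i in seq_len(n_small_veins)) {
      speed <- runif(1, 0.8, 2)
      protos[[length(protos) + 1]] <- list(
        footprint = random_footprint(sample(1:8, 1, prob = 8:1)),
        class_label = "small_vein", territory = NA,
        mean_speed = -speed, pulse_amplitude = 0.3 * speed,
        lag_ms = vein_lag_ms + rnorm(1, sd = 10),
        volume_fraction = runif(1, 0.6, 1))
    }
    # place the sinus by hand near the posterior (high-row) edge, and mark
    # its footprint (plus margin) occupied before placing the rest
    sinus <- protos[[1]]
    sinus$center <- c(grid_size - 8, round(grid_size / 2))
    occupied <- matrix(FALSE, grid_size, grid_size)
    srr <- sinus$center[1] + sinus$footprint[, 1]
    scc <- sinus$center[2] + sinus$footprint[, 2]
    for (dr in -1:1) for (dc in -1:1) {
      occupied[cbind(pmin(pmax(srr + dr, 1), grid_size),
                     pmin(pmax(scc + dc, 1), grid_size))] <- TRUE
    }
    placed <- .place_vessels(protos[-1], grid_size, occupied)
    vessels <- lapply(c(list(sinus), placed), function(p) {
      vessel_spec(center = p$center, footprint = p$footprint,
                  class_label = p$class_label, territory = p$territory,
                  mean_speed = p$mean_speed,
                  pulse_amplitude = p$pulse_amplitude,
                  lag_ms = p$lag_ms, volume_fraction = p$volume_fraction)
    })
    scene_config(vessels = vessels, grid_size = grid_size,
                 n_phases = n_phases, noise_sd_phase = noise_sd_phase,
                 background_coef = c(0.3, 0.2, -0.15, 0.05, 0.04,
                                     -0.05, 0.01, 0, -0.01, 0.02),
                 seed = seed, ...)
  })
}

#' Simulate a cohort of subjects
#'
#' Builds one \code{\link{scene_config}} per subject with between-subject
#' variability in vessel counts, cardiac sampling, and injected lags: the
#' subject-level mean vein delay is drawn from N(\code{vein_lag_ms}, 15 ms)
#' and the artery delay from N(\code{artery_lag_ms}, 20 ms), mirroring a
#' cohort in which veins are systematically delayed relative to the sinus
#' and arteries are not.
#'
#' @param n_subjects number of subjects.
#' @param seed master RNG seed; per-subject seeds are derived from it.
#' @param vein_lag_ms,artery_lag_ms cohort-mean injected lags (ms).
#' @param ... forwarded to \code{\link{demo_scene_config}}.
#' @return named list of \code{scene_config} objects, one per subject.
#' @export
simulate_cohort <- function(n_subjects = 8, seed = 1, vein_lag_ms = 60,
                            artery_lag_ms = 0, ...) {
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1, n_subjects)
    sub_lag <- rnorm(n_subjects, vein_lag_ms, 15)
    art_lag <- rnorm(n_subjects, artery_lag_ms, 20)
    n_small <- sample(6:10, n_subjects, replace = TRUE)
    n_surface <- sample(3:5, n_subjects, replace = TRUE)
    n_ph <- sample(33:45, n_subjects, replace = TRUE)
    configs <- lapply(seq_len(n_subjects), function(i) {
      demo_scene_config(seed = sub_seeds[i], n_small_veins = n_small[i],
                        n_surface_veins = n_surface[i],
                        vein_lag_ms = sub_lag[i], artery_lag_ms = art_lag[i],
                        n_phases = n_ph[i], ...)
    })
    names(configs) <- sprintf("sub-%02d", seq_len(n_subjects))
    configs
  })
}
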