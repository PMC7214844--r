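# Independent oracles, coded from first principles and kept separate from
# the package's computational paths.

# Savitzky-Golay central kernel by explicit least squares: the row of the
# hat matrix evaluating the order-p fit at the window center.
ls_sg_kernel <- function(order = 3, frame = 15) {
  hw <- (frame - 1) / 2
  A <- outer(-hw:hw, 0:order, "^")
  as.numeric(A %*% solve(crossprod(A)))[seq_len(frame)]
}

# Brute-force Savitzky-Golay smoothing: per-timepoint polynomial fits.
# edgefit: interior points use a centered window fit evaluated at 0; the
# first/last half-frames re-use the first/last full window's fit evaluated
# at their off-center positions. circular: centered fit on the wrapped
# window.
brute_sg_smooth <- function(v, order = 3, frame = 15,
                            boundary = c("edgefit", "circular")) {
  boundary <- match.arg(boundary)
  n <- length(v)
  hw <- (frame - 1) / 2
  fit_eval <- function(y, at) {
    A <- outer(-hw:hw, 0:order, "^")
    beta <- solve(crossprod(A), crossprod(A, y))
    as.numeric(outer(at, 0:order, "^") %*% beta)
  }
  out <- numeric(n)
  if (boundary == "circular") {
    for (t in seq_len(n)) {
      idx <- ((t - 1 + (-hw:hw)) %% n) + 1
      out[t] <- fit_eval(v[idx], 0)
    }
  } else {
    for (t in (hw + 1):(n - hw)) out[t] <- fit_eval(v[(t - hw):(t + hw)], 0)
    out[1:hw] <- fit_eval(v[1:frame], -hw:-1)
    out[(n - hw + 1):n] <- fit_eval(v[(n - frame + 1):n], 1:hw)
  }
  out
}

# Brute-force PCNR per its definition: range of the filtered curve over the
# (N-1)-normalized residual SD.
brute_pcnr <- function(v, order = 3, frame = 15, boundary = "edgefit") {
  f <- brute_sg_smooth(v, order, frame, boundary)
  dv <- max(f) - min(f)
  rs <- sqrt(sum((v - f)^2) / (length(v) - 1))
  if (rs == 0) {
    if (dv > 0) Inf else 0
  } else {
    dv / rs
  }
}

# Connected components under 8-adjacency by iterative label relaxation:
# every voxel starts with a unique label and repeatedly takes the minimum
# label in its 8-neighborhood until a fixed point. Returns the partition as
# a canonical list of sorted voxel-index vectors.
flood_fill_partition <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (mask[ii, jj] && lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  parts <- split(which(mask), lab[mask])
  unname(lapply(parts, sort))
}

# canonical partition of a vessel_cluster_map, for comparison with the oracle
map_partition <- function(map) {
  parts <- lapply(map$voxels, sort)
  parts[order(vapply(parts, min, 0L))]
}

# exhaustive circular cross-correlation argmax (independent of temporal_lag)
brute_lag <- function(x, y) {
  N <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  lags <- (-floor(N / 2)):(ceiling(N / 2) - 1)
  r <- sapply(lags, function(l) sum(xc * yc[((seq_len(N) - 1 - l) %% N) + 1]))
  cand <- lags[r == max(r)]
  cand[order(abs(cand), cand < 0)][1]
}

# a small single-vein + sinus scene used by velocimetry/lag tests
lag_scene_config <- function(seed, lag_samples, noise_sd_phase = 0.02,
                             vein_size = 4) {
  set.seed(seed)
  vein <- vessel_spec(c(15, 15), random_footprint(vein_size), "small_vein",
                      territory = "ACA", mean_speed = -1.5,
                      pulse_amplitude = 0.45,
                      lag_ms = lag_samples * 23.1, volume_fraction = 1)
  sinus <- vessel_spec(c(32, 20), random_footprint(22), "sinus",
                       mean_speed = -12, pulse_amplitude = 2.5, lag_ms = 0)
  scene_config(list(vein, sinus), grid_size = 40,
               noise_sd_phase = noise_sd_phase,
               background_coef = c(0.3, 0.2, -0.15, 0.05, 0.04, -0.05,
                                   0.01, 0, -0.01, 0.02),
               seed = seed + 1000L)
}
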