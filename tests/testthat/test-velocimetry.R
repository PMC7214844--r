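test_that("median filter removes a constant background exactly", {
  ph <- array(0.7, c(40, 40, 3))
  out <- remove_background_phase(ph, window = 17)
  expect_equal(max(abs(out)), 0)
})

test_that("median filter window preconditions are enforced", {
  ph <- array(0, c(2, 2, 3))
  expect_error(remove_background_phase(ph, window = 3), "larger than image")
  expect_error(remove_background_phase(array(0, c(40, 40, 2)), window = 4),
               "odd")
  expect_error(remove_background_phase(array(0, c(40, 40, 2)), window = 1),
               "odd")
})

test_that("vessel phase survives background removal on a constant offset", {
  ph <- matrix(0.9, 40, 40)
  vess <- cbind(c(20, 20, 21), c(20, 21, 20))
  ph[vess] <- ph[vess] + c(0.5, 0.6, 0.4)
  out <- remove_background_phase(ph, window = 17)
  # 3 vessel voxels never dominate a 289-voxel window: median = background
  expect_equal(out[vess], c(0.5, 0.6, 0.4), tolerance = 1e-12)
})

test_that("vessel phase is nearly preserved on a smooth linear background", {
  G <- 40
  u <- (seq_len(G) - (G + 1) / 2) / ((G - 1) / 2)
  bg <- 0.3 + 0.2 * matrix(u, G, G) - 0.15 * matrix(u, G, G, byrow = TRUE)
  ph <- bg
  vess <- cbind(c(20, 20, 21), c(20, 21, 20))
  ph[vess] <- ph[vess] + 0.5
  out <- remove_background_phase(ph, window = 17)
  # the window median tracks the plane up to a few sorted-value spacings
  expect_lt(max(abs(out[vess] - 0.5)), 0.01)
})

test_that("temporal unwrapping recovers a wrapped linear ramp", {
  ramp <- seq(0, 3 * pi, length.out = 20)
  wrapped <- ramp - 2 * pi * ceiling((ramp - pi) / (2 * pi))
  un <- unwrap_temporal(matrix(wrapped, 1))
  expect_equal(as.numeric(un), ramp, tolerance = 1e-9)
})

test_that("temporal unwrapping is the identity without jumps", {
  x <- c(0, 0.5, -0.5, 0.2, 0.9)  # successive differences all <= pi
  expect_equal(as.numeric(unwrap_temporal(matrix(x, 1))), x)
  expect_equal(as.numeric(unwrap_temporal(matrix(1.2, 1, 6))), rep(1.2, 6))
  expect_error(unwrap_temporal(matrix(0, 3, 1)), "at least 2")
})

test_that("cluster waveform scales phase by venc/pi", {
  ph <- matrix(pi, 1, 38)  # single voxel, constant phase pi
  w <- cluster_waveform(ph, 1, venc = 10, phase_duration = 23.1)
  expect_equal(w$values, rep(10, 38))
  # symmetric phases average to zero velocity
  ph2 <- rbind(rep(0.4, 38), rep(-0.4, 38))
  w2 <- cluster_waveform(ph2, 1:2, venc = 10, phase_duration = 23.1)
  expect_equal(w2$values, rep(0, 38))
  expect_error(cluster_waveform(ph, integer(0), 10, 23.1), "empty")
  expect_error(cluster_waveform(ph, 1, -1, 23.1), "venc")
})

test_that("velocity output is linear in venc", {
  set.seed(8)
  ph <- matrix(rnorm(5 * 38, sd = 0.3), 5, 38)
  w1 <- cluster_waveform(ph, 1:5, venc = 10, phase_duration = 23.1)
  w3 <- cluster_waveform(ph, 1:5, venc = 30, phase_duration = 23.1)
  expect_equal(w3$values, 3 * w1$values, tolerance = 1e-12)
})

test_that("sinus spatial unwrap subtracts 2 pi from positive-phase voxels", {
  G <- 40; N <- 16
  ph <- array(0, c(G, G, N))
  mag <- array(10, c(G, G, N))
  vox <- cbind(c(20, 21, 22), 20)
  vals <- c(-0.9 * pi, -0.9 * pi, 0.9 * pi)
  for (t in seq_len(N)) {
    sl <- ph[, , t]; sl[vox] <- vals; ph[, , t] <- sl
    ms <- mag[, , t]; ms[vox] <- 100; mag[, , t] <- ms
  }
  s <- gated_pc_series(mag, ph, venc = 10, phase_duration = 23.1)
  region <- (vox[, 2] - 1) * G + vox[, 1]
  expect_warning(w <- sinus_waveform(s, region), "fewer than")
  # hand oracle: third voxel becomes -1.1*pi; median is -0.9*pi -> -9 cm/s
  expect_equal(w$values, rep(-9, N), tolerance = 1e-12)
  expect_error(sinus_waveform(s, integer(0)), "empty")
})

test_that("sinus pathway with all-negative phases skips the spatial shift", {
  G <- 40; N <- 16
  ph <- array(0, c(G, G, N))
  mag <- array(10, c(G, G, N))
  vox <- cbind(20:22, 20)
  for (t in seq_len(N)) {
    sl <- ph[, , t]; sl[vox] <- -0.5 * pi; ph[, , t] <- sl
    ms <- mag[, , t]; ms[vox] <- 100; mag[, , t] <- ms
  }
  s <- gated_pc_series(mag, ph, venc = 10, phase_duration = 23.1)
  region <- (vox[, 2] - 1) * G + vox[, 1]
  expect_warning(w <- sinus_waveform(s, region))
  expect_equal(w$values, rep(-5, N), tolerance = 1e-12)
})

test_that("sinus waveform preserves the timing of the injected pulse", {
  cfg <- lag_scene_config(seed = 31, lag_samples = 0, noise_sd_phase = 0.01)
  sc <- render_scene(cfg)
  map <- annotate_clusters(
    label_clusters(threshold_mask(time_average_magnitude(sc$series))),
    ref_labels = sc$truth$label_image, ref_classes = sc$truth$class_table)
  wf <- extract_waveforms(sc$series, map)
  sid <- which(sc$truth$class_table$class_label == "sinus")
  injected <- sc$truth$true_waveforms[sid, ]
  ref <- wf$reference
  # argmax cardiac phase matches the injected sinus waveform within 1 phase
  lag <- temporal_lag(velocity_waveform(injected, 23.1), ref)
  expect_lte(abs(lag$lag_samples), 1)
})

test_that("waveform extraction follows the filter-then-unwrap order", {
  # a phase series whose unwrap result differs by order: wrapping ramp on a
  # large constant background; filtering first removes the background so no
  # spurious jumps are introduced at the vessel
  cfg <- lag_scene_config(seed = 32, lag_samples = 2, noise_sd_phase = 0)
  sc <- render_scene(cfg)
  corrected <- unwrap_temporal(remove_background_phase(sc$series$phase))
  map <- annotate_clusters(
    label_clusters(threshold_mask(time_average_magnitude(sc$series))),
    ref_labels = sc$truth$label_image, ref_classes = sc$truth$class_table)
  wf <- extract_waveforms(sc$series, map)
  vid <- map$clusters$id[map$clusters$class_label == "small_vein"]
  w2 <- cluster_waveform(corrected, map$voxels[[vid]], sc$series$venc,
                         sc$series$phase_duration)
  expect_equal(wf$waveforms[[as.character(vid)]]$values, w2$values)
})
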