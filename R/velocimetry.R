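# Phase-to-velocity conversion: background-phase removal by 2D median
# filtering, temporal phase unwrapping, cluster averaging and venc scaling,
# plus the dedicated superior-sagittal-sinus reference pathway.

#' Velocity waveform for one vessel
#'
#' @param values velocity per cardiac phase, cm/s (signed).
#' @param phase_duration ms per cardiac phase.
#' @param source_cluster originating cluster id (optional).
#' @param pathway \code{"cluster_mean"} or \code{"sinus_median"}.
#' @return object of class \code{velocity_waveform}.
#' @export
velocity_waveform <- function(values, phase_duration, source_cluster = NA,
                              pathway = c("cluster_mean", "sinus_median")) {
  pathway <- match.arg(pathway)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("waveform values must be finite")
  structure(list(values = values, n_phases = length(values),
                 phase_duration = phase_duration,
                 source_cluster = source_cluster, pathway = pathway),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf(
    "velocity_waveform (%s): %d cardiac phases x %.1f ms, mean |v| %.3g cm/s\n",
    x$pathway, x$n_phases, x$phase_duration, mean(abs(x$values))))
  invisible(x)
}

.wave_values <- function(w) if (inherits(w, "velocity_waveform")) w$values else as.numeric(w)

#' Remove background phase offsets with a 2D median filter
#'
#' Subtracts, independently for each cardiac phase, the voxelwise output of
#' a \code{window} x \code{window} median filter (reflection edge handling)
#' from the raw phase image. Sparse vessel clusters occupy well under half of
#' any filter window, so the median tracks the smooth background offset and
#' the corrected vessel phase is preserved. The corrected values may leave
#' (-pi, pi].
#'
#' @param phase 3D phase stack (x, y, cardiac phase) or 2D matrix, radians.
#' @param window odd window side length >= 3; default 17 (10 mm at 0.6 mm
#'   voxels).
#' @return corrected stack of the same shape.
#' @export
remove_background_phase <- function(phase, window = 17) {
  if (window < 3 || window %% 2 != 1) stop("window must be odd and >= 3")
  if (is.matrix(phase)) {
    if (window > min(dim(phase))) stop("window larger than image")
    return(phase - medfilt2_cpp(phase, as.integer(window)))
  }
  stopifnot(length(dim(phase)) == 3)
  if (window > min(dim(phase)[1:2])) stop("window larger than image")
  out <- phase
  for (t in seq_len(dim(phase)[3])) {
    out[, , t] <- phase[, , t] - medfilt2_cpp(phase[, , t], as.integer(window))
  }
  out
}

#' Temporal phase unwrapping
#'
#' Standard 1D unwrapping voxelwise along the cardiac-phase axis: whenever
#' successive samples differ by more than pi, the multiple of 2 pi that
#' minimizes the jump is added; the first sample is unchanged.
#'
#' @param phase 3D stack (x, y, cardiac phase) or a matrix with voxels in
#'   rows and cardiac phases in columns.
#' @return unwrapped array of the same shape.
#' @export
unwrap_temporal <- function(phase) {
  d3 <- length(dim(phase)) == 3
  if (d3) {
    dd <- dim(phase)
    m <- matrix(phase, dd[1] * dd[2], dd[3])
  } else {
    m <- as.matrix(phase)
  }
  N <- ncol(m)
  if (N < 2) stop("need at least 2 cardiac phases")
  acc <- numeric(nrow(m))
  for (t in 2:N) {
    jump <- m[, t] - m[, t - 1] + acc
    acc <- acc - 2 * pi * round(jump / (2 * pi))
    m[, t] <- m[, t] + acc
  }
  if (d3) array(m, dd) else m
}

#' Cluster-mean velocity waveform
#'
#' Averages the corrected, unwrapped phase over the cluster's voxels at each
#' cardiac phase and scales by venc / pi to convert radians to cm/s.
#'
#' @param corrected_phase unwrapped phase stack (3D array) or voxels-by-phase
#'   matrix.
#' @param voxels linear voxel indices of the cluster (into one 2D slice).
#' @param venc velocity encoding, cm/s.
#' @param phase_duration ms per cardiac phase.
#' @param cluster_id id recorded on the waveform.
#' @return a \code{\link{velocity_waveform}}.
#' @export
cluster_waveform <- function(corrected_phase, voxels, venc, phase_duration,
                             cluster_id = NA) {
  if (!length(voxels)) stop("empty cluster")
  if (venc <= 0) stop("venc must be positive")
  if (length(dim(corrected_phase)) == 3) {
    dd <- dim(corrected_phase)
    m <- matrix(corrected_phase, dd[1] * dd[2], dd[3])
  } else {
    m <- as.matrix(corrected_phase)
  }
  vals <- colMeans(m[voxels, , drop = FALSE]) * venc / pi
  velocity_waveform(vals, phase_duration, cluster_id, "cluster_mean")
}

#' Superior sagittal sinus reference waveform
#'
#' The sinus flows fast enough that its signal phase wraps several times;
#' the resulting waveform is valid for timing, not absolute speed. The
#' pathway: select the \code{n_top} voxels of highest cycle-averaged
#' magnitude within \code{sinus_region} (ties broken in scan order), apply
#' median-filter background removal and temporal unwrapping as for vessel
#' clusters, then align the wrapping point across voxels by subtracting
#' 2 pi from any voxel-timepoint with positive phase (the posterior sinus
#' encodes negative phase), take the voxelwise median across the selected
#' voxels at each cardiac phase, and scale by venc / pi.
#'
#' @param series a \code{\link{gated_pc_series}}.
#' @param sinus_region linear voxel indices delimiting the sinus; if fewer
#'   than \code{n_top} voxels, all are used with a warning.
#' @param window median-filter window (see
#'   \code{\link{remove_background_phase}}).
#' @param n_top number of brightest voxels to pool; default 20.
#' @param flow_sign -1 (default) when the sinus encodes negative phase;
#'   +1 mirrors the spatial-unwrap rule (adding 2 pi to negative voxels)
#'   for the opposite geometry.
#' @param corrected_phase optional precomputed corrected+unwrapped stack, to
#'   avoid refiltering when waveforms for many clusters are extracted.
#' @return a \code{\link{velocity_waveform}} with pathway
#'   \code{"sinus_median"}.
#' @export
sinus_waveform <- function(series, sinus_region, window = 17, n_top = 20,
                           flow_sign = -1, corrected_phase = NULL) {
  stopifnot(inherits(series, "gated_pc_series"))
  if (!length(sinus_region)) stop("empty sinus region")
  avg <- time_average_magnitude(series)
  if (length(sinus_region) < n_top) {
    warning("sinus region has fewer than ", n_top, " voxels; using all")
    top <- sinus_region
  } else {
    ord <- order(-avg[sinus_region], sinus_region)
    top <- sinus_region[ord[seq_len(n_top)]]
  }
  if (is.null(corrected_phase)) {
    corrected_phase <- unwrap_temporal(remove_background_phase(series$phase,
                                                               window))
  }
  dd <- dim(corrected_phase)
  m <- matrix(corrected_phase, dd[1] * dd[2], dd[3])[top, , drop = FALSE]
  if (flow_sign < 0) {
    m[m > 0] <- m[m > 0] - 2 * pi
  } else {
    m[m < 0] <- m[m < 0] + 2 * pi
  }
  vals <- apply(m, 2, median) * series$venc / pi
  velocity_waveform(vals, series$phase_duration, NA, "sinus_median")
}

#' Extract velocity waveforms for all clusters
#'
#' Runs the full velocimetry path (median-filter background removal,
#' temporal unwrapping, cluster averaging, venc scaling) for every cluster
#' in the map, and the sinus reference pathway for clusters annotated as
#' \code{"sinus"}.
#'
#' @param series a \code{\link{gated_pc_series}}.
#' @param map an annotated \code{vessel_cluster_map}.
#' @param window median-filter window.
#' @return list with \code{waveforms} (one \code{velocity_waveform} per
#'   cluster, named by id) and \code{reference} (sinus waveform, or NULL if
#'   no sinus cluster is annotated).
#' @export
extract_waveforms <- function(series, map, window = 17) {
  stopifnot(inherits(series, "gated_pc_series"),
            inherits(map, "vessel_cluster_map"))
  corrected <- unwrap_temporal(remove_background_phase(series$phase, window))
  waveforms <- lapply(map$clusters$id, function(i) {
    cluster_waveform(corrected, map$voxels[[i]], series$venc,
                     series$phase_duration, i)
  })
  names(waveforms) <- map$clusters$id
  reference <- NULL
  sinus_ids <- map$clusters$id[!is.na(map$clusters$class_label) &
                                 map$clusters$class_label == "sinus"]
  if (length(sinus_ids)) {
    region <- unlist(map$voxels[sinus_ids])
    reference <- sinus_waveform(series, region, window = window,
                                corrected_phase = corrected)
  }
  list(waveforms = waveforms, reference = reference)
}

#' Waveform table in long format
#'
#' @param waveforms list of \code{velocity_waveform} objects.
#' @return data frame with cluster id, cardiac phase index, time in ms, and
#'   velocity in cm/s.
#' @export
waveform_table <- function(waveforms) {
  do.call(rbind, lapply(waveforms, function(w) {
    data.frame(cluster = w$source_cluster,
               cardiac_phase = seq_len(w$n_phases),
               time_ms = (seq_len(w$n_phases) - 1) * w$phase_duration,
               velocity = w$values)
  }))
}
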