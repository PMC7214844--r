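# File interfaces: NIfTI image stacks (RNifti), tab-separated tables, and
# YAML configuration. Images are written at double precision so that
# pipelines round-trip through disk without loss.

#' Write a gated series to NIfTI
#'
#' @param series a \code{\link{gated_pc_series}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (magnitude, phase, metadata YAML).
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "gated_pc_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("magnitude.nii.gz", "phase.nii.gz",
                            "series.yaml"))
  RNifti::writeNifti(series$magnitude, paths[1], datatype = "double")
  RNifti::writeNifti(series$phase, paths[2], datatype = "double")
  yaml::write_yaml(list(venc = series$venc,
                        phase_duration = series$phase_duration,
                        n_phases = series$n_phases,
                        voxel_size = series$voxel_size), paths[3])
  invisible(paths)
}

#' Read a gated series from NIfTI
#'
#' @param magnitude,phase NIfTI paths of the 3D (x, y, cardiac phase)
#'   stacks.
#' @param venc,phase_duration,voxel_size acquisition metadata; read from
#'   \code{meta} when NULL.
#' @param meta optional path of a metadata YAML written by
#'   \code{\link{write_series}}.
#' @return a \code{\link{gated_pc_series}}.
#' @export
read_series <- function(magnitude, phase, venc = NULL, phase_duration = NULL,
                        voxel_size = NULL, meta = NULL) {
  if (!is.null(meta)) {
    m <- yaml::read_yaml(meta)
    if (is.null(venc)) venc <- m$venc
    if (is.null(phase_duration)) phase_duration <- m$phase_duration
    if (is.null(voxel_size)) voxel_size <- m$voxel_size
  }
  if (is.null(voxel_size)) voxel_size <- 0.6
  plain <- function(path) {
    x <- RNifti::readNifti(path)
    array(as.numeric(x), dim(x))
  }
  gated_pc_series(plain(magnitude), plain(phase),
                  venc = venc, phase_duration = phase_duration,
                  voxel_size = voxel_size)
}

#' Write scene ground truth
#'
#' Writes the truth label image as NIfTI and the class table and true
#' waveforms as tab-separated tables.
#'
#' @param truth a \code{scene_truth} (see \code{\link{render_scene}}).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_scene_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("truth_labels.nii.gz", "truth_classes.tsv",
                            "truth_waveforms.tsv"))
  RNifti::writeNifti(truth$label_image, paths[1], datatype = "int32")
  write_tsv(truth$class_table, paths[2])
  wf <- as.data.frame(truth$true_waveforms)
  names(wf) <- paste0("t", seq_len(ncol(wf)))
  write_tsv(cbind(cluster = truth$class_table$cluster, wf), paths[3])
  invisible(paths)
}

#' Write a cluster map
#'
#' @param map a \code{vessel_cluster_map}.
#' @param dir output directory.
#' @return invisibly, the paths written (label NIfTI, cluster TSV).
#' @export
write_cluster_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cluster_labels.nii.gz", "clusters.tsv"))
  RNifti::writeNifti(map$label_image, paths[1], datatype = "int32")
  write_tsv(map$clusters, paths[2])
  invisible(paths)
}

#' Write a data frame as tab-separated values
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-separated table
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize a scene configuration to YAML
#'
#' @param config a \code{\link{scene_config}}.
#' @param path output path.
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  lst <- unclass(config)
  lst$vessels <- lapply(lst$vessels, function(v) {
    v <- unclass(v)
    v$center <- as.integer(v$center)
    v$footprint <- apply(v$footprint, 1, function(r) as.integer(r),
                         simplify = FALSE)
    v
  })
  yaml::write_yaml(lst, path, precision = 15)
}

#' Read a scene configuration from YAML
#'
#' @param path YAML path written by \code{\link{write_scene_config}}.
#' @return a \code{\link{scene_config}}.
#' @export
read_scene_config <- function(path) {
  lst <- yaml::read_yaml(path)
  vessels <- lapply(lst$vessels, function(v) {
    vessel_spec(center = v$center,
                footprint = do.call(rbind, v$footprint),
                class_label = v$class_label, territory = v$territory,
                mean_speed = v$mean_speed,
                pulse_amplitude = v$pulse_amplitude,
                lag_ms = v$lag_ms, volume_fraction = v$volume_fraction)
  })
  scene_config(vessels = vessels, grid_size = lst$grid_size,
               n_phases = lst$n_phases,
               phase_duration = lst$phase_duration, venc = lst$venc,
               background_coef = if (length(lst$background_coef))
                 as.numeric(lst$background_coef) else numeric(10),
               noise_sd_phase = lst$noise_sd_phase,
               noise_sd_mag = lst$noise_sd_mag, mag_base = lst$mag_base,
               mag_gain = lst$mag_gain, n_harmonics = lst$n_harmonics,
               gating_smooth = lst$gating_smooth,
               voxel_size = lst$voxel_size, seed = lst$seed)
}
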