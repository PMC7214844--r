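# Vessel segmentation from the cycle-averaged pcMRI magnitude image:
# mean + k*SD thresholding, then 8-connected component labeling.

#' Cardiac-cycle-averaged magnitude image
#'
#' @param series a \code{\link{gated_pc_series}}.
#' @return 2D matrix: voxelwise arithmetic mean of the magnitude stack over
#'   cardiac phases.
#' @export
time_average_magnitude <- function(series) {
  stopifnot(inherits(series, "gated_pc_series"))
  rowMeans(series$magnitude, dims = 2)
}

#' Threshold an image at mean + k standard deviations
#'
#' Selects voxels strictly brighter than \code{mean + k * SD}, the criterion
#' used to pick out small blood vessels from the cycle-averaged magnitude
#' image. Statistics are computed over \code{roi} when given (e.g. a brain
#' mask), otherwise over the whole image; the returned mask is restricted to
#' the ROI in that case.
#'
#' @param image 2D numeric matrix.
#' @param k SD multiplier (> 0); default 2.
#' @param roi optional logical matrix of the same shape.
#' @return logical matrix.
#' @export
threshold_mask <- function(image, k = 2, roi = NULL) {
  stopifnot(is.matrix(image), k > 0)
  if (is.null(roi)) {
    vals <- image
    mask <- image > mean(vals) + k * sd(vals)
  } else {
    stopifnot(identical(dim(roi), dim(image)))
    if (!any(roi)) stop("roi is empty")
    vals <- image[roi]
    mask <- image > mean(vals) + k * sd(vals)
    mask <- mask & roi
  }
  mask
}

#' Label 8-connected clusters in a binary mask
#'
#' Groups super-threshold voxels into vessel clusters: a voxel joins the same
#' cluster as any of its eight immediately or diagonally adjacent voxels that
#' are also in the mask. Cluster ids are assigned consecutively from 1 in
#' scan order (column-major) of each component's first-encountered voxel, so
#' labeling is deterministic.
#'
#' @param mask logical matrix.
#' @return object of class \code{vessel_cluster_map}: \code{label_image}
#'   (integer matrix, 0 = background), \code{clusters} (data frame with
#'   \code{id}, \code{size}, \code{class_label}, \code{territory}), and
#'   \code{voxels} (list of linear voxel index vectors per cluster).
#' @export
label_clusters <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  voxels <- list()
  next_id <- 0L
  todo <- which(mask)
  for (p in todo) {
    if (lab[p] > 0L) next
    next_id <- next_id + 1L
    comp <- integer(0)
    queue <- p
    lab[p] <- next_id
    while (length(queue)) {
      q <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, q)
      qi <- (q - 1L) %% nr + 1L
      qj <- (q - 1L) %/% nr + 1L
      for (dj in -1:1) {
        jj <- qj + dj
        if (jj < 1L || jj > nc) next
        for (di in -1:1) {
          ii <- qi + di
          if (ii < 1L || ii > nr || (di == 0L && dj == 0L)) next
          nb <- (jj - 1L) * nr + ii
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- next_id
            queue <- c(queue, nb)
          }
        }
      }
    }
    voxels[[next_id]] <- sort(comp)
  }
  clusters <- data.frame(
    id = seq_len(next_id),
    size = if (next_id) vapply(voxels, length, 0L) else integer(0),
    class_label = rep(NA_character_, next_id),
    territory = rep("none", next_id),
    stringsAsFactors = FALSE)
  structure(list(label_image = lab, clusters = clusters, voxels = voxels),
            class = "vessel_cluster_map")
}

#' @export
print.vessel_cluster_map <- function(x, ...) {
  cat(sprintf("vessel_cluster_map: %d clusters on a %d x %d grid\n",
              nrow(x$clusters), nrow(x$label_image), ncol(x$label_image)))
  if (!all(is.na(x$clusters$class_label))) {
    print(table(x$clusters$class_label, useNA = "no"))
  }
  invisible(x)
}

#' Attach vessel class and territory annotations to clusters
#'
#' Stands in for manual vessel classification: annotations come either from
#' a \code{legend} keyed by cluster id, or from a reference label image with
#' its own class table (e.g. the scene truth, or a manually drawn map) that
#' is intersected with the clusters. A cluster overlapping reference vessels
#' of two different classes, or no reference vessel at all, is set to
#' \code{"discard"}.
#'
#' @param map a \code{\link{label_clusters}} result.
#' @param legend data frame with columns \code{id}, \code{class_label} and
#'   optionally \code{territory}, keyed by cluster id.
#' @param ref_labels integer matrix: reference vessel label image.
#' @param ref_classes data frame with \code{cluster}, \code{class_label} and
#'   optionally \code{territory} rows for each reference label.
#' @return the map with \code{class_label} and \code{territory} filled in.
#' @export
annotate_clusters <- function(map, legend = NULL, ref_labels = NULL,
                              ref_classes = NULL) {
  stopifnot(inherits(map, "vessel_cluster_map"))
  ok_classes <- c(.vessel_classes, "discard")
  if (!is.null(legend)) {
    if (!all(legend$class_label %in% ok_classes)) {
      stop("unknown class names in legend")
    }
    idx <- match(legend$id, map$clusters$id)
    if (anyNA(idx)) stop("legend refers to unknown cluster ids")
    map$clusters$class_label[idx] <- legend$class_label
    if (!is.null(legend$territory)) {
      map$clusters$territory[idx] <- legend$territory
    }
    return(map)
  }
  stopifnot(!is.null(ref_labels), !is.null(ref_classes))
  if (!all(ref_classes$class_label %in% ok_classes)) {
    stop("unknown class names in reference table")
  }
  for (i in map$clusters$id) {
    hit <- ref_labels[map$voxels[[i]]]
    hit <- hit[hit > 0L]
    if (!length(hit)) {
      map$clusters$class_label[i] <- "discard"
      next
    }
    rows <- match(unique(hit), ref_classes$cluster)
    cls <- unique(ref_classes$class_label[rows])
    if (length(cls) > 1L) {
      map$clusters$class_label[i] <- "discard"
    } else {
      map$clusters$class_label[i] <- cls
      if (!is.null(ref_classes$territory)) {
        # majority-overlap territory
        terr <- ref_classes$territory[match(hit, ref_classes$cluster)]
        map$clusters$territory[i] <- names(sort(table(terr),
                                                decreasing = TRUE))[1]
      }
    }
  }
  map
}

#' Per-class cluster size summary
#'
#' @param map annotated \code{vessel_cluster_map}.
#' @return data frame per class: number of clusters, median size, and 10th
#'   and 90th percentiles (linear interpolation). Classes without clusters
#'   are omitted.
#' @export
cluster_size_summary <- function(map) {
  stopifnot(inherits(map, "vessel_cluster_map"))
  cl <- map$clusters
  cl <- cl[!is.na(cl$class_label) & cl$class_label != "discard", ]
  if (!nrow(cl)) {
    return(data.frame(class_label = character(0), n = integer(0),
                      median = numeric(0), p10 = numeric(0),
                      p90 = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(cl$size, cl$class_label), function(s) {
    data.frame(n = length(s), median = median(s),
               p10 = unname(quantile(s, 0.1)),
               p90 = unname(quantile(s, 0.9)))
  }))
  out <- cbind(class_label = rownames(out), out)
  rownames(out) <- NULL
  out
}
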