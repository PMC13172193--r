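# Particle counting: IsoData (iterative intermeans) threshold, watershed
# splitting of touching objects on the distance transform, and per-ROI
# particle statistics.

#' IsoData (iterative intermeans) intensity threshold
#'
#' Starting from the image mid-range, iterates
#' T <- (mean below T + mean above T) / 2 until the change is below
#' `tol` (0.5 gray levels, matching 8/16-bit default thresholding);
#' foreground is pixels > T. This is the iterative-intermeans "default"
#' threshold of common image-analysis software, without replicating any
#' histogram-binning quirks.
#'
#' @param pixels numeric matrix (2-D intensity image).
#' @param tol convergence tolerance in gray levels (default 0.5).
#' @param max_iter iteration cap (default 1000).
#' @return the threshold intensity.
#' @export
isodata_threshold <- function(pixels, tol = 0.5, max_iter = 1000L) {
  v <- as.numeric(pixels)
  if (!length(v) || any(!is.finite(v)))
    stop_invalid("image must be non-empty and finite")
  if (length(unique(v)) < 2L)
    stop_invalid("constant image: no threshold exists")
  thr <- (min(v) + max(v)) / 2
  for (k in seq_len(max_iter)) {
    lo <- v[v <= thr]; hi <- v[v > thr]
    if (!length(hi)) break
    new_thr <- (mean(lo) + mean(hi)) / 2
    if (abs(new_thr - thr) < tol) {
      thr <- new_thr
      break
    }
    thr <- new_thr
  }
  thr
}

#' Watershed splitting of a binary mask
#'
#' Labels connected foreground objects and splits touching ones along the
#' ridges of the Euclidean distance transform: seeds are the regional
#' maxima of the distance map merged within a 0.5 px tolerance, and
#' watershed lines separate the basins. Disjoint objects are unchanged.
#'
#' @param mask logical or 0/1 matrix.
#' @param tolerance seed merge tolerance in px of distance-map height
#'   (default 0.5).
#' @return an integer label matrix (0 = background).
#' @export
watershed_split <- function(mask, tolerance = 0.5) {
  m <- (as.matrix(mask) > 0) * 1
  if (!sum(m)) return(matrix(0L, nrow(m), ncol(m)))
  d <- EBImage::distmap(m)
  w <- EBImage::watershed(d, tolerance = tolerance, ext = 1)
  matrix(as.integer(EBImage::imageData(w)), nrow(m), ncol(m))
}

#' Particle statistics per cell ROI
#'
#' Each labelled particle is assigned to the ROI containing its centroid
#' (boundary particles are counted exactly once); particles smaller than
#' `min_area_px` are excluded. Areas are pixel counts scaled by the pixel
#' size squared.
#'
#' @param labels integer label matrix from [watershed_split()].
#' @param roi_mask integer ROI label matrix (0 = outside any cell); must
#'   match `labels` in shape.
#' @param pixel_size_um pixel size, um/px.
#' @param min_area_px minimum particle area in px (default 1).
#' @return a list with `per_roi` (roi_id, count, mean_area_um2) and
#'   `per_particle` (roi_id, particle_id, area_px, area_um2).
#' @export
count_particles <- function(labels, roi_mask, pixel_size_um,
                            min_area_px = 1) {
  labels <- as.matrix(labels); roi_mask <- as.matrix(roi_mask)
  if (!all(dim(labels) == dim(roi_mask)))
    stop_invalid("labels and roi_mask must have the same shape")
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               strict_lower = TRUE)
  check_number(min_area_px, "min_area_px", lower = 0)
  roi_ids <- sort(setdiff(unique(as.integer(roi_mask)), 0L))
  ids <- setdiff(unique(as.integer(labels)), 0L)
  rows <- list()
  for (id in ids) {
    idx <- which(labels == id, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < min_area_px) next
    cx <- round(mean(idx[, 1])); cy <- round(mean(idx[, 2]))
    cx <- min(max(cx, 1L), nrow(labels)); cy <- min(max(cy, 1L), ncol(labels))
    roi <- roi_mask[cx, cy]
    if (roi == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      roi_id = roi, particle_id = id, area_px = area,
      area_um2 = area * pixel_size_um^2)
  }
  per_particle <- if (length(rows)) do.call(rbind, rows) else
    data.frame(roi_id = integer(0), particle_id = integer(0),
               area_px = numeric(0), area_um2 = numeric(0))
  per_roi <- do.call(rbind, lapply(roi_ids, function(r) {
    d <- per_particle[per_particle$roi_id == r, ]
    data.frame(roi_id = r, count = nrow(d),
               mean_area_um2 = if (nrow(d)) mean(d$area_um2) else NA_real_)
  }))
  if (is.null(per_roi))
    per_roi <- data.frame(roi_id = integer(0), count = integer(0),
                          mean_area_um2 = numeric(0))
  list(per_roi = per_roi, per_particle = per_particle)
}

#' Threshold, split and count in one call
#'
#' Convenience wrapper: IsoData threshold, watershed split, particle
#' statistics.
#'
#' @inheritParams count_particles
#' @param pixels 2-D intensity matrix.
#' @return as [count_particles()], plus `threshold`.
#' @export
segment_and_count <- function(pixels, roi_mask, pixel_size_um,
                              min_area_px = 1) {
  thr <- isodata_threshold(pixels)
  labels <- watershed_split(pixels > thr)
  out <- count_particles(labels, roi_mask, pixel_size_um, min_area_px)
  out$threshold <- thr
  out
}
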