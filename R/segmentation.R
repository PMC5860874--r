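# Fly segmentation: foreground extraction, small-object rejection,
# largest-blob observation inside the tube ROI, and the median-gray
# core/periphery split.

#' Extract the foreground (fly) mask
#'
#' A pixel is foreground when it is darker than the background by more
#' than `C0` gray levels; at the default `C0 = 10` this excludes
#' essentially all sensor fluctuations.
#'
#' @param frame,background grayscale matrices of equal dimensions.
#' @param C0 grayscale-change threshold.
#' @return logical matrix.
#' @export
extract_foreground <- function(frame, background, C0 = 10) {
  if (!identical(dim(frame), dim(background))) {
    stop("frame and background dimensions differ", call. = FALSE)
  }
  (background - frame) > C0
}

#' Remove small connected components from a mask
#'
#' Erases every 8-connected component with area strictly less than `C1`
#' pixels; components of `C1` pixels or more are untouched. With
#' `C1 = 25` this removes residual noise blobs without affecting a fly
#' of typical ~300-pixel area.
#'
#' @param mask logical matrix.
#' @param C1 minimum component area kept (pixels).
#' @return logical matrix.
#' @export
remove_small_objects <- function(mask, C1 = 25) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(mask)
  lab <- .label_components(mask)
  sizes <- tabulate(lab)
  keep <- c(FALSE, sizes >= C1)[lab + 1L]
  dim(keep) <- dim(mask)
  keep
}

#' Observe the fly in one frame
#'
#' Takes the largest size-filtered component inside the ROI as the fly.
#' The centroid is projected on the tube's long axis; movement
#' perpendicular to the tube is ignored throughout the pipeline. Ties in
#' component size are resolved toward the component first met in
#' column-major scan order.
#'
#' @param mask logical matrix, already size-filtered.
#' @param frame grayscale matrix the grays are sampled from.
#' @param roi a [tube_roi()].
#' @param frame_index native frame index recorded in the observation.
#' @return object of class `groom_obs`: list with `frame_index`, `idx`
#'   (linear pixel indices into the full frame), `grays`, `area`,
#'   `centroid` (row, col), `centroid_axis`, `detected`, and (after
#'   [split_core_periphery()]) `core_idx` / `periphery_idx`.
#' @export
observe_fly <- function(mask, frame, roi, frame_index = NA_integer_) {
  r1 <- max(1L, as.integer(roi$rect[1])); c1 <- max(1L, as.integer(roi$rect[2]))
  r2 <- min(nrow(mask), as.integer(roi$rect[3]))
  c2 <- min(ncol(mask), as.integer(roi$rect[4]))
  sub <- mask[r1:r2, c1:c2, drop = FALSE]
  empty <- structure(
    list(frame_index = frame_index, idx = integer(0), grays = numeric(0),
         area = 0L, centroid = c(NA_real_, NA_real_),
         centroid_axis = NA_real_, detected = FALSE, held = FALSE,
         fly_id = roi$fly_id, frame_nrow = nrow(mask)),
    class = "groom_obs"
  )
  if (!any(sub)) return(empty)
  lab <- .label_components(sub)
  sizes <- tabulate(lab)
  best <- which.max(sizes)  # ties -> lowest label, i.e. first in scan order
  sel <- which(lab == best)
  rows <- ((sel - 1L) %% nrow(sub)) + r1
  cols <- ((sel - 1L) %/% nrow(sub)) + c1
  idx <- (cols - 1L) * nrow(mask) + rows
  centroid <- c(mean(rows), mean(cols))
  structure(
    list(frame_index = frame_index, idx = idx, grays = as.numeric(frame[idx]),
         area = length(idx), centroid = centroid,
         centroid_axis = sum(centroid * roi$axis), detected = TRUE,
         held = FALSE, fly_id = roi$fly_id, frame_nrow = nrow(mask)),
    class = "groom_obs"
  )
}

#' Split a fly observation into core and periphery
#'
#' The median of the fly's pixel gray values (computed separately for
#' each fly, each analyzed frame) splits the body into a darker core and
#' a lighter periphery of near-equal size: pixels below the median go to
#' the core, pixels above it to the periphery, and median-valued pixels
#' fill the core up to `ceiling(area/2)` in pixel-index order (the rest
#' go to the periphery). A constant-gray blob degenerates to an
#' index-order split into equal halves.
#'
#' @param obs a detected `groom_obs` with at least 2 pixels.
#' @return the observation with `core_idx` and `periphery_idx` added;
#'   the two are disjoint and their union is `idx`.
#' @export
split_core_periphery <- function(obs) {
  stopifnot(inherits(obs, "groom_obs"))
  if (!isTRUE(obs$detected) || obs$area < 2L) {
    stop("core/periphery split needs a detected observation with >= 2 pixels",
         call. = FALSE)
  }
  ord <- order(obs$idx)
  grays <- obs$grays[ord]
  idx <- obs$idx[ord]
  med <- stats::median(grays)
  core <- grays < med
  target <- ceiling(length(idx) / 2)
  need <- target - sum(core)
  if (need > 0L) {
    ties <- which(grays == med)
    core[ties[seq_len(min(need, length(ties)))]] <- TRUE
  }
  obs$core_idx <- idx[core]
  obs$periphery_idx <- idx[!core]
  obs
}
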