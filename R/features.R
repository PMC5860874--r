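# Movement features between consecutive analyzed frames: periphery
# movement (PM), core movement (CM) and centroid displacement (CD),
# normalized to fly size so different individuals share one feature
# space.

#' Pixel turnover of a body part between two frames
#'
#' PM and CM count the non-overlapping part pixels in two consecutive
#' analyzed frames, i.e. the size of the symmetric difference between
#' the part's pixel sets. Correspondence across frames is by part label
#' (core to core, periphery to periphery).
#'
#' @param prev_part_pixels,curr_part_pixels integer pixel indices in a
#'   common coordinate frame.
#' @return non-overlap count (pixels).
#' @examples
#' compute_part_movement(c(1, 2, 3), c(2, 3, 4))  # 2
#' @export
compute_part_movement <- function(prev_part_pixels, curr_part_pixels) {
  sum(!(prev_part_pixels %in% curr_part_pixels)) +
    sum(!(curr_part_pixels %in% prev_part_pixels))
}

#' Centroid displacement along the tube axis
#'
#' Displacements smaller than `min_cd` (half a pixel by default) are
#' attributed to noise and zeroed; at the default this excludes
#' essentially all false displacements of a stationary fly.
#'
#' @param prev_centroid_axis,curr_centroid_axis axis coordinates of the
#'   fly centroid in the two frames (gap-filled for undetected frames).
#' @param min_cd minimum displacement accepted as real (pixels).
#' @return displacement in pixels (0 if below `min_cd`).
#' @export
compute_cd <- function(prev_centroid_axis, curr_centroid_axis, min_cd = 0.5) {
  d <- abs(curr_centroid_axis - prev_centroid_axis)
  ifelse(is.na(d) | d < min_cd, 0, d)
}

#' Normalize raw features to fly size
#'
#' PM and CM are areas while CD is a distance, so the square roots of PM
#' and CM are taken to make the feature dimensions homogeneous; all
#' three are then divided by the scale parameter `SP = sqrt(area)`.
#' Setting `sqrt_transform = FALSE` divides the raw pixel counts by SP
#' instead (an alternative reading of the normalization; the
#' dimensionally homogeneous default is recommended).
#'
#' @param raw_pm,raw_cm raw pixel-turnover counts.
#' @param raw_cd raw centroid displacement (pixels).
#' @param area fly area in pixels (> 0).
#' @param sqrt_transform take square roots of PM and CM first.
#' @return data.frame with columns `nPM`, `nCM`, `nCD`.
#' @export
normalize_features <- function(raw_pm, raw_cm, raw_cd, area,
                               sqrt_transform = TRUE) {
  if (any(area <= 0)) stop("`area` must be positive", call. = FALSE)
  sp <- sqrt(area)
  if (sqrt_transform) {
    data.frame(nPM = sqrt(raw_pm) / sp, nCM = sqrt(raw_cm) / sp,
               nCD = raw_cd / sp)
  } else {
    data.frame(nPM = raw_pm / sp, nCM = raw_cm / sp, nCD = raw_cd / sp)
  }
}

#' Segment a video into per-analyzed-frame fly observations
#'
#' Runs background construction on the refresh schedule, extracts the
#' foreground of every analyzed frame, removes small objects, observes
#' the fly inside the ROI, gap-fills undetected frames by holding the
#' last position, and splits each observation into core and periphery.
#'
#' @param video a `groom_video` or `rows x cols x frames` array.
#' @param roi a [tube_roi()]; defaults to the video's own ROI.
#' @param C0,C1 segmentation thresholds.
#' @param background_interval_s background refresh interval.
#' @param analysis_step analyze every `analysis_step`-th frame.
#' @param frame_rate native frame rate; defaults to the video attribute.
#' @param seed seed for the background frame draws.
#' @return list with `observations` (gap-filled, split), `clock`,
#'   `schedule` and `backgrounds`. If the fly is never detected an error
#'   is thrown.
#' @export
segment_video <- function(video, roi = NULL, C0 = 10, C1 = 25,
                          background_interval_s = 1000, analysis_step = 2L,
                          frame_rate = NULL, seed = NULL) {
  frame_rate <- frame_rate %||% attr(video, "frame_rate") %||% 10
  roi <- roi %||% attr(video, "roi")
  if (is.null(roi)) stop("an ROI is required", call. = FALSE)
  d <- dim(video)
  if (roi$rect[1] < 1 || roi$rect[2] < 1 || roi$rect[3] > d[1] ||
      roi$rect[4] > d[2]) {
    stop("ROI extends outside the video frame", call. = FALSE)
  }
  n_frames <- d[3]
  clock <- analysis_clock(n_frames, frame_rate, analysis_step)
  schedule <- refresh_schedule(n_frames, frame_rate, background_interval_s,
                               seed = seed)
  backgrounds <- build_backgrounds(video, schedule, C0 = C0)
  obs <- vector("list", clock$n_analyzed)
  for (i in seq_len(clock$n_analyzed)) {
    f <- clock$analyzed_native[i]
    bi <- findInterval(f, schedule$from)
    frame <- video[, , f]
    mask <- extract_foreground(frame, backgrounds[[bi]], C0 = C0)
    mask <- remove_small_objects(mask, C1 = C1)
    obs[[i]] <- observe_fly(mask, frame, roi, frame_index = f)
  }
  obs <- hold_last_position(obs)
  if (isTRUE(attr(obs, "never_detected"))) {
    stop("fly never detected in the video; fly excluded", call. = FALSE)
  }
  for (i in seq_along(obs)) {
    if (isTRUE(obs[[i]]$detected) && is.null(obs[[i]]$core_idx)) {
      obs[[i]] <- split_core_periphery(obs[[i]])
    }
  }
  list(observations = obs, clock = clock, schedule = schedule,
       backgrounds = backgrounds)
}

#' Feature series from segmented observations
#'
#' One feature vector per consecutive pair of analyzed frames.
#'
#' @param observations gap-filled, core/periphery-split observations
#'   (see [segment_video()]).
#' @param min_cd minimum centroid displacement accepted as real.
#' @param sqrt_transform see [normalize_features()].
#' @return a `groom_features` data.frame: `analyzed_pair`,
#'   `native_frame` (later frame of the pair), `nPM`, `nCM`, `nCD`, the
#'   raw counterparts, `area`, `centroid_axis` (later frame) and
#'   `detected`.
#' @export
features_from_observations <- function(observations, min_cd = 0.5,
                                       sqrt_transform = TRUE) {
  m <- length(observations)
  if (m < 2L) stop("need at least two analyzed frames", call. = FALSE)
  raw_pm <- raw_cm <- raw_cd <- area <- cax <- numeric(m - 1L)
  native <- integer(m - 1L)
  det <- logical(m - 1L)
  for (i in seq_len(m - 1L)) {
    a <- observations[[i]]
    b <- observations[[i + 1L]]
    native[i] <- b$frame_index
    det[i] <- isTRUE(a$detected) && isTRUE(b$detected)
    if (!det[i]) {
      area[i] <- NA_real_
      cax[i] <- NA_real_
      next
    }
    raw_pm[i] <- compute_part_movement(a$periphery_idx, b$periphery_idx)
    raw_cm[i] <- compute_part_movement(a$core_idx, b$core_idx)
    raw_cd[i] <- compute_cd(a$centroid_axis, b$centroid_axis, min_cd)
    area[i] <- (a$area + b$area) / 2
    cax[i] <- b$centroid_axis
  }
  ok <- det & area > 0
  nf <- data.frame(nPM = rep(NA_real_, m - 1L), nCM = NA_real_, nCD = NA_real_)
  if (any(ok)) {
    nf[ok, ] <- normalize_features(raw_pm[ok], raw_cm[ok], raw_cd[ok],
                                   area[ok], sqrt_transform)
  }
  structure(
    data.frame(analyzed_pair = seq_len(m - 1L), native_frame = native,
               nPM = nf$nPM, nCM = nf$nCM, nCD = nf$nCD,
               raw_PM = raw_pm, raw_CM = raw_cm, raw_CD = raw_cd,
               area = area, centroid_axis = cax, detected = det),
    class = c("groom_features", "data.frame")
  )
}

#' Extract the full feature series from a video
#'
#' Convenience wrapper running [segment_video()] and
#' [features_from_observations()].
#'
#' @inheritParams segment_video
#' @inheritParams features_from_observations
#' @return a `groom_features` data.frame with the segmentation attached
#'   as attribute `segmentation`.
#' @export
extract_feature_series <- function(video, roi = NULL, C0 = 10, C1 = 25,
                                   min_cd = 0.5, background_interval_s = 1000,
                                   analysis_step = 2L, frame_rate = NULL,
                                   sqrt_transform = TRUE, seed = NULL) {
  seg <- segment_video(video, roi, C0 = C0, C1 = C1,
                       background_interval_s = background_interval_s,
                       analysis_step = analysis_step, frame_rate = frame_rate,
                       seed = seed)
  feats <- features_from_observations(seg$observations, min_cd = min_cd,
                                      sqrt_transform = sqrt_transform)
  attr(feats, "segmentation") <- seg
  feats
}
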