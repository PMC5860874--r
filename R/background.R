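# Fly-free background construction and refresh scheduling.
#
# The background is built from one template frame and several contrast
# frames drawn at random from the same stretch of video. A fly is always
# darker than its surroundings, so any template pixel that is darker
# than the corresponding contrast pixel by more than C0 belonged to the
# (moving) fly and is replaced by the contrast value. Applied over seven
# contrast frames this erases the fly wherever it moved at least once.

#' Build a fly-free background frame
#'
#' @param template grayscale matrix used as the starting frame.
#' @param contrast_frames a list of matrices (or a 3-D array sliced along
#'   the third dimension) compared against the template.
#' @param C0 minimum grayscale difference accepted as a real change.
#' @return background matrix of the same dimensions.
#' @examples
#' tmpl <- matrix(120, 4, 4); tmpl[2, 2] <- 40  # dark fly pixel
#' ctr <- matrix(120, 4, 4)
#' build_background(tmpl, list(ctr))[2, 2]  # 120: fly erased
#' @export
build_background <- function(template, contrast_frames, C0 = 10) {
  stop_if_not_scalar_pos(C0, "C0")
  if (is.array(contrast_frames) && length(dim(contrast_frames)) == 3L) {
    contrast_frames <- lapply(seq_len(dim(contrast_frames)[3]),
                              function(i) contrast_frames[, , i])
  }
  if (!is.list(contrast_frames) || length(contrast_frames) < 1L) {
    stop("at least one contrast frame is required", call. = FALSE)
  }
  bg <- template
  storage.mode(bg) <- "double"
  for (ct in contrast_frames) {
    if (!identical(dim(ct), dim(template))) {
      stop("contrast frame dimensions do not match the template", call. = FALSE)
    }
    repl <- (ct - bg) > C0
    bg[repl] <- ct[repl]
  }
  bg
}

#' Background refresh schedule
#'
#' Splits a video into consecutive intervals of `interval_s` seconds
#' (the last may be shorter) and draws, uniformly at random within each
#' interval, one template frame and `n_contrast` contrast frames for the
#' background of that interval.
#'
#' @param n_frames total native frames.
#' @param frame_rate native frames per second.
#' @param interval_s seconds between background regenerations.
#' @param n_contrast number of contrast frames per background.
#' @param seed RNG seed for the frame draws.
#' @return a `groom_schedule` data.frame with columns `from`, `to`
#'   (inclusive native-frame bounds), `template_frame` and a list column
#'   `contrast_frames`.
#' @export
refresh_schedule <- function(n_frames, frame_rate = 10, interval_s = 1000,
                             n_contrast = 7, seed = NULL) {
  stop_if_not_scalar_pos(n_frames, "n_frames")
  stop_if_not_scalar_pos(interval_s, "interval_s")
  n_frames <- as.integer(n_frames)
  per <- max(1L, as.integer(round(interval_s * frame_rate)))
  starts <- seq.int(1L, n_frames, by = per)
  ends <- pmin(starts + per - 1L, n_frames)
  with_seed(seed, {
    tmpl <- integer(length(starts))
    ctr <- vector("list", length(starts))
    for (i in seq_along(starts)) {
      pool <- starts[i]:ends[i]
      tmpl[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      ctr[[i]] <- if (length(pool) >= n_contrast) {
        sort(sample(pool, n_contrast))
      } else {
        sort(sample(pool, n_contrast, replace = TRUE))
      }
    }
    out <- data.frame(from = starts, to = ends, template_frame = tmpl)
    out$contrast_frames <- ctr
    class(out) <- c("groom_schedule", "data.frame")
    out
  })
}

#' Build one background per schedule interval
#'
#' @param video a `groom_video` or `rows x cols x frames` array.
#' @param schedule a [refresh_schedule()] result.
#' @param C0 grayscale-change threshold.
#' @return list of background matrices, one per interval.
#' @export
build_backgrounds <- function(video, schedule, C0 = 10) {
  lapply(seq_len(nrow(schedule)), function(i) {
    build_background(
      video[, , schedule$template_frame[i]],
      lapply(schedule$contrast_frames[[i]], function(f) video[, , f]),
      C0 = C0
    )
  })
}

#' Fill detection gaps by holding the last detected position
#'
#' A fly that does not move for longer than the background refresh
#' interval is absorbed into the background and temporarily undetected.
#' Those frames inherit the full observation (pixels, centroid) of the
#' most recent detected frame, i.e. the fly is considered stationary at
#' the position where it was last seen. Frames before the first
#' detection stay undetected.
#'
#' @param observations list of `groom_obs` (see [observe_fly()]).
#' @return the gap-filled list. If the fly was never detected the list is
#'   returned with attribute `never_detected = TRUE`.
#' @export
hold_last_position <- function(observations) {
  last <- NULL
  any_detected <- FALSE
  for (i in seq_along(observations)) {
    ob <- observations[[i]]
    if (isTRUE(ob$detected)) {
      last <- ob
      any_detected <- TRUE
    } else if (!is.null(last)) {
      filled <- last
      filled$frame_index <- ob$frame_index
      filled$held <- TRUE
      observations[[i]] <- filled
    }
  }
  if (!any_detected) attr(observations, "never_detected") <- TRUE
  observations
}
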