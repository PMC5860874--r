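# Synthetic ground-truth generator: scripted ethograms, rendered fly
# videos, and rhythmic binned series. Every downstream stage of the
# pipeline is testable against these without any recorded video.

#' Fly appearance parameters for the synthetic renderer
#'
#' A fly is drawn as a two-tone elongated blob: a dark inner core
#' surrounded by a lighter periphery, both darker than the tube
#' background. Defaults follow the empirical grayscale structure of real
#' recordings: core around gray level 40, periphery around 90, a body of
#' roughly 300 pixels, and sensor noise of about 2 gray levels.
#'
#' @param area target number of fly pixels.
#' @param core_gray,periphery_gray,background_gray 8-bit gray levels;
#'   must satisfy `core_gray < periphery_gray < background_gray`.
#' @param noise_sd standard deviation of i.i.d. additive Gaussian pixel
#'   noise (gray levels).
#' @return an object of class `groom_appearance`.
#' @export
fly_appearance <- function(area = 300, core_gray = 40, periphery_gray = 90,
                           background_gray = 180, noise_sd = 2) {
  stop_if_not_scalar_pos(area, "area")
  if (area <= 25) {
    stop("`area` must exceed the minimum blob size C1 (25 pixels)", call. = FALSE)
  }
  if (!(core_gray < periphery_gray && periphery_gray < background_gray)) {
    stop("appearance must satisfy core_gray < periphery_gray < background_gray",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(area = area, core_gray = core_gray, periphery_gray = periphery_gray,
         background_gray = background_gray, noise_sd = noise_sd),
    class = "groom_appearance"
  )
}

#' Tube region of interest
#'
#' Describes the rectangular region holding one fly's tube, the direction
#' of the tube's long axis, and the coordinate of the food end along that
#' axis. Pixel coordinates are 1-based `(row, col)`; the rectangle is
#' inclusive.
#'
#' @param rect integer vector `c(row_min, col_min, row_max, col_max)`.
#' @param axis unit direction of the tube long axis as `c(row, col)`
#'   components; the default tube runs along image columns.
#' @param food_position coordinate of the food end projected on `axis`
#'   (pixels).
#' @param fly_id identifier carried through all outputs.
#' @return an object of class `groom_roi`.
#' @export
tube_roi <- function(rect, axis = c(0, 1), food_position, fly_id = 1L) {
  stopifnot(length(rect) == 4L, rect[1] <= rect[3], rect[2] <= rect[4])
  axis <- axis / sqrt(sum(axis^2))
  proj <- sort(c(axis[1] * rect[c(1, 3)], axis[2] * rect[c(2, 4)]))
  lo <- axis[1] * rect[1] + axis[2] * rect[2]
  hi <- axis[1] * rect[3] + axis[2] * rect[4]
  if (food_position < min(lo, hi) || food_position > max(lo, hi)) {
    stop("`food_position` must lie within the ROI projection on `axis`",
         call. = FALSE)
  }
  structure(
    list(rect = as.numeric(rect), axis = axis,
         food_position = food_position, fly_id = fly_id),
    class = "groom_roi"
  )
}

default_bout_means <- function() {
  # grooming ~0.23 min and locomotion ~0.44 min reflect observed mean
  # event durations; rest/feeding/sleep means are generator choices
  # (sleep mean counts the whole bout, which is >= 300 s by construction)
  c(grooming = 13.8, locomotion = 26.4, rest = 20,
    feeding = 30, sleep = 1500)
}

#' Generate a scripted ground-truth ethogram
#'
#' Produces a per-frame behavior label sequence by alternating bouts
#' whose durations are exponential with per-behavior means (floored at
#' one analyzed frame). Sleep bouts are 300 s plus an exponential excess,
#' so they are always at least 5 min; rest bouts are capped just under
#' 5 min. When `rhythm_params` is supplied, the probability of starting
#' an active bout (grooming, locomotion, feeding) is modulated by a
#' two-peak 24-h profile, giving the script circadian structure.
#'
#' @param duration_s script length in seconds.
#' @param frame_rate native frames per second.
#' @param behaviors subset of
#'   `c("grooming","locomotion","rest","feeding","sleep")` to use.
#' @param bout_means_s named mean bout durations in seconds; defaults per
#'   behavior via the package's generator settings.
#' @param behavior_weights named base weights for choosing the next
#'   behavior (uniform by default).
#' @param rhythm_params optional list with `period_h`, `depth` (0-1) and
#'   optionally `peak_width_h`; modulates active-bout probability.
#' @param analysis_step frames per analyzed frame (bout floor).
#' @param seed RNG seed; fixed seed gives an identical script.
#' @return object of class `groom_script`: list with `frame_rate`,
#'   `labels` (character, one per native frame), `bouts` (data.frame),
#'   and the generating parameters.
#' @examples
#' sc <- generate_ethogram_script(60, behaviors = c("grooming", "rest"), seed = 1)
#' table(sc$labels)
#' @export
generate_ethogram_script <- function(duration_s, frame_rate = 10,
                                     behaviors = c("grooming", "locomotion", "rest"),
                                     bout_means_s = NULL,
                                     behavior_weights = NULL,
                                     rhythm_params = NULL,
                                     analysis_step = 2L,
                                     seed = NULL) {
  stop_if_not_scalar_pos(duration_s, "duration_s")
  stop_if_not_scalar_pos(frame_rate, "frame_rate")
  all_behaviors <- c("grooming", "locomotion", "rest", "feeding", "sleep")
  behaviors <- match.arg(behaviors, all_behaviors, several.ok = TRUE)
  means <- default_bout_means()
  if (!is.null(bout_means_s)) means[names(bout_means_s)] <- bout_means_s
  if (any(means[behaviors] <= 0)) stop("bout means must be positive", call. = FALSE)
  if ("sleep" %in% behaviors && means["sleep"] <= 300) {
    stop("mean sleep bout must exceed 300 s", call. = FALSE)
  }
  w <- rep(1, length(behaviors))
  names(w) <- behaviors
  if (!is.null(behavior_weights)) {
    w[names(behavior_weights)] <- behavior_weights
  }
  active_set <- intersect(behaviors, c("grooming", "locomotion", "feeding"))

  n_frames <- round(duration_s * frame_rate)
  min_bout_frames <- as.integer(analysis_step)

  with_seed(seed, {
    labels <- character(n_frames)
    bout_behavior <- character(0)
    bout_start <- integer(0)
    bout_len <- integer(0)
    pos <- 1L
    prev <- NA_character_
    while (pos <= n_frames) {
      wt <- w
      if (!is.na(prev) && length(behaviors) > 1L) wt[prev] <- 0
      if (!is.null(rhythm_params) && length(active_set)) {
        t_h <- (pos - 1L) / frame_rate / 3600
        prof <- unit_two_peak_profile(
          t_h,
          period_h = rhythm_params$period_h %||% 24,
          peak_width_h = rhythm_params$peak_width_h %||% 3
        )
        depth <- rhythm_params$depth %||% 0.8
        wt[active_set] <- wt[active_set] * (1 - depth + depth * prof)
      }
      beh <- sample(behaviors, 1L, prob = wt)
      mean_s <- means[[beh]]
      d <- if (beh == "sleep") {
        300 + rexp(1, 1 / (mean_s - 300))
      } else if (beh == "rest") {
        min(rexp(1, 1 / mean_s), 299.8)  # short rest stays under 5 min
      } else {
        rexp(1, 1 / mean_s)
      }
      len <- max(min_bout_frames, round(d * frame_rate))
      len <- min(len, n_frames - pos + 1L)
      # a sleep bout truncated by the end of the script below 300 s is
      # no longer sleep; record it as rest instead
      if (beh == "sleep" && len < 300 * frame_rate) beh <- "rest"
      labels[pos:(pos + len - 1L)] <- beh
      bout_behavior <- c(bout_behavior, beh)
      bout_start <- c(bout_start, pos)
      bout_len <- c(bout_len, len)
      prev <- beh
      pos <- pos + len
    }
    structure(
      list(
        frame_rate = frame_rate,
        labels = labels,
        bouts = data.frame(behavior = bout_behavior, start_frame = bout_start,
                           n_frames = bout_len,
                           duration_s = bout_len / frame_rate),
        bout_means_s = means[behaviors],
        rhythm_params = rhythm_params,
        seed = seed
      ),
      class = "groom_script"
    )
  })
}

# Elliptical two-tone fly template: pixel offsets from the body center
# with a core flag on the innermost half. Semi-axis along the tube is
# twice the perpendicular one (elongated body).
make_fly_shape <- function(area) {
  a <- sqrt(area / (2 * pi))      # semi-minor (rows)
  b <- 2 * a                      # semi-major (cols, along tube)
  dr <- seq(-ceiling(a), ceiling(a))
  dc <- seq(-ceiling(b), ceiling(b))
  grid <- expand.grid(dr = dr, dc = dc)
  rad2 <- (grid$dr / a)^2 + (grid$dc / b)^2
  inside <- rad2 <= 1
  shape <- grid[inside, ]
  shape$rad2 <- rad2[inside]
  shape <- shape[order(shape$rad2, shape$dr, shape$dc), ]
  n <- nrow(shape)
  shape$core <- seq_len(n) <= ceiling(n / 2)
  # outward unit step for grooming jitter (dominant normalized direction)
  shape$out_r <- sign(shape$dr) * (abs(shape$dr) / a >= 0.4)
  shape$out_c <- sign(shape$dc) * (abs(shape$dc) / b >= 0.4)
  # periphery pixels sorted by polar angle so an index range is a
  # contiguous arc
  ang <- atan2(shape$dr / a, shape$dc / b)
  shape$angle <- ang
  rownames(shape) <- NULL
  shape
}

#' Render a scripted ethogram as a noisy grayscale fly video
#'
#' Draws the fly as a dark two-tone blob on a uniform lighter background
#' and animates it according to the script: rest and sleep leave the fly
#' pixels unchanged (noise only); locomotion translates the whole body
#' along the tube axis by at least one pixel per analyzed frame pair;
#' grooming redraws a contiguous 10-40% arc of periphery pixels one step
#' outward each frame while the core stays put and the centroid moves
#' less than half a pixel; feeding holds the fly at the food end.
#' I.i.d. Gaussian noise is added per pixel and clipped to `[0, 255]`.
#'
#' @param script a `groom_script`.
#' @param appearance a [fly_appearance()].
#' @param roi a [tube_roi()]; default spans the whole frame with food at
#'   the left end. Only horizontal tubes (axis along columns) are
#'   rendered.
#' @param frame_dim frame size `c(rows, cols)` when `roi` is NULL.
#' @param background_drift gray levels per hour of uniform background
#'   drift (exercises the periodic background refresh).
#' @param seed RNG seed; fixed seed gives a bit-identical video.
#' @return object of class `groom_video`: integer array
#'   `rows x cols x frames` with attributes `frame_rate`, `appearance`,
#'   `roi`, `scene` (clean time-zero background), `script`, and
#'   `true_centroid_col` (continuous ground-truth body center per frame).
#' @export
render_video <- function(script, appearance = fly_appearance(), roi = NULL,
                         frame_dim = c(40, 200), background_drift = 0,
                         seed = NULL) {
  stopifnot(inherits(script, "groom_script"))
  if (!inherits(appearance, "groom_appearance")) {
    stop("`appearance` must be created by fly_appearance()", call. = FALSE)
  }
  if (is.null(roi)) {
    roi <- tube_roi(c(1, 1, frame_dim[1], frame_dim[2]),
                    food_position = 8, fly_id = 1L)
  }
  if (abs(roi$axis[2]) < 0.999) {
    stop("the renderer supports horizontal tubes only (axis along columns)",
         call. = FALSE)
  }
  nr <- as.integer(roi$rect[3] - roi$rect[1] + 1)
  nc <- as.integer(roi$rect[4] - roi$rect[2] + 1)
  shape <- make_fly_shape(appearance$area)
  half_h <- max(abs(shape$dr))
  half_w <- max(abs(shape$dc))
  if (nr < 2 * half_h + 5 || nc < 2 * half_w + 9) {
    stop("ROI too small to contain the fly plus its displacement margin",
         call. = FALSE)
  }
  labels <- script$labels
  n_frames <- length(labels)
  frame_rate <- script$frame_rate

  periph <- shape[!shape$core, ]
  periph <- periph[order(periph$angle), ]
  core <- shape[shape$core, ]

  with_seed(seed, {
    # trajectory of the continuous body-center column, per bout
    x_min <- half_w + 3
    x_max <- nc - half_w - 2
    x <- numeric(n_frames)
    cur <- runif(1, x_min, x_max)
    for (bi in seq_len(nrow(script$bouts))) {
      beh <- script$bouts$behavior[bi]
      from <- script$bouts$start_frame[bi]
      len <- script$bouts$n_frames[bi]
      idxs <- from:(from + len - 1L)
      if (beh == "locomotion") {
        dir <- sample(c(-1, 1), 1)
        v <- runif(1, 0.75, 2.5)  # px per native frame along the tube
        for (i in idxs) {
          cur <- cur + dir * v
          if (cur > x_max) { cur <- x_max - (cur - x_max); dir <- -dir }
          if (cur < x_min) { cur <- x_min + (x_min - cur); dir <- -dir }
          x[i] <- cur
        }
      } else if (beh == "feeding") {
        cur <- min(max(roi$food_position - roi$rect[2] + 1, x_min), x_max)
        x[idxs] <- cur
      } else {
        x[idxs] <- cur
      }
    }

    r0 <- round(nr / 2)
    scene0 <- matrix(appearance$background_gray, nr, nc)
    video <- array(0L, dim = c(nr, nc, n_frames))
    n_per <- nrow(periph)
    for (t in seq_len(n_frames)) {
      drift <- background_drift * (t - 1) / frame_rate / 3600
      frame <- scene0 + drift
      cx <- round(x[t])
      rows_core <- r0 + core$dr
      cols_core <- cx + core$dc
      if (labels[t] == "grooming") {
        # two antipodal arcs keep the jitter balanced so the rendered
        # centroid stays within half a pixel of the body center
        m <- max(2L, round(runif(1, 0.1, 0.4) * n_per / 2) * 2L)
        start <- sample.int(n_per, 1)
        arc1 <- ((start + seq_len(m / 2) - 2L) %% n_per) + 1L
        arc2 <- ((start + n_per %/% 2 + seq_len(m / 2) - 2L) %% n_per) + 1L
        sel <- unique(c(arc1, arc2))
        keep <- setdiff(seq_len(n_per), sel)
        rows_p <- c(periph$dr[keep], periph$dr[sel] + periph$out_r[sel]) + r0
        cols_p <- c(periph$dc[keep], periph$dc[sel] + periph$out_c[sel]) + cx
      } else {
        rows_p <- r0 + periph$dr
        cols_p <- cx + periph$dc
      }
      frame[cbind(rows_p, cols_p)] <- appearance$periphery_gray
      frame[cbind(rows_core, cols_core)] <- appearance$core_gray
      if (appearance$noise_sd > 0) {
        frame <- frame + rnorm(length(frame), 0, appearance$noise_sd)
      }
      video[, , t] <- as.integer(pmin(255, pmax(0, round(frame))))
    }
    structure(
      video,
      frame_rate = frame_rate,
      appearance = appearance,
      roi = roi,
      scene = scene0,
      script = script,
      true_centroid_col = x,
      class = "groom_video"
    )
  })
}

#' Generate a rhythmic binned activity series
#'
#' A nonnegative fraction-of-time series on a regular bin grid with
#' sinusoidal or two-peak modulation at a chosen period plus Gaussian
#' noise, clipped to `[0, 1]`. Used as a synthetic input to the spectral
#' stages.
#'
#' @param period_h modulation period (hours); must exceed twice the bin
#'   width (Nyquist).
#' @param days number of days of data.
#' @param bin_min bin width (minutes).
#' @param amplitude relative modulation depth.
#' @param baseline mean level of the series.
#' @param noise_sd additive Gaussian noise sd.
#' @param shape `"sinusoid"` or `"two_peak"`.
#' @param seed RNG seed.
#' @return object of class `groom_binned`: data.frame with columns
#'   `bin_start_min`, `value`, `lights_on`, and attribute `bin_minutes`.
#' @export
generate_rhythmic_series <- function(period_h = 24, days = 4, bin_min = 30,
                                     amplitude = 1, baseline = 0.3,
                                     noise_sd = 0.05,
                                     shape = c("sinusoid", "two_peak"),
                                     seed = NULL) {
  shape <- match.arg(shape)
  stop_if_not_scalar_pos(period_h, "period_h")
  stop_if_not_scalar_pos(days, "days")
  stop_if_not_scalar_pos(bin_min, "bin_min")
  if (period_h <= 2 * bin_min / 60) {
    stop("bin too coarse for the requested period (Nyquist violated)",
         call. = FALSE)
  }
  n <- round(days * 24 * 60 / bin_min)
  t_h <- (seq_len(n) - 1) * bin_min / 60
  mod <- switch(shape,
    sinusoid = sin(2 * pi * t_h / period_h),
    two_peak = 2 * unit_two_peak_profile(t_h, period_h = period_h) - 1
  )
  with_seed(seed, {
    v <- baseline * (1 + amplitude * mod)
    if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
    v <- pmin(1, pmax(0, v))
    binned_series(v, bin_minutes = bin_min,
                  lights_on = (t_h %% 24) < 12)
  })
}

#' Construct a binned series object
#'
#' @param values numeric vector of per-bin values (fractions of time).
#' @param bin_minutes bin width in minutes.
#' @param t0_min start time of the first bin, minutes from lights-on.
#' @param lights_on logical per bin (LD annotation); all-FALSE for DD.
#' @return a `groom_binned` data.frame.
#' @export
binned_series <- function(values, bin_minutes = 30, t0_min = 0,
                          lights_on = NULL) {
  n <- length(values)
  starts <- t0_min + (seq_len(n) - 1) * bin_minutes
  if (is.null(lights_on)) lights_on <- ((starts / 60) %% 24) < 12
  structure(
    data.frame(bin_start_min = starts, value = as.numeric(values),
               lights_on = lights_on),
    bin_minutes = bin_minutes,
    t0_min = t0_min,
    class = c("groom_binned", "data.frame")
  )
}
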