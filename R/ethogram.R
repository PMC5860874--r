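# Five-behavior ethogram assembly: feeding and sleep rules on top of the
# pruned three-class stream, fraction-of-time binning and bout
# statistics.

ETHOGRAM_CLASSES <- c("grooming", "locomotion", "feeding", "short_rest",
                      "sleep")

#' Estimate body length along the tube axis
#'
#' The median, over detected frames, of the fly's pixel extent projected
#' on the tube axis. Used as the distance scale of the feeding proxy.
#'
#' @param observations list of `groom_obs`.
#' @param roi the [tube_roi()] supplying the axis.
#' @return body length in pixels.
#' @export
estimate_body_length <- function(observations, roi) {
  ext <- vapply(observations, function(ob) {
    if (!isTRUE(ob$detected) || ob$area == 0L) return(NA_real_)
    rows <- ((ob$idx - 1L) %% ob$frame_nrow) + 1L
    cols <- ((ob$idx - 1L) %/% ob$frame_nrow) + 1L
    proj <- roi$axis[1] * rows + roi$axis[2] * cols
    diff(range(proj)) + 1
  }, numeric(1))
  if (all(is.na(ext))) stop("no detected frames to estimate body length from",
                            call. = FALSE)
  stats::median(ext, na.rm = TRUE)
}

#' Detect feeding intervals from food proximity
#'
#' Prolonged proximity to the food end -- centroid within one body
#' length of the food coordinate for strictly more than `min_duration_s`
#' seconds -- is accepted as a proxy for feeding.
#'
#' @param centroid_axis gap-filled centroid coordinate per analyzed
#'   frame (or frame pair).
#' @param food_position food-end coordinate on the same axis.
#' @param body_length fly body length in pixels (> 0).
#' @param analysis_rate analyzed frames per second.
#' @param min_duration_s minimum duration (exclusive) of a feeding
#'   interval.
#' @return data.frame with `start_frame`, `end_frame` (inclusive) and
#'   `duration_s`; empty when the fly never lingers near food.
#' @export
detect_feeding <- function(centroid_axis, food_position, body_length,
                           analysis_rate = 5, min_duration_s = 3) {
  stop_if_not_scalar_pos(body_length, "body_length")
  near <- !is.na(centroid_axis) &
    abs(centroid_axis - food_position) < body_length
  runs <- logical_runs(near)
  if (nrow(runs) == 0L) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0)))
  }
  runs$duration_s <- (runs$end - runs$start + 1L) / analysis_rate
  runs <- runs[runs$duration_s > min_duration_s, , drop = FALSE]
  data.frame(start_frame = runs$start, end_frame = runs$end,
             duration_s = runs$duration_s, row.names = NULL)
}

#' Tag rest bouts as sleep or short rest
#'
#' Maximal runs of rest lasting at least 5 minutes (300 s, inclusive)
#' are sleep; shorter quiescence is short rest.
#'
#' @param labels pruned three-class label stream.
#' @param analysis_rate analyzed frames per second.
#' @param sleep_threshold_s quiescence duration from which rest counts
#'   as sleep.
#' @return data.frame with `start_frame`, `end_frame`, `duration_s`,
#'   `type` (`"sleep"` or `"short_rest"`).
#' @export
classify_rest_bouts <- function(labels, analysis_rate = 5,
                                sleep_threshold_s = 300) {
  runs <- logical_runs(labels == "rest")
  if (nrow(runs) == 0L) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0), type = character(0)))
  }
  dur <- (runs$end - runs$start + 1L) / analysis_rate
  data.frame(start_frame = runs$start, end_frame = runs$end,
             duration_s = dur,
             type = ifelse(dur >= sleep_threshold_s, "sleep", "short_rest"),
             row.names = NULL)
}

#' Assemble the five-behavior ethogram
#'
#' Combines the pruned grooming/locomotion/rest stream with feeding
#' intervals and sleep/short-rest bout tags into one label per analyzed
#' frame. Precedence: sleep outranks everything (it is defined purely by
#' quiescence length); feeding overrides only locomotion and short-rest
#' frames, never grooming or sleep (feeding frames are initially
#' classified as locomotion by the three-class classifier). Exactly one
#' class per frame; wake is the complement of sleep.
#'
#' @param pruned pruned three-class label stream.
#' @param feeding_intervals from [detect_feeding()]; NULL for none.
#' @param rest_bouts from [classify_rest_bouts()]; computed from
#'   `pruned` when NULL.
#' @param analysis_rate analyzed frames per second.
#' @param fly_id identifier carried into outputs.
#' @return object of class `groom_ethogram`: data.frame with
#'   `analyzed_frame`, `behavior` (five classes), `wake`.
#' @export
assemble_ethogram <- function(pruned, feeding_intervals = NULL,
                              rest_bouts = NULL, analysis_rate = 5,
                              fly_id = 1L) {
  n <- length(pruned)
  if (is.null(rest_bouts)) {
    rest_bouts <- classify_rest_bouts(pruned, analysis_rate)
  }
  beh <- pruned
  beh[beh == "rest"] <- "short_rest"
  for (i in seq_len(nrow(rest_bouts))) {
    if (rest_bouts$type[i] == "sleep") {
      beh[rest_bouts$start_frame[i]:rest_bouts$end_frame[i]] <- "sleep"
    }
  }
  if (!is.null(feeding_intervals)) {
    for (i in seq_len(nrow(feeding_intervals))) {
      span <- feeding_intervals$start_frame[i]:feeding_intervals$end_frame[i]
      override <- span[beh[span] %in% c("locomotion", "short_rest")]
      beh[override] <- "feeding"
    }
  }
  structure(
    data.frame(analyzed_frame = seq_len(n), behavior = beh,
               wake = beh != "sleep"),
    analysis_rate = analysis_rate,
    fly_id = fly_id,
    class = c("groom_ethogram", "data.frame")
  )
}

#' Fraction of time per behavior in fixed bins
#'
#' Fractions are computed over the analyzed frames falling in each bin
#' (default 30 min); the final partial bin is normalized by its own
#' length, so the five fractions sum to one in every bin.
#'
#' @param ethogram a `groom_ethogram`.
#' @param bin_minutes bin width.
#' @param analysis_rate analyzed frames per second (defaults to the
#'   ethogram attribute).
#' @param t0_min zeitgeber time of the first frame, minutes from
#'   lights-on.
#' @param lights schedule: `"LD"` (12:12) or `"DD"` (constant dark).
#' @return long data.frame of class `groom_binned_ethogram` with
#'   `bin_start_min`, `behavior`, `fraction`, `lights_on`.
#' @export
bin_fractions <- function(ethogram, bin_minutes = 30, analysis_rate = NULL,
                          t0_min = 0, lights = c("LD", "DD")) {
  lights <- match.arg(lights)
  analysis_rate <- analysis_rate %||% attr(ethogram, "analysis_rate") %||% 5
  beh <- ethogram$behavior
  n <- length(beh)
  if (n == 0L) stop("ethogram is empty", call. = FALSE)
  fpb <- bin_minutes * 60 * analysis_rate
  bin <- (seq_len(n) - 1L) %/% fpb
  counts <- table(factor(bin), factor(beh, levels = ETHOGRAM_CLASSES))
  denom <- as.numeric(table(factor(bin)))
  frac <- sweep(unclass(counts), 1L, denom, "/")
  bins <- as.integer(rownames(counts))
  starts <- t0_min + bins * bin_minutes
  out <- data.frame(
    bin_start_min = rep(starts, times = length(ETHOGRAM_CLASSES)),
    behavior = rep(ETHOGRAM_CLASSES, each = length(bins)),
    fraction = as.vector(frac),
    lights_on = if (lights == "LD") {
      rep(((starts / 60) %% 24) < 12, times = length(ETHOGRAM_CLASSES))
    } else {
      FALSE
    }
  )
  structure(out, bin_minutes = bin_minutes, t0_min = t0_min,
            class = c("groom_binned_ethogram", "data.frame"))
}

#' Extract one behavior's binned series
#'
#' @param binned a `groom_binned_ethogram` from [bin_fractions()].
#' @param behavior one of the five classes, or `"wake"` for the sum of
#'   the four wake behaviors.
#' @return a `groom_binned` univariate series usable by the rhythm
#'   stages.
#' @export
behavior_series <- function(binned, behavior) {
  bm <- attr(binned, "bin_minutes") %||% 30
  t0 <- attr(binned, "t0_min") %||% 0
  if (behavior == "wake") {
    keep <- binned$behavior != "sleep"
    v <- tapply(binned$fraction[keep], binned$bin_start_min[keep], sum)
    starts <- as.numeric(names(v))
    lights <- binned$lights_on[match(starts, binned$bin_start_min)]
    ord <- order(starts)
    out <- binned_series(as.numeric(v)[ord], bin_minutes = bm, t0_min = t0,
                        lights_on = lights[ord])
    return(out)
  }
  sub <- binned[binned$behavior == behavior, , drop = FALSE]
  ord <- order(sub$bin_start_min)
  binned_series(sub$fraction[ord], bin_minutes = bm, t0_min = t0,
                lights_on = sub$lights_on[ord])
}

#' Bout durations and inter-event pauses
#'
#' Bouts are maximal runs of one behavior. Reports every bout and a
#' per-behavior summary: bout count, mean duration, and the longest
#' pause between two subsequent bouts of the behavior (end of one to
#' start of the next). Behaviors absent from the ethogram get `NA`
#' summaries.
#'
#' @param ethogram a `groom_ethogram` or a label vector.
#' @param analysis_rate analyzed frames per second.
#' @return list of class `groom_bouts` with `bouts` and `summary`
#'   data.frames.
#' @export
bout_statistics <- function(ethogram, analysis_rate = NULL) {
  if (inherits(ethogram, "groom_ethogram")) {
    analysis_rate <- analysis_rate %||% attr(ethogram, "analysis_rate")
    labels <- ethogram$behavior
  } else {
    labels <- as.character(ethogram)
  }
  analysis_rate <- analysis_rate %||% 5
  classes <- intersect(ETHOGRAM_CLASSES, unique(labels))
  classes <- union(classes, setdiff(unique(labels), ETHOGRAM_CLASSES))
  bouts <- do.call(rbind, lapply(classes, function(cl) {
    runs <- logical_runs(labels == cl)
    if (nrow(runs) == 0L) return(NULL)
    data.frame(behavior = cl, start_frame = runs$start,
               end_frame = runs$end,
               duration_s = (runs$end - runs$start + 1L) / analysis_rate)
  }))
  if (is.null(bouts)) {
    bouts <- data.frame(behavior = character(0), start_frame = integer(0),
                        end_frame = integer(0), duration_s = numeric(0))
  }
  all_classes <- union(ETHOGRAM_CLASSES, unique(labels))
  summary <- do.call(rbind, lapply(all_classes, function(cl) {
    b <- bouts[bouts$behavior == cl, , drop = FALSE]
    if (nrow(b) == 0L) {
      return(data.frame(behavior = cl, n_bouts = 0L,
                        mean_duration_min = NA_real_,
                        longest_pause_min = NA_real_))
    }
    pauses <- if (nrow(b) >= 2L) {
      (b$start_frame[-1L] - b$end_frame[-nrow(b)] - 1L) / analysis_rate / 60
    } else {
      NA_real_
    }
    data.frame(behavior = cl, n_bouts = nrow(b),
               mean_duration_min = mean(b$duration_s) / 60,
               longest_pause_min = if (all(is.na(pauses))) NA_real_
                                   else max(pauses, na.rm = TRUE))
  }))
  structure(list(bouts = bouts, summary = summary), class = "groom_bouts")
}
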