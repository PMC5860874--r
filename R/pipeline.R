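# End-to-end orchestration: configuration, training-set construction
# from synthetic videos, full detection runs, and rhythm batches.

#' Pipeline configuration
#'
#' Collects every threshold of the pipeline, with defaults equal to the
#' platform's standard values: C0 = 10 gray levels, C1 = 25 px, minimum
#' CD 0.5 px, 12/15 pruning, k = 10 neighbors, 5-min sleep rule, 3-s
#' feeding rule, 30-min bins, 1000-s background refresh, 10 Hz video
#' analyzed at 5 Hz.
#'
#' @param C0 grayscale-change threshold.
#' @param C1 minimum blob area (px).
#' @param min_cd minimum centroid displacement (px).
#' @param window,min_grooming pruning filter size and minimum.
#' @param k kNN neighbors.
#' @param sleep_threshold_s quiescence duration defining sleep.
#' @param feeding_min_s minimum (exclusive) feeding duration.
#' @param bin_minutes ethogram bin width.
#' @param background_interval_s background refresh interval.
#' @param native_rate,analysis_step video rate and analysis stride.
#' @param sqrt_transform dimension-homogenizing square root in feature
#'   normalization.
#' @param seed base seed used for all stochastic stages.
#' @return object of class `groom_config`.
#' @export
groom_config <- function(C0 = 10, C1 = 25, min_cd = 0.5, window = 15,
                         min_grooming = 12, k = 10, sleep_threshold_s = 300,
                         feeding_min_s = 3, bin_minutes = 30,
                         background_interval_s = 1000, native_rate = 10,
                         analysis_step = 2L, sqrt_transform = TRUE,
                         seed = 1L) {
  cfg <- list(C0 = C0, C1 = C1, min_cd = min_cd, window = window,
              min_grooming = min_grooming, k = k,
              sleep_threshold_s = sleep_threshold_s,
              feeding_min_s = feeding_min_s, bin_minutes = bin_minutes,
              background_interval_s = background_interval_s,
              native_rate = native_rate, analysis_step = analysis_step,
              sqrt_transform = sqrt_transform, seed = seed)
  for (nm in setdiff(names(cfg), c("seed", "sqrt_transform"))) {
    stop_if_not_scalar_pos(cfg[[nm]], nm)
  }
  structure(cfg, class = "groom_config")
}

# ground-truth label of each analyzed-frame pair: the script label of
# the later native frame; `pure` additionally requires both analyzed
# frames of the pair to carry the same script label
pair_truth <- function(script, clock, pure = FALSE) {
  lab <- script$labels[clock$analyzed_native]
  later <- lab[-1L]
  if (!pure) return(later)
  earlier <- lab[-length(lab)]
  later[earlier != later] <- NA_character_
  later
}

# collapse the five-class script alphabet to the classifier's three
to_three_class <- function(labels) {
  labels[labels %in% c("sleep", "short_rest")] <- "rest"
  labels[labels == "feeding"] <- "locomotion"
  labels
}

#' Build a labeled training set from synthetic videos
#'
#' Renders scripted grooming/locomotion/rest videos, runs segmentation
#' and feature extraction, and labels each analyzed-frame pair with the
#' script's ground truth. Pairs straddling a bout boundary are dropped,
#' mirroring how visually unambiguous frames would be picked for manual
#' labeling.
#'
#' @param n_videos number of training videos.
#' @param duration_s length of each video (seconds).
#' @param appearance a [fly_appearance()].
#' @param config a [groom_config()].
#' @param seed base seed (each video derives its own).
#' @return data.frame of class `groom_training` with `nPM`, `nCM`,
#'   `nCD`, `label`.
#' @export
make_training_set <- function(n_videos = 4, duration_s = 600,
                              appearance = fly_appearance(),
                              config = groom_config(), seed = 100L) {
  out <- vector("list", n_videos)
  for (v in seq_len(n_videos)) {
    sc <- generate_ethogram_script(duration_s, config$native_rate,
                                   behaviors = c("grooming", "locomotion", "rest"),
                                   analysis_step = config$analysis_step,
                                   seed = child_seed(seed, v))
    vid <- render_video(sc, appearance, seed = child_seed(seed, 1000 + v))
    feats <- extract_feature_series(
      vid, C0 = config$C0, C1 = config$C1, min_cd = config$min_cd,
      background_interval_s = config$background_interval_s,
      analysis_step = config$analysis_step,
      sqrt_transform = config$sqrt_transform,
      seed = child_seed(seed, 2000 + v)
    )
    clock <- attr(feats, "segmentation")$clock
    truth <- pair_truth(sc, clock, pure = TRUE)
    keep <- !is.na(truth) & feats$detected
    out[[v]] <- data.frame(nPM = feats$nPM[keep], nCM = feats$nCM[keep],
                           nCD = feats$nCD[keep], label = truth[keep])
  }
  res <- do.call(rbind, out)
  class(res) <- c("groom_training", "data.frame")
  res
}

#' Run the full detection pipeline on one video
#'
#' Background modeling, segmentation, feature extraction, kNN
#' classification, temporal pruning, feeding and sleep annotation,
#' ethogram assembly, binning and bout statistics.
#'
#' @param video a `groom_video` (or array with `roi`/`frame_rate`
#'   supplied through `roi` and `config`).
#' @param model a fitted [fit_knn()] classifier.
#' @param roi optional [tube_roi()] override.
#' @param config a [groom_config()].
#' @param out_dir optional directory for CSV outputs.
#' @return list of class `groom_detection` with `features`,
#'   `raw_labels`, `pruned_labels`, `feeding`, `rest_bouts`, `ethogram`,
#'   `binned`, `bouts`, `body_length`, `config`.
#' @export
run_detect <- function(video, model, roi = NULL, config = groom_config(),
                       out_dir = NULL) {
  stopifnot(inherits(model, "groom_knn"))
  roi <- roi %||% attr(video, "roi")
  feats <- extract_feature_series(
    video, roi, C0 = config$C0, C1 = config$C1, min_cd = config$min_cd,
    background_interval_s = config$background_interval_s,
    analysis_step = config$analysis_step, frame_rate = config$native_rate,
    sqrt_transform = config$sqrt_transform, seed = config$seed
  )
  seg <- attr(feats, "segmentation")
  rate <- seg$clock$analysis_rate
  raw <- classify(model, feats)
  pruned <- prune_labels(raw, config$window, config$min_grooming)
  body_len <- estimate_body_length(seg$observations, roi)
  food <- roi$food_position
  feeding <- detect_feeding(feats$centroid_axis, food, body_len,
                            analysis_rate = rate,
                            min_duration_s = config$feeding_min_s)
  rest_bouts <- classify_rest_bouts(pruned, analysis_rate = rate,
                                    sleep_threshold_s = config$sleep_threshold_s)
  eth <- assemble_ethogram(pruned, feeding, rest_bouts,
                           analysis_rate = rate, fly_id = roi$fly_id)
  binned <- bin_fractions(eth, bin_minutes = config$bin_minutes,
                          analysis_rate = rate)
  bouts <- bout_statistics(eth, analysis_rate = rate)
  res <- structure(
    list(features = feats, raw_labels = raw, pruned_labels = pruned,
         feeding = feeding, rest_bouts = rest_bouts, ethogram = eth,
         binned = binned, bouts = bouts, body_length = body_len,
         config = config),
    class = "groom_detection"
  )
  if (!is.null(out_dir)) write_detection(res, out_dir, fly_id = roi$fly_id)
  res
}

#' Train (and cross-validate) the kNN classifier
#'
#' @param labeled data.frame with `nPM`, `nCM`, `nCD`, `label`, or a
#'   path to a CSV in that format. Rows with labels outside the
#'   three-class alphabet are rejected with a warning.
#' @param config a [groom_config()].
#' @param cv run 10-fold cross-validation over `k_range`.
#' @param k_range candidate k values for the CV report.
#' @param out_file optional path to persist the model (RDS).
#' @return list with `model` (a `groom_knn`) and `cv` (data.frame or
#'   NULL).
#' @export
run_train <- function(labeled, config = groom_config(), cv = FALSE,
                      k_range = 1:50, out_file = NULL) {
  if (is.character(labeled)) labeled <- read_training_csv(labeled)
  if (nrow(labeled) == 0L) stop("training set is empty", call. = FALSE)
  bad <- !(labeled$label %in% BEHAVIOR_CLASSES)
  if (any(bad)) {
    warning(sprintf("rejected %d rows with labels outside %s", sum(bad),
                    paste(BEHAVIOR_CLASSES, collapse = "/")))
    labeled <- labeled[!bad, , drop = FALSE]
  }
  model <- fit_knn(labeled, labeled$label, k = config$k)
  cv_report <- if (cv) {
    cross_validate(labeled, labeled$label, k_range = k_range,
                   seed = child_seed(config$seed, 7))
  } else {
    NULL
  }
  if (!is.null(out_file)) saveRDS(list(model = model, cv = cv_report),
                                  out_file)
  list(model = model, cv = cv_report)
}

#' Rhythm analysis of one or more binned series
#'
#' @param series a `groom_binned` or list of them.
#' @param band_h circadian band for the dominant period.
#' @param fit also fit the two-peak model.
#' @param period_band_h,oversample periodogram grid settings.
#' @return for each series: list with `periodogram`, `dominant` and
#'   optionally `fit`.
#' @export
run_rhythm <- function(series, band_h = c(16, 32), fit = FALSE,
                       period_band_h = c(1, 48), oversample = 16) {
  one <- function(s) {
    pg <- lomb_scargle(s, period_band_h = period_band_h,
                       oversample = oversample)
    out <- list(periodogram = pg, dominant = dominant_period(pg, band_h))
    if (fit) out$fit <- fit_two_peak_model(s)
    out
  }
  if (inherits(series, "groom_binned")) one(series) else lapply(series, one)
}

#' Benchmark the pipeline on synthetic videos
#'
#' Generates scripted grooming/locomotion/rest videos, runs the full
#' detection chain with a supplied classifier, and pools the frame-level
#' grooming confusion counts against the scripts' ground truth.
#'
#' @param model classifier trained on a disjoint fixture.
#' @param n_videos,duration_s benchmark size.
#' @param appearance appearance used for the benchmark videos.
#' @param config a [groom_config()].
#' @param seed base seed; must differ from the training fixture's.
#' @return list with pooled `accuracy` (grooming precision),
#'   `sensitivity` (recall), the pooled counts and a per-video
#'   data.frame.
#' @export
benchmark_pipeline <- function(model, n_videos = 10, duration_s = 600,
                               appearance = fly_appearance(),
                               config = groom_config(), seed = 500L) {
  tp <- fp <- fn <- 0
  per_video <- vector("list", n_videos)
  for (v in seq_len(n_videos)) {
    sc <- generate_ethogram_script(duration_s, config$native_rate,
                                   behaviors = c("grooming", "locomotion", "rest"),
                                   analysis_step = config$analysis_step,
                                   seed = child_seed(seed, v))
    vid <- render_video(sc, appearance, seed = child_seed(seed, 1000 + v))
    feats <- extract_feature_series(
      vid, C0 = config$C0, C1 = config$C1, min_cd = config$min_cd,
      background_interval_s = config$background_interval_s,
      analysis_step = config$analysis_step,
      sqrt_transform = config$sqrt_transform,
      seed = child_seed(seed, 2000 + v)
    )
    clock <- attr(feats, "segmentation")$clock
    truth <- pair_truth(sc, clock, pure = FALSE)
    raw <- classify(model, feats)
    pruned <- prune_labels(raw, config$window, config$min_grooming)
    ev <- evaluate_labels(pruned, truth)
    tp <- tp + ev$tp; fp <- fp + ev$fp; fn <- fn + ev$fn
    per_video[[v]] <- data.frame(video = v, tp = ev$tp, fp = ev$fp,
                                 fn = ev$fn)
  }
  list(
    accuracy = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn,
    per_video = do.call(rbind, per_video)
  )
}
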