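# Plain-text and PNG I/O: frame sequences, ROI configuration, label and
# training CSVs. Every CSV written by the package carries a provenance
# header (package version and seed) as comment lines.

provenance_header <- function(seed = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("groomr")),
                  error = function(e) "dev")
  c(sprintf("# groomr %s", ver),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

write_groomr_csv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_groomr_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a video as a numbered PNG frame sequence
#'
#' @param video a `groom_video` or 3-D array with values in 0-255.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix; frames are `prefix_000001.png`, ...
#' @return invisibly, the written file paths.
#' @export
write_frames_png <- function(video, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(video)[3]
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix, seq_len(n)))
  for (i in seq_len(n)) {
    png::writePNG(video[, , i] / 255, paths[i])
  }
  invisible(paths)
}

#' Read a PNG frame sequence as a video array
#'
#' Files are read in lexicographic order. Color PNGs are converted to
#' grayscale by channel averaging with a warning.
#'
#' @param dir directory containing the frames, or a character vector of
#'   file paths.
#' @param frame_rate native frame rate recorded on the result.
#' @return a `groom_video` integer array.
#' @export
read_frames_png <- function(dir, frame_rate = 10) {
  paths <- if (length(dir) == 1L && dir.exists(dir)) {
    sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  } else {
    dir
  }
  if (length(paths) == 0L) stop("no PNG frames found", call. = FALSE)
  first <- png::readPNG(paths[1])
  to_gray <- function(img) {
    if (length(dim(img)) == 3L) {
      img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                   c(1, 2), mean)
    }
    img
  }
  warned <- FALSE
  first <- png::readPNG(paths[1])
  if (length(dim(first)) == 3L) {
    warning("color frames converted to grayscale by channel averaging")
    warned <- TRUE
  }
  first <- to_gray(first)
  video <- array(0L, dim = c(nrow(first), ncol(first), length(paths)))
  for (i in seq_along(paths)) {
    img <- to_gray(png::readPNG(paths[i]))
    video[, , i] <- as.integer(round(img * 255))
  }
  structure(video, frame_rate = frame_rate, class = "groom_video")
}

#' Write / read a tube ROI configuration (JSON)
#'
#' @param rois a [tube_roi()] or list of them.
#' @param path JSON file path.
#' @return `write_roi_json` returns the path invisibly; `read_roi_json`
#'   a list of `groom_roi`.
#' @export
write_roi_json <- function(rois, path) {
  if (inherits(rois, "groom_roi")) rois <- list(rois)
  payload <- lapply(rois, function(r) {
    list(fly_id = r$fly_id, rect = r$rect, axis = r$axis,
         food_position = r$food_position)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    tube_roi(rect = unlist(payload$rect[i]), axis = unlist(payload$axis[i]),
             food_position = payload$food_position[i],
             fly_id = payload$fly_id[i])
  })
}

#' Read a labeled training CSV
#'
#' Expected columns: `nPM`, `nCM`, `nCD`, `label`.
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @return data.frame.
#' @export
read_training_csv <- function(path) {
  df <- read_groomr_csv(path)
  need <- c("nPM", "nCM", "nCD", "label")
  if (!all(need %in% names(df))) {
    stop("training CSV must have columns nPM, nCM, nCD, label", call. = FALSE)
  }
  df[, need]
}

# write the CSV outputs of one detection run
write_detection <- function(res, out_dir, fly_id = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- res$config$seed
  n <- length(res$raw_labels)
  write_groomr_csv(
    data.frame(fly_id = fly_id, analyzed_frame = seq_len(n),
               raw_label = res$raw_labels, pruned_label = res$pruned_labels),
    file.path(out_dir, sprintf("labels_fly%s.csv", fly_id)), seed)
  write_groomr_csv(
    data.frame(fly_id = fly_id, res$ethogram),
    file.path(out_dir, sprintf("ethogram_fly%s.csv", fly_id)), seed)
  write_groomr_csv(
    data.frame(fly_id = fly_id, res$binned),
    file.path(out_dir, sprintf("binned_fly%s.csv", fly_id)), seed)
  write_groomr_csv(
    data.frame(fly_id = fly_id, res$bouts$bouts),
    file.path(out_dir, sprintf("bouts_fly%s.csv", fly_id)), seed)
  invisible(out_dir)
}
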