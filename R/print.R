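# Compact print methods for the package's S3 containers.

#' @export
print.groom_script <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<groom_script> %d frames @ %g Hz (%.1f min), %d bouts\n",
              length(x$labels), x$frame_rate,
              length(x$labels) / x$frame_rate / 60, nrow(x$bouts)))
  print(round(tb / sum(tb), 3))
  invisible(x)
}

#' @export
print.groom_video <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<groom_video> %d x %d px, %d frames @ %g Hz\n",
              d[1], d[2], d[3], attr(x, "frame_rate") %||% NA))
  invisible(x)
}

#' @export
print.groom_knn <- function(x, ...) {
  cat(sprintf("<groom_knn> k = %d, %d training samples (%s)\n",
              x$k, x$n, paste(names(table(x$labels)), table(x$labels),
                              sep = ": ", collapse = ", ")))
  invisible(x)
}

#' @export
print.groom_config <- function(x, ...) {
  cat("<groom_config>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s = %s\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.groom_periodogram <- function(x, ...) {
  cat(sprintf(
    "<groom_periodogram> %d frequencies (N_eff = %d), thresholds p05 = %.2f, p01 = %.2f\n",
    attr(x, "N"), attr(x, "N_eff"), attr(x, "threshold_p05"),
    attr(x, "threshold_p01")))
  peak <- x[which.max(x$power), ]
  cat(sprintf("  peak: %.2f h at power %.2f\n", peak$period_h, peak$power))
  invisible(x)
}

#' @export
print.groom_peakfit <- function(x, ...) {
  cat(sprintf("<groom_peakfit> %s, fit_error = %.4g\n",
              x$message, x$fit_error))
  print(round(x$params, 4))
  invisible(x)
}

#' @export
print.groom_cor <- function(x, ...) {
  cat(sprintf("<groom_cor> r = %.3f, bootstrap p = %.3g (%d resamples)\n",
              x$r, x$p_boot, x$n_resamples))
  invisible(x)
}

#' @export
print.groom_detection <- function(x, ...) {
  tb <- table(x$ethogram$behavior)
  cat(sprintf("<groom_detection> %d analyzed frame pairs\n",
              nrow(x$ethogram)))
  print(round(tb / sum(tb), 3))
  invisible(x)
}
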