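#' Analysis clock: mapping from native to analyzed frames
#'
#' Video is recorded at a native rate (10 Hz by default) but analyzed on
#' every `analysis_step`-th frame (every second frame, i.e. 5 Hz), which
#' is sufficient to capture grooming events. The clock records the
#' native-frame index of every analyzed frame.
#'
#' @param n_native_frames total number of native video frames.
#' @param native_rate native frame rate in frames/second.
#' @param analysis_step analyze every `analysis_step`-th native frame.
#' @return an object of class `groom_clock` with elements `native_rate`,
#'   `analysis_rate`, `analyzed_native` (1-based native indices of the
#'   analyzed frames) and `n_analyzed`.
#' @examples
#' ck <- analysis_clock(100)
#' ck$analysis_rate  # 5
#' head(ck$analyzed_native)
#' @export
analysis_clock <- function(n_native_frames, native_rate = 10,
                           analysis_step = 2L) {
  stop_if_not_scalar_pos(n_native_frames, "n_native_frames")
  stop_if_not_scalar_pos(native_rate, "native_rate")
  stop_if_not_scalar_pos(analysis_step, "analysis_step")
  analyzed <- seq.int(1L, as.integer(n_native_frames), by = as.integer(analysis_step))
  structure(
    list(
      native_rate = native_rate,
      analysis_rate = native_rate / analysis_step,
      analyzed_native = analyzed,
      n_analyzed = length(analyzed)
    ),
    class = "groom_clock"
  )
}
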