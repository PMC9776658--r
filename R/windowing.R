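#' Overlapping-window specification
#'
#' Windows of `window_len` frames are cut from each clip with their start
#' indices `overlap_factor` frames apart (the "overlapping factor" is the
#' start stride, so consecutive windows share `window_len - overlap_factor`
#' frames). Trailing frames that cannot fill a complete window are
#' discarded.
#'
#' @param window_len Window length in frames (default 16).
#' @param overlap_factor Start-index stride in frames (default 5).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_len = 16L, overlap_factor = 5L) {
  window_len <- as.integer(window_len)
  overlap_factor <- as.integer(overlap_factor)
  if (is.na(window_len) || window_len < 1)
    stop_input("window_len must be >= 1")
  if (is.na(overlap_factor) || overlap_factor < 1)
    stop_input("overlap_factor must be >= 1")
  structure(list(window_len = window_len, overlap_factor = overlap_factor),
            class = "window_spec")
}

#' Number of complete windows in a clip
#'
#' Computes `floor((n_frames - window_len) / overlap_factor + 1)` when the
#' clip holds at least one full window, else 0; incomplete trailing windows
#' are never counted.
#'
#' @param n_frames Clip length(s) in frames (vectorized).
#' @param spec A [window_spec()].
#' @return Integer vector of window counts.
#' @export
#' @examples
#' count_windows(63)   # 10
#' count_windows(144)  # 26
count_windows <- function(n_frames, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  n_frames <- as.integer(n_frames)
  if (any(is.na(n_frames)) || any(n_frames < 0))
    stop_input("n_frames must be nonnegative")
  ifelse(n_frames >= spec$window_len,
         (n_frames - spec$window_len) %/% spec$overlap_factor + 1L,
         0L)
}

#' Enumerate the labeled windows of a clip
#'
#' Emits one record per complete window: the k-th window (k = 0, 1, ...)
#' covers frames `[k * overlap_factor, k * overlap_factor + window_len)`,
#' 0-based half-open, and inherits the clip's phase label.
#'
#' @param clip A labeled `raw_clip`, or any list with elements
#'   `source_id`, `label` and either `frames` or `n_frames`.
#' @param spec A [window_spec()].
#' @return A data frame with columns `clip_id`, `window_index` (0-based),
#'   `start`, `end` (0-based half-open) and `label`.
#' @export
enumerate_windows <- function(clip, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  nf <- if (!is.null(clip$frames)) length(clip$frames) else as.integer(clip$n_frames)
  label <- clip$label
  if (is.null(label) || identical(label, "none"))
    stop_input("clip '", clip$source_id, "' is unlabeled")
  if (!label %in% PHASES)
    stop_input("unknown label '", label, "'")
  k <- count_windows(nf, spec)
  if (k == 0)
    return(data.frame(clip_id = character(), window_index = integer(),
                      start = integer(), end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  idx <- 0:(k - 1L)
  data.frame(clip_id = clip$source_id,
             window_index = idx,
             start = idx * spec$overlap_factor,
             end = idx * spec$overlap_factor + spec$window_len,
             label = label,
             stringsAsFactors = FALSE)
}

#' Write / read a window manifest
#'
#' The manifest is the JSON serialization of the sample records produced by
#' [enumerate_windows()] (one array of records per dataset split).
#'
#' @param manifest Data frame of sample records.
#' @param path JSON file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the data frame.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Extract the grayscale frame window for one sample record
#'
#' @param gray_frames List of canonical 128 x 128 grayscale frames for the
#'   whole clip (see [to_gray_frame()]).
#' @param record One row of the manifest (list or single-row data frame).
#' @return List of `window_len` frames.
#' @export
window_frames <- function(gray_frames, record) {
  start <- as.integer(record$start)
  end <- as.integer(record$end)
  if (start < 0 || end > length(gray_frames))
    stop_input("frame range [", start, ",", end, ") outside clip bounds")
  gray_frames[(start + 1L):end]
}
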