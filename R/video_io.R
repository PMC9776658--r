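#' @section Frame geometry:
#' All internal processing uses single-channel frames of FRAME_SIDE x
#' FRAME_SIDE pixels with intensities in [0,1]; 8-bit quantization happens
#' only at file boundaries.
#' @name video_io
#' @keywords internal
NULL

FRAME_SIDE <- 128L

## Separable resampling weights mapping n_in samples onto n_out.
## Downscaling uses area (box) overlap weights, which preserve the image
## mean exactly; upscaling uses bilinear interpolation of pixel centers.
resample_weights <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  w <- matrix(0, n_out, n_in)
  if (n_out < n_in) {
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * scale
      hi <- i * scale
      j0 <- floor(lo) + 1L
      j1 <- ceiling(hi)
      for (j in j0:min(j1, n_in)) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) w[i, j] <- ov / scale
      }
    }
  } else {
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * scale - 0.5
      j <- floor(src)
      frac <- src - j
      j0 <- min(max(j + 1L, 1L), n_in)
      j1 <- min(max(j + 2L, 1L), n_in)
      w[i, j0] <- w[i, j0] + (1 - frac)
      w[i, j1] <- w[i, j1] + frac
    }
  }
  w
}

resize_gray <- function(x, side = FRAME_SIDE) {
  wr <- resample_weights(nrow(x), side)
  wc <- resample_weights(ncol(x), side)
  wr %*% x %*% t(wc)
}

#' Convert an image to a canonical grayscale frame
#'
#' Reduces a 1- or 3-channel intensity image to a single channel with
#' ITU-R BT.601 luminance weights (0.299 R + 0.587 G + 0.114 B) and resizes
#' it to the canonical 128 x 128 geometry. Downscaling uses area-weighted
#' (anti-aliased) resampling so the image mean is preserved; upscaling uses
#' bilinear interpolation. Output intensities are clamped to [0,1].
#'
#' @param image A numeric matrix (grayscale) or H x W x 3 array (RGB, in
#'   that channel order) with finite intensities in [0,1].
#' @return A 128 x 128 numeric matrix with values in [0,1].
#' @export
#' @examples
#' f <- to_gray_frame(matrix(0.5, 64, 64))
#' dim(f)
to_gray_frame <- function(image) {
  if (is.null(image) || length(image) == 0)
    stop_input("empty image")
  if (!is.numeric(image))
    stop_input("image must be numeric")
  if (any(!is.finite(image)))
    stop_input("image contains non-finite pixels")
  d <- dim(image)
  if (is.null(d) || length(d) < 2 || d[1] < 1 || d[2] < 1)
    stop_input("image must be a 2-D matrix or H x W x C array")
  if (length(d) == 3) {
    if (d[3] == 1) {
      image <- image[, , 1]
    } else if (d[3] >= 3) {
      image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    } else {
      stop_input("image must have 1 or 3 channels, got ", d[3])
    }
  }
  out <- resize_gray(image)
  pmin(pmax(out, 0), 1)
}

#' Construct a raw video clip
#'
#' A raw clip is an ordered list of same-sized intensity frames at their
#' native resolution, with a nominal frame rate and an optional fall-phase
#' label.
#'
#' @param frames List of numeric matrices (grayscale) or H x W x 3 arrays,
#'   all sharing one native size.
#' @param fps Nominal frames per second (default 30).
#' @param label One of `fall_phases()` or `"none"` for unlabeled clips.
#' @param source_id Opaque identifier string for the clip.
#' @return An object of class `raw_clip`.
#' @export
raw_clip <- function(frames, fps = 30, label = "none", source_id = "clip") {
  if (!is.list(frames) || length(frames) < 1)
    stop_input("a clip needs at least one frame")
  sizes <- vapply(frames, function(f) paste(dim(f)[1:2], collapse = "x"), "")
  if (length(unique(sizes)) != 1)
    stop_input("all frames must share one native size; got ",
               paste(unique(sizes), collapse = ", "))
  if (!label %in% c(PHASES, "none"))
    stop_input("label must be one of ", paste(c(PHASES, "none"), collapse = ", "))
  structure(list(frames = frames, fps = fps, label = label,
                 source_id = source_id),
            class = "raw_clip")
}

#' @export
print.raw_clip <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<raw_clip '%s': %d frames %dx%d @ %g fps, label=%s>\n",
              x$source_id, length(x$frames), d[1], d[2], x$fps, x$label))
  invisible(x)
}

#' Number of frames in a clip
#' @param clip A `raw_clip`.
#' @return Integer frame count.
#' @export
n_frames <- function(clip) length(clip$frames)

#' Write a clip as a directory of PNG frames
#'
#' Frames are written as zero-padded `frame_0001.png`, ... (8-bit grayscale
#' or RGB) plus a `clip.json` sidecar holding fps, label and source id.
#'
#' @param clip A `raw_clip`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_clip <- function(clip, dir) {
  stopifnot(inherits(clip, "raw_clip"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(clip$frames)) {
    png::writePNG(pmin(pmax(clip$frames[[i]], 0), 1),
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  meta <- list(fps = clip$fps, label = clip$label, source_id = clip$source_id,
               n_frames = length(clip$frames))
  jsonlite::write_json(meta, file.path(dir, "clip.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a clip from a directory of frame images
#'
#' Reads all PNG files in `path` in strict lexicographic order as the frame
#' sequence. A `clip.json` sidecar (as written by [write_clip()]) supplies
#' fps, label and source id; otherwise fps defaults to 30 and the clip is
#' unlabeled unless `label` is given. Video containers are not decoded;
#' extract frames to a directory first.
#'
#' @param path Directory containing frame images.
#' @param label Optional phase label overriding the sidecar.
#' @return A `raw_clip`.
#' @export
load_clip <- function(path, label = NULL) {
  if (!dir.exists(path)) {
    if (file.exists(path))
      stop_input("'", path, "' is a file, not a frame directory; ",
                 "video containers are not decoded - extract frames first")
    stop_input("cannot read '", path, "'")
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    stop_input("no decodable frames in '", path, "'")
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    d <- dim(img)
    if (length(d) == 3 && d[3] == 4) img <- img[, , 1:3]   # drop alpha
    if (length(d) == 3 && d[3] == 2) img <- img[, , 1]     # gray+alpha
    img
  })
  meta <- list(fps = 30, label = "none", source_id = basename(path))
  mf <- file.path(path, "clip.json")
  if (file.exists(mf)) {
    got <- jsonlite::read_json(mf, simplifyVector = TRUE)
    meta[names(got)[names(got) %in% names(meta)]] <-
      got[names(got) %in% names(meta)]
  }
  if (!is.null(label)) meta$label <- label
  raw_clip(frames, fps = meta$fps, label = meta$label,
           source_id = meta$source_id)
}

#' Write a fused stack to disk
#'
#' Writes the four level-2 fused images as 8-bit PNGs named
#' `<clip_id>_w<window_idx>_b<1..4>.png` plus a JSON sidecar recording the
#' clip id, label, window index and frame range.
#'
#' @param stack A `fused_stack` (see [two_level_fuse()]).
#' @param dir Output directory (created if missing).
#' @param clip_id Source clip identifier.
#' @param window_idx 0-based window index within the clip.
#' @param label Phase label of the window.
#' @param frame_range Integer `c(start, end)`, 0-based half-open.
#' @return Character vector of the four PNG paths, invisibly.
#' @export
write_fused_stack <- function(stack, dir, clip_id, window_idx,
                              label = "none", frame_range = c(NA, NA)) {
  stopifnot(inherits(stack, "fused_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(4)
  for (b in 1:4) {
    paths[b] <- file.path(dir, sprintf("%s_w%d_b%d.png", clip_id, window_idx, b))
    png::writePNG(stack[[b]], paths[b])
  }
  side <- list(clip_id = clip_id, label = label, window_index = window_idx,
               frame_range = frame_range, images = basename(paths))
  jsonlite::write_json(side,
                       file.path(dir, sprintf("%s_w%d.json", clip_id, window_idx)),
                       auto_unbox = TRUE)
  invisible(paths)
}

#' Read a fused stack written by [write_fused_stack()]
#'
#' @param dir Directory holding the PNGs and sidecar.
#' @param clip_id,window_idx Identify the stack.
#' @return A `fused_stack` with the sidecar metadata attached as attributes.
#' @export
read_fused_stack <- function(dir, clip_id, window_idx) {
  side <- jsonlite::read_json(
    file.path(dir, sprintf("%s_w%d.json", clip_id, window_idx)),
    simplifyVector = TRUE)
  imgs <- lapply(file.path(dir, side$images), png::readPNG)
  st <- structure(imgs, class = "fused_stack")
  attr(st, "label") <- side$label
  attr(st, "clip_id") <- side$clip_id
  attr(st, "window_index") <- side$window_index
  st
}
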