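#' Pairwise false-color image fusion
#'
#' Combines two grayscale frames into one RGB image that colorizes their
#' temporal difference: the first frame drives the green channel, the second
#' drives red and blue. Pixels where the frames agree come out achromatic
#' (equal channels, i.e. gray); pixels that changed between the frames come
#' out green or magenta depending on the sign of the change. The operator is
#' purely per-pixel channel assignment, so outputs stay in [0,1] without
#' clipping and the result is deterministic and local.
#'
#' @param a,b Numeric matrices of identical size with values in [0,1];
#'   `a` is the earlier frame.
#' @return An H x W x 3 array of class `fused_image` with attribute
#'   `level = 1`.
#' @export
#' @examples
#' f <- fuse_pair(matrix(0, 8, 8), matrix(1, 8, 8))
#' f[1, 1, ]  # pure magenta: R = B = 1, G = 0
fuse_pair <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b))
    stop_input("fuse_pair expects single-channel matrices")
  if (!identical(dim(a), dim(b)))
    stop_input("frame shape mismatch: ", paste(dim(a), collapse = "x"),
               " vs ", paste(dim(b), collapse = "x"))
  out <- array(0, c(dim(a), 3L))
  out[, , 1] <- b
  out[, , 2] <- a
  out[, , 3] <- b
  structure(out, class = "fused_image", level = 1L)
}

#' Luminance of an RGB image
#'
#' ITU-R BT.601 weighted sum 0.299 R + 0.587 G + 0.114 B, used to reduce a
#' level-1 fused image back to a single channel before level-2 fusion.
#'
#' @param img H x W x 3 numeric array.
#' @return H x W numeric matrix.
#' @export
luminance <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Two-level temporal fusion of a 16-frame window
#'
#' Reduces 16 grayscale frames to four RGB images, each summarizing four
#' consecutive frames. Level 1 fuses every odd frame with its successor
#' (frames 1+2, 3+4, ..., 15+16), giving eight fused images; each is reduced
#' to luminance and level 2 fuses them pairwise again, giving the four
#' level-2 images B1..B4 in temporal order. B1 depends only on frames 1-4,
#' B2 on 5-8, B3 on 9-12 and B4 on 13-16. A static window produces four
#' achromatic (zero-chroma) images; motion appears as green/magenta color.
#'
#' @param window List of exactly 16 grayscale frames (equal-size numeric
#'   matrices in [0,1]), in temporal order.
#' @return A `fused_stack`: list of 4 `fused_image` arrays (level 2).
#' @export
two_level_fuse <- function(window) {
  if (!is.list(window) || length(window) != 16)
    stop_input("two_level_fuse needs exactly 16 frames, got ",
               if (is.list(window)) length(window) else "a non-list")
  level1 <- lapply(1:8, function(k) fuse_pair(window[[2 * k - 1]], window[[2 * k]]))
  level2 <- lapply(1:4, function(k) {
    img <- fuse_pair(luminance(level1[[2 * k - 1]]), luminance(level1[[2 * k]]))
    attr(img, "level") <- 2L
    img
  })
  structure(level2, class = "fused_stack")
}

#' Per-pixel chroma of a fused image
#'
#' Max channel minus min channel at every pixel; zero wherever the two fused
#' inputs were equal (no motion), positive where they differed.
#'
#' @param img A `fused_image` or H x W x 3 array.
#' @return H x W numeric matrix of chroma values.
#' @export
chroma <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  pmax(img[, , 1], img[, , 2], img[, , 3]) -
    pmin(img[, , 1], img[, , 2], img[, , 3])
}

#' Convert a fused stack to a 4-D array
#'
#' @param stack A `fused_stack`.
#' @return Numeric array H x W x 3 x 4 (the model's input sample layout).
#' @export
stack_to_array <- function(stack) {
  stopifnot(inherits(stack, "fused_stack"), length(stack) == 4)
  d <- dim(stack[[1]])
  out <- array(0, c(d[1], d[2], 3L, 4L))
  for (b in 1:4) out[, , , b] <- stack[[b]]
  out
}

#' @export
print.fused_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<fused_stack: 4 level-2 images %dx%dx3>\n", d[1], d[2]))
  invisible(x)
}
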