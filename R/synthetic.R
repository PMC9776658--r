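#' Scene configuration for the synthetic fall simulator
#'
#' The simulator renders one actor — an ellipse silhouette — against a flat
#' background, producing pre-segmented clips (one fall phase per clip) with
#' the structure the classifier assumes: 63-144 frames at a nominal 30 fps,
#' one of four phase labels per clip. It exercises the full pipeline
#' (motion -> fusion chroma -> classification) deterministically and without
#' external data; it does not emulate occlusions, shadows, illumination
#' changes or articulated motion.
#'
#' @param image_size Native frame size c(height, width) in pixels.
#' @param fps Nominal frames per second.
#' @param n_clips_per_class Clips rendered per phase label.
#' @param frame_count_range Inclusive range the per-clip frame count is
#'   drawn from (uniformly).
#' @param actor Ellipse half-axes in pixels, c(half_width, half_height) of
#'   the standing body.
#' @param fall_duration Frames over which a falling clip rotates from
#'   vertical to horizontal; `NA` (default) spans the whole clip, matching
#'   pre-segmented falling sub-clips that contain exactly the transition.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise;
#'   0 renders noiseless (and fully static for static phases).
#' @param background Background intensity in [0,1].
#' @param actor_intensity Silhouette intensity in [0,1].
#' @param jitter_px Amplitude of the walking actor's random lateral jitter.
#' @param seed Base seed for [make_dataset()].
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(240L, 320L), fps = 30,
                         n_clips_per_class = 10L,
                         frame_count_range = c(63L, 144L),
                         actor = c(half_width = 14, half_height = 55),
                         fall_duration = NA, noise_sigma = 0.02,
                         background = 0.15, actor_intensity = 0.85,
                         jitter_px = 2, seed = 1L) {
  if (any(frame_count_range < 1) ||
      frame_count_range[2] < frame_count_range[1])
    stop_input("frame_count_range must be a positive increasing range")
  if (noise_sigma < 0) stop_input("noise_sigma must be >= 0")
  structure(list(image_size = as.integer(image_size), fps = fps,
                 n_clips_per_class = as.integer(n_clips_per_class),
                 frame_count_range = as.integer(frame_count_range),
                 actor = actor, fall_duration = fall_duration,
                 noise_sigma = noise_sigma, background = background,
                 actor_intensity = actor_intensity, jitter_px = jitter_px,
                 seed = as.integer(seed)),
            class = "scene_config")
}

render_ellipse <- function(X, Yup, cx, cy_up, long, short, theta_deg,
                           bg, fg) {
  th <- theta_deg * pi / 180
  u <- (X - cx) * cos(th) + (Yup - cy_up) * sin(th)
  v <- -(X - cx) * sin(th) + (Yup - cy_up) * cos(th)
  inside <- (u / long)^2 + (v / short)^2 <= 1
  bg + (fg - bg) * inside
}

#' Render one synthetic fall-phase clip
#'
#' Phase semantics: `standing` is an upright ellipse walking in place
#' (lateral sway plus random jitter); `falling` rotates the body from
#' vertical (90 degrees) to horizontal (0 degrees) over `fall_duration`
#' frames while the center drops to the ground; `fallen` is a horizontal
#' ellipse lying still (micro-jitter only when noise is enabled); `other` is
#' a sitting motion — the vertical half-axis shrinks to ~60% and holds.
#' Gaussian pixel noise of `noise_sigma` is added to every frame and values
#' are clamped to [0,1]. The per-frame pose schedule (orientation, center,
#' axes) is attached to the clip as attribute `"schedule"`.
#'
#' @param phase One of [fall_phases()].
#' @param cfg A [scene_config()].
#' @param seed Integer seed; the same seed renders a bit-identical clip.
#' @param source_id Clip identifier.
#' @return A labeled `raw_clip`.
#' @export
render_clip <- function(phase, cfg = scene_config(), seed = 1L,
                        source_id = paste0(phase, "_", seed)) {
  if (!phase %in% PHASES)
    stop_input("invalid phase '", phase, "'")
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  hw <- unname(cfg$actor[1]); hh <- unname(cfg$actor[2])
  floor_up <- 8  # ground line height in up-coordinates
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Yup <- matrix(rep(H - seq_len(H), times = W), H, W)  # y measured upward
  with_local_seed(seed, {
    rng <- cfg$frame_count_range
    n <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    micro <- if (cfg$noise_sigma > 0) 1 else 0
    i <- seq_len(n)
    t01 <- if (n > 1) (i - 1) / (n - 1) else rep(0, n)
    sched <- switch(phase,
      standing = data.frame(
        theta = rep(90, n),
        cx = W / 2 + 8 * sin(2 * pi * 1.5 * t01) +
          runif(n, -cfg$jitter_px, cfg$jitter_px),
        cy = floor_up + hh + runif(n, -micro, micro),
        long = rep(hh, n), short = rep(hw, n)),
      falling = {
        dur <- if (is.finite(cfg$fall_duration)) cfg$fall_duration else n
        tf <- pmin((i - 1) / max(dur - 1, 1), 1)
        data.frame(
          theta = 90 * (1 - tf),
          cx = W / 2 + 0.6 * hh * tf,
          cy = floor_up + hh + (hw - hh) * tf,
          long = rep(hh, n), short = rep(hw, n))
      },
      fallen = data.frame(
        theta = rep(0, n),
        cx = W / 2 + runif(n, -micro, micro),
        cy = rep(floor_up + hw, n),
        long = rep(hh, n), short = rep(hw, n)),
      other = {
        shrink <- 1 - 0.4 * pmin(t01 / 0.4, 1)
        data.frame(
          theta = rep(90, n),
          cx = W / 2 + runif(n, -micro, micro),
          cy = floor_up + hh * shrink,
          long = hh * shrink, short = rep(hw, n))
      })
    frames <- lapply(seq_len(n), function(j) {
      f <- render_ellipse(X, Yup, sched$cx[j], sched$cy[j], sched$long[j],
                          sched$short[j], sched$theta[j],
                          cfg$background, cfg$actor_intensity)
      if (cfg$noise_sigma > 0)
        f <- f + matrix(rnorm(H * W, 0, cfg$noise_sigma), H, W)
      pmin(pmax(f, 0), 1)
    })
    clip <- raw_clip(frames, fps = cfg$fps, label = phase,
                     source_id = source_id)
    attr(clip, "schedule") <- sched
    clip
  })
}

#' Generate a class-balanced synthetic dataset
#'
#' Renders `n_clips_per_class` clips for each of the four phases with
#' deterministic per-clip seeds derived from `cfg$seed`, and assembles the
#' clip manifest. If `dir` is given, clips are written as PNG frame
#' directories (see [write_clip()]) plus a `manifest.json`.
#'
#' @param cfg A [scene_config()].
#' @param dir Optional output directory.
#' @return List with `clips` (list of `raw_clip`) and `manifest` (data frame
#'   with `clip_id`, `label`, `n_frames`, `fps`).
#' @export
make_dataset <- function(cfg = scene_config(), dir = NULL) {
  if (cfg$n_clips_per_class < 1)
    stop_input("n_clips_per_class must be >= 1")
  clips <- list()
  for (ci in seq_along(PHASES)) {
    for (j in seq_len(cfg$n_clips_per_class)) {
      id <- sprintf("%s_%03d", PHASES[ci], j)
      clip_seed <- (cfg$seed + ci * 7919L + j * 104729L) %%
        .Machine$integer.max
      clips[[id]] <- render_clip(PHASES[ci], cfg, seed = clip_seed,
                                 source_id = id)
    }
  }
  manifest <- data.frame(
    clip_id = names(clips),
    label = vapply(clips, function(c) c$label, ""),
    n_frames = vapply(clips, n_frames, 0L),
    fps = vapply(clips, function(c) c$fps, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(clips)) write_clip(clips[[id]], file.path(dir, id))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  list(clips = clips, manifest = manifest)
}
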