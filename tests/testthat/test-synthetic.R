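test_that("rendering is deterministic and respects the frame-count range", {
  cfg <- tiny_scene(frames = c(18L, 25L))
  c1 <- render_clip("standing", cfg, seed = 11)
  c2 <- render_clip("standing", cfg, seed = 11)
  expect_identical(c1$frames, c2$frames)
  expect_true(n_frames(c1) >= 18 && n_frames(c1) <= 25)
  expect_equal(c1$label, "standing")
  expect_error(render_clip("jumping", cfg), "invalid phase")
})

test_that("a noiseless fallen clip is fully static", {
  cfg <- tiny_scene(noise = 0)
  clip <- render_clip("fallen", cfg, seed = 2)
  for (i in 2:n_frames(clip))
    expect_identical(clip$frames[[i]], clip$frames[[1]])
  # hence downstream fusion is achromatic
  gray <- lapply(clip$frames[1:16], to_gray_frame)
  st <- two_level_fuse(gray)
  for (b in 1:4) expect_equal(max(chroma(st[[b]])), 0)
})

test_that("a falling clip rotates the body by 90 degrees", {
  cfg <- tiny_scene(frames = c(63L, 63L))
  cfg$fall_duration <- 16
  clip <- render_clip("falling", cfg, seed = 3)
  sched <- attr(clip, "schedule")
  expect_equal(abs(sched$theta[1] - sched$theta[16]), 90, tolerance = 1)
  # default: the rotation spans the whole clip
  cfg$fall_duration <- NA
  clip2 <- render_clip("falling", cfg, seed = 3)
  sched2 <- attr(clip2, "schedule")
  expect_equal(sched2$theta[1], 90)
  expect_equal(sched2$theta[n_frames(clip2)], 0)
})

test_that("datasets are class-balanced with deterministic per-clip seeds", {
  cfg <- tiny_scene(n_clips_per_class = 2L, frames = c(21L, 21L))
  ds <- make_dataset(cfg)
  expect_length(ds$clips, 8)
  expect_equal(unname(table(ds$manifest$label)[fall_phases()]),
               rep(2L, 4), ignore_attr = TRUE)
  ds2 <- make_dataset(cfg)
  expect_identical(ds$clips[[1]]$frames, ds2$clips[[1]]$frames)

  # 63-frame clips each yield exactly 10 windows at overlap 5
  cfg63 <- tiny_scene(n_clips_per_class = 1L, frames = c(63L, 63L))
  ds63 <- make_dataset(cfg63)
  prep <- prepare_samples(ds63)
  expect_equal(nrow(prep$records), 4 * count_windows(63))
  expect_equal(dim(prep$samples[[1]]), c(128L, 128L, 3L, 4L))
})

test_that("clip directories written by the simulator feed the loader", {
  d <- withr::local_tempdir()
  cfg <- tiny_scene(n_clips_per_class = 1L, frames = c(21L, 21L))
  ds <- make_dataset(cfg, dir = d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  id <- ds$manifest$clip_id[1]
  back <- load_clip(file.path(d, id))
  expect_equal(n_frames(back), ds$manifest$n_frames[1])
  expect_equal(back$label, ds$manifest$label[1])
})

test_that("standing and fallen silhouettes separate by centroid height", {
  cfg <- tiny_scene(n_clips_per_class = 4L, frames = c(21L, 21L), noise = 0)
  centroid_row <- function(phase, seed) {
    clip <- render_clip(phase, cfg, seed = seed)
    gray <- lapply(clip$frames[1:16], to_gray_frame)
    b4 <- two_level_fuse(gray)[[4]]
    lum <- luminance(b4)
    mask <- lum > (min(lum) + 0.3 * (max(lum) - min(lum)))
    mean(which(mask, arr.ind = TRUE)[, "row"])
  }
  stand <- vapply(1:4, function(s) centroid_row("standing", s), 0)
  fall <- vapply(1:4, function(s) centroid_row("fallen", s), 0)
  # every fallen centroid lies below (larger row index) every standing one
  expect_true(max(stand) < min(fall))
})

test_that("too few clips per class surfaces a configuration error", {
  cfg <- tiny_scene(n_clips_per_class = 2L, frames = c(21L, 21L))
  prep <- prepare_samples(make_dataset(cfg))
  expect_error(
    run_cv(prep, tiny_model_config(4L),
           train_config(epochs = 1, seed = 1), k = 3),
    class = "fallstream_config_error")
})
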