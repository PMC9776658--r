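test_that("default graph reproduces the published architecture", {
  g <- build_model(model_config())
  expect_equal(nrow(g$layers), 67L)
  expect_equal(spatial_trace(g), c(128L, 63L, 31L, 15L, 7L, 5L, 4L))
  expect_equal(g$concat_width, 1024L)

  # golden per-layer shape/channel table for one stream
  b1 <- g$layers[g$layers$branch == "1", ]
  conv <- b1[b1$kind == "conv", ]
  expect_equal(conv$out_h, c(63L, 15L, 5L))
  expect_equal(conv$out_c, c(64L, 128L, 256L))
  pool <- b1[b1$kind == "maxpool", ]
  expect_equal(pool$out_h, c(31L, 7L, 4L))
  gap <- b1[b1$kind == "gap", ]
  expect_equal(c(gap$out_h, gap$out_c), c(1L, 256L))
  fc <- g$layers[g$layers$kind == "fc", ]
  expect_equal(fc$out_c, c(64L, 32L, 4L))

  # every branch has the identical trace
  for (b in 2:4) {
    bb <- g$layers[g$layers$branch == as.character(b), ]
    expect_equal(bb$out_h, b1$out_h)
    expect_equal(bb$params, b1$params)
  }
})

test_that("shape propagation follows the valid-padding rule", {
  g <- propagate_shapes(build_model(model_config()))
  tr <- spatial_trace(g)
  # out = floor((in - k)/stride) + 1 at every step
  expect_equal(tr[2], (128L - 4L) %/% 2L + 1L)  # conv1 -> 63
  expect_equal(tr[3], (63L - 3L) %/% 2L + 1L)   # pool1 -> 31
  expect_equal(tr[4], (31L - 3L) %/% 2L + 1L)   # conv2 -> 15
  expect_equal(tr[5], (15L - 3L) %/% 2L + 1L)   # pool2 -> 7
  expect_equal(tr[6], (7L - 3L) %/% 1L + 1L)    # conv3 -> 5
  expect_equal(tr[7], (5L - 2L) %/% 1L + 1L)    # pool3 -> 4
})

test_that("parameter counting uses the standard learnable formulas", {
  g <- build_model(model_config())
  L <- g$layers
  expect_equal(L$params[L$name == "conv1_b1"], 4 * 4 * 3 * 64 + 64)   # 3136
  expect_equal(L$params[L$name == "fc1"], 1024 * 64 + 64)             # 65600
  expect_equal(L$params[L$name == "bn1_b1"], 2 * 64)
  expect_equal(count_parameters(g), sum(L$params))
  expect_equal(params_millions(g), 1.5)
})

test_that("degenerate single-stream configs build consistently", {
  cfg <- model_config(input_shape = c(32L, 32L, 1L, 3L),
                      branch_conv_filters = 8L,
                      conv_kernels = list(c(3L, 3L)),
                      conv_strides = list(c(2L, 2L)),
                      pool_windows = list(c(2L, 2L)),
                      pool_strides = list(c(2L, 2L)),
                      fc_widths = c(8L, 4L),
                      n_branches = 1L)
  g <- build_model(cfg)
  expect_equal(sum(g$layers$kind == "split"), 1L)
  expect_equal(sum(g$layers$kind == "conv"), 1L)
  expect_equal(sum(g$layers$kind == "concat"), 0L)  # nothing to merge
  expect_equal(g$concat_width, 8L)
  expect_lte(g$concat_width, 256L)
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(branch_conv_filters = c(64L, 100L, 256L)),
               "double")
  expect_error(model_config(fc_widths = c(64L, 48L, 4L)), "halve")
  expect_error(model_config(n_branches = 0L), "n_branches")
  # kernel larger than the shrunken map -> non-positive size
  bad <- model_config(input_shape = c(8L, 8L, 4L, 3L),
                      branch_conv_filters = c(4L, 8L, 16L),
                      conv_kernels = list(c(4L, 4L), c(3L, 3L), c(3L, 3L)),
                      conv_strides = list(c(2L, 2L), c(2L, 2L), c(1L, 1L)),
                      pool_windows = list(c(3L, 3L), c(3L, 3L), c(2L, 2L)),
                      pool_strides = list(c(2L, 2L), c(2L, 2L), c(1L, 1L)),
                      fc_widths = c(64L, 32L, 4L))
  expect_error(build_model(bad), "non-positive")
})

test_that("model table and JSON export carry the layer inventory", {
  g <- build_model(model_config())
  txt <- format_model_table(g)
  expect_true(any(grepl("Layers: 67", txt)))
  expect_true(any(grepl("1.5 M", txt, fixed = TRUE)))
  p <- withr::local_tempfile(fileext = ".json")
  model_to_json(g, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(nrow(back$layers), 67L)
  expect_equal(back$total_params, count_parameters(g))
})
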