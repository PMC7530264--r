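quantized <- function(values, names = NULL) {
  if (is.null(names)) names <- paste0("CH", seq_len(nrow(values)))
  storage.mode(values) <- "integer"
  structure(list(channel_names = names, values = values,
                 quant_levels = 256L, label = "unknown", subject_id = ""),
            class = "quantized_recording")
}

test_that("channel blocks replicate the quantized series down the rows", {
  q <- quantized(matrix(c(0:3, 10 * (1:4)), 2, 4, byrow = TRUE))
  img <- compose_heatmap(q, pipeline_config(time_length = 4,
                                            block_width = 3))
  expect_identical(dim(img$pixels), c(4L, 6L))
  for (col in 1:3) expect_equal(img$pixels[, col], 0:3)
  for (col in 4:6) expect_equal(img$pixels[, col], 10 * (1:4))
  expect_identical(img$layout$col_start, c(1L, 4L))
  expect_identical(img$layout$col_end, c(3L, 6L))

  # averaging each block's columns inverts the composition exactly
  rec <- vapply(seq_len(nrow(img$layout)), function(i)
    rowMeans(img$pixels[, img$layout$col_start[i]:img$layout$col_end[i]]),
    numeric(4))
  expect_equal(t(rec), matrix(as.numeric(q$values), 2, 4, byrow = FALSE),
               ignore_attr = TRUE)
})

test_that("geometry follows k * block_width for any channel count", {
  for (k in c(1, 5, 11)) {
    q <- quantized(matrix(0L, k, 64))
    img <- compose_heatmap(q, pipeline_config(time_length = 64))
    expect_equal(ncol(img$pixels), k * 32)
    blocks <- img$pixels[, img$layout$col_start]
    for (i in seq_len(nrow(img$layout))) {
      cols <- img$layout$col_start[i]:img$layout$col_end[i]
      expect_true(all(img$pixels[, cols] ==
                        img$pixels[, img$layout$col_start[i]]))
    }
  }
})

test_that("length mismatches truncate, pad on request, or error", {
  q <- quantized(matrix(0:9, 1, 10))
  cfg <- pipeline_config(time_length = 6, block_width = 2)
  expect_equal(compose_heatmap(q, cfg)$pixels[, 1], 0:5)
  short <- quantized(matrix(0:3, 1, 4))
  expect_error(compose_heatmap(short, cfg), "4 samples")
  padded <- compose_heatmap(short, pipeline_config(time_length = 6,
                                                   block_width = 2,
                                                   pad_mode = "edge"))
  expect_equal(padded$pixels[, 1], c(0:3, 3, 3))
})

test_that("PNG round trip is pixel-identical and rejects RGB input", {
  q <- quantized(matrix(sample(0:255, 32 * 8, replace = TRUE), 8, 32))
  img <- compose_heatmap(q, pipeline_config(time_length = 32,
                                            block_width = 4))
  path <- withr::local_tempfile(fileext = ".png")
  write_png(img, path)
  expect_gt(file.info(path)$size, 0)
  back <- read_png(path)
  expect_identical(back$pixels, img$pixels)

  rgb_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(12), dim = c(2, 2, 3)), rgb_path)
  expect_error(read_png(rgb_path), "grayscale")
})
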