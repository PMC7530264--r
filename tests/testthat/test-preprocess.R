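make_rec <- function(m, names = NULL) {
  if (is.null(names)) names <- paste0("CH", seq_len(nrow(m)))
  eeg_recording(m, names, 256)
}

test_that("mean-variance ranking matches closed forms and the tie rule", {
  n <- 100
  r <- make_rec(rbind(rep(5, n), rep(c(-1, 1), n / 2)), c("FLAT", "ALT"))
  rk <- channel_variance_ranking(list(r))
  expect_identical(rk$channel, c("ALT", "FLAT"))
  expect_equal(rk$mean_variance, c(n / (n - 1), 0))  # sample variance

  # averaging across recordings
  r2 <- make_rec(rbind(rep(c(-2, 2), n / 2), rep(0, n)), c("FLAT", "ALT"))
  rk2 <- channel_variance_ranking(list(r, r2))
  expect_equal(rk2$mean_variance[rk2$channel == "FLAT"],
               (0 + 4 * n / (n - 1)) / 2)

  # all-constant channels: variance 0, alphabetical order
  r3 <- make_rec(matrix(1, 3, 10), c("B", "A", "C"))
  rk3 <- channel_variance_ranking(list(r3))
  expect_identical(rk3$channel, c("A", "B", "C"))
  expect_identical(rk3$mean_variance, c(0, 0, 0))

  r4 <- make_rec(matrix(0, 2, 10), c("A", "X"))
  expect_error(channel_variance_ranking(list(r, r4)), "inconsistent")
})

test_that("channel selection honors fixed lists and top-k ranking", {
  rec <- generate_recording(synthetic_config(n_samples = 128), "control",
                            seed = 2)
  sel <- select_channels(rec, pipeline_config())
  expect_identical(sel$channel_names, default_channels())
  expect_identical(nrow(sel$data), 11L)

  two <- make_rec(rbind(rep(0, 10), rep(c(-1, 1), 5)), c("FLAT", "ALT"))
  top1 <- select_channels(two, pipeline_config(channel_mode = "top-k",
                                               top_k = 1))
  expect_identical(top1$channel_names, "ALT")

  dropped <- eeg_recording(rec$data[-1, ], rec$channel_names[-1], 256)
  expect_error(select_channels(dropped, pipeline_config()), "FP1")
})

test_that("outlier removal clips or interpolates at the 73.3 uV rule", {
  expect_equal(remove_outliers(c(80, -80, 10)), c(73.3, -73.3, 10))
  inside <- c(-73.3, 0, 73.3, 12.5)
  expect_identical(remove_outliers(inside), inside)
  expect_equal(remove_outliers(c(0, 100, 0), mode = "drop"), c(0, 0, 0))
  # endpoints take the nearest valid value in drop mode
  expect_equal(remove_outliers(c(100, 5, 10, -100), mode = "drop"),
               c(5, 5, 10, 10))
  expect_error(remove_outliers(c(100, -100), mode = "drop"), "all samples")
  # clipping is idempotent
  once <- remove_outliers(rnorm(200, sd = 60))
  expect_identical(remove_outliers(once), once)
})

test_that("quantization maps the range to 0..255 with round-half-up", {
  r <- make_rec(matrix(c(0, 5, 10), 1), "A")
  q <- normalize_quantize(r)
  expect_identical(as.vector(q$values), c(0L, 128L, 255L))

  const <- normalize_quantize(make_rec(matrix(7, 2, 5)))
  expect_true(all(const$values == 0L))

  for (s in 1:20) {
    set.seed(s)
    q <- normalize_quantize(make_rec(matrix(runif(60, -50, 50), 3)))
    expect_identical(min(q$values), 0L)
    expect_identical(max(q$values), 255L)
  }
})

test_that("quantization is monotone and offset-invariant", {
  set.seed(4)
  m <- matrix(runif(80, -60, 60), 4)
  q <- normalize_quantize(make_rec(m))
  ord <- order(m)
  expect_true(all(diff(q$values[ord]) >= 0))
  q_off <- normalize_quantize(make_rec(m + 12.34))
  expect_identical(q$values, q_off$values)
})

test_that("global normalization preserves relative channel amplitude", {
  m <- rbind(seq(-10, 10, length.out = 21), seq(-40, 40, length.out = 21))
  qg <- normalize_quantize(make_rec(m))
  expect_lt(max(qg$values[1, ]), max(qg$values[2, ]))
  qp <- normalize_quantize(make_rec(m),
                           pipeline_config(normalization = "per-channel"))
  expect_identical(max(qp$values[1, ]), max(qp$values[2, ]))
})
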