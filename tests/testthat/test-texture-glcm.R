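test_that("co-occurrence counting matches hand enumeration", {
  img <- matrix(c(0, 1, 0, 1), 2, 2)      # rows: (0,0) and (1,1)
  g <- compute_glcm(img, offsets = list(c(0L, 1L)), levels = 2)
  expect_equal(g$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_true(g$symmetric)

  const <- compute_glcm(matrix(7, 4, 4), levels = 256)
  expect_equal(sum(const$p), 1)
  expect_equal(const$p[8, 8], 1)           # p(v, v) = 1 at v = 7

  set.seed(2)
  any_img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  expect_equal(sum(compute_glcm(any_img)$p), 1, tolerance = 1e-12)
})

test_that("symmetric matrices equal their transpose; offsets validated", {
  set.seed(3)
  img <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
  g <- compute_glcm(img, levels = 8)
  expect_equal(g$p, t(g$p))
  expect_error(compute_glcm(img, offsets = list(c(0L, 9L)), levels = 8),
               "exceeds")
  expect_error(compute_glcm(matrix(numeric(0), 0, 0)), "empty")
})

test_that("asm and entropy agree with their closed-form examples", {
  uniform <- structure(list(p = matrix(0.25, 2, 2)), class = "cooccurrence_matrix")
  expect_equal(asm(uniform), 0.25)
  expect_equal(glcm_entropy(uniform), 2)

  single <- structure(list(p = diag(c(1, 0))), class = "cooccurrence_matrix")
  expect_equal(asm(single), 1)
  expect_equal(glcm_entropy(single), 0)

  two_point <- structure(list(p = diag(c(0.5, 0.5))),
                         class = "cooccurrence_matrix")
  expect_equal(asm(two_point), 0.5)
  expect_equal(glcm_entropy(two_point), 1)
})

test_that("asm and entropy reach their extremes together", {
  # maximal uniformity (constant image) <=> zero entropy
  g <- compute_glcm(matrix(3, 5, 5), levels = 8)
  expect_equal(asm(g), 1)
  expect_equal(glcm_entropy(g), 0)
  set.seed(7)
  for (i in 1:5) {
    g <- compute_glcm(matrix(sample(0:7, 49, replace = TRUE), 7, 7),
                      levels = 8)
    expect_lt(asm(g), 1)
    expect_gt(glcm_entropy(g), 0)
  }
})

test_that("the 14 Haralick features match the brute-force oracle", {
  fv <- haralick_features(compute_glcm(matrix(sample(0:7, 64, TRUE), 8, 8),
                                       levels = 8))
  expect_length(fv, 14)
  expect_identical(names(fv)[c(1, 9, 14)], c("asm", "entropy", "mcc"))

  for (s in 1:25) {
    set.seed(1000 + s)
    img <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    g <- compute_glcm(img, levels = 8)
    expect_equal(as.numeric(haralick_features(g)), brute_haralick(g$p),
                 tolerance = 1e-8)
  }
})

test_that("constant-image Haralick features hit their degenerate values", {
  fv <- haralick_features(compute_glcm(matrix(5, 6, 6), levels = 8))
  expect_equal(fv[["asm"]], 1)
  expect_equal(fv[["contrast"]], 0)
  expect_equal(fv[["idm"]], 1)
  expect_equal(fv[["entropy"]], 0)
  expect_equal(fv[["correlation"]], 0)  # zero marginal variance fallback
})
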