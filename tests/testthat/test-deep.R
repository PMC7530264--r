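test_that("the registry returns the published feature dimensions", {
  expected <- c(DenseNet121 = 1024, DenseNet169 = 1664, DenseNet201 = 1920,
                InceptionResNetV2 = 1536, InceptionV3 = 2048,
                MobileNet = 1024, NASNetLarge = 4032, NASNetMobile = 1056,
                ResNet50 = 2048, VGG16 = 512, VGG19 = 512, Xception = 2048)
  for (nm in names(expected))
    expect_identical(feature_dim(nm), unname(expected[nm]))
  expect_identical(feature_dim("mobilenet"), 1024)  # case-insensitive
  expect_error(feature_dim("LeNet"), "DenseNet121")
  expect_identical(nrow(backbone_registry()), 12L)
})

test_that("prepare_image resizes, replicates channels and scales", {
  spec <- backbone_spec("MobileNet")
  img <- matrix(runif(64 * 32, 0, 255), 64, 32)
  arr <- prepare_image(img, spec)
  expect_identical(dim(arr), c(224L, 224L, 3L))
  expect_identical(arr[, , 1], arr[, , 2])

  # constant image -> constant output
  carr <- prepare_image(matrix(127.5, 10, 10), spec)
  expect_equal(max(abs(carr)), 0)     # tf scaling maps 127.5 to 0

  # an image already at the input size is passed through unresized
  at_size <- matrix(runif(224 * 224, 0, 255), 224, 224)
  arr2 <- prepare_image(at_size, spec)
  expect_equal(arr2[, , 1], at_size / 127.5 - 1)
})

test_that("extraction pools activations to the registry length", {
  img <- matrix(0:255, 16, 16)
  spec <- backbone_spec("MobileNet")
  fv <- extract_deep(img, spec, stub_backbone(1024))
  expect_length(fv, 1024)
  expect_identical(attr(fv, "extractor_id"), "mobilenet")

  # global average pooling over a spatial activation stack
  gap <- extract_deep(img, spec, function(x)
    array(rep(1:1024, each = 4), dim = c(2, 2, 1024)))
  expect_equal(as.numeric(gap), as.numeric(1:1024))

  expect_error(extract_deep(img, spec, stub_backbone(512)),
               "512.*1024|1024.*512")
})

test_that("every registered backbone keeps the length contract", {
  img <- matrix(runif(100, 0, 255), 10, 10)
  for (nm in backbone_registry()$name) {
    spec <- backbone_spec(nm)
    fv <- extract_deep(img, spec, stub_backbone(spec$feature_dim))
    expect_length(fv, feature_dim(nm))
  }
})

test_that("the random-projection stub is a pure function of its seed", {
  spec <- backbone_spec("VGG16")
  img <- matrix(runif(400, 0, 255), 20, 20)
  a <- extract_deep(img, spec, random_projection_backbone(spec, seed = 3))
  b <- extract_deep(img, spec, random_projection_backbone(spec, seed = 3))
  expect_identical(as.numeric(a), as.numeric(b))
  d <- extract_deep(img, spec, random_projection_backbone(spec, seed = 4))
  expect_false(identical(as.numeric(a), as.numeric(d)))
  expect_length(a, 512)
})
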