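#' Backbone registry for headless transfer-learning extraction
#'
#' Twelve well-known convolutional architectures, used with their
#' classification head removed so the final convolutional stack — after
#' global average pooling — serves as a fixed feature extractor. The
#' registry records each backbone's canonical input size, the length of
#' the pooled feature vector and its input scaling convention
#' (`"tf"`: to \[-1, 1\]; `"torch"`: /255 then ImageNet mean/sd;
#' `"caffe"`: BGR with ImageNet channel means subtracted).
#'
#' @return Data.frame with columns `name`, `input_h`, `input_w`,
#'   `feature_dim`, `scaling`.
#' @export
#' @examples
#' backbone_registry()[, c("name", "feature_dim")]
backbone_registry <- function() {
  data.frame(
    name = c("DenseNet121", "DenseNet169", "DenseNet201",
             "InceptionResNetV2", "InceptionV3", "MobileNet",
             "NASNetLarge", "NASNetMobile", "ResNet50",
             "VGG16", "VGG19", "Xception"),
    input_h = c(224, 224, 224, 299, 299, 224, 331, 224, 224, 224, 224, 299),
    input_w = c(224, 224, 224, 299, 299, 224, 331, 224, 224, 224, 224, 299),
    feature_dim = c(1024, 1664, 1920, 1536, 2048, 1024,
                    4032, 1056, 2048, 512, 512, 2048),
    scaling = c("torch", "torch", "torch", "tf", "tf", "tf",
                "tf", "tf", "caffe", "caffe", "caffe", "tf"),
    stringsAsFactors = FALSE)
}

#' Feature dimensionality of a registered backbone
#'
#' @param name Backbone name (case-insensitive match against the
#'   registry).
#' @return Integer feature-vector length.
#' @export
#' @examples
#' feature_dim("MobileNet")
feature_dim <- function(name) {
  reg <- backbone_registry()
  i <- match(tolower(name), tolower(reg$name))
  if (is.na(i))
    stop(sprintf("unknown backbone '%s'; registered: %s", name,
                 paste(reg$name, collapse = ", ")))
  reg$feature_dim[i]
}

#' Specification of one backbone
#'
#' @inheritParams feature_dim
#' @param pretrained Whether ImageNet-pretrained weights are intended
#'   (informational; the package never downloads weights).
#' @return An object of class `backbone_spec` with fields `name`,
#'   `input_size`, `feature_dim`, `scaling`, `pretrained`.
#' @export
backbone_spec <- function(name, pretrained = FALSE) {
  reg <- backbone_registry()
  i <- match(tolower(name), tolower(reg$name))
  if (is.na(i))
    stop(sprintf("unknown backbone '%s'; registered: %s", name,
                 paste(reg$name, collapse = ", ")))
  structure(list(name = reg$name[i],
                 input_size = c(reg$input_h[i], reg$input_w[i]),
                 feature_dim = reg$feature_dim[i],
                 scaling = reg$scaling[i],
                 pretrained = pretrained),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec> %s: input %dx%d, %d features, %s scaling\n",
              x$name, x$input_size[1], x$input_size[2], x$feature_dim,
              x$scaling))
  invisible(x)
}

#' Prepare a heat-map image for a convolutional backbone
#'
#' Bilinearly resizes the grayscale image to the backbone's input size,
#' replicates it to 3 channels, and applies the backbone's input scaling
#' convention.
#'
#' @param image An `eeg_heatmap` or numeric matrix (gray values 0..255).
#' @param spec A [backbone_spec()].
#' @return Numeric array of shape `(input_h, input_w, 3)`.
#' @export
prepare_image <- function(image, spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  px <- as_pixel_matrix(image)
  h <- spec$input_size[1]; w <- spec$input_size[2]
  if (h < 1 || w < 1) stop("zero-size resize target")
  m <- if (all(dim(px) == c(h, w))) px * 1.0
  else as.matrix(EBImage::resize(EBImage::Image(px), w = h, h = w,
                                 filter = "bilinear"))
  out <- array(0, dim = c(h, w, 3))
  switch(spec$scaling,
    tf = { for (k in 1:3) out[, , k] <- m / 127.5 - 1 },
    torch = {
      mean <- c(0.485, 0.456, 0.406); sd <- c(0.229, 0.224, 0.225)
      for (k in 1:3) out[, , k] <- (m / 255 - mean[k]) / sd[k]
    },
    caffe = {
      bgr_means <- c(103.939, 116.779, 123.68)
      for (k in 1:3) out[, , k] <- m - bgr_means[k]
    })
  out
}

#' Headless deep feature extraction
#'
#' Runs an injected backbone callable on the prepared image and reduces
#' its final convolutional activations to a flat feature vector by
#' global average pooling over the spatial dimensions. The backbone is
#' any function mapping the prepared `(H, W, 3)` array to an activation
#' array `(h, w, channels)` (or directly to a vector); the channel count
#' must equal the registry dimension for `spec$name`.
#'
#' Backbones are injected rather than bundled, so the extraction
#' contract is usable with any deep-learning runtime the caller has, and
#' testable with stubs without one.
#'
#' @param image An `eeg_heatmap` or numeric matrix.
#' @param spec A [backbone_spec()].
#' @param backbone Function taking the prepared array and returning the
#'   final activation stack.
#' @return A [feature_vector()] of length `spec$feature_dim`.
#' @export
#' @examples
#' stub <- stub_backbone(feature_dim("MobileNet"))
#' img <- matrix(0:255, 16, 16)
#' length(extract_deep(img, backbone_spec("MobileNet"), stub))
extract_deep <- function(image, spec, backbone) {
  stopifnot(inherits(spec, "backbone_spec"), is.function(backbone))
  act <- backbone(prepare_image(image, spec))
  v <- if (is.array(act) && length(dim(act)) == 3)
    apply(act, 3, mean)               # global average pooling
  else as.numeric(act)
  if (length(v) != spec$feature_dim)
    stop(sprintf(
      "backbone produced %d features but registry expects %d for %s",
      length(v), spec$feature_dim, spec$name))
  feature_vector(v, sprintf("%s_f%04d", tolower(spec$name),
                            seq_along(v)),
                 extractor_id = tolower(spec$name))
}

#' Stub backbones for testing the extraction contract
#'
#' `stub_backbone(dim)` returns a callable emitting a constant
#' `1 x 1 x dim` activation stack. `random_projection_backbone()` is a
#' synthetic stand-in for a real convolutional backbone: it average-pools
#' the prepared image over a coarse grid and applies a fixed seeded
#' random linear map followed by a ReLU, emitting `1 x 1 x feature_dim`
#' activations. Neither learns anything; they exist so the headless
#' extraction contract is exercisable without a deep-learning runtime.
#'
#' @param dim Number of output channels for `stub_backbone`.
#' @return A function suitable as the `backbone` argument of
#'   [extract_deep()].
#' @export
stub_backbone <- function(dim) {
  force(dim)
  function(x) array(1, dim = c(1, 1, dim))
}

#' @rdname stub_backbone
#' @param spec A [backbone_spec()].
#' @param seed Seed fixing the random projection weights.
#' @param grid Pooling grid size (default 4, i.e. 4 x 4 x 3 = 48 pooled
#'   inputs).
#' @export
random_projection_backbone <- function(spec, seed = 1, grid = 4) {
  stopifnot(inherits(spec, "backbone_spec"))
  w <- with_seed(seed, matrix(stats::rnorm(spec$feature_dim * grid^2 * 3),
                              nrow = spec$feature_dim))
  function(x) {
    h <- dim(x)[1]; wd <- dim(x)[2]
    ri <- pmin(floor((seq_len(h) - 1) * grid / h) + 1, grid)
    ci <- pmin(floor((seq_len(wd) - 1) * grid / wd) + 1, grid)
    pooled <- numeric(0)
    for (k in 1:3) {
      s <- rowsum(t(rowsum(x[, , k], ri)), ci)  # grid x grid sums
      n <- outer(tabulate(ci, grid), tabulate(ri, grid))
      pooled <- c(pooled, as.vector(s / n))
    }
    act <- pmax(0, as.vector(w %*% pooled))
    array(act, dim = c(1, 1, spec$feature_dim))
  }
}
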