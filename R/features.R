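#' Specify a feature-extraction backend
#'
#' Three interchangeable backend kinds turn JNP images into fixed-length
#' feature vectors:
#'
#' * `"moments"` — stateless per-joint colour moments: for each of the 15
#'   palette colours, \{pixel count, centroid column/row, column/row standard
#'   deviation, bounding-box width/height\} = 15 x 7 = 105 dimensions.
#' * `"scratch_cnn"` — a small convolutional network trained from random
#'   initialization on the training split for `epochs` epochs; features are
#'   read from its 64-unit fully connected layer.
#' * `"pretrained"` — a named large backbone (`alexnet`, `densenet201`,
#'   `resnet50`, `vgg16`, `vgg19`) fine-tuned for `epochs` epochs with
#'   features read at a fixed layer. Pretrained weights must be supplied by
#'   the user; fitting without them raises an explicit "weights unavailable"
#'   error — never a silent fallback.
#'
#' @param kind backend kind.
#' @param backbone_id pretrained backbone name (pretrained kind only).
#' @param epochs training epochs, one of 10, 15, 20 (training kinds only).
#' @param feature_layer layer index to read features from (pretrained);
#'   defaults per backbone: alexnet 17, densenet201 706, resnet50 175,
#'   vgg16 33, vgg19 39.
#' @param input_size network input edge in px (pretrained); defaults:
#'   alexnet 227, others 224.
#' @param train_seed integer seed for weight initialization and batch order.
#' @return an object of class `backend_spec`.
#' @export
backend_spec <- function(kind = c("moments", "scratch_cnn", "pretrained"),
                         backbone_id = NULL, epochs = NULL,
                         feature_layer = NULL, input_size = NULL,
                         train_seed = 1L) {
  kind <- match.arg(kind)
  meta <- list(
    alexnet     = list(input_size = 227L, feature_layer = 17L),
    densenet201 = list(input_size = 224L, feature_layer = 706L),
    resnet50    = list(input_size = 224L, feature_layer = 175L),
    vgg16       = list(input_size = 224L, feature_layer = 33L),
    vgg19       = list(input_size = 224L, feature_layer = 39L)
  )
  if (kind == "pretrained") {
    if (is.null(backbone_id) || !backbone_id %in% names(meta))
      stop("pretrained backend needs backbone_id in {",
           paste(names(meta), collapse = ", "), "}")
    if (is.null(input_size)) input_size <- meta[[backbone_id]]$input_size
    if (is.null(feature_layer))
      feature_layer <- meta[[backbone_id]]$feature_layer
  } else {
    backbone_id <- NULL
  }
  if (kind %in% c("scratch_cnn", "pretrained")) {
    if (is.null(epochs)) epochs <- 10L
    if (!epochs %in% c(10L, 15L, 20L))
      stop("epochs must be one of 10, 15, 20; got ", epochs)
  } else {
    epochs <- NA_integer_
  }
  structure(list(kind = kind, backbone_id = backbone_id,
                 epochs = as.integer(epochs),
                 feature_layer = feature_layer, input_size = input_size,
                 train_seed = as.integer(train_seed)),
            class = "backend_spec")
}

#' Short identifying string for a backend spec
#' @param spec a `backend_spec`.
#' @return character scalar, e.g. `"moments"` or `"scratch_cnn_e15"`.
#' @export
backend_key <- function(spec) {
  switch(spec$kind,
    moments = "moments",
    scratch_cnn = sprintf("scratch_cnn_e%d", spec$epochs),
    pretrained = sprintf("%s_e%d", spec$backbone_id, spec$epochs))
}

# Downsample one JNP by block-averaging to about a quarter of the linear
# resolution (875 x 656 -> 219 x 164); returns height x width x 3 in [0, 1].
downsample_jnp <- function(img, factor = 4L) {
  px <- jnp_pixels(img) / 255
  h <- dim(px)[1]; w <- dim(px)[2]
  ho <- ceiling(h / factor); wo <- ceiling(w / factor)
  cidx <- pmin(wo, (seq_len(w) - 1) %/% factor + 1)
  B <- matrix(0, w, wo); B[cbind(seq_len(w), cidx)] <- 1
  B <- sweep(B, 2, colSums(B), "/")
  out <- array(0, dim = c(ho, wo, 3))
  if (h %% factor == 0) {
    # exact row blocks: fold rows into the first array dimension and average
    for (ch in 1:3)
      out[, , ch] <- colMeans(array(px[, , ch], c(factor, ho, w))) %*% B
  } else {
    ridx <- pmin(ho, (seq_len(h) - 1) %/% factor + 1)
    A <- matrix(0, ho, h); A[cbind(ridx, seq_len(h))] <- 1
    A <- A / rowSums(A)
    for (ch in 1:3) out[, , ch] <- A %*% px[, , ch] %*% B
  }
  out
}

# Stack a list of images into an (h, w, 3, n) array of downsampled planes.
downsample_stack <- function(images, factor = 4L) {
  first <- downsample_jnp(images[[1]], factor)
  out <- array(0, dim = c(dim(first), length(images)))
  out[, , , 1] <- first
  if (length(images) > 1)
    for (i in 2:length(images)) out[, , , i] <- downsample_jnp(images[[i]],
                                                               factor)
  out
}

scratch_cnn_init <- function(seed) {
  with_seed(derive_seed(seed, 5001), {
    he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
    list(W1 = he(8, 27),  b1 = numeric(8),
         W2 = he(16, 72), b2 = numeric(16),
         W3 = he(32, 144), b3 = numeric(32),
         Wf1 = he(64, 32), bf1 = numeric(64),
         Wf2 = he(2, 64),  bf2 = numeric(2))
  })
}

#' Fit a feature backend on the training split
#'
#' `moments` is stateless and fits instantly (labels are ignored). The
#' `scratch_cnn` backend downsamples the images by 4, then trains a small
#' network — three 3x3 convolution blocks (8/16/32 channels) each followed by
#' 2x2 max-pooling and rectification, global average pooling, a 64-unit
#' fully connected feature layer and a 2-unit head — with an Adam-style
#' optimizer (learning rate 1e-3, batch 16) for `spec$epochs` epochs on the
#' training split only. Training is deterministic given the spec seed.
#'
#' @param train_images list of `jnp_image` (training split only).
#' @param train_labels group labels aligned to `train_images` (ignored by
#'   `moments`).
#' @param spec a `backend_spec`.
#' @return an object of class `fitted_backend` carrying the spec, any
#'   trained weights, the per-epoch training loss, and a fingerprint.
#' @export
fit_backend <- function(train_images, train_labels = NULL, spec) {
  stopifnot(inherits(spec, "backend_spec"))
  if (spec$kind == "pretrained")
    stop("weights unavailable for pretrained backbone '", spec$backbone_id,
         "': supply downloaded weights or use the scratch_cnn / moments ",
         "backends")
  if (spec$kind == "moments") {
    return(structure(list(spec = spec, weights = NULL, loss = NULL,
                          fingerprint = "moments_v1"),
                     class = "fitted_backend"))
  }
  # scratch_cnn
  if (length(train_images) < 2) stop("need at least 2 training images")
  y <- as.character(train_labels)
  if (length(unique(y)) < 2)
    stop("training set contains a single class; cannot train the backend")
  if (length(y) != length(train_images))
    stop("labels and images differ in length")
  x <- downsample_stack(train_images)
  y01 <- as.integer(y == "experimental")
  n <- length(train_images)
  perms <- with_seed(derive_seed(spec$train_seed, 6007), {
    vapply(seq_len(spec$epochs), function(e) sample.int(n),
           integer(n))
  })
  weights <- scratch_cnn_init(spec$train_seed)
  fit <- cnn_train_cpp(x, y01, weights, perms, 1e-3, 16L)
  fp <- sprintf("%s_seed%d_%.6e", backend_key(spec), spec$train_seed,
                sum(vapply(fit$weights, function(w) sum(abs(w)), 0)))
  structure(list(spec = spec, weights = fit$weights, loss = fit$loss,
                 fingerprint = fp),
            class = "fitted_backend")
}

#' @export
print.fitted_backend <- function(x, ...) {
  cat(sprintf("<fitted_backend> %s (%s)\n", backend_key(x$spec),
              x$fingerprint))
  if (!is.null(x$loss))
    cat(sprintf("  training loss: %.4f -> %.4f over %d epochs\n",
                x$loss[1], x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

# Per-joint colour moments of one image: for each palette colour,
# {count, centroid col, centroid row, sd col, sd row, bbox width, height}.
# Standard deviations use the population convention so single-pixel sets
# stay finite; empty sets yield all zeros (count 0).
moments_features_one <- function(img) {
  px <- jnp_pixels(img)
  pal <- img$config$palette
  h <- dim(px)[1]; w <- dim(px)[2]
  code <- px[, , 1] * 65536L + px[, , 2] * 256L + px[, , 3]
  pal_codes <- pal[, 1] * 65536L + pal[, 2] * 256L + pal[, 3]
  out <- numeric(0)
  rows0 <- matrix(rep(0:(h - 1), w), h, w)
  cols0 <- matrix(rep(0:(w - 1), each = h), h, w)
  for (k in seq_len(nrow(pal))) {
    sel <- code == pal_codes[k]
    n <- sum(sel)
    if (n == 0) {
      out <- c(out, rep(0, 7))
    } else {
      rc <- rows0[sel]; cc <- cols0[sel]
      out <- c(out,
               n, mean(cc), mean(rc),
               sqrt(mean((cc - mean(cc))^2)), sqrt(mean((rc - mean(rc))^2)),
               max(cc) - min(cc) + 1, max(rc) - min(rc) + 1)
    }
  }
  names(out) <- as.vector(t(outer(
    rownames(pal),
    c("count", "centroid_col", "centroid_row", "sd_col", "sd_row",
      "bbox_w", "bbox_h"), paste, sep = ".")))
  out
}

#' Extract features for a set of images
#'
#' Deterministic given the fitted backend state. All images must share one
#' canvas size.
#'
#' @param backend a `fitted_backend`.
#' @param images list of `jnp_image`.
#' @param downsampled optional precomputed [downsample_stack()] array for
#'   the same images (scratch_cnn only; avoids recomputation across grid
#'   cells).
#' @return a `feature_matrix`: numeric matrix with one row per image,
#'   row names from the image source ids, and attributes `fingerprint` and
#'   `backend_key`.
#' @export
extract_features <- function(backend, images, downsampled = NULL) {
  stopifnot(inherits(backend, "fitted_backend"))
  dims <- vapply(images, function(im) dim(im$pixels)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("images disagree in size; all images must share one canvas")
  if (backend$spec$kind == "moments") {
    mat <- t(vapply(images, moments_features_one,
                    numeric(105)))
  } else {
    if (is.null(downsampled)) downsampled <- downsample_stack(images)
    if (dim(downsampled)[4] != length(images))
      stop("downsampled stack does not match the image list")
    mat <- cnn_features_cpp(downsampled, backend$weights)
    colnames(mat) <- sprintf("cnn_f%02d", seq_len(ncol(mat)))
  }
  rownames(mat) <- unname(vapply(images, function(im) im$source_id,
                                 character(1)))
  if (anyNA(mat) || !all(is.finite(mat)))
    stop("non-finite feature values produced by backend ",
         backend_key(backend$spec))
  structure(mat, fingerprint = backend$fingerprint,
            backend_key = backend_key(backend$spec),
            class = c("feature_matrix", class(mat)))
}

#' Write / read a feature matrix cache (CSV + JSON fingerprint sidecar)
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path` invisibly.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(id = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(backend = attr(fm, "backend_key"),
         fingerprint = attr(fm, "fingerprint"),
         dim = dim(fm)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
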