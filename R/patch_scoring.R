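# The patch-model contract: a CNN that (a) scores patches with a class
# probability, and (b) exposes a named convolutional layer's post-ReLU
# activations together with the gradient of the class objective with respect
# to them. A compact default backbone is provided; any model honouring the
# contract can replace it.

#' Configuration for the default patch scorer
#'
#' An average-pooling stem that halves the input resolution, then three
#' convolution blocks (ReLU, the first two followed by 2x2 max pooling),
#' global average pooling and a dense head. The last convolutional block's
#' post-ReLU activations are the exposed layer used for class-activation
#' mapping, so a `patch_size`-sided input yields activation maps of side
#' `patch_size / 8`.
#'
#' @param channels kernels per convolution block.
#' @param optimizer `"adam"` or `"sgd"` with momentum.
#' @param epochs,learning_rate,batch_size,momentum optimiser settings.
#' @param seed integer seed for initialisation and shuffling.
#' @return a `patch_model_config` list.
#' @export
patch_model_config <- function(channels = c(8L, 16L, 16L), epochs = 10L,
                               optimizer = c("adam", "sgd"),
                               learning_rate = NULL, batch_size = 32L,
                               momentum = 0.9, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (is.null(learning_rate))
    learning_rate <- if (optimizer == "adam") 0.003 else 0.05
  structure(list(channels = as.integer(channels), epochs = as.integer(epochs),
                 optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "patch_model_config")
}

patches_batch <- function(patches) {
  if (is.list(patches)) {
    if (length(patches) == 0) stop("no patches")
    if (is.list(patches[[1]]) && !is.null(patches[[1]]$img))
      patches <- lapply(patches, `[[`, "img")
    d <- dim(patches[[1]])
    array(unlist(patches, use.names = FALSE), dim = c(d, length(patches)))
  } else if (length(dim(patches)) == 3) {
    array(patches, dim = c(dim(patches), 1L))
  } else patches
}

#' Train the default patch scorer
#'
#' @param patches training patches: a list of `(H, W, C)` arrays (or of
#'   `list(img = ...)` entries) or an `(H, W, C, N)` array.
#' @param labels one label per patch: 0/1 for binary, or 1-based class
#'   indices / a factor for more classes. At least two classes must be
#'   present.
#' @param config a [patch_model_config()].
#' @return an `hm_patch_model` with the fitted network, input size, number
#'   of classes, the exposed layer name and the training history.
#' @export
train_patch_model <- function(patches, labels, config = patch_model_config()) {
  stopifnot(inherits(config, "patch_model_config"))
  x <- patches_batch(patches)
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.numeric(labels)
  if (length(labels) != dim(x)[4]) stop("one label per patch required")
  ul <- sort(unique(labels))
  if (length(ul) < 2) stop("patch training requires at least 2 classes")
  binary <- all(ul %in% c(0, 1))
  n_classes <- if (binary) 2L else as.integer(max(ul))
  input_dim <- dim(x)[1:3]
  ch <- config$channels
  layers <- list(layer_pool(2L, "avg", name = "stem"),
                 layer_conv(ch[1]), layer_relu(), layer_pool(2L),
                 layer_conv(ch[2]), layer_relu(), layer_pool(2L),
                 layer_conv(ch[3]), layer_relu(name = "exposed"),
                 layer_gap(),
                 layer_dense(if (binary) 1L else n_classes))
  net <- nn_build(layers, input_dim = input_dim,
                  head = if (binary) "sigmoid" else "softmax",
                  exposed = "exposed", seed = config$seed)
  y <- if (binary) labels else as.integer(labels)
  net <- nn_train(net, x, y, loss = if (binary) "bce" else "ce",
                  epochs = config$epochs, learning_rate = config$learning_rate,
                  batch_size = config$batch_size,
                  optimizer = config$optimizer %||% "adam",
                  momentum = config$momentum, seed = config$seed)
  act <- nn_activation_at(net, array(0, dim = c(input_dim, 1L)), "exposed")
  structure(list(net = net, input_dim = input_dim, n_classes = n_classes,
                 binary = binary, exposed = "exposed",
                 act_dim = dim(act)[1:3], config = config,
                 history = net$history),
            class = "hm_patch_model")
}

check_patch_size <- function(model, x) {
  if (!all(dim(x)[1:3] == model$input_dim))
    stop(sprintf("patch size mismatch: model expects %s, got %s",
                 paste(model$input_dim, collapse = "x"),
                 paste(dim(x)[1:3], collapse = "x")))
}

patch_prob <- function(model, p, class_index) {
  if (model$binary) {
    if (!class_index %in% c(1L, 2L)) stop("class_index out of range")
    if (class_index == 1L) p[, 1] else 1 - p[, 1]
  } else {
    if (class_index < 1 || class_index > ncol(p)) stop("class_index out of range")
    p[, class_index]
  }
}

#' Score every patch of a slide
#'
#' @param model an `hm_patch_model` (or any list with an `hm_cnn` in `net`,
#'   `input_dim`, `binary` flag and `exposed` layer name).
#' @param slide an `hm_slide`, a list of patches, or an `(H, W, C, N)` array.
#' @param class_index 1-based class whose probability is reported (for a
#'   binary scorer, class 1 is the positive class).
#' @return data frame with one row per patch, in slide order: `patch_index`
#'   (1-based), `grid_row`, `grid_col` (when available), `prob`, and
#'   `mean_activation` (mean over the exposed activation stack, used for
#'   rank tie-breaking).
#' @export
score_patches <- function(model, slide, class_index = 1L) {
  patches <- if (inherits(slide, "hm_slide")) slide$patches else slide
  grid <- NULL
  if (is.list(patches) && length(patches) > 0 && is.list(patches[[1]]) &&
      !is.null(patches[[1]]$grid_row))
    grid <- data.frame(grid_row = as.integer(vapply(patches, `[[`, 0, "grid_row")),
                       grid_col = as.integer(vapply(patches, `[[`, 0, "grid_col")))
  if ((is.list(patches) && length(patches) == 0))
    return(data.frame(patch_index = integer(), grid_row = integer(),
                      grid_col = integer(), prob = numeric(),
                      mean_activation = numeric()))
  x <- patches_batch(patches)
  check_patch_size(model, x)
  n <- dim(x)[4]
  prob <- numeric(n)
  mact <- numeric(n)
  for (s in seq(1, n, by = 64)) {
    sel <- s:min(s + 63, n)
    xb <- x[, , , sel, drop = FALSE]
    p <- nn_predict(model$net, xb)
    prob[sel] <- patch_prob(model, p, as.integer(class_index))
    a <- nn_activation_at(model$net, xb, model$exposed)
    d <- dim(a)
    mact[sel] <- colMeans(matrix(a, prod(d[1:3]), d[4]))
  }
  out <- data.frame(patch_index = seq_len(n), prob = prob,
                    mean_activation = mact)
  if (!is.null(grid)) out <- cbind(out[1], grid, out[2:3])
  out
}

#' Activation bundle for one patch
#'
#' Runs the patch through the model, capturing the exposed layer's
#' activations and the gradient of the class objective `P_C` with respect to
#' each activation value, as needed by the class-activation representation.
#'
#' @param model an `hm_patch_model`.
#' @param patch one `(H, W, C)` array (or `list(img = ...)`).
#' @param class_index 1-based target class `C`.
#' @param layer exposed layer name; defaults to the model's registered one.
#' @param wrt `"prob"` (gradient of the post-activation class probability,
#'   the default) or `"logit"` (pre-activation score).
#' @return an `hm_activation_bundle`: `activations` and `gradients`, both
#'   `(H, W, M)` arrays, plus `class_index` and the model output.
#' @export
activation_bundle <- function(model, patch, class_index = 1L,
                              layer = NULL, wrt = c("prob", "logit")) {
  wrt <- match.arg(wrt)
  if (is.list(patch) && !is.null(patch$img)) patch <- patch$img
  x <- patches_batch(list(patch))
  check_patch_size(model, x)
  layer <- layer %||% model$exposed
  ci <- as.integer(class_index)
  # for a binary sigmoid scorer the lone output models class 1; class 2's
  # probability is its complement, whose gradient is the negation
  negate <- FALSE
  if (isTRUE(model$binary)) {
    if (!ci %in% c(1L, 2L)) stop("class_index out of range")
    if (ci == 2L) { negate <- TRUE }
    target <- 1L
  } else target <- ci
  g <- nn_class_gradient(model$net, x, layer, class_index = target, wrt = wrt)
  grad <- if (negate) -g$gradient else g$gradient
  structure(list(activations = g$activation, gradients = grad,
                 class_index = ci, output = g$output),
            class = "hm_activation_bundle")
}

#' Save / load a patch model
#'
#' The model weights are serialised with `saveRDS`; a JSON sidecar records
#' the input size, class count and exposed layer name.
#'
#' @param model an `hm_patch_model`.
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `path`, invisibly (or the loaded model).
#' @export
save_patch_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(input_dim = model$input_dim,
                            n_classes = model$n_classes,
                            binary = model$binary, exposed = model$exposed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_patch_model
#' @export
load_patch_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "hm_patch_model"))
  model
}
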