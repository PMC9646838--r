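# Compact CPU CNN engine.
#
# The slide-representation method needs direct access to an internal
# convolutional layer's activations and to the gradient of the class
# objective with respect to them, so the engine implements explicit
# forward/backward passes over a small set of layers: stride-1 "same"
# convolution, ReLU, non-overlapping max/average pooling, global average
# pooling, flatten, and dense. Batches are (H, W, C, N) arrays up to the
# first flatten/gap, then (N, features) matrices.

#' Build a sequential convolutional network
#'
#' Constructs an untrained network from a list of layer descriptions. Layers
#' are created with [layer_conv()], [layer_relu()], [layer_pool()],
#' [layer_gap()], [layer_flatten()] and [layer_dense()]. Weight
#' initialisation is He-normal and driven by `seed`.
#'
#' @param layers list of layer descriptions.
#' @param input_dim integer `c(H, W, C)` of one input sample.
#' @param head output activation: `"sigmoid"`, `"softmax"` or `"linear"`.
#' @param exposed name of the layer whose activations are exposed for
#'   class-activation mapping, or `NULL`.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `hm_cnn`.
#' @export
nn_build <- function(layers, input_dim, head = c("sigmoid", "softmax", "linear"),
                     exposed = NULL, seed = 1L) {
  head <- match.arg(head)
  stopifnot(length(input_dim) == 3)
  set.seed(as.integer(seed))
  dim_cur <- as.integer(input_dim)   # H, W, C while spatial; length-1 after flatten
  spatial <- TRUE
  counts <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    counts[[ly$type]] <- (counts[[ly$type]] %||% 0L) + 1L
    if (is.null(ly$name)) ly$name <- paste0(ly$type, counts[[ly$type]])
    ly <- switch(ly$type,
      conv = {
        if (!spatial) stop("conv layer after flatten")
        fan_in <- ly$k * ly$k * dim_cur[3]
        ly$w <- array(stats::rnorm(ly$k * ly$k * dim_cur[3] * ly$filters,
                                   sd = sqrt(2 / fan_in)),
                      dim = c(ly$k, ly$k, dim_cur[3], ly$filters))
        # slightly positive bias keeps ReLU units alive at initialisation
        ly$b <- rep(0.05, ly$filters)
        dim_cur[3] <- ly$filters
        ly
      },
      relu = ly,
      pool = {
        if (!spatial) stop("pool layer after flatten")
        dim_cur[1:2] <- dim_cur[1:2] %/% ly$size
        ly
      },
      gap = {
        dim_cur <- dim_cur[3]; spatial <- FALSE; ly
      },
      flatten = {
        dim_cur <- prod(dim_cur); spatial <- FALSE; ly
      },
      dense = {
        if (spatial) stop("dense layer requires flatten or gap first")
        ly$w <- matrix(stats::rnorm(dim_cur * ly$units, sd = sqrt(2 / dim_cur)),
                       dim_cur, ly$units)
        ly$b <- numeric(ly$units)
        dim_cur <- ly$units
        ly
      },
      stop("unknown layer type: ", ly$type)
    )
    layers[[i]] <- ly
  }
  if (!is.null(exposed) && !exposed %in% vapply(layers, `[[`, "", "name"))
    stop("exposed layer '", exposed, "' not found; available: ",
         paste(vapply(layers, `[[`, "", "name"), collapse = ", "))
  structure(list(layers = layers, input_dim = as.integer(input_dim),
                 head = head, n_out = dim_cur, exposed = exposed),
            class = "hm_cnn")
}

#' @rdname nn_build
#' @param filters,k number and side of convolution kernels (k odd).
#' @export
layer_conv <- function(filters, k = 3L, name = NULL) {
  stopifnot(k %% 2 == 1)
  list(type = "conv", filters = as.integer(filters), k = as.integer(k), name = name)
}
#' @rdname nn_build
#' @param name optional layer name; defaults to type plus counter.
#' @export
layer_relu <- function(name = NULL) list(type = "relu", name = name)
#' @rdname nn_build
#' @param size pooling window side.
#' @param kind `"max"` or `"avg"`.
#' @export
layer_pool <- function(size = 2L, kind = c("max", "avg"), name = NULL) {
  list(type = "pool", size = as.integer(size), kind = match.arg(kind), name = name)
}
#' @rdname nn_build
#' @export
layer_gap <- function(name = NULL) list(type = "gap", name = name)
#' @rdname nn_build
#' @export
layer_flatten <- function(name = NULL) list(type = "flatten", name = name)
#' @rdname nn_build
#' @param units dense layer width.
#' @export
layer_dense <- function(units, name = NULL) {
  list(type = "dense", units = as.integer(units), name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_layer_names <- function(model) vapply(model$layers, `[[`, "", "name")

as_batch <- function(x, input_dim) {
  if (is.list(x)) x <- array(unlist(x, use.names = FALSE),
                             dim = c(input_dim, length(x)))
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4)
  x
}

# Forward pass from layer `from + 1` given its input `x`.
# Returns list(out, caches) where caches[[i]] holds what backward needs.
nn_forward <- function(model, x, from = 0L, keep = TRUE) {
  layers <- model$layers
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    if (i <= from) next
    ly <- layers[[i]]
    if (ly$type == "conv") {
      if (keep) caches[[i]] <- list(x = x)
      x <- nn_conv_fwd(x, ly$w, ly$b)
    } else if (ly$type == "relu") {
      x <- pmax(x, 0)
      if (keep) caches[[i]] <- list(mask = x > 0)
    } else if (ly$type == "pool") {
      r <- nn_pool_fwd(x, ly$size, if (ly$kind == "max") 0L else 1L)
      if (keep) caches[[i]] <- list(idx = r$idx, xdim = dim(x))
      x <- r$y
    } else if (ly$type == "gap") {
      d <- dim(x)
      if (keep) caches[[i]] <- list(xdim = d)
      x <- t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
    } else if (ly$type == "flatten") {
      d <- dim(x)
      if (keep) caches[[i]] <- list(xdim = d)
      x <- t(matrix(x, prod(d[1:3]), d[4]))
    } else if (ly$type == "dense") {
      if (keep) caches[[i]] <- list(x = x)
      x <- sweep(x %*% ly$w, 2, ly$b, `+`)
    }
  }
  list(out = x, caches = caches)
}

nn_head <- function(model, z) {
  switch(model$head,
    sigmoid = 1 / (1 + exp(-z)),
    softmax = {
      e <- exp(z - apply(z, 1, max))
      e / rowSums(e)
    },
    linear = z)
}

#' Predict with a compact CNN
#'
#' @param model an `hm_cnn`.
#' @param x input batch: an `(H, W, C, N)` array, a single `(H, W, C)` array,
#'   or a list of such arrays.
#' @return matrix `N x n_out` of head-activated outputs.
#' @export
nn_predict <- function(model, x) {
  x <- as_batch(x, model$input_dim)
  nn_head(model, nn_forward(model, x, keep = FALSE)$out)
}

# Backward pass from the output gradient `dz` (N x n_out, gradient w.r.t. the
# pre-head outputs) down to layer `to + 1`. Returns parameter gradients and
# the gradient arriving at the output of layer `to` (input of `to + 1`).
nn_backward <- function(model, caches, dz, to = 0L) {
  layers <- model$layers
  grads <- vector("list", length(layers))
  g <- dz
  for (i in rev(seq_along(layers))) {
    if (i <= to) break
    ly <- layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(dw = crossprod(cc$x, g), db = colSums(g))
      g <- g %*% t(ly$w)
    } else if (ly$type == "flatten") {
      g <- array(t(g), dim = cc$xdim)
    } else if (ly$type == "gap") {
      d <- cc$xdim
      gg <- array(0, dim = d)
      per <- t(g) / (d[1] * d[2])          # C x N
      gg[] <- rep(as.vector(per), each = d[1] * d[2])
      g <- gg
    } else if (ly$type == "pool") {
      g <- nn_pool_bwd(g, cc$idx, as.integer(cc$xdim), ly$size,
                       if (ly$kind == "max") 0L else 1L)
    } else if (ly$type == "relu") {
      g <- g * cc$mask
    } else if (ly$type == "conv") {
      r <- nn_conv_bwd(cc$x, ly$w, g)
      grads[[i]] <- list(dw = r$dw, db = r$db)
      g <- r$dx
    }
  }
  list(grads = grads, dx = g)
}

# Loss value and gradient w.r.t. pre-head outputs z (N x n_out).
nn_loss <- function(loss, z, y, head) {
  n <- nrow(z)
  eps <- 1e-12
  if (loss == "bce") {
    p <- 1 / (1 + exp(-z[, 1]))
    list(value = -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)),
         dz = matrix((p - y) / n, ncol = 1))
  } else if (loss == "ce") {
    e <- exp(z - apply(z, 1, max))
    p <- e / rowSums(e)
    ymat <- diag(ncol(z))[y, , drop = FALSE]
    list(value = -mean(log(p[cbind(seq_len(n), y)] + eps)),
         dz = (p - ymat) / n)
  } else if (loss == "mse") {
    r <- z[, 1] - y
    list(value = mean(r^2), dz = matrix(2 * r / n, ncol = 1))
  } else if (loss == "cox") {
    cx <- cox_npll_grad(z[, 1], y$time, y$event)
    list(value = cx$value, dz = matrix(cx$grad, ncol = 1))
  } else stop("unknown loss: ", loss)
}

#' Train a compact CNN by mini-batch SGD with momentum
#'
#' @param model an `hm_cnn`.
#' @param x input batch (see [nn_predict()]).
#' @param y targets: 0/1 vector for `"bce"`, 1-based class index for `"ce"`,
#'   numeric for `"mse"`, or a list/data frame with `time` and `event` for
#'   `"cox"` (trained full-batch so risk sets are complete).
#' @param loss one of `"bce"`, `"ce"`, `"mse"`, `"cox"`.
#' @param epochs,learning_rate,batch_size optimiser settings.
#' @param optimizer `"adam"` (default) or `"sgd"` (momentum SGD).
#' @param momentum momentum for `"sgd"`.
#' @param weight_decay decoupled L2 weight decay per update (weights only,
#'   not biases).
#' @param seed integer seed controlling shuffling.
#' @param verbose print per-epoch loss.
#' @return the trained model with a `history` element (mean loss per epoch).
#' @export
nn_train <- function(model, x, y, loss, epochs = 10L, learning_rate = NULL,
                     batch_size = 32L, optimizer = c("adam", "sgd"),
                     momentum = 0.9, weight_decay = 0, seed = 1L,
                     verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (is.null(learning_rate))
    learning_rate <- if (optimizer == "adam") 0.003 else 0.05
  x <- as_batch(x, model$input_dim)
  n <- dim(x)[4]
  if (loss == "cox") batch_size <- n
  set.seed(as.integer(seed))
  state <- lapply(model$layers, function(ly)
    if (ly$type %in% c("conv", "dense"))
      list(vw = ly$w * 0, vb = ly$b * 0, mw = ly$w * 0, mb = ly$b * 0)
    else NULL)
  b1 <- 0.9; b2 <- 0.999; adeps <- 1e-8
  step <- 0L
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- if (batch_size >= n) seq_len(n) else sample.int(n)
    tot <- 0
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      sel <- ord[s:min(s + batch_size - 1, n)]
      xb <- x[, , , sel, drop = FALSE]
      yb <- if (loss == "cox") list(time = y$time[sel], event = y$event[sel])
            else if (is.list(y)) lapply(y, `[`, sel) else y[sel]
      fw <- nn_forward(model, xb)
      ls <- nn_loss(loss, fw$out, yb, model$head)
      bw <- nn_backward(model, fw$caches, ls$dz)
      step <- step + 1L
      for (i in seq_along(model$layers)) {
        if (is.null(bw$grads[[i]])) next
        gw <- bw$grads[[i]]$dw; gb <- bw$grads[[i]]$db
        if (optimizer == "sgd") {
          state[[i]]$vw <- momentum * state[[i]]$vw - learning_rate * gw
          state[[i]]$vb <- momentum * state[[i]]$vb - learning_rate * gb
          model$layers[[i]]$w <- model$layers[[i]]$w + state[[i]]$vw
          model$layers[[i]]$b <- model$layers[[i]]$b + state[[i]]$vb
        } else {
          state[[i]]$mw <- b1 * state[[i]]$mw + (1 - b1) * gw
          state[[i]]$mb <- b1 * state[[i]]$mb + (1 - b1) * gb
          state[[i]]$vw <- b2 * state[[i]]$vw + (1 - b2) * gw^2
          state[[i]]$vb <- b2 * state[[i]]$vb + (1 - b2) * gb^2
          corr <- learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
          model$layers[[i]]$w <- model$layers[[i]]$w -
            corr * state[[i]]$mw / (sqrt(state[[i]]$vw) + adeps)
          model$layers[[i]]$b <- model$layers[[i]]$b -
            corr * state[[i]]$mb / (sqrt(state[[i]]$vb) + adeps)
        }
        if (weight_decay > 0)
          model$layers[[i]]$w <- model$layers[[i]]$w *
            (1 - learning_rate * weight_decay)
      }
      tot <- tot + ls$value * length(sel)
    }
    history[ep] <- tot / n
    if (verbose) message(sprintf("epoch %d loss %.5f", ep, history[ep]))
  }
  model$history <- c(model$history, history)
  model
}

# Activations at the named layer (post that layer) for a single sample.
nn_activation_at <- function(model, x, layer_name) {
  i <- match(layer_name, nn_layer_names(model))
  if (is.na(i)) stop("layer '", layer_name, "' not found; available: ",
                     paste(nn_layer_names(model), collapse = ", "))
  x <- as_batch(x, model$input_dim)
  layers <- model$layers
  for (j in seq_len(i)) {
    ly <- layers[[j]]
    x <- switch(ly$type,
      conv = nn_conv_fwd(x, ly$w, ly$b),
      relu = pmax(x, 0),
      pool = nn_pool_fwd(x, ly$size, if (ly$kind == "max") 0L else 1L)$y,
      gap = { d <- dim(x); t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])) },
      flatten = { d <- dim(x); t(matrix(x, prod(d[1:3]), d[4])) },
      dense = sweep(x %*% ly$w, 2, ly$b, `+`))
  }
  x
}

# Forward from the output of the named layer, injecting activations `a`
# (with the layer's output shape, batch dim included). Used by tests to
# finite-difference the class objective w.r.t. internal activations.
nn_forward_from <- function(model, a, layer_name) {
  i <- match(layer_name, nn_layer_names(model))
  if (is.na(i)) stop("layer '", layer_name, "' not found")
  nn_head(model, nn_forward(model, a, from = i, keep = FALSE)$out)
}

# Gradient of the class objective P_C (head output for class `class_index`,
# or the pre-head logit if wrt = "logit") with respect to the activations at
# the named layer, for a single sample. Returns list(activation, gradient,
# output) with activation/gradient shaped (H, W, M).
nn_class_gradient <- function(model, x, layer_name, class_index = 1L,
                              wrt = c("prob", "logit")) {
  wrt <- match.arg(wrt)
  i <- match(layer_name, nn_layer_names(model))
  if (is.na(i)) stop("layer '", layer_name, "' not found; available: ",
                     paste(nn_layer_names(model), collapse = ", "))
  x <- as_batch(x, model$input_dim)
  stopifnot(dim(x)[4] == 1)
  fw <- nn_forward(model, x)
  z <- fw$out
  p <- nn_head(model, z)
  k <- as.integer(class_index)
  if (k < 1 || k > ncol(z)) stop("class_index out of range")
  dz <- matrix(0, 1, ncol(z))
  if (wrt == "logit") {
    dz[1, k] <- 1
  } else if (model$head == "sigmoid") {
    dz[1, k] <- p[1, k] * (1 - p[1, k])
  } else if (model$head == "softmax") {
    dz[1, ] <- -p[1, k] * p[1, ]
    dz[1, k] <- dz[1, k] + p[1, k]
  } else {
    dz[1, k] <- 1
  }
  bw <- nn_backward(model, fw$caches, dz, to = i)
  act <- nn_activation_at(model, x, layer_name)
  g <- bw$dx
  list(activation = array(act, dim = dim(act)[1:3]),
       gradient = array(g, dim = dim(g)[1:3]),
       output = p[1, ])
}
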