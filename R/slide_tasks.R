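# Slide-level analyses on stacked patch-representation matrices: a small CNN
# with a task-specific head (sigmoid for binary classification, softmax for
# subtypes, linear for Cox survival and survival regression), the Cox partial
# likelihood loss, Harrell's concordance index, standard evaluation metrics,
# and the post-hoc pooling baselines.

#' Configuration for the slide-level CNN
#'
#' The default architecture is three convolution + pooling blocks followed by
#' a fully connected ReLU layer and a task-specific head: 64 kernels of 3x3
#' per convolution, 2x2 pooling, and a 1024-unit dense layer. All sizes are
#' configurable; small cohorts train comfortably with far fewer kernels.
#'
#' @param task `"binary"`, `"multiclass"`, `"cox"` or `"regression"`.
#' @param n_classes number of classes (multiclass only).
#' @param conv_blocks number of convolution + pooling blocks.
#' @param conv_kernels kernels per convolution layer.
#' @param kernel_size convolution kernel side.
#' @param pool `"max"` (default) or `"avg"` pooling in the blocks.
#' @param fc_width width of the fully connected layer.
#' @param optimizer `"adam"` (default; robust on the sparse map inputs) or
#'   `"sgd"` with momentum.
#' @param weight_decay decoupled L2 weight decay; defaults to 0.01 for the
#'   survival tasks (whose partial-likelihood/OLS signal is noisy at cohort
#'   scale) and 0 otherwise.
#' @param learning_rate,epochs,batch_size,momentum optimiser settings
#'   (survival tasks always train full-batch so risk sets are complete).
#' @param seed integer seed for initialisation and shuffling.
#' @return a `slide_model_config` list.
#' @export
slide_model_config <- function(task = c("binary", "multiclass", "cox", "regression"),
                               n_classes = 2L, conv_blocks = 3L,
                               conv_kernels = 64L, kernel_size = 3L,
                               pool = c("max", "avg"), fc_width = 1024L,
                               optimizer = c("adam", "sgd"),
                               weight_decay = NULL,
                               learning_rate = NULL, epochs = 30L,
                               batch_size = 16L, momentum = 0.9, seed = 1L) {
  task <- match.arg(task)
  pool <- match.arg(pool)
  optimizer <- match.arg(optimizer)
  if (is.null(weight_decay))
    weight_decay <- if (task %in% c("cox", "regression")) 0.01 else 0
  if (is.null(learning_rate)) {
    learning_rate <- if (optimizer == "adam")
      switch(task, cox = 0.01, 0.003)
    else
      switch(task, binary = 0.05, multiclass = 0.05,
             cox = 0.01, regression = 0.001)
  }
  structure(list(task = task, n_classes = as.integer(n_classes),
                 conv_blocks = as.integer(conv_blocks),
                 conv_kernels = as.integer(conv_kernels),
                 kernel_size = as.integer(kernel_size), pool = pool,
                 fc_width = as.integer(fc_width), optimizer = optimizer,
                 weight_decay = weight_decay,
                 head = switch(task, binary = "sigmoid", multiclass = "softmax",
                               cox = "linear", regression = "linear"),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "slide_model_config")
}

# Stack maps as (K, HW, 1, N); matrix rows are the leading dimension.
maps_array <- function(maps) {
  if (inherits(maps, "hm_hipomap")) maps <- list(maps)
  k <- maps[[1]]$K
  hw <- ncol(maps[[1]]$X)
  x <- array(0, dim = c(k, hw, 1L, length(maps)))
  for (i in seq_along(maps)) {
    if (maps[[i]]$K != k || ncol(maps[[i]]$X) != hw)
      stop("maps have inconsistent dimensions")
    x[, , 1L, i] <- maps[[i]]$X
  }
  x
}

#' Train the slide-level CNN on a set of slide maps
#'
#' @param maps list of [build_hipomap()] outputs with identical dimensions.
#' @param outcomes task-dependent: 0/1 vector (`binary`), 1-based class index
#'   or factor (`multiclass`), a data frame with `time` and `event` columns
#'   (`cox`), or a numeric vector (`regression`).
#' @param config a [slide_model_config()].
#' @return an `hm_slide_model`: the fitted network, the input scale factor,
#'   and the training history.
#' @export
train_slide_model <- function(maps, outcomes, config) {
  stopifnot(inherits(config, "slide_model_config"))
  x <- maps_array(maps)
  n <- dim(x)[4]
  if (n < 2) stop("need at least 2 slides")
  task <- config$task
  if (task == "binary") {
    y <- as.numeric(outcomes)
    if (!all(y %in% c(0, 1))) stop("binary task requires 0/1 outcomes")
    if (length(unique(y)) < 2) stop("binary task requires both classes")
    loss <- "bce"; n_out <- 1L
  } else if (task == "multiclass") {
    y <- if (is.factor(outcomes)) as.integer(outcomes) else as.integer(outcomes)
    if (min(y) < 1 || max(y) > config$n_classes)
      stop("multiclass outcomes must be 1..n_classes")
    loss <- "ce"; n_out <- config$n_classes
  } else if (task == "cox") {
    if (!all(c("time", "event") %in% names(outcomes)))
      stop("cox task requires outcomes with time and event")
    if (sum(outcomes$event) == 0)
      stop("cox task: all observations censored; partial likelihood undefined")
    y <- list(time = outcomes$time, event = outcomes$event)
    loss <- "cox"; n_out <- 1L
  } else {
    y <- as.numeric(outcomes)
    loss <- "mse"; n_out <- 1L
  }
  if (length(if (is.list(y)) y$time else y) != n)
    stop("outcomes length does not match number of maps")

  # One cohort-level scalar keeps inputs in a trainable range while
  # preserving relative intensities across slides.
  scale_factor <- max(abs(x))
  if (scale_factor <= 0) scale_factor <- 1
  x <- x / scale_factor

  k <- dim(x)[1]; hw <- dim(x)[2]
  blocks <- config$conv_blocks
  while (blocks > 0 && (k %/% 2^blocks < 1 || hw %/% 2^blocks < 1))
    blocks <- blocks - 1L
  layers <- list()
  for (b in seq_len(blocks)) {
    layers <- c(layers, list(layer_conv(config$conv_kernels, config$kernel_size),
                             layer_relu(), layer_pool(2L, config$pool)))
  }
  layers <- c(layers, list(layer_flatten(), layer_dense(config$fc_width),
                           layer_relu(), layer_dense(n_out)))
  net <- nn_build(layers, input_dim = c(k, hw, 1L), head = config$head,
                  seed = config$seed)
  net <- nn_train(net, x, y, loss, epochs = config$epochs,
                  learning_rate = config$learning_rate,
                  batch_size = config$batch_size,
                  optimizer = config$optimizer %||% "adam",
                  momentum = config$momentum,
                  weight_decay = config$weight_decay %||% 0,
                  seed = config$seed)
  structure(list(net = net, scale_factor = scale_factor, config = config,
                 history = net$history),
            class = "hm_slide_model")
}

#' Predict slide-level outputs
#'
#' @param model an `hm_slide_model`.
#' @param maps list of slide maps.
#' @return numeric vector (binary probability, prognostic index, or months),
#'   or an `N x n_classes` probability matrix for the multiclass task.
#' @export
predict_slide <- function(model, maps) {
  x <- maps_array(maps) / model$scale_factor
  p <- nn_predict(model$net, x)
  if (ncol(p) == 1) as.vector(p) else p
}

# ---- Cox partial likelihood ------------------------------------------------

cox_npll_grad <- function(risk, time, event) {
  d <- sum(event)
  if (d == 0) stop("cox partial likelihood requires at least one event")
  er <- exp(risk)
  # S_i = sum of exp(risk) over subjects still at risk at time_i (time >= t_i)
  atrisk <- outer(time, time, `>=`)            # [j, i] TRUE if t_j >= t_i
  S <- colSums(atrisk * er)
  ev <- event == 1
  value <- -sum(risk[ev] - log(S[ev])) / d
  # dl/dr_k = e_k - exp(r_k) * sum_{i: event, t_i <= t_k} 1 / S_i
  contrib <- atrisk[, ev, drop = FALSE] %*% (1 / S[ev])
  grad <- -(event - er * as.vector(contrib)) / d
  list(value = value, grad = grad)
}

#' Cox negative log partial likelihood
#'
#' Breslow convention for tied event times; the risk set at an event time
#' `t` contains every subject with follow-up time `>= t`. The sum over event
#' terms is divided by the number of events so the loss scale does not grow
#' with cohort size.
#'
#' @param risk numeric prognostic index per subject.
#' @param time follow-up time (months).
#' @param event 0/1 event indicator.
#' @return the loss value (single number).
#' @export
cox_npll <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  cox_npll_grad(risk, time, event)$value
}

#' Harrell's concordance index
#'
#' Fraction of admissible pairs whose predicted risk ordering matches the
#' observed survival ordering. A pair (i, j) is admissible when
#' `time[i] < time[j]` and subject i had the event; it scores 1 when
#' `risk[i] > risk[j]`, 0.5 on a risk tie, 0 otherwise.
#'
#' @inheritParams cox_npll
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  earlier <- outer(time, time, `<`)                 # [i, j]: t_i < t_j
  admissible <- earlier & (event == 1)              # row i must be an event
  npairs <- sum(admissible)
  if (npairs == 0) stop("no comparable pairs")
  hi <- outer(risk, risk, `>`)
  tie <- outer(risk, risk, `==`)
  (sum(hi & admissible) + 0.5 * sum(tie & admissible)) / npairs
}

# ---- Metrics ---------------------------------------------------------------

auc_rank <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes in the truth")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

f1_scores <- function(pred, truth, classes) {
  tp <- fp <- fn <- numeric(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp[i] <- sum(pred == k & truth == k)
    fp[i] <- sum(pred == k & truth != k)
    fn[i] <- sum(pred != k & truth == k)
  }
  per_class <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  micro <- if (sum(tp) + sum(fp) + sum(fn) == 0) 0 else
    2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn))
  list(micro_f1 = micro, macro_f1 = mean(per_class), per_class = per_class)
}

#' Evaluate slide-level predictions
#'
#' @param predictions task-dependent: probabilities (`binary`), a probability
#'   matrix or class index (`multiclass`), a prognostic index (`cox`), or
#'   predicted values (`regression`).
#' @param truth matching ground truth; for `cox` a data frame with `time`
#'   and `event`.
#' @param task the task the predictions came from.
#' @return a named list of metrics: AUC and accuracy (`binary`); micro- and
#'   macro-F1 and accuracy (`multiclass`); concordance (`cox`); RMSE and R^2
#'   (`regression`).
#' @export
evaluate <- function(predictions, truth,
                     task = c("binary", "multiclass", "cox", "regression")) {
  task <- match.arg(task)
  if (task == "binary") {
    stopifnot(length(predictions) == length(truth))
    list(auc = auc_rank(predictions, truth),
         accuracy = mean((predictions >= 0.5) == (truth == 1)))
  } else if (task == "multiclass") {
    pred <- if (is.matrix(predictions)) max.col(predictions, "first")
            else as.integer(predictions)
    truth <- if (is.factor(truth)) as.integer(truth) else as.integer(truth)
    stopifnot(length(pred) == length(truth))
    classes <- sort(unique(c(truth, pred)))
    c(f1_scores(pred, truth, classes)[c("micro_f1", "macro_f1")],
      list(accuracy = mean(pred == truth)))
  } else if (task == "cox") {
    list(c_index = concordance_index(predictions, truth$time, truth$event))
  } else {
    stopifnot(length(predictions) == length(truth))
    ss_res <- sum((truth - predictions)^2)
    ss_tot <- sum((truth - mean(truth))^2)
    list(rmse = sqrt(mean((predictions - truth)^2)),
         r2 = 1 - ss_res / ss_tot)
  }
}

# ---- Post-hoc pooling baselines -------------------------------------------

score_vector <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$prob
  scores <- as.numeric(scores)
  if (length(scores) == 0) stop("no patch scores")
  scores
}

#' Mean-pooling slide score baseline
#'
#' The mean of the patch probability scores, used as a slide-level score.
#'
#' @param scores numeric vector of patch probabilities or a patch-score
#'   data frame with a `prob` column.
#' @return a single slide score.
#' @export
baseline_mean <- function(scores) mean(score_vector(scores))

#' Max-pooling slide score baseline
#'
#' The highest patch probability score, used as a slide-level score.
#'
#' @inheritParams baseline_mean
#' @return a single slide score.
#' @export
baseline_max <- function(scores) max(score_vector(scores))
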