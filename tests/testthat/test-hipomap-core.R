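test_that("top-K ranking orders by score, then mean activation, then index", {
  sc <- data.frame(patch_index = 1:3, prob = c(0.9, 0.1, 0.5),
                   mean_activation = c(1, 1, 1))
  expect_identical(rank_top_k(sc, 2), c(1L, 3L))

  tie <- data.frame(patch_index = 1:2, prob = c(0.5, 0.5),
                    mean_activation = c(1.0, 2.0))
  expect_identical(rank_top_k(tie, 1), 2L)

  expect_error(rank_top_k(sc, 0), "k")
})

test_that("full ranking agrees with an exhaustive pairwise-comparison oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    sc <- data.frame(patch_index = seq_len(n),
                     prob = sample(c(0.2, 0.5, 0.9), n, replace = TRUE),
                     mean_activation = sample(c(1, 2), n, replace = TRUE))
    got <- rank_top_k(sc, n + 5)
    # oracle: selection sort with explicit precedence comparisons
    left <- seq_len(n); want <- integer(0)
    prec <- function(i, j) {
      if (sc$prob[i] != sc$prob[j]) return(sc$prob[i] > sc$prob[j])
      if (sc$mean_activation[i] != sc$mean_activation[j])
        return(sc$mean_activation[i] > sc$mean_activation[j])
      i < j
    }
    while (length(left)) {
      best <- left[1]
      for (cand in left) if (prec(cand, best)) best <- cand
      want <- c(want, best); left <- setdiff(left, best)
    }
    expect_identical(got, want)
  }
})

test_that("importance scores are per-map gradient sums clamped at zero", {
  b <- manual_bundle(array(1, dim = c(2, 2, 1)),
                     array(0.5, dim = c(2, 2, 1)))
  expect_equal(compute_importance(b), 2.0)

  g <- array(0, dim = c(2, 2, 2))
  g[, , 1] <- 0.25
  g[, , 2] <- -0.75                   # sums to -3: eliminated by the ReLU
  b2 <- manual_bundle(array(1, dim = c(2, 2, 2)), g)
  expect_equal(compute_importance(b2), c(1, 0))
  expect_equal(compute_importance(b2, relu = FALSE), c(1, -3))
  expect_equal(compute_importance(b2, reduce = "mean"), c(0.25, 0))
})

test_that("importance from a live network matches finite-difference sums", {
  net <- nn_build(list(layer_conv(2), layer_relu(name = "exp"), layer_gap(),
                       layer_dense(2)),
                  input_dim = c(4, 4, 1), head = "softmax", exposed = "exp",
                  seed = 13)
  x <- array(stats::runif(16, 0, 1), dim = c(4, 4, 1))
  model <- structure(list(net = net, input_dim = c(4L, 4L, 1L), binary = FALSE,
                          n_classes = 2L, exposed = "exp"),
                     class = "hm_patch_model")
  bundle <- activation_bundle(model, x, class_index = 1)
  fd <- fd_class_gradient(net, array(x, dim = c(4, 4, 1, 1)), "exp",
                          class_index = 1)
  alpha_fd <- pmax(apply(fd, 3, sum), 0)
  expect_equal(compute_importance(bundle), alpha_fd, tolerance = 1e-4)
})

test_that("the class feature map is the alpha-weighted sum of activation maps", {
  a <- array(0, dim = c(2, 2, 2))
  a[, , 1] <- 1
  a[, , 2] <- diag(2)
  b <- manual_bundle(a, a * 0)
  expect_equal(class_feature_map(c(1, 0), b), matrix(1, 2, 2))
  b2 <- manual_bundle(array(rep(diag(2), 2), dim = c(2, 2, 2)), a * 0)
  expect_equal(class_feature_map(c(2, 3), b2), 5 * diag(2))
  expect_error(class_feature_map(c(1, 2, 3), b), "does not match M")

  set.seed(3)
  ar <- array(stats::rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  alpha <- stats::runif(5)
  tm <- class_feature_map(alpha, manual_bundle(ar, ar * 0))
  loop <- matrix(0, 3, 4)
  for (m in 1:5) for (i in 1:3) for (j in 1:4)
    loop[i, j] <- loop[i, j] + alpha[m] * ar[i, j, m]
  expect_equal(tm, loop, tolerance = 1e-12)
})

test_that("patch representations are descending-sorted flattenings", {
  expect_equal(patch_representation(rbind(c(3, 1), c(2, 4))), c(4, 3, 2, 1))
  expect_equal(patch_representation(matrix(7, 2, 3)), rep(7, 6))
  set.seed(5)
  tm <- matrix(stats::rnorm(24), 4)
  f <- patch_representation(tm)
  expect_true(all(diff(f) <= 0))
  expect_equal(sort(f), sort(as.vector(tm)))
})

test_that("aggregation sorts rows by sum, pads with zeros, and records provenance", {
  reps <- list(rep(0.25, 4), rep(1.25, 4), rep(0.75, 4))   # sums 1, 5, 3
  hm <- build_hipomap(reps, 3)
  expect_identical(hm$patch_index, c(2L, 3L, 1L))
  expect_equal(hm$X[1, ], rep(1.25, 4))
  expect_identical(hm$pad_count, 0L)

  hm2 <- build_hipomap(reps[1:2], 4)
  expect_identical(dim(hm2$X), c(4L, 4L))
  expect_identical(hm2$pad_count, 2L)
  expect_true(all(hm2$X[3:4, ] == 0))
  expect_identical(hm2$patch_index, c(2L, 1L, NA_integer_, NA_integer_))

  expect_error(build_hipomap(list(1:3, 1:4), 2), "inconsistent")
  expect_error(build_hipomap(reps, 2), "more representations")
})

test_that("slide maps are fixed-size, non-negative, ordered, and order-invariant", {
  fx <- unit_scorer()
  k <- 6L
  for (s in fx$slides[1:4]) {
    hm <- slide_to_hipomap(s, fx$model, k = k)
    expect_identical(dim(hm$X), c(k, as.integer(prod(fx$model$act_dim[1:2]))))
    expect_true(all(hm$X >= 0))
    rs <- rowSums(hm$X)
    expect_true(all(diff(rs) <= 1e-9))
    live <- seq_len(k - hm$pad_count)
    for (r in live) expect_true(all(diff(hm$X[r, ]) <= 1e-12))
  }

  s <- fx$slides[[2]]
  set.seed(31)
  perm <- sample(length(s$patches))
  shuffled <- s
  shuffled$patches <- s$patches[perm]
  h1 <- slide_to_hipomap(s, fx$model, k = k)
  h2 <- slide_to_hipomap(shuffled, fx$model, k = k)
  expect_equal(h1$X, h2$X, tolerance = 1e-10)
})

test_that("slides smaller than K are zero-padded to the fixed shape", {
  fx <- unit_scorer()
  one <- fx$slides[[1]]
  one$patches <- one$patches[1]
  hm <- slide_to_hipomap(one, fx$model, k = 50)
  expect_identical(dim(hm$X), c(50L, 16L))
  expect_identical(hm$pad_count, 49L)
  expect_true(all(hm$X[2:50, ] == 0))
  expect_gt(sum(hm$X[1, ]), 0)
})

test_that("the original-variant switch changes only what it should", {
  fx <- unit_scorer()
  s <- fx$slides[[3]]
  hm_mod <- slide_to_hipomap(s, fx$model, k = 4)
  hm_orig <- slide_to_hipomap(s, fx$model, k = 4, variant = "original")
  expect_identical(dim(hm_mod$X), dim(hm_orig$X))
  expect_true(all(hm_orig$X >= 0))   # the original variant rectifies T
})
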