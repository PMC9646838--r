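test_that("cox partial likelihood: closed-form cases", {
  # two subjects with equal risks, one event: -log(1/2)
  expect_equal(cox_npll(c(0.3, 0.3), c(1, 2), c(1, 0)), log(2))
  # a single subject is its own risk set
  expect_equal(cox_npll(1.7, 5, 1), 0)
  expect_error(cox_npll(c(1, 2), c(1, 2), c(0, 0)), "event")
})

test_that("cox partial likelihood matches the survival-package evaluator", {
  skip_if_not_installed("survival")
  set.seed(41)
  for (rep in 1:5) {
    n <- 20
    r <- stats::rnorm(n)
    tt <- stats::rexp(n)
    ev <- stats::rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[1] <- 1
    fit <- survival::coxph(survival::Surv(tt, ev) ~ offset(r))
    expect_equal(cox_npll(r, tt, ev), -fit$loglik[1] / sum(ev),
                 tolerance = 1e-8)
  }
})

test_that("raising an event subject's risk lowers the cox loss", {
  set.seed(6)
  r <- stats::rnorm(10); tt <- stats::rexp(10); ev <- rep(c(1, 0), 5)
  r2 <- r; r2[1] <- r2[1] + 0.5
  expect_lt(cox_npll(r2, tt, ev), cox_npll(r, tt, ev))
})

test_that("concordance: perfect ordering, ties, and oracle agreement", {
  tt <- c(1, 2, 3, 4)
  expect_equal(concordance_index(c(4, 3, 2, 1), tt, rep(1, 4)), 1)
  expect_equal(concordance_index(rep(2, 4), tt, rep(1, 4)), 0.5)
  expect_error(concordance_index(1, 5, 0), "comparable")

  set.seed(10)
  n <- 30
  r <- stats::rnorm(n); tt <- stats::rexp(n); ev <- stats::rbinom(n, 1, 0.7)
  # brute force over all ordered pairs
  num <- den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i != j && tt[i] < tt[j] && ev[i] == 1) {
      den <- den + 1
      num <- num + (r[i] > r[j]) + 0.5 * (r[i] == r[j])
    }
  }
  ci <- concordance_index(r, tt, ev)
  expect_equal(ci, num / den)
  expect_equal(concordance_index(-r, tt, ev), 1 - ci)

  skip_if_not_installed("survival")
  co <- survival::concordance(survival::Surv(tt, ev) ~ r, reverse = TRUE)
  expect_equal(ci, unname(co$concordance), tolerance = 1e-12)
})

test_that("regression metrics reproduce the printed survival-example error", {
  pred <- c(3.2, 28.2, 46.4, 2.8, 17.2, 73.4)
  truth <- c(1, 23.3, 53.1, 1, 12.1, 87.4)
  m <- evaluate(pred, truth, "regression")
  expect_equal(m$rmse, sqrt(mean((pred - truth)^2)), tolerance = 1e-12)
  expect_gt(m$rmse, 7.0); expect_lt(m$rmse, 7.1)
  ident <- evaluate(truth, truth, "regression")
  expect_equal(ident$rmse, 0)
  expect_equal(ident$r2, 1)
})

test_that("classification metrics: AUC rank statistic and F1 pooling", {
  expect_equal(evaluate(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), "binary")$auc, 1)
  expect_error(evaluate(c(0.1, 0.2), c(1, 1), "binary"), "both classes")

  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- stats::runif(40); y <- stats::rbinom(40, 1, 0.5)
  expect_equal(evaluate(sc, y, "binary")$auc,
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
               tolerance = 1e-12)

  pred <- c(1, 2, 2, 3, 3, 3)
  truth <- c(1, 2, 3, 3, 3, 1)
  m <- evaluate(pred, truth, "multiclass")
  expect_equal(m$micro_f1, mean(pred == truth))           # single-label micro
  # macro: per-class F1 = (1: p=1,r=.5 -> 2/3), (2: p=.5,r=1 -> 2/3), (3: p=2/3,r=2/3)
  expect_equal(m$macro_f1, mean(c(2 / 3, 2 / 3, 2 / 3)))
})

test_that("pooling baselines and their invariants", {
  expect_equal(baseline_mean(c(0.2, 0.4)), 0.3)
  expect_equal(baseline_max(c(0.2, 0.9, 0.4)), 0.9)
  expect_equal(baseline_mean(0.7), 0.7)
  expect_equal(baseline_max(rep(0.5, 4)), 0.5)
  expect_error(baseline_mean(numeric(0)), "no patch scores")
  set.seed(20)
  for (rep in 1:10) {
    v <- stats::runif(sample(1:20, 1))
    expect_lte(baseline_mean(v), baseline_max(v))
    expect_equal(baseline_max(c(v, min(v))), baseline_max(v))
  }
  df <- data.frame(prob = c(0.1, 0.5))
  expect_equal(baseline_mean(df), 0.3)
})

make_toy_maps <- function(strength, k = 8, hw = 16, seed = 1) {
  set.seed(seed)
  lapply(strength, function(s) {
    rows <- lapply(seq_len(k), function(r)
      sort(stats::runif(hw, 0, 0.2) + s * (k - r + 1) / k, decreasing = TRUE))
    build_hipomap(rows, k)
  })
}

test_that("slide model heads match tasks and training is reproducible", {
  y <- rep(c(0, 1), each = 10)
  maps <- make_toy_maps(strength = 0.1 + 0.5 * y, seed = 2)
  cfg <- slide_model_config("binary", conv_kernels = 4L, fc_width = 8L,
                            epochs = 60, seed = 5)
  m1 <- train_slide_model(maps, y, cfg)
  m2 <- train_slide_model(maps, y, cfg)
  expect_identical(m1$history, m2$history)
  expect_lt(utils::tail(m1$history, 1), m1$history[1])
  pr <- predict_slide(m1, maps)
  expect_gte(evaluate(pr, y, "binary")$auc, 0.95)

  expect_error(train_slide_model(maps, rep(1, 20), cfg), "both classes")
  expect_error(train_slide_model(maps, c(0, 1, 0, 1, 0), cfg), "length")

  cfg_cox <- slide_model_config("cox", conv_kernels = 4L, fc_width = 8L,
                                epochs = 2, seed = 5)
  expect_error(train_slide_model(maps, data.frame(time = stats::rexp(20),
                                                  event = rep(0, 20)),
                                 cfg_cox),
               "censored")
})

test_that("the cox head learns a risk ordering on toy maps", {
  n <- 40
  set.seed(4)
  strength <- stats::runif(n, 0, 1)
  maps <- make_toy_maps(strength = strength, seed = 3)
  tt <- stats::rexp(n, rate = exp(2 * strength) / 20)
  ev <- rep(1L, n)
  cfg <- slide_model_config("cox", conv_kernels = 4L, fc_width = 8L,
                            epochs = 60, seed = 6)
  m <- train_slide_model(maps, data.frame(time = tt, event = ev), cfg)
  r <- predict_slide(m, maps)
  expect_gt(stats::cor(r, strength, method = "spearman"), 0.7)
})
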