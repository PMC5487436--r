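test_that("histograms count spikes per index and normalize by the maximum", {
  ev <- tibble::tibble(t = c(1, 2, 3), idx = c(0, 0, 1), sign = 1)
  h <- build_histograms(ev, 4)
  expect_equal(h[1, ], c(1, 0.5, 0, 0))
  # no events: the zero vector
  expect_equal(build_histograms(tibble::tibble(t = numeric(),
                                               idx = integer(),
                                               sign = numeric()), 4)[1, ],
               rep(0, 4))
  # out-of-range index
  expect_error(build_histograms(tibble::tibble(t = 0, idx = 4, sign = 1), 4),
               class = "spikehist_validation_error")
  # random multiset against a brute-force tally
  set.seed(14)
  ev2 <- tibble::tibble(t = sort(sample(0:99, 500, TRUE)),
                        idx = sample(0:19, 500, TRUE), sign = 1)
  tally <- tabulate(ev2$idx + 1, 20)
  expect_equal(build_histograms(ev2, 20)[1, ], tally / max(tally))
  # windowed build matches per-window brute force
  win <- tibble::tibble(t_start = c(0, 40), t_end = c(40, 100))
  hw <- build_histograms(ev2, 20, win)
  for (i in 1:2) {
    sel <- ev2$t >= win$t_start[i] & ev2$t < win$t_end[i] |
      (i == 2 & ev2$t == 100)
    tl <- tabulate(ev2$idx[sel] + 1, 20)
    expect_equal(hw[i, ], tl / max(tl))
  }
  # determinism: bit-identical on rebuild
  expect_identical(build_histograms(ev2, 20), build_histograms(ev2, 20))
})

test_that("softmax probabilities normalize and match direct evaluation", {
  # zero weights: uniform prediction
  expect_equal(softmax_forward(matrix(0, 4, 3), c(1, 2, 3))[1, ], rep(0.25, 4))
  set.seed(15)
  for (i in 1:20) {
    W <- matrix(rnorm(5 * 8, sd = 2), 5, 8)
    x <- runif(8)
    y <- softmax_forward(W, x)[1, ]
    expect_equal(sum(y), 1, tolerance = 1e-12)
    direct <- exp(as.vector(W %*% x))
    expect_equal(y, direct / sum(direct), tolerance = 1e-12)
  }
})

test_that("the NLL loss matches term-by-term evaluation", {
  # uniform prediction over 4 classes: loss log(4)
  X <- matrix(runif(12), 3, 4)
  expect_equal(nll_loss(matrix(0, 4, 4), X, c(0, 1, 2)), log(4))
  # highly confident correct predictions drive the loss to ~0
  Wc <- 50 * diag(3)
  expect_lt(nll_loss(Wc, diag(3), 0:2), 1e-6)
  # random batch against a direct sum
  set.seed(16)
  W <- matrix(rnorm(3 * 6), 3, 6)
  Xb <- matrix(runif(30), 5, 6)
  lb <- sample(0:2, 5, TRUE)
  direct <- -mean(vapply(1:5, function(i) {
    z <- as.vector(W %*% Xb[i, ])
    log(exp(z[lb[i] + 1]) / sum(exp(z)))
  }, numeric(1)))
  expect_equal(nll_loss(W, Xb, lb), direct, tolerance = 1e-12)
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(17)
  W <- matrix(rnorm(3 * 7, sd = 0.5), 3, 7)
  X <- matrix(runif(4 * 7), 4, 7)
  lb <- c(0, 2, 1, 2)
  g <- spikehist:::softmax_grad(W, X, lb)
  eps <- 1e-6
  for (i in 1:3) {
    for (j in 1:7) {
      Wp <- W; Wp[i, j] <- Wp[i, j] + eps
      Wm <- W; Wm[i, j] <- Wm[i, j] - eps
      num <- (nll_loss(Wp, X, lb) - nll_loss(Wm, X, lb)) / (2 * eps)
      expect_lt(abs(g[i, j] - num), 1e-6)
    }
  }
})

test_that("training leaves weights at zero when eta is zero and learns when not", {
  set.seed(18)
  X <- matrix(runif(20 * 6), 20, 6)
  lb <- rep(0:1, each = 10)
  f0 <- train_msgd(X, lb, eta = 0, epochs = 5, seed = 3)
  expect_equal(f0$W, matrix(0, 2, 6))
  # linearly separable two-class set reaches 100% training accuracy
  X2 <- rbind(cbind(matrix(runif(60, 0.6, 1), 10), matrix(runif(60, 0, 0.4), 10)),
              cbind(matrix(runif(60, 0, 0.4), 10), matrix(runif(60, 0.6, 1), 10)))
  f1 <- train_msgd(X2, rep(0:1, each = 10), epochs = 200, seed = 3)
  expect_equal(predict(f1, X2), rep(0:1, each = 10))
  # empty class errors
  expect_error(train_msgd(X, rep(c(0L, 2L), 10), epochs = 1),
               class = "spikehist_validation_error")
})

test_that("prediction is the argmax of the logits with low-index ties", {
  W <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  fit <- structure(list(W = W, classes = 3L), class = "softmax_fit")
  expect_equal(predict(fit, c(0, 1, 0)), 1L)
  # zero weights tie on every class: the lowest index wins
  fit0 <- structure(list(W = matrix(0, 3, 3), classes = 3L),
                    class = "softmax_fit")
  expect_equal(predict(fit0, c(1, 1, 1)), 0L)
  # argmax over probabilities agrees with argmax over logits
  set.seed(19)
  for (i in 1:20) {
    W <- matrix(rnorm(4 * 5), 4, 5)
    x <- runif(5)
    f <- structure(list(W = W, classes = 4L), class = "softmax_fit")
    expect_equal(predict(f, x),
                 which.max(softmax_forward(W, x)[1, ]) - 1L)
  }
})

test_that("weight scaling is a rounded multiple with the threshold at K", {
  fit <- structure(list(W = matrix(c(0.5, 0, -0.123), 1)), # 1 x 3
                   class = "softmax_fit")
  sc <- scale_weights(fit, 1e7)
  expect_equal(sc$W_int[1, ], c(5e6, 0, -1230000))
  expect_equal(sc$th_fc, 1e7)
  expect_lte(sc$max_round_error, 0.5 / 1e7)
  # the scaled decision rule agrees with the analog one whenever the
  # logit gap exceeds the rounding slack h * 0.5 / K
  set.seed(20)
  h <- 12
  for (i in 1:50) {
    W <- matrix(rnorm(3 * h), 3, h)
    counts <- sample(0:20, h, TRUE)
    za <- as.vector(W %*% counts)
    zi <- as.vector(round(W * 1e7) %*% counts) / 1e7
    gap <- sort(za, decreasing = TRUE)
    if (gap[1] - gap[2] > h * 0.5 / 1e7) {
      expect_equal(which.max(zi), which.max(za))
    }
  }
})

test_that("predictions are invariant to positive rescaling of the weights", {
  set.seed(22)
  W <- matrix(rnorm(4 * 9), 4, 9)
  X <- matrix(runif(30 * 9), 30, 9)
  f1 <- structure(list(W = W), class = "softmax_fit")
  for (c in c(0.01, 3, 1e7)) {
    f2 <- structure(list(W = c * W), class = "softmax_fit")
    expect_equal(predict(f1, X), predict(f2, X))
  }
})

test_that("tidy and glance expose the fitted classifier", {
  set.seed(23)
  X <- matrix(runif(40), 10, 4)
  fit <- scale_weights(train_msgd(X, rep(0:1, 5), epochs = 10, seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 8L)
  expect_equal(td$weight_int, as.vector(fit$W_int))
  gl <- glance(fit)
  expect_equal(gl$classes, 2L)
  expect_equal(gl$k_scale, 1e7)
  expect_true(gl$final_loss >= 0)
})
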