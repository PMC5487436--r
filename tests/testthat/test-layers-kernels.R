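test_that("gabor kernels match pointwise evaluation of the closed form", {
  # direct, independent evaluation over the 7x7 grid for theta = 0
  k <- gabor_kernel(theta = 0, sigma = 4, lambda = 8, psi = 0, gamma = 0.5,
                    size = 7)
  for (yy in -3:3) {
    for (xx in -3:3) {
      expected <- exp(-(xx^2 + 0.25 * yy^2) / 32) * cos(2 * pi * xx / 8)
      expect_equal(k[yy + 4, xx + 4], expected, tolerance = 1e-12)
    }
  }
  # center value is exactly 1 for psi = 0, any orientation
  for (th in seq(0, 160, by = 20)) {
    expect_identical(gabor_kernel(th)[4, 4], 1)
  }
  # psi = 0 kernels are even: g(x, y) == g(-x, -y)
  for (th in c(0, 20, 40, 140)) {
    g <- gabor_kernel(th)
    expect_equal(g, g[7:1, 7:1])
  }
})

test_that("the default bank has one kernel per (theta, psi), theta-major", {
  bank <- gabor_bank()
  expect_length(bank, 18L)
  p <- bank_params(bank)
  expect_equal(p$theta, rep(seq(0, 160, by = 20), each = 2))
  expect_equal(p$psi, rep(c(0, 1.7), 9))
  # a single-combination bank has one kernel
  expect_length(gabor_bank(theta_list = 45, psi_list = 0.5), 1L)
  # theta and theta + 180 give identical kernels at psi = 0
  expect_equal(gabor_bank(theta_list = 30, psi_list = 0)[[1L]],
               gabor_bank(theta_list = 210, psi_list = 0)[[1L]])
})

test_that("kernel quantization rounds taps and bounds the error", {
  bank <- gabor_bank()
  q <- quantize_kernels(bank, scale = 1e6)
  expect_equal(q[[1L]][4, 4], 1e6)  # tap 1.0 at the psi=0 center
  expect_true(all(purrr::map_lgl(q, ~all(.x == round(.x)))))
  set.seed(8)
  for (scale in c(10, 1234, 1e6)) {
    qq <- quantize_kernels(bank, scale)
    err <- max(purrr::map2_dbl(bank, qq,
                               ~max(abs(.x - .y / scale))))
    expect_lte(err, 0.5 / scale)
    expect_equal(attr(qq, "max_quant_error"), err)
  }
  expect_equal(quantize_kernels(list(matrix(0, 3, 3)), 1e6)[[1L]],
               matrix(0, 3, 3))
})

test_that("one input event updates exactly the covered receptive fields", {
  # single kernel of distinct taps; thresholds too high to fire
  K <- list(matrix(1:9, 3, 3, byrow = TRUE))
  cfg <- convnet_config(6, bank = structure(K, class = "kernel_bank"),
                        c1_th_plus = 1e9)
  # center event: k^2 membrane updates arranged as the flipped kernel
  s <- event_stream(data.frame(t = 0, x = 3, y = 3, sign = 1), 6, 6)
  vm <- run_convnet(s, cfg, record_c1_vm = TRUE)$c1_vm[[1L]]
  expect_equal(sum(vm != 0), 9L)
  # output neuron (xo, yo) got tap (3 - xo, 3 - yo): the flipped kernel
  for (yo in 1:3) for (xo in 1:3) {
    expect_equal(vm[yo + 1, xo + 1], K[[1L]][3 - yo + 1, 3 - xo + 1])
  }
  # corner event: exactly one valid output neuron (no padding)
  s2 <- event_stream(data.frame(t = 0, x = 0, y = 0, sign = 1), 6, 6)
  vm2 <- run_convnet(s2, cfg, record_c1_vm = TRUE)$c1_vm[[1L]]
  expect_equal(sum(vm2 != 0), 1L)
  expect_equal(vm2[1, 1], K[[1L]][1, 1])
})

test_that("with leak off and thresholds at infinity the membrane map is a convolution", {
  # frame-equivalence limit: final membranes equal the dense valid
  # cross-correlation of the signed event-count image with each kernel
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    ks <- sample(c(3, 5), 1)
    bank <- quantize_kernels(gabor_bank(theta_list = c(0, 80),
                                        psi_list = c(0, 1.7), size = ks),
                             scale = 1000)
    cfg <- convnet_config(n, bank = bank, c1_th_plus = 1e15,
                          pool = if ((n - ks + 1) %% 2) 1L else 2L)
    s <- random_stream(60, n, t_max = 500)
    maps <- run_convnet(s, cfg, record_c1_vm = TRUE)$c1_vm
    img <- event_count_image(s, n, n)
    for (fm in seq_along(bank)) {
      expect_identical(maps[[fm]], dense_xcorr(img, bank[[fm]]))
    }
  }
})

test_that("subsampling remap decimates addresses and conserves events", {
  ev <- tibble::tibble(t = c(0, 1), x = c(4, 5), y = c(5, 4), sign = 1)
  out <- subsample_events(ev, 2, "remap")
  expect_equal(out$x, c(2, 2))
  expect_equal(out$y, c(2, 2))
  set.seed(9)
  big <- tibble::tibble(t = 1:500, x = sample(0:9, 500, TRUE),
                        y = sample(0:9, 500, TRUE),
                        sign = sample(c(-1, 1), 500, TRUE))
  expect_equal(nrow(subsample_events(big, 2, "remap")), 500L)
})

test_that("accumulate pooling emits one event per m net inputs per block", {
  ev <- tibble::tibble(t = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                       sign = 1)
  out <- subsample_events(ev, 2, "accumulate", m = 4)
  expect_equal(nrow(out), 1L)
  expect_equal(out$t, 4)
  expect_equal(out$sign, 1)
  # counting oracle on a random stream: per-block output count equals the
  # net count integer-divided by m (all-positive input)
  set.seed(10)
  big <- tibble::tibble(t = 1:400, x = sample(0:7, 400, TRUE),
                        y = sample(0:7, 400, TRUE), sign = 1)
  out2 <- subsample_events(big, 2, "accumulate", m = 3)
  blocks <- paste(big$x %/% 2, big$y %/% 2)
  expect_equal(nrow(out2), sum(floor(table(blocks) / 3)))
})

test_that("flatten addressing is the documented bijection", {
  expect_equal(flatten_index(0, 0, 0, 11), 0)
  expect_equal(flatten_index(1, 0, 0, 11), 121)
  expect_equal(flatten_index(0, 3, 2, 11), 25)
  # full enumeration over 18 maps of 11x11 covers [0, 2178) exactly once
  grid <- expand.grid(fm = 0:17, x = 0:10, y = 0:10)
  idx <- flatten_index(grid$fm, grid$x, grid$y, 11)
  expect_equal(sort(idx), 0:2177)
  back <- flatten_address(idx, 11)
  expect_equal(back$fm, grid$fm)
  expect_equal(back$x, grid$x)
  expect_equal(back$y, grid$y)
})

test_that("the spiking classifier layer equals a scalar accumulator without leak", {
  # leak off: each class's spike count follows floor-threshold resets of
  # its running weighted sum; compare with a direct scalar oracle
  set.seed(12)
  h <- 30
  W <- matrix(runif(3 * h, -2e6, 8e6), nrow = 3)
  th <- 1e7
  ev <- tibble::tibble(t = sort(sample(0:999, 200, TRUE)),
                       idx = sample(0:(h - 1), 200, TRUE),
                       sign = 1)
  res <- run_fc_layer(ev, W, th)
  for (cl in 0:2) {
    vm <- 0; spikes <- 0
    for (i in seq_len(nrow(ev))) {
      vm <- vm + W[cl + 1, ev$idx[i] + 1]
      if (vm >= th) { spikes <- spikes + 1; vm <- 0 }
    }
    expect_equal(sum(res$class == cl), spikes)
  }
  # one input spike through a weight equal to TH_FC fires immediately
  W1 <- matrix(0, 2, 4); W1[2, 3] <- 1e7
  r1 <- run_fc_layer(tibble::tibble(t = 5, idx = 2, sign = 1), W1, 1e7)
  expect_equal(r1$class, 1L)
  expect_equal(r1$t, 5)
  # all-zero weights never produce output
  r0 <- run_fc_layer(ev, matrix(0, 3, h), th)
  expect_equal(nrow(r0), 0L)
})
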