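test_that("the cell recurrence reproduces hand-computed values", {
  # all weights zero: gates sit at 1/2, candidate at 0
  z <- matrix(0, 1, 1)
  p0 <- list(U = list(i = z, f = z, o = z, g = z),
             W = list(i = z, f = z, o = z, g = z),
             b = list(i = 0, f = 0, o = 0, g = 0))
  st <- lstm_cell_step(0, 0, 0, p0)
  expect_equal(st$c, 0)
  expect_equal(st$h, 0)
  # single unit, every weight 1, x = 0, h = 0, C_prev = 1:
  # i = f = o = 1/2, candidate = 0, C = 1/2, h = tanh(1/2)/2
  o1 <- matrix(1, 1, 1)
  p1 <- list(U = list(i = o1, f = o1, o = o1, g = o1),
             W = list(i = o1, f = o1, o = o1, g = o1),
             b = list(i = 0, f = 0, o = 0, g = 0))
  st1 <- lstm_cell_step(0, 0, 1, p1)
  expect_equal(st1$c, 0.5)
  expect_equal(st1$h, tanh(0.5) * 0.5, tolerance = 1e-12)
  expect_equal(st1$h, 0.2311, tolerance = 1e-3)
  # gates bounded: cell state stays bounded for bounded history
  set.seed(2)
  rnd <- function() matrix(rnorm(1), 1, 1)
  p2 <- list(U = list(i = rnd(), f = rnd(), o = rnd(), g = rnd()),
             W = list(i = rnd(), f = rnd(), o = rnd(), g = rnd()),
             b = list(i = 0.3, f = -0.2, o = 0.1, g = 0))
  cc <- 0.7; h <- 0.1
  for (t in 1:100) {
    st2 <- lstm_cell_step(rnorm(1), h, cc, p2)
    h <- st2$h; cc <- st2$c
    expect_lt(abs(cc), 101)    # |C_t| <= f|C_{t-1}| + 1
    expect_lt(abs(h), 1)
  }
})

test_that("the compiled recurrence matches the R cell step to 1e-5", {
  set.seed(31)
  for (act in c("tanh", "sigmoid")) {
    d <- 3; u <- 4; B <- 2; T <- 12
    Wx <- matrix(rnorm(d * 4 * u, sd = 0.4), d, 4 * u)
    Wh <- matrix(rnorm(u * 4 * u, sd = 0.4), u, 4 * u)
    b <- rnorm(4 * u, sd = 0.2)
    x <- array(rnorm(B * d * T), c(B, d, T))
    H_cpp <- seizecast:::lstm_layer_forward_cpp(
      Wx, Wh, b, x, if (act == "tanh") 0L else 1L)
    H_ref <- r_layer_forward(Wx, Wh, b, x, act)
    expect_lt(max(abs(H_cpp - H_ref)), 1e-5)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(17)
  cfg <- lstm_config(layer_units = c(4, 3, 3, 2), pool_size = 2,
                     n_labels = 2, recurrent_dropout = 0, seed = 7)
  m <- build_lstm_model(cfg, input_shape = c(16, 3))
  x <- array(rnorm(4 * 3 * 16), c(4, 3, 16))
  y <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  g <- seizecast:::lstm_grad_cpp(m$params, x, y, 2L, 0L)
  eps <- 1e-6
  for (pi in seq_along(m$params)) {
    for (k in sample(length(m$params[[pi]]), min(3, length(m$params[[pi]])))) {
      up <- m$params; up[[pi]][k] <- up[[pi]][k] + eps
      dn <- m$params; dn[[pi]][k] <- dn[[pi]][k] - eps
      fd <- (seizecast:::lstm_grad_cpp(up, x, y, 2L, 0L)$loss -
               seizecast:::lstm_grad_cpp(dn, x, y, 2L, 0L)$loss) / (2 * eps)
      an <- g$grads[[pi]][k]
      expect_lt(abs(fd - an), 1e-6 + 1e-3 * (abs(fd) + abs(an)))
    }
  }
})

test_that("max pooling is invariant to permutation within a window", {
  set.seed(23)
  x <- array(rnorm(3 * 2 * 12), c(3, 2, 12))
  p <- 4L
  out <- seizecast:::max_pool_cpp(x, p)
  expect_equal(dim(out), c(3, 2, 3))
  # reference: max over each non-overlapping window
  for (w in 1:3) {
    win <- x[, , ((w - 1) * p + 1):(w * p), drop = FALSE]
    expect_equal(out[, , w], apply(win, c(1, 2), max))
  }
  # permute time inside windows: output unchanged
  perm <- as.vector(vapply(0:2, function(w) 4 * w + sample(4), numeric(4)))
  expect_equal(seizecast:::max_pool_cpp(x[, , perm, drop = FALSE], p), out)
})

test_that("the model structure is 4 LSTM + 3 pooling + dense layers", {
  cfg <- lstm_config(layer_units = c(64, 32, 16, 8), pool_size = 4,
                     n_labels = 2)
  m <- build_lstm_model(cfg, input_shape = c(4000, 16))
  rep_ <- lstm_structure_report(m)
  expect_equal(sum(rep_$kind == "lstm"), 4)
  expect_equal(sum(rep_$kind == "maxpool"), 3)
  expect_equal(sum(rep_$kind == "dense"), 1)
  # temporal trace 4000 -> 1000 -> 250 -> 62 (floor)
  expect_equal(rep_$time_steps[rep_$kind == "maxpool"], c(1000, 250, 62))
  # only the last LSTM stops returning the sequence
  expect_equal(rep_$returns_sequence[rep_$kind == "lstm"],
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(rep_$units[rep_$kind == "dense"], 2)
  m5 <- build_lstm_model(lstm_config(n_labels = 5), c(4000, 16))
  expect_equal(tail(m5$structure$units, 1), 5)
  expect_error(build_lstm_model(lstm_config(pool_size = 20), c(100, 4)),
               "collapsed")
  expect_error(lstm_config(layer_units = c(8, 16, 4, 4)))
  expect_error(lstm_config(recurrent_dropout = 1))
})

test_that("training is deterministic, converges to the MSE floor, predicts in [0,1]", {
  set.seed(5)
  # identical inputs with half/half labels: best loss is the target
  # variance 0.25
  x <- array(rep(rnorm(2 * 8), each = 40), c(40, 2, 8))
  lab <- rep(0:1, 20)
  cfg <- lstm_config(layer_units = c(4, 3, 3, 2), pool_size = 2,
                     n_labels = 2, learning_rate = 5e-3, epochs = 8,
                     patience = 8, seed = 9, batch_size = 8)
  m1 <- train_lstm(build_lstm_model(cfg, c(8, 2)), x, lab)
  m2 <- train_lstm(build_lstm_model(cfg, c(8, 2)), x, lab)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params, m2$params)
  expect_lt(abs(tail(m1$history$train_loss, 1) - 0.25), 0.05)
  p <- predict_segment(m1, x)
  expect_equal(dim(p), c(40, 2))
  expect_true(all(p >= 0 & p <= 1))
  # inference is pure: repeated predictions identical
  expect_identical(p, predict_segment(m1, x))
  expect_identical(predict_segment(m1, x[1, , ]),
                   p[1, , drop = FALSE])
  expect_error(train_lstm(build_lstm_model(cfg, c(8, 2)),
                          x[0, , , drop = FALSE], integer()), "empty")
})

test_that("a learnable amplitude difference is learned quickly", {
  set.seed(77)
  n <- 80
  x <- array(rnorm(n * 2 * 16), c(n, 2, 16))
  lab <- rep(0:1, each = n / 2)
  x[lab == 1, , ] <- x[lab == 1, , ] * 3
  cfg <- lstm_config(layer_units = c(8, 4, 4, 2), pool_size = 2,
                     n_labels = 2, learning_rate = 1e-2, epochs = 15,
                     patience = 15, seed = 3)
  m <- train_lstm(build_lstm_model(cfg, c(16, 2)), x, lab)
  p <- predict_segment(m, x)
  auc <- roc_auc(combine_scores(p[, 2], p[, 1]), lab == 1)$auc
  expect_gt(auc, 0.95)
})
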