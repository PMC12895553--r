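test_that("mish matches its closed form and asymptotes", {
  expect_equal(mish(0), 0)
  expect_equal(mish(1), 1 * tanh(log(1 + exp(1))))
  expect_equal(mish(1), 0.86509839, tolerance = 1e-7)
  # large-|u| stability: ratio tends to 1 (positive) / value tends to 0 (negative)
  expect_equal(mish(50) / 50, 1, tolerance = 1e-12)
  expect_equal(mish(800) / 800, 1, tolerance = 1e-12)
  expect_equal(mish(-800), 0, tolerance = 1e-12)
  expect_error(mish(Inf), "finite")
})

test_that("count_main_params: hand counts and linearity in output dims", {
  tiny <- twin_config(n_in = 4, n_hidden_hyper = 2, n_sensor_plus_cond = 1,
                      n_hidden_main = 1, n_action = 1, n_bold = 0)
  expect_identical(count_main_params(tiny), 6L)  # 1+1+1+1+1+1
  base <- twin_config(n_in = 4, n_hidden_hyper = 2, n_sensor_plus_cond = 5,
                      n_hidden_main = 7, n_action = 3, n_bold = 4)
  dbl <- twin_config(n_in = 4, n_hidden_hyper = 2, n_sensor_plus_cond = 5,
                     n_hidden_main = 7, n_action = 6, n_bold = 4)
  expect_identical(count_main_params(dbl) - count_main_params(base),
                   3L * 7L + 3L)
})

test_that("pack/unpack round-trips exactly across configurations", {
  cfgs <- list(
    twin_config(n_in = 5, n_hidden_hyper = 3, n_sensor_plus_cond = 2,
                n_hidden_main = 4, n_action = 2, n_bold = 3),
    twin_config(n_in = 5, n_hidden_hyper = 3, n_sensor_plus_cond = 9,
                n_hidden_main = 6, n_action = 3, n_bold = 1),
    twin_config(n_in = 5, n_hidden_hyper = 3, n_sensor_plus_cond = 1,
                n_hidden_main = 1, n_action = 1, n_bold = 0)
  )
  set.seed(42)
  for (cfg in cfgs) {
    x <- rnorm(count_main_params(cfg))
    views <- unpack_main_params(x, cfg)
    expect_identical(pack_main_params(views, cfg), x)
    # row-major packing: first n_sensor entries are the first row of W_ih
    expect_equal(views$W_ih[1, ], x[seq_len(cfg$n_sensor_plus_cond)])
  }
  expect_error(unpack_main_params(1:5, cfgs[[1]]), "does not match")
})

test_that("hypernet_forward: zero weights, determinism, hand example", {
  cfg <- twin_config(n_in = 2, n_hidden_hyper = 2, dropout = 0.5,
                     n_sensor_plus_cond = 1, n_hidden_main = 1,
                     n_action = 1, n_bold = 0)
  hp0 <- init_hypernet(cfg, 1)
  for (nm in names(hp0)) hp0[[nm]] <- hp0[[nm]] * 0
  expect_equal(hypernet_forward(c(1, -2), hp0)$packed, rep(0, 6))

  # dropout off is deterministic
  hp <- init_hypernet(cfg, 2)
  expect_identical(hypernet_forward(c(1, -2), hp)$packed,
                   hypernet_forward(c(1, -2), hp)$packed)

  # 2-unit hand example: y = W3 mish(W2 mish(W1 x + b1) + b2) + b3
  hp$W1 <- matrix(c(0.5, -0.3, 0.2, 0.1), 2, 2)
  hp$b1 <- c(0.1, -0.2)
  hp$W2 <- matrix(c(1, 0.5, -0.5, 0.25), 2, 2)
  hp$b2 <- c(0, 0.3)
  hp$W3 <- matrix(seq(0.1, 1.2, by = 0.1), 6, 2)
  hp$b3 <- rep(0.05, 6)
  x <- c(0.7, -1.1)
  h1 <- mish(drop(hp$W1 %*% x) + hp$b1)
  h2 <- mish(drop(hp$W2 %*% h1) + hp$b2)
  expect_equal(hypernet_forward(x, hp)$packed,
               drop(hp$W3 %*% h2) + hp$b3, tolerance = 1e-12)
  expect_error(hypernet_forward(c(1, 2, 3), hp), "n_in")
})

test_that("input dropout is applied only when requested and is seeded", {
  cfg <- twin_config(n_in = 50, n_hidden_hyper = 4, dropout = 0.5,
                     n_sensor_plus_cond = 1, n_hidden_main = 2,
                     n_action = 1, n_bold = 1)
  hp <- init_hypernet(cfg, 3)
  x <- rep(1, 50)
  a <- hypernet_forward(x, hp, dropout_on = TRUE, seed = 9)$packed
  b <- hypernet_forward(x, hp, dropout_on = TRUE, seed = 9)$packed
  d <- hypernet_forward(x, hp, dropout_on = TRUE, seed = 10)$packed
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_error(hypernet_forward(x, hp, dropout_on = TRUE), "seed")
})

test_that("rnn_rollout: zero parameters and tanh range", {
  cfg <- twin_config(n_in = 3, n_hidden_hyper = 2, n_sensor_plus_cond = 9,
                     n_hidden_main = 5, n_action = 3, n_bold = 2)
  params <- unpack_main_params(rep(0, count_main_params(cfg)), cfg)
  ro <- rnn_rollout(params, matrix(0, 4, 9), cfg)
  expect_equal(ro$hidden, matrix(0, 4, 5))
  expect_equal(ro$action_prob, matrix(0.5, 4, 3))  # sigmoid(0)
  expect_equal(ro$bold_pred, matrix(0, 4, 2))

  set.seed(7)
  params <- unpack_main_params(rnorm(count_main_params(cfg), sd = 0.5), cfg)
  ro <- rnn_rollout(params, matrix(rnorm(40 * 9), 40, 9), cfg)
  expect_true(all(abs(ro$hidden) < 1))
  expect_true(all(ro$action_prob > 0 & ro$action_prob < 1))
})

test_that("rnn_rollout matches pencil-and-paper recursion on a 1-unit net", {
  cfg <- twin_config(n_in = 2, n_hidden_hyper = 2, n_sensor_plus_cond = 1,
                     n_hidden_main = 1, n_action = 1, n_bold = 1)
  views <- list(W_ih = matrix(0.5), b_ih = 0.1, W_hh = matrix(0.8),
                b_hh = -0.05, W_ho = matrix(c(1.2, -0.7), 2, 1),
                b_ho = c(0.3, 0.2))
  params <- unpack_main_params(pack_main_params(views, cfg), cfg)
  x <- c(1, 0.5, -1)
  h <- 0; H <- A <- B <- numeric(3)
  for (t in 1:3) {
    h <- tanh(0.5 * x[t] + 0.1 + 0.8 * h - 0.05)
    H[t] <- h
    A[t] <- 1 / (1 + exp(-(1.2 * h + 0.3)))
    B[t] <- -0.7 * h + 0.2
  }
  ro <- rnn_rollout(params, matrix(x, 3, 1), cfg)
  expect_equal(drop(ro$hidden), H, tolerance = 1e-12)
  expect_equal(drop(ro$action_prob), A, tolerance = 1e-12)
  expect_equal(drop(ro$bold_pred), B, tolerance = 1e-12)
})

test_that("constant input drives the hidden state to a fixed point", {
  cfg <- twin_config(n_in = 2, n_hidden_hyper = 2, n_sensor_plus_cond = 3,
                     n_hidden_main = 6, n_action = 1, n_bold = 1)
  set.seed(11)
  packed <- rnorm(count_main_params(cfg), sd = 0.3)
  params <- unpack_main_params(packed, cfg)
  inputs <- matrix(rep(c(0.3, -0.2, 1), each = 400), 400, 3)
  ro <- rnn_rollout(params, inputs, cfg)
  expect_lt(max(abs(ro$hidden[400, ] - ro$hidden[399, ])), 1e-6)
})

test_that("end-to-end gradient wrt the connectome matches finite differences", {
  cfg <- twin_config(n_in = 8, n_hidden_hyper = 4, dropout = 0,
                     n_sensor_plus_cond = 3, n_hidden_main = 4,
                     n_action = 2, n_bold = 2)
  set.seed(5)
  hp <- init_hypernet(cfg, 5)
  for (nm in c("W1", "W2", "W3")) hp[[nm]] <- hp[[nm]] * 3
  x <- rnorm(8)
  Tn <- 6; S <- 2
  arrs <- list(X = matrix(rnorm(3 * S * Tn), 3),
               A = matrix(rbinom(2 * S * Tn, 1, 0.3), 2),
               B = matrix(rnorm(2 * S * Tn), 2), S = S, Tn = Tn)
  lc <- loss_config()
  loss_of <- function(x_) {
    fwd <- twinbrain:::hypernet_fwd(x_, hp, NULL)
    views <- unpack_main_params(fwd$y, cfg)
    pp <- twinbrain:::participant_pass(views, arrs, cfg, lc, want_grad = FALSE)
    pp$sum_bce / pp$n_act + pp$sum_se / pp$n_bold
  }
  fwd <- twinbrain:::hypernet_fwd(x, hp, NULL)
  views <- unpack_main_params(fwd$y, cfg)
  pp <- twinbrain:::participant_pass(views, arrs, cfg, lc)
  gx <- twinbrain:::hypernet_bwd(fwd, hp, pp$gpacked)$gx
  h <- 1e-5
  fd <- vapply(seq_len(8), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (loss_of(xp) - loss_of(xm)) / (2 * h)
  }, 0)
  expect_lt(max(abs(fd - gx) / pmax(abs(fd), 1e-6)), 1e-4)
})

test_that("non-finite rollout is reported with a step index", {
  cfg <- twin_config(n_in = 2, n_hidden_hyper = 2, n_sensor_plus_cond = 1,
                     n_hidden_main = 1, n_action = 1, n_bold = 1)
  views <- unpack_main_params(rep(0.5, count_main_params(cfg)), cfg)
  expect_error(rnn_rollout(views, matrix(NaN, 3, 1), cfg), "step")
})
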