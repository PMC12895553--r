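small_pls <- function(cfg, seed = 1) {
  # PLS over packed parameters generated from random connectomes
  set.seed(seed)
  n <- 12
  hp <- init_hypernet(cfg, seed)
  W <- t(vapply(seq_len(n), function(i) {
    hypernet_forward(rnorm(cfg$n_in), hp)$packed
  }, numeric(count_main_params(cfg))))
  s <- rnorm(n)
  list(hp = hp, W = W,
       pls = pls_direction(W, s, main_param_layout(cfg)$hash))
}

test_that("SmoothGrad at noise 0 equals the exact gradient, seeded runs repeat", {
  cfg <- twin_config(n_in = 20, n_hidden_hyper = 6, dropout = 0,
                     n_sensor_plus_cond = 3, n_hidden_main = 4,
                     n_action = 2, n_bold = 2)
  obj <- small_pls(cfg)
  x <- rnorm(20)
  g0 <- smoothgrad_edges(obj$hp, x, obj$pls, smoothgrad_config(50, 0, 1))
  exact <- twinbrain:::z1_input_grad(x, obj$hp, obj$pls)
  expect_equal(g0$gradient, exact, tolerance = 1e-12)
  a <- smoothgrad_edges(obj$hp, x, obj$pls, smoothgrad_config(20, 0.1, 5))
  b <- smoothgrad_edges(obj$hp, x, obj$pls, smoothgrad_config(20, 0.1, 5))
  expect_identical(a$gradient, b$gradient)
  expect_false(identical(a$gradient, g0$gradient))
})

test_that("linear surrogate hypernetwork has the closed-form attribution", {
  # independent-oracle check of the analytic input gradient via central
  # finite differences of z1(x) computed through the public forward pass
  cfg <- twin_config(n_in = 6, n_hidden_hyper = 4, dropout = 0,
                     n_sensor_plus_cond = 2, n_hidden_main = 2,
                     n_action = 1, n_bold = 1)
  obj <- small_pls(cfg, seed = 2)
  x <- rnorm(6)
  g <- twinbrain:::z1_input_grad(x, obj$hp, obj$pls)
  # independent check: central finite differences of z1(x)
  z1_of <- function(x_) {
    y <- hypernet_forward(x_, obj$hp)$packed
    sum(((y - obj$pls$col_mean) / obj$pls$col_sd) * obj$pls$v)
  }
  h <- 1e-6
  fd <- vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (z1_of(xp) - z1_of(xm)) / (2 * h)
  }, 0)
  expect_lt(max(abs(fd - g) / pmax(abs(fd), 1e-8)), 1e-5)
})

test_that("SmoothGrad maps converge with the sample count", {
  cfg <- twin_config(n_in = 15, n_hidden_hyper = 5, dropout = 0,
                     n_sensor_plus_cond = 2, n_hidden_main = 3,
                     n_action = 1, n_bold = 1)
  obj <- small_pls(cfg, seed = 3)
  x <- rnorm(15)
  m100 <- smoothgrad_edges(obj$hp, x, obj$pls, smoothgrad_config(100, 0.1, 7))
  m200 <- smoothgrad_edges(obj$hp, x, obj$pls, smoothgrad_config(200, 0.1, 8))
  expect_gt(cor(m100$gradient, m200$gradient), 0.99)
})

test_that("select_top_edges splits strengthen/weaken at the SD threshold", {
  flat <- structure(list(gradient = rep(1, 100)), class = "gradient_map")
  expect_identical(nrow(select_top_edges(flat, 2.5)), 0L)
  g <- c(rnorm(999, sd = 1e-3), 5)
  map <- structure(list(gradient = g), class = "gradient_map")
  top <- select_top_edges(map, 2.5)
  expect_identical(top$edge, 1000L)
  expect_identical(top$direction, "strengthen")
  g[1] <- -5
  top2 <- select_top_edges(structure(list(gradient = g),
                                     class = "gradient_map"), 2.5)
  expect_setequal(top2$direction, c("strengthen", "weaken"))
  # threshold 0 returns every edge
  expect_identical(nrow(select_top_edges(map, 0)), 1000L)
})

test_that("perturb_weights: identity at alpha 0, substitution, inverse", {
  cfg <- twin_config(n_in = 4, n_hidden_hyper = 3, n_sensor_plus_cond = 1,
                     n_hidden_main = 1, n_action = 1, n_bold = 0)
  params <- unpack_main_params(rep(0, 6), cfg)
  lay <- main_param_layout(cfg)
  spec0 <- structure(list(v_raw = c(1, 0, 0, 0, 0, 0), alpha = 0,
                          layout_hash = lay$hash),
                     class = "intervention_spec")
  expect_identical(perturb_weights(params, spec0, cfg)$packed, params$packed)
  spec2 <- spec0; spec2$alpha <- 2
  expect_equal(perturb_weights(params, spec2, cfg)$packed,
               c(2, 0, 0, 0, 0, 0))
  # alpha then -alpha restores the original
  set.seed(3)
  p1 <- unpack_main_params(rnorm(6), cfg)
  v <- rnorm(6); v <- v / sqrt(sum(v^2))
  sp <- structure(list(v_raw = v, alpha = 0.7, layout_hash = lay$hash),
                  class = "intervention_spec")
  sm <- sp; sm$alpha <- -0.7
  back <- perturb_weights(perturb_weights(p1, sp, cfg), sm, cfg)
  expect_equal(back$packed, p1$packed, tolerance = 1e-12)
  # layout-hash mismatch is refused
  bad <- sp; bad$layout_hash <- "nope"
  expect_error(perturb_weights(p1, bad, cfg), "layout hash")
})

test_that("intervention_spec de-standardizes the direction by column SDs", {
  pls <- structure(list(v = c(0.6, 0.8), col_sd = c(2, 1), z1 = c(-1, 0, 1),
                        kind = "cognitive", layout_hash = "h"),
                   class = "pls_result")
  spec <- intervention_spec(pls, alpha = 1)
  expect_equal(spec$v_raw, c(1.2, 0.8) / sqrt(1.2^2 + 0.8^2))
  # default alpha is twice the SD of z1
  expect_equal(intervention_spec(pls)$alpha, 2 * sd(c(-1, 0, 1)))
})

test_that("near-linear regime: indicator change is proportional to alpha", {
  # with tiny weights the tanh RNN and linear BOLD readout operate in
  # their linear range, so the mean BOLD response must scale linearly
  # with the perturbation intensity
  cfg <- twin_config(n_in = 4, n_hidden_hyper = 3, n_sensor_plus_cond = 2,
                     n_hidden_main = 3, n_action = 1, n_bold = 1)
  set.seed(14)
  np <- count_main_params(cfg)
  packed <- rnorm(np, sd = 0.01)
  base <- unpack_main_params(packed, cfg)
  v <- rnorm(np); v <- v / sqrt(sum(v^2))
  lay <- main_param_layout(cfg)
  inputs <- matrix(runif(30 * 2), 30, 2)
  indicator <- function(params) {
    mean(rnn_rollout(params, inputs, cfg)$bold_pred)
  }
  i0 <- indicator(base)
  deltas <- vapply(c(0.005, 0.01, 0.02), function(alpha) {
    sp <- structure(list(v_raw = v, alpha = alpha, layout_hash = lay$hash),
                    class = "intervention_spec")
    indicator(perturb_weights(base, sp, cfg)) - i0
  }, 0)
  expect_equal(deltas[2] / deltas[1], 2, tolerance = 0.05)
  expect_equal(deltas[3] / deltas[1], 4, tolerance = 0.1)
})

test_that("effect sizes follow the (pre - post) / SD(pre) formula", {
  es <- effect_sizes(c(0, 2), c(0, 0))
  expect_equal(es$sd_pre, sqrt(2))
  expect_equal(es$d, c(0, sqrt(2)))
  expect_equal(es$frac_large, 0.5)
  es0 <- effect_sizes(c(1, 3, 5), c(1, 3, 5))
  expect_equal(es0$d, c(0, 0, 0))
  expect_error(effect_sizes(c(1, 1), c(0, 2)), "constant")
  # missing pairs are excluded and counted
  es2 <- effect_sizes(c(1, 2, NA), c(0, 1, 1))
  expect_identical(es2$n_excluded, 1L)
})
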