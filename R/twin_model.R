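#' Model configuration for the hypernetwork / main-network pair
#'
#' The architecture couples two networks. A hypernetwork (a 2-hidden-layer
#' multilayer perceptron with Mish activations) maps an individual's
#' Fisher-z vectorized resting-state connectome of length `n_in` to the
#' packed parameter vector of that individual's main network. The main
#' network is a vanilla recurrent network with `n_hidden_main` tanh units
#' that receives, at every 80 ms step, the 8-dimensional sensory channel
#' plus the 1-dimensional task-condition channel (`n_sensor_plus_cond`)
#' and emits next-step action probabilities (`n_action`) and regional BOLD
#' predictions (`n_bold`).
#'
#' Defaults follow the full-scale reference configuration: 200 hypernetwork
#' hidden units, 400 main-network hidden units, dropout 0.1 on the
#' connectome input, 3 action dimensions and 20 BOLD regions. At
#' `n_in = 99235` (446 regions) this yields 173,623 main-network parameters.
#'
#' @param n_in length of the rsFCM edge vector fed to the hypernetwork.
#' @param n_hidden_hyper hidden units in each hypernetwork layer.
#' @param dropout dropout rate applied to the rsFCM input during training.
#' @param n_sensor_plus_cond input dimensionality of the main network
#'   (sensory dims + task-condition dim).
#' @param n_hidden_main hidden units of the recurrent main network.
#' @param n_action action output dimensions (button channels).
#' @param n_bold number of BOLD regions predicted.
#' @return an object of class `twin_config`.
#' @export
#' @examples
#' cfg <- twin_config(n_in = 99235)
#' count_main_params(cfg)  # 173623
twin_config <- function(n_in,
                        n_hidden_hyper = 200L,
                        dropout = 0.1,
                        n_sensor_plus_cond = 9L,
                        n_hidden_main = 400L,
                        n_action = 3L,
                        n_bold = 20L) {
  cfg <- list(
    n_in = as.integer(n_in),
    n_hidden_hyper = as.integer(n_hidden_hyper),
    dropout = dropout,
    n_sensor_plus_cond = as.integer(n_sensor_plus_cond),
    n_hidden_main = as.integer(n_hidden_main),
    n_action = as.integer(n_action),
    n_bold = as.integer(n_bold)
  )
  stop_ifnot(all(vapply(cfg[c(1, 2, 4, 5, 6)], function(x) x >= 1L, TRUE)),
             "all dimensions except n_bold must be >= 1")
  stop_ifnot(cfg$n_bold >= 0L, "n_bold must be >= 0")
  stop_ifnot(is.numeric(dropout) && dropout >= 0 && dropout < 1,
             "dropout must lie in [0, 1)")
  class(cfg) <- "twin_config"
  cfg
}

#' Mish activation
#'
#' `mish(u) = u * tanh(softplus(u))`, computed stably for large `|u|`.
#'
#' @param u numeric vector.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' mish(0)        # 0
#' mish(1)        # ~0.8651
mish <- function(u) {
  stop_ifnot(all(is.finite(u)), "mish: input must be finite")
  u * tanh(softplus(u))
}

# d/du mish(u) = tanh(sp(u)) + u * sigmoid(u) * (1 - tanh(sp(u))^2)
mish_grad <- function(u) {
  t_sp <- tanh(softplus(u))
  t_sp + u * sigmoid(u) * (1 - t_sp^2)
}

#' Layout of the packed main-network parameter vector
#'
#' Parameters are packed in the fixed order (W_ih, b_ih, W_hh, b_hh, W_ho,
#' b_ho), each matrix row-major. All partial-least-squares coefficient
#' vectors and intervention directions live in this coordinate system; the
#' layout hash guards against applying a vector computed under one
#' configuration to parameters packed under another.
#'
#' @param cfg a [twin_config()].
#' @return list with per-block dimensions, offsets, total length and a
#'   `hash` identifying the layout.
#' @export
main_param_layout <- function(cfg) {
  nh <- cfg$n_hidden_main
  ns <- cfg$n_sensor_plus_cond
  no <- cfg$n_action + cfg$n_bold
  blocks <- list(
    W_ih = c(nh, ns), b_ih = c(nh, 1L),
    W_hh = c(nh, nh), b_hh = c(nh, 1L),
    W_ho = c(no, nh), b_ho = c(no, 1L)
  )
  sizes <- vapply(blocks, prod, 0)
  offsets <- cumsum(c(0, sizes[-length(sizes)]))
  names(offsets) <- names(blocks)
  hash <- digest::digest(list("main_param_layout_v1", nh, ns, cfg$n_action, cfg$n_bold))
  list(blocks = blocks, sizes = sizes, offsets = offsets,
       total = as.integer(sum(sizes)), hash = hash)
}

#' Number of learnable parameters of the main network
#'
#' @param cfg a [twin_config()].
#' @return integer count |W_ih|+|b_ih|+|W_hh|+|b_hh|+|W_ho|+|b_ho|.
#' @export
#' @examples
#' count_main_params(twin_config(n_in = 99235))  # 173623
count_main_params <- function(cfg) {
  main_param_layout(cfg)$total
}

#' Unpack a flat main-network parameter vector into structured views
#'
#' @param packed numeric vector of length [count_main_params()].
#' @param cfg a [twin_config()].
#' @return object of class `main_net_params`: list of matrices/vectors
#'   `W_ih`, `b_ih`, `W_hh`, `b_hh`, `W_ho`, `b_ho` plus the `packed`
#'   vector and the layout hash.
#' @export
unpack_main_params <- function(packed, cfg) {
  lay <- main_param_layout(cfg)
  stop_ifnot(length(packed) == lay$total,
             "packed length %d does not match layout total %d",
             length(packed), lay$total)
  views <- vector("list", length(lay$blocks))
  names(views) <- names(lay$blocks)
  for (nm in names(lay$blocks)) {
    d <- lay$blocks[[nm]]
    seg <- packed[(lay$offsets[[nm]] + 1):(lay$offsets[[nm]] + prod(d))]
    views[[nm]] <- if (startsWith(nm, "b_")) as.numeric(seg)
                   else matrix(seg, nrow = d[1], ncol = d[2], byrow = TRUE)
  }
  structure(c(views, list(packed = as.numeric(packed), layout_hash = lay$hash)),
            class = "main_net_params")
}

#' Pack structured main-network views into the flat vector
#'
#' Inverse of [unpack_main_params()]; `pack(unpack(x)) == x` exactly.
#'
#' @param views a `main_net_params` object or plain list with the six views.
#' @param cfg a [twin_config()].
#' @return numeric vector of length [count_main_params()].
#' @export
pack_main_params <- function(views, cfg) {
  lay <- main_param_layout(cfg)
  out <- numeric(lay$total)
  for (nm in names(lay$blocks)) {
    d <- lay$blocks[[nm]]
    v <- views[[nm]]
    seg <- if (startsWith(nm, "b_")) as.numeric(v) else as.vector(t(v))
    stop_ifnot(length(seg) == prod(d), "block %s has wrong size", nm)
    out[(lay$offsets[[nm]] + 1):(lay$offsets[[nm]] + prod(d))] <- seg
  }
  out
}

#' Initialize hypernetwork parameters
#'
#' Scaled-Gaussian initialization: hidden layers use sd `1/sqrt(fan_in)`;
#' the output layer gain is additionally shrunk by `1/sqrt(n_hidden_hyper)`
#' so that the input-dependent part of the generated parameters starts
#' small.
#'
#' The output bias `b3` — the shared baseline main network around which
#' the hypernetwork learns individual deviations — is initialized as a
#' conventional recurrent-network starting point rather than zeros
#' (`baseline = "rnn"`): Gaussian input weights (sd `1/3`), an orthogonal
#' recurrent matrix scaled to spectral radius 0.9, zero readout weights,
#' and an action-readout bias of -4 (press probability near the sparse
#' base rate). An all-zero baseline generates main networks with no
#' temporal memory, and pilot runs showed press-timing learning stalls
#' there; see the methods vignette. `baseline = "zero"` restores the
#' plain scheme.
#'
#' @param cfg a [twin_config()].
#' @param seed integer seed.
#' @param baseline `"rnn"` (default) or `"zero"`.
#' @return object of class `hypernet_params` (list W1,b1,W2,b2,W3,b3 with
#'   the config attached).
#' @export
init_hypernet <- function(cfg, seed = 1L, baseline = c("rnn", "zero")) {
  baseline <- match.arg(baseline)
  nh <- cfg$n_hidden_hyper
  nm <- cfg$n_hidden_main
  np <- count_main_params(cfg)
  with_seed(seed, {
    hp <- list(
      W1 = matrix(stats::rnorm(nh * cfg$n_in, sd = 1 / sqrt(cfg$n_in)), nh, cfg$n_in),
      b1 = numeric(nh),
      W2 = matrix(stats::rnorm(nh * nh, sd = 1 / sqrt(nh)), nh, nh),
      b2 = numeric(nh),
      W3 = matrix(stats::rnorm(np * nh, sd = 1 / (nh)), np, nh),
      b3 = numeric(np)
    )
    if (baseline == "rnn") {
      no <- cfg$n_action + cfg$n_bold
      ortho <- qr.Q(qr(matrix(stats::rnorm(nm * nm), nm, nm)))
      hp$b3 <- pack_main_params(list(
        W_ih = matrix(stats::rnorm(nm * cfg$n_sensor_plus_cond, sd = 1 / 3),
                      nm, cfg$n_sensor_plus_cond),
        b_ih = numeric(nm),
        W_hh = 0.9 * ortho,
        b_hh = numeric(nm),
        W_ho = matrix(0, no, nm),
        b_ho = c(rep(-4, cfg$n_action), rep(0, cfg$n_bold))
      ), cfg)
    }
    attr(hp, "config") <- cfg
    class(hp) <- "hypernet_params"
    hp
  })
}

# forward pass keeping the cache needed for backprop.
# dropout_mask: NULL (no dropout) or a 0/scale vector applied to x.
hypernet_fwd <- function(x, hp, dropout_mask = NULL) {
  xd <- if (is.null(dropout_mask)) x else x * dropout_mask
  u1 <- drop(hp$W1 %*% xd) + hp$b1
  h1 <- mish(u1)
  u2 <- drop(hp$W2 %*% h1) + hp$b2
  h2 <- mish(u2)
  y <- drop(hp$W3 %*% h2) + hp$b3
  list(y = y, xd = xd, u1 = u1, h1 = h1, u2 = u2, h2 = h2,
       dropout_mask = dropout_mask)
}

# backprop through the hypernetwork given dL/dy; returns parameter grads
# and the gradient with respect to the (pre-dropout) input x.
hypernet_bwd <- function(cache, hp, gy) {
  gW3 <- tcrossprod(gy, cache$h2)
  gb3 <- gy
  gh2 <- drop(crossprod(hp$W3, gy))
  gu2 <- gh2 * mish_grad(cache$u2)
  gW2 <- tcrossprod(gu2, cache$h1)
  gb2 <- gu2
  gh1 <- drop(crossprod(hp$W2, gu2))
  gu1 <- gh1 * mish_grad(cache$u1)
  gW1 <- tcrossprod(gu1, cache$xd)
  gb1 <- gu1
  gx <- drop(crossprod(hp$W1, gu1))
  if (!is.null(cache$dropout_mask)) gx <- gx * cache$dropout_mask
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3),
       gx = gx)
}

#' Generate main-network parameters from a connectome vector
#'
#' Runs the hypernetwork forward: two Mish hidden layers and a linear
#' output producing the packed main-network parameter vector. Dropout on
#' the input vector is active only when `dropout_on = TRUE` (training);
#' evaluation, attribution and intervention simulation run with dropout
#' disabled and are fully deterministic.
#'
#' @param x rsFCM edge vector of length `cfg$n_in` (or an `rsfcm` object).
#' @param hp a [init_hypernet()] parameter set (or trained equivalent).
#' @param dropout_on logical; apply input dropout.
#' @param seed seed for the dropout mask (required if `dropout_on`).
#' @return a `main_net_params` object (see [unpack_main_params()]).
#' @export
hypernet_forward <- function(x, hp, dropout_on = FALSE, seed = NULL) {
  cfg <- attr(hp, "config")
  if (inherits(x, "rsfcm")) x <- x$edges
  stop_ifnot(length(x) == cfg$n_in,
             "input length %d does not match configured n_in %d",
             length(x), cfg$n_in)
  mask <- NULL
  if (dropout_on && cfg$dropout > 0) {
    stop_ifnot(!is.null(seed), "dropout_on = TRUE requires a seed")
    mask <- with_seed(seed,
      (stats::runif(cfg$n_in) >= cfg$dropout) / (1 - cfg$dropout))
  }
  fwd <- hypernet_fwd(as.numeric(x), hp, mask)
  unpack_main_params(fwd$y, cfg)
}

#' Roll out the main recurrent network over an input sequence
#'
#' Vanilla RNN dynamics
#' `h_t = tanh(W_ih x_t + b_ih + W_hh h_{t-1} + b_hh)` with linear readout
#' `y_t = W_ho h_t + b_ho`. Row `t` of the outputs is the model's
#' prediction for step `t + 1`. The first `n_action` readout dimensions
#' are passed through a logistic sigmoid (press probabilities); the
#' remaining `n_bold` dimensions are returned raw for mean-squared-error
#' comparison against normalized BOLD.
#'
#' @param params a `main_net_params` object.
#' @param inputs T x n_sensor_plus_cond matrix of sensory+condition input.
#' @param cfg a [twin_config()] describing the dimensions.
#' @param h0 initial hidden state (default zeros).
#' @return object of class `rollout_result`: list with `hidden`
#'   (T x n_hidden), `action_prob` (T x n_action), `bold_pred`
#'   (T x n_bold) and `action_logit`.
#' @export
rnn_rollout <- function(params, inputs, cfg, h0 = NULL) {
  inputs <- as.matrix(inputs)
  stop_ifnot(ncol(inputs) == cfg$n_sensor_plus_cond,
             "inputs have %d columns, expected %d",
             ncol(inputs), cfg$n_sensor_plus_cond)
  Tn <- nrow(inputs)
  nh <- cfg$n_hidden_main
  if (is.null(h0)) h0 <- numeric(nh)
  stop_ifnot(length(h0) == nh, "h0 length %d != n_hidden_main %d",
             length(h0), nh)
  # batched path: treat the single sequence as one segment
  X <- array(t(inputs), dim = c(cfg$n_sensor_plus_cond, 1L, Tn))
  fwd <- rnn_fwd_batch(params, X, h0 = matrix(h0, nh, 1L))
  hidden <- t(matrix(fwd$H, nh, Tn))
  Y <- t(matrix(fwd$Y, cfg$n_action + cfg$n_bold, Tn))
  if (any(!is.finite(hidden))) {
    bad <- which(!is.finite(rowSums(hidden)))[1]
    stop(sprintf("non-finite hidden state at step %d", bad), call. = FALSE)
  }
  act_logit <- Y[, seq_len(cfg$n_action), drop = FALSE]
  structure(list(
    hidden = hidden,
    action_logit = act_logit,
    action_prob = sigmoid(act_logit),
    bold_pred = Y[, cfg$n_action + seq_len(cfg$n_bold), drop = FALSE]
  ), class = "rollout_result")
}

# Batched RNN forward over S segments of equal length.
# X: array [n_in_main, S, T] (or the matching flat matrix [n_in, S*T]
# with time-major column blocks); h0: n_hidden x S matrix.
# The input and output projections are hoisted out of the time loop; only
# the recurrent update runs per step. Returns flat matrices H and Y
# [*, S*T], block t in columns ((t-1)S+1):(tS), plus the dims.
rnn_fwd_batch <- function(params, X, h0 = NULL, S = NULL, Tn = NULL) {
  if (is.null(S)) { d <- dim(X); S <- d[2]; Tn <- d[3] }
  nh <- nrow(params$W_hh)
  Xf <- matrix(X, nrow = if (length(dim(X)) == 3) dim(X)[1] else nrow(X))
  if (is.null(h0)) h0 <- matrix(0, nh, S)
  out <- .rnn_fwd_cpp(params$W_ih, params$b_ih, params$W_hh, params$b_hh,
                      params$W_ho, params$b_ho, Xf, S, Tn, h0)
  list(H = out$H, Y = out$Y, S = S, Tn = Tn, Xf = Xf)
}

# Backward pass (BPTT). gY: flat matrix [n_out, S*T] of dL/dY.
# Returns the gradient with respect to the packed parameter vector.
rnn_bwd_batch <- function(params, Xf, fwd, gY, cfg, h0 = NULL) {
  S <- fwd$S; Tn <- fwd$Tn
  nh <- nrow(params$W_hh)
  if (is.null(h0)) h0 <- matrix(0, nh, S)
  Xm <- matrix(Xf, nrow = if (length(dim(Xf)) == 3) dim(Xf)[1] else nrow(Xf))
  g <- .rnn_bwd_cpp(params$W_hh, params$W_ho, Xm, fwd$H, gY, S, Tn, h0)
  pack_main_params(list(W_ih = g$W_ih, b_ih = drop(g$b_h),
                        W_hh = g$W_hh, b_hh = drop(g$b_h),
                        W_ho = g$W_ho, b_ho = drop(g$b_ho)), cfg)
}
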