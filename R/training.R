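#' Loss configuration
#'
#' Binary cross-entropy for the action channel plus mean squared error
#' for the BOLD channel, each weighted and summed:
#' `L = lambda_action * mean(BCE) + lambda_bold * mean(SE)`, means taken
#' over all (segment, time step, dimension) elements.
#'
#' @param lambda_action,lambda_bold non-negative weights (defaults 1, 1).
#' @return object of class `loss_config`.
#' @export
loss_config <- function(lambda_action = 1, lambda_bold = 1) {
  stop_ifnot(lambda_action >= 0 && lambda_bold >= 0,
             "loss weights must be >= 0")
  stop_ifnot(lambda_action > 0 || lambda_bold > 0,
             "at least one loss weight must be positive")
  structure(list(lambda_action = lambda_action, lambda_bold = lambda_bold),
            class = "loss_config")
}

#' Training configuration
#'
#' Reference full-scale values: 262-step segments (20.96 s), batch size
#' 50, Adam at learning rate 1e-6, up to 800 epochs with early stopping
#' on a validation split. For scaled-down synthetic cohorts the default
#' learning rate here is 1e-3 (the full-scale 1e-6 is far too small for
#' toy dimensions; see the methods vignette).
#'
#' @param segment_len steps per training segment.
#' @param batch_size participants per optimization step.
#' @param lr Adam learning rate.
#' @param max_epochs maximum epochs.
#' @param early_stop_patience epochs without validation improvement
#'   before stopping.
#' @param val_fraction fraction of each participant's training segments
#'   held out (from the end) for validation.
#' @param seed training seed (shuffling, dropout masks).
#' @return object of class `train_config`.
#' @export
train_config <- function(segment_len = 262L, batch_size = 50L, lr = 1e-3,
                         max_epochs = 800L, early_stop_patience = 50L,
                         val_fraction = 0.1, seed = 1L) {
  stop_ifnot(segment_len >= 1, "segment_len must be >= 1")
  stop_ifnot(val_fraction > 0 && val_fraction < 1,
             "val_fraction must be in (0,1)")
  structure(list(segment_len = as.integer(segment_len),
                 batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Cut a sequence into contiguous non-overlapping segments
#'
#' The trailing remainder shorter than `segment_len` is dropped
#' (2460 training steps at 262-step segments give 9 segments, 102 steps
#' dropped). Segmentation acts as data augmentation: each segment is an
#' independent training example with hidden state reset at its start.
#'
#' @param n_steps sequence length (or a `multimodal_sequence`).
#' @param segment_len steps per segment.
#' @return integer matrix with columns `from`, `to` (1-based, inclusive).
#' @export
segment_sequences <- function(n_steps, segment_len) {
  if (inherits(n_steps, "multimodal_sequence")) n_steps <- nrow(n_steps$sensory)
  n_steps <- as.integer(n_steps)
  segment_len <- as.integer(segment_len)
  stop_ifnot(n_steps >= segment_len,
             "sequence (%d steps) shorter than segment_len %d",
             n_steps, segment_len)
  k <- n_steps %/% segment_len
  from <- (seq_len(k) - 1L) * segment_len + 1L
  cbind(from = from, to = from + as.integer(segment_len) - 1L)
}

# stable BCE from logits: max(z,0) - z*a + log(1+exp(-|z|))
bce_from_logits <- function(logit, target) {
  pmax(logit, 0) - logit * target + log1p(exp(-abs(logit)))
}

#' Combined action/BOLD loss
#'
#' @param pred a `rollout_result` (or list with `action_logit`/
#'   `action_prob` and `bold_pred`).
#' @param target_action matrix of 0/1 press targets, same shape as the
#'   predicted action channel.
#' @param target_bold matrix of (normalized) BOLD targets.
#' @param cfg a [loss_config()].
#' @return list with `total`, `action`, `bold`.
#' @export
combined_loss <- function(pred, target_action, target_bold,
                          cfg = loss_config()) {
  stop_ifnot(all(target_action %in% c(0, 1)),
             "action targets must be 0/1")
  stop_ifnot(all(dim(target_action) == dim(pred$action_prob)) &&
               all(dim(target_bold) == dim(pred$bold_pred)),
             "prediction/target shape mismatch")
  l_act <- if (!is.null(pred$action_logit)) {
    mean(bce_from_logits(pred$action_logit, target_action))
  } else {
    p <- pmin(pmax(pred$action_prob, 1e-12), 1 - 1e-12)
    mean(-target_action * log(p) - (1 - target_action) * log1p(-p))
  }
  l_bold <- mean((pred$bold_pred - target_bold)^2)
  l_act <- cfg$lambda_action * l_act
  l_bold <- cfg$lambda_bold * l_bold
  list(total = l_act + l_bold, action = l_act, bold = l_bold)
}

# ---- dataset preparation -------------------------------------------------

#' Assemble training/validation/test tensors from a cohort
#'
#' Applies the temporal split (train half / test half), fits the BOLD
#' normalization on the pooled training halves of all participants and
#' applies it to both halves, then cuts the training half into segments.
#' One-step prediction alignment: inputs at steps `1..T-1` are paired
#' with targets at steps `2..T`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param train_duration_s length of the training half (s).
#' @param segment_len training segment length in steps.
#' @param val_fraction fraction of each participant's segments (taken
#'   from the end of the training half) used for validation.
#' @return object of class `twin_dataset`.
#' @export
twin_dataset <- function(cohort, train_duration_s = 196.8,
                         segment_len = 262L, val_fraction = 0.1) {
  tasks <- cohort$tasks
  halves <- lapply(cohort$sessions, function(sess) {
    lapply(sess, temporal_split, train_duration_s = train_duration_s)
  })
  train_bold <- unlist(lapply(halves, function(h) {
    lapply(h, function(x) t(x$train$bold))
  }), recursive = FALSE)
  stats <- fit_normalization(train_bold)
  n_half <- floor(train_duration_s / cohort$sessions[[1]][[1]]$step_s + 1e-9)
  prep_half <- function(half) {
    X <- cbind(half$sensory, half$condition)
    B <- t(apply_normalization(t(half$bold), stats))
    list(X = X, A = half$action, B = B, events = half$events,
         offset_s = half$offset_s, task = half$task, step_s = half$step_s)
  }
  participants <- lapply(seq_along(cohort$sessions), function(p) {
    per_task <- lapply(tasks, function(task) {
      h <- halves[[p]][[task]]
      list(train = prep_half(h$train), test = prep_half(h$test))
    })
    names(per_task) <- tasks
    list(x = cohort$rsfcm[[p]]$edges, tasks = per_task)
  })
  # segment index over the training half (same for everyone: equal lengths)
  segs <- segment_sequences(n_half - 1L, segment_len)
  n_val <- max(1L, ceiling(val_fraction * nrow(segs)))
  stop_ifnot(nrow(segs) > n_val,
             "not enough segments (%d) for validation fraction %.2f",
             nrow(segs), val_fraction)
  structure(list(participants = participants, tasks = tasks,
                 norm_stats = stats, segments = segs,
                 val_idx = (nrow(segs) - n_val + 1L):nrow(segs),
                 train_idx = seq_len(nrow(segs) - n_val),
                 segment_len = as.integer(segment_len),
                 n_half = n_half,
                 region_labels = cohort$region_labels,
                 step_s = cohort$sessions[[1]][[1]]$step_s),
            class = "twin_dataset")
}

# build input/target arrays [dims, n_seg, T] for a set of segments of one
# participant-task training half, with the one-step target shift.
seg_arrays <- function(half, segs) {
  Tn <- segs[1, "to"] - segs[1, "from"] + 1L
  S <- nrow(segs)
  X <- array(0, dim = c(ncol(half$X), S, Tn))
  A <- array(0, dim = c(ncol(half$A), S, Tn))
  B <- array(0, dim = c(ncol(half$B), S, Tn))
  for (s in seq_len(S)) {
    idx <- segs[s, "from"]:segs[s, "to"]
    X[, s, ] <- t(half$X[idx, , drop = FALSE])
    A[, s, ] <- t(half$A[idx + 1L, , drop = FALSE])
    B[, s, ] <- t(half$B[idx + 1L, , drop = FALSE])
  }
  # flat time-major-block matrices [dims, S*T] for the fast batched path
  list(X = matrix(X, dim(X)[1]), A = matrix(A, dim(A)[1]),
       B = matrix(B, dim(B)[1]), S = S, Tn = Tn)
}

# pool the per-task segment arrays of one participant into a single batch
pool_arrays <- function(arr_list) {
  Tn <- arr_list[[1]]$Tn
  stop_ifnot(all(vapply(arr_list, function(a) a$Tn, 0) == Tn),
             "segment lengths differ across tasks")
  Ss <- vapply(arr_list, function(a) a$S, 0)
  S <- sum(Ss)
  bind <- function(field, d) {
    out <- matrix(0, d, S * Tn)
    for (t in seq_len(Tn)) {
      cols <- ((t - 1L) * S + 1L):(t * S)
      pieces <- lapply(arr_list, function(a) {
        a[[field]][, ((t - 1L) * a$S + 1L):(t * a$S), drop = FALSE]
      })
      out[, cols] <- do.call(cbind, pieces)
    }
    out
  }
  list(X = bind("X", nrow(arr_list[[1]]$X)),
       A = bind("A", nrow(arr_list[[1]]$A)),
       B = bind("B", nrow(arr_list[[1]]$B)), S = S, Tn = Tn)
}

# forward + loss (+ optional gradient wrt packed params) for one
# participant over prepared arrays; losses are sums plus element counts so
# the caller can normalize across tasks.
participant_pass <- function(views, arrs, cfg, loss_cfg, want_grad = TRUE) {
  na <- cfg$n_action
  fwd <- rnn_fwd_batch(views, arrs$X, S = arrs$S, Tn = arrs$Tn)
  Y <- fwd$Y
  if (any(!is.finite(Y))) stop("non-finite rollout output", call. = FALSE)
  zl <- Y[seq_len(na), , drop = FALSE]
  bp <- Y[na + seq_len(cfg$n_bold), , drop = FALSE]
  sum_bce <- sum(bce_from_logits(zl, arrs$A))
  sum_se <- sum((bp - arrs$B)^2)
  out <- list(sum_bce = sum_bce, n_act = length(zl),
              sum_se = sum_se, n_bold = length(bp))
  if (want_grad) {
    gY <- matrix(0, nrow(Y), ncol(Y))
    gY[seq_len(na), ] <- loss_cfg$lambda_action *
      (sigmoid(zl) - arrs$A) / length(zl)
    gY[na + seq_len(cfg$n_bold), ] <- loss_cfg$lambda_bold *
      2 * (bp - arrs$B) / length(bp)
    out$gpacked <- rnn_bwd_batch(views, arrs$X, fwd, gY, cfg)
  }
  out
}

adam_init <- function(hp) {
  list(m = lapply(hp[names(hp)], function(x) x * 0),
       v = lapply(hp[names(hp)], function(x) x * 0), t = 0L)
}

adam_step <- function(hp, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    hp[[nm]] <- hp[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(hp = hp, state = state)
}

# pooled per-participant arrays (all tasks) for a set of segment rows
build_arr_cache <- function(dataset, seg_idx) {
  segs <- dataset$segments[seg_idx, , drop = FALSE]
  lapply(dataset$participants, function(part) {
    pool_arrays(lapply(dataset$tasks,
                       function(task) seg_arrays(part$tasks[[task]]$train, segs)))
  })
}

# evaluate mean loss of the hypernetwork on cached arrays (no dropout)
dataset_loss <- function(hp, dataset, cfg, loss_cfg,
                         seg_idx = NULL, cache = NULL) {
  if (is.null(cache)) cache <- build_arr_cache(dataset, seg_idx)
  tot_bce <- 0; n_act <- 0; tot_se <- 0; n_bold <- 0
  for (p in seq_along(dataset$participants)) {
    views <- hypernet_forward(dataset$participants[[p]]$x, hp)
    pp <- participant_pass(views, cache[[p]], cfg, loss_cfg,
                           want_grad = FALSE)
    tot_bce <- tot_bce + pp$sum_bce; n_act <- n_act + pp$n_act
    tot_se <- tot_se + pp$sum_se; n_bold <- n_bold + pp$n_bold
  }
  l_act <- loss_cfg$lambda_action * tot_bce / n_act
  l_bold <- loss_cfg$lambda_bold * tot_se / n_bold
  list(total = l_act + l_bold, action = l_act, bold = l_bold)
}

#' Train the hypernetwork end to end through the main network
#'
#' Adam optimization of the hypernetwork parameters; gradients flow
#' through the unrolled main network (backpropagation through time) and
#' the parameter packing into the hypernetwork. Batches are sets of
#' participants; each participant contributes all of their training
#' segments (both tasks) to each epoch. Hidden state is reset at every
#' segment boundary. Early stopping monitors the validation segments
#' (the tail of each participant's training half) with dropout disabled.
#'
#' @param dataset a [twin_dataset()].
#' @param cfg a [twin_config()] whose `n_in` matches the connectome
#'   length and `n_bold` the region count.
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @param init optional initial `hypernet_params` (default fresh
#'   initialization from `train_cfg$seed`).
#' @param verbose print per-epoch losses.
#' @return list with `hp` (trained parameters, best validation epoch),
#'   `log` (per-epoch data frame), `stopped_epoch`, `wall_time_s`.
#' @export
train_twin <- function(dataset, cfg, loss_cfg = loss_config(),
                       train_cfg = train_config(), init = NULL,
                       verbose = FALSE) {
  t0 <- Sys.time()
  stop_ifnot(length(dataset$participants) >= 1, "empty dataset")
  hp <- init %||% init_hypernet(cfg, seed = train_cfg$seed)
  state <- adam_init(hp)
  n_part <- length(dataset$participants)
  log <- vector("list", train_cfg$max_epochs)
  best_val <- Inf; best_hp <- hp; best_epoch <- 0L; wait <- 0L
  rng_counter <- 0L
  # precompute pooled per-participant arrays once (train and validation)
  arr_cache <- build_arr_cache(dataset, dataset$train_idx)
  val_cache <- build_arr_cache(dataset, dataset$val_idx)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    order_p <- with_seed(derive_seed(train_cfg$seed, 50000L + epoch),
                         sample.int(n_part))
    batches <- split(order_p, ceiling(seq_along(order_p) / train_cfg$batch_size))
    ep_bce <- 0; ep_act_n <- 0; ep_se <- 0; ep_bold_n <- 0
    err <- tryCatch({
    for (batch in batches) {
      grads <- NULL
      for (p in batch) {
        part <- dataset$participants[[p]]
        rng_counter <- rng_counter + 1L
        mask <- NULL
        if (cfg$dropout > 0) {
          mask <- with_seed(derive_seed(train_cfg$seed, rng_counter),
            (stats::runif(cfg$n_in) >= cfg$dropout) / (1 - cfg$dropout))
        }
        fwd <- hypernet_fwd(part$x, hp, mask)
        views <- unpack_main_params(fwd$y, cfg)
        pp <- participant_pass(views, arr_cache[[p]], cfg, loss_cfg)
        ep_bce <- ep_bce + pp$sum_bce; ep_act_n <- ep_act_n + pp$n_act
        ep_se <- ep_se + pp$sum_se; ep_bold_n <- ep_bold_n + pp$n_bold
        bwd <- hypernet_bwd(fwd, hp, pp$gpacked / length(batch))
        if (is.null(grads)) grads <- bwd$grads
        else for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + bwd$grads[[nm]]
      }
      upd <- adam_step(hp, grads, state, train_cfg$lr)
      hp <- upd$hp; state <- upd$state
    }
    NULL
    }, error = function(e) e)
    if (!is.null(err)) {
      stop(sprintf("training aborted at epoch %d: %s", epoch,
                   conditionMessage(err)), call. = FALSE)
    }
    train_action <- loss_cfg$lambda_action * ep_bce / ep_act_n
    train_bold <- loss_cfg$lambda_bold * ep_se / ep_bold_n
    if (!is.finite(train_action + train_bold)) {
      stop(sprintf("divergent (non-finite) loss at epoch %d", epoch),
           call. = FALSE)
    }
    val <- tryCatch(dataset_loss(hp, dataset, cfg, loss_cfg, cache = val_cache),
                    error = function(e) {
      stop(sprintf("training aborted at epoch %d: %s", epoch,
                   conditionMessage(e)), call. = FALSE)
    })
    log[[epoch]] <- data.frame(epoch = epoch,
                               train_total = train_action + train_bold,
                               train_action = train_action,
                               train_bold = train_bold,
                               val_total = val$total,
                               val_action = val$action,
                               val_bold = val$bold)
    if (verbose) {
      message(sprintf("epoch %4d train %.5f val %.5f", epoch,
                      train_action + train_bold, val$total))
    }
    if (val$total < best_val - 1e-9) {
      best_val <- val$total; best_hp <- hp; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$early_stop_patience) break
    }
  }
  attr(best_hp, "config") <- cfg
  list(hp = best_hp,
       log = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
       stopped_epoch = best_epoch,
       wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

# roll the main network over a prepared half and return predictions
# re-aligned to absolute time: row t is the prediction FOR step t
# (the model emits it at t-1; step 1 has no prediction and stays at the
# channel's resting value).
predict_half <- function(views, half, cfg) {
  ro <- rnn_rollout(views, half$X, cfg)
  Tn <- nrow(half$X)
  act <- rbind(matrix(0, 1, cfg$n_action),
               ro$action_prob[-Tn, , drop = FALSE])
  bold <- rbind(matrix(0, 1, cfg$n_bold), ro$bold_pred[-Tn, , drop = FALSE])
  list(action_prob = act, bold_pred = bold, rollout = ro)
}

# shift events of a half into half-local time
local_events <- function(half) {
  ev <- half$events
  if (is.null(ev) || !nrow(ev)) return(ev)
  for (cc in c("onset_s", "stim_onset_s", "response_onset_s")) {
    ev[[cc]] <- ev[[cc]] - half$offset_s
  }
  ev
}

#' Evaluate a trained twin on the held-out halves
#'
#' Rolls out each participant's generated main network on the test (or
#' train) half, decodes choices and reaction times from the predicted
#' action probabilities, and compares them with the observed behavior.
#'
#' @param hp trained `hypernet_params`.
#' @param dataset a [twin_dataset()].
#' @param cfg the [twin_config()] used in training.
#' @param split `"test"` or `"train"`.
#' @param threshold action detection threshold.
#' @return list with `per_participant` (data frame: concordance, mean
#'   predicted/observed RT per task), `bold_means` (long data frame of
#'   per participant/region/task observed and predicted BOLD means),
#'   `rt_cor` (per task and pooled), `bold_cor`, `concordance` (per-task
#'   means), `predictions` (per participant, per task `predict_half()`
#'   output).
#' @export
evaluate_twin <- function(hp, dataset, cfg, split = c("test", "train"),
                          threshold = 0.5) {
  split <- match.arg(split)
  tasks <- dataset$tasks
  rows <- list(); bold_rows <- list(); preds <- list()
  for (p in seq_along(dataset$participants)) {
    part <- dataset$participants[[p]]
    views <- hypernet_forward(part$x, hp)
    preds[[p]] <- list()
    for (task in tasks) {
      half <- part$tasks[[task]][[split]]
      pr <- predict_half(views, half, cfg)
      preds[[p]][[task]] <- pr
      ev <- local_events(half)
      obs_choice <- ev$response_choice
      pred_choice <- decode_choices(pr$action_prob, ev, task,
                                    half$step_s, threshold)
      rt <- extract_reaction_times(pr$action_prob, ev, half$step_s, threshold)
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, task = task,
        concordance = concordance_rate(pred_choice, obs_choice),
        pred_rt_ms = mean(rt$rt_ms, na.rm = TRUE),
        obs_rt_ms = mean(ev$response_time_s, na.rm = TRUE) * 1000,
        n_trials = nrow(ev), n_rt_excluded = rt$n_excluded)
      bold_rows[[length(bold_rows) + 1]] <- data.frame(
        participant = p, task = task, region = dataset$region_labels,
        obs_mean = colMeans(half$B), pred_mean = colMeans(pr$bold_pred))
    }
  }
  per <- do.call(rbind, rows)
  bold_means <- do.call(rbind, bold_rows)
  rt_cor <- vapply(tasks, function(task) {
    d <- per[per$task == task & is.finite(per$pred_rt_ms), ]
    if (nrow(d) < 3) return(NA_real_)
    stats::cor(d$pred_rt_ms, d$obs_rt_ms)
  }, 0)
  # pooled correlation: participants with a detected mean RT in every
  # task (unweighted mean of task means; mixing partial coverage would
  # conflate between-task offsets with between-participant differences)
  ok <- per[is.finite(per$pred_rt_ms), , drop = FALSE]
  pooled_cor <- NA_real_
  full <- names(which(table(ok$participant) == length(tasks)))
  if (length(full) >= 3) {
    pooled <- stats::aggregate(cbind(pred_rt_ms, obs_rt_ms) ~ participant,
                               data = ok[ok$participant %in% full, ],
                               FUN = mean)
    pooled_cor <- stats::cor(pooled$pred_rt_ms, pooled$obs_rt_ms)
  }
  rt_cor <- c(rt_cor, pooled = pooled_cor)
  list(per_participant = per, bold_means = bold_means,
       rt_cor = rt_cor,
       bold_cor = stats::cor(bold_means$obs_mean, bold_means$pred_mean),
       concordance = tapply(per$concordance, per$task, mean),
       predictions = preds)
}
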