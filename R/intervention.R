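#' SmoothGrad configuration
#'
#' @param n_samples noisy samples to average (reference default 100).
#' @param noise_level noise SD as a fraction of the SD of the input
#'   connectome vector (reference default 0.1).
#' @param seed seed for the noise draws.
#' @return list of class `smoothgrad_config`.
#' @export
smoothgrad_config <- function(n_samples = 100L, noise_level = 0.1,
                              seed = 1L) {
  stop_ifnot(n_samples >= 1, "n_samples must be >= 1")
  stop_ifnot(noise_level >= 0, "noise_level must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "smoothgrad_config")
}

# gradient of z1 = <(y - mu)/sigma, v> with respect to the input x
z1_input_grad <- function(x, hp, pls) {
  fwd <- hypernet_fwd(x, hp, NULL)
  gy <- ifelse(pls$v == 0, 0, pls$v / pls$col_sd)
  hypernet_bwd(fwd, hp, gy)$gx
}

#' SmoothGrad attribution of connectome edges for a latent direction
#'
#' Averages, over `n_samples` noise-perturbed copies of the participant's
#' rsFCM vector, the gradient of the first latent score
#' `z1 = <standardized hypernetwork output, v>` with respect to the
#' input. Noise is Gaussian with SD `noise_level * SD(x)` where `SD(x)`
#' is taken over all edges of the participant's connectome. Dropout is
#' disabled; the stored training-cohort standardization statistics of the
#' PLS result are used.
#'
#' @param hp trained `hypernet_params`.
#' @param x rsFCM edge vector (or `rsfcm` object).
#' @param pls a [pls_direction()] result.
#' @param cfg a [smoothgrad_config()].
#' @return object of class `gradient_map`: `gradient` (per edge),
#'   `n_samples`, `noise_sd`, `averaged` flag.
#' @export
smoothgrad_edges <- function(hp, x, pls, cfg = smoothgrad_config()) {
  if (inherits(x, "rsfcm")) x <- x$edges
  stop_ifnot(!is.null(pls$col_sd), "PLS result lacks standardization stats")
  noise_sd <- cfg$noise_level * stats::sd(x)
  g <- numeric(length(x))
  with_seed(cfg$seed, {
    for (k in seq_len(cfg$n_samples)) {
      xt <- if (noise_sd > 0) x + stats::rnorm(length(x), sd = noise_sd) else x
      g <- g + z1_input_grad(xt, hp, pls)
    }
  })
  structure(list(gradient = g / cfg$n_samples, n_samples = cfg$n_samples,
                 noise_sd = noise_sd, averaged = FALSE),
            class = "gradient_map")
}

#' Cohort-averaged SmoothGrad map
#'
#' @param hp trained `hypernet_params`.
#' @param xs list of rsFCM vectors (or a `twin_dataset`).
#' @param pls a [pls_direction()] result.
#' @param cfg a [smoothgrad_config()].
#' @return a `gradient_map` with `averaged = TRUE`.
#' @export
smoothgrad_cohort <- function(hp, xs, pls, cfg = smoothgrad_config()) {
  if (inherits(xs, "twin_dataset")) {
    xs <- lapply(xs$participants, function(p) p$x)
  }
  maps <- lapply(seq_along(xs), function(i) {
    ci <- cfg; ci$seed <- derive_seed(cfg$seed, i)
    smoothgrad_edges(hp, xs[[i]], pls, ci)$gradient
  })
  structure(list(gradient = Reduce(`+`, maps) / length(maps),
                 n_samples = cfg$n_samples, noise_sd = NA_real_,
                 averaged = TRUE),
            class = "gradient_map")
}

#' Select edges whose attribution deviates strongly from the mean
#'
#' Edges with `|g - mean(g)| > sd_threshold * SD(g)` (2.5 SD in the
#' reference display), split into strengthen (positive gradient) and
#' weaken (negative gradient) lists with magnitudes in SD units.
#'
#' @param map a `gradient_map`.
#' @param sd_threshold threshold in SD units.
#' @param edge_index optional 2-column region-pair matrix for labeling.
#' @param region_labels optional region names.
#' @return data frame with `edge`, `i`, `j`, `direction`, `sd_units`.
#' @export
select_top_edges <- function(map, sd_threshold = 2.5, edge_index = NULL,
                             region_labels = NULL) {
  g <- map$gradient
  stop_ifnot(all(is.finite(g)), "gradient map contains non-finite values")
  mu <- mean(g); sdev <- stats::sd(g)
  if (sdev == 0) dev <- rep(0, length(g)) else dev <- (g - mu) / sdev
  sel <- which(abs(dev) > sd_threshold)
  out <- data.frame(
    edge = sel,
    i = if (is.null(edge_index)) rep(NA_integer_, length(sel))
        else edge_index[sel, 1],
    j = if (is.null(edge_index)) rep(NA_integer_, length(sel))
        else edge_index[sel, 2],
    direction = ifelse(g[sel] > mu, "strengthen", "weaken"),
    sd_units = abs(dev[sel]))
  if (!is.null(region_labels) && !is.null(edge_index)) {
    out$region_i <- region_labels[out$i]
    out$region_j <- region_labels[out$j]
  }
  out[order(-out$sd_units), , drop = FALSE]
}

#' Intervention specification
#'
#' The manipulation adds `alpha * v_raw` to the packed main-network
#' parameters, where `v_raw` is the PLS direction mapped back from
#' standardized-parameter space to raw units (elementwise multiplication
#' by the stored column SDs, renormalized to unit length) and `alpha`
#' defaults to twice the SD of the latent score `z1`.
#'
#' @param pls a [pls_direction()] result.
#' @param alpha manipulation intensity; default `2 * sd(z1)`.
#' @return list of class `intervention_spec`.
#' @export
intervention_spec <- function(pls, alpha = NULL) {
  if (is.null(alpha)) alpha <- 2 * stats::sd(pls$z1)
  stop_ifnot(is.finite(alpha), "alpha must be finite")
  v_raw <- pls$v * pls$col_sd
  nrm <- sqrt(sum(v_raw^2))
  stop_ifnot(nrm > 0, "degenerate de-standardized direction")
  structure(list(v_raw = v_raw / nrm, alpha = alpha, kind = pls$kind,
                 layout_hash = pls$layout_hash),
            class = "intervention_spec")
}

#' Perturb main-network weights along an intervention direction
#'
#' @param params a `main_net_params` object.
#' @param spec an [intervention_spec()].
#' @param cfg the [twin_config()] (for re-unpacking the views).
#' @return perturbed `main_net_params`.
#' @export
perturb_weights <- function(params, spec, cfg) {
  lay <- main_param_layout(cfg)
  if (!is.null(spec$layout_hash)) {
    stop_ifnot(identical(spec$layout_hash, lay$hash),
               "layout hash mismatch: intervention vector was computed under a different packing")
  }
  stop_ifnot(length(spec$v_raw) == length(params$packed),
             "direction length %d != parameter count %d",
             length(spec$v_raw), length(params$packed))
  unpack_main_params(params$packed + spec$alpha * spec$v_raw, cfg)
}

#' Simulate an intervention on every participant
#'
#' Rolls out each participant's main network on the chosen split with the
#' original and the perturbed parameters (identical sensory inputs),
#' computing both functional indicators before and after manipulation.
#'
#' @param hp trained `hypernet_params`.
#' @param dataset a [twin_dataset()].
#' @param cfg the [twin_config()].
#' @param spec an [intervention_spec()].
#' @param split `"test"` or `"train"` half.
#' @param threshold press detection threshold.
#' @return data frame, one row per participant: pre/post affective
#'   (right-amygdala t) and cognitive (mean RT ms, `NA` when no press was
#'   detected) indicators.
#' @export
simulate_intervention <- function(hp, dataset, cfg, spec,
                                  split = "test", threshold = 0.5) {
  tasks <- dataset$tasks
  amyg <- match("amygdala_R", dataset$region_labels)
  out <- vector("list", length(dataset$participants))
  for (p in seq_along(dataset$participants)) {
    part <- dataset$participants[[p]]
    base <- hypernet_forward(part$x, hp)
    pert <- perturb_weights(base, spec, cfg)
    row <- list(participant = p)
    for (lab in c("pre", "post")) {
      views <- if (lab == "pre") base else pert
      rts <- c(); aff <- NA_real_
      for (task in tasks) {
        half <- part$tasks[[task]][[split]]
        pr <- predict_half(views, half, cfg)
        ev <- local_events(half)
        rt <- extract_reaction_times(pr$action_prob, ev, half$step_s,
                                     threshold)
        rts <- c(rts, mean(rt$rt_ms, na.rm = TRUE))
        if (task == "emotional_faces" && !is.na(amyg)) {
          design <- build_design(ev, nrow(pr$bold_pred), half$step_s)
          aff <- fit_glm(design, pr$bold_pred[, amyg])$t_by_contrast[["face>shape"]]
        }
      }
      row[[paste0(lab, "_affective")]] <- aff
      row[[paste0(lab, "_cognitive")]] <-
        if (any(is.finite(rts))) mean(rts[is.finite(rts)]) else NA_real_
    }
    out[[p]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}

#' Standardized intervention effect sizes
#'
#' `d_i = (pre_i - post_i) / SD(pre)`, the SD taken across participants;
#' positive values mean the indicator decreased (weaker amygdala
#' response, shorter reaction time). Benchmarked against Cohen's d = 0.8.
#'
#' @param pre,post per-participant indicator values; pairs with a missing
#'   value are excluded and counted.
#' @param benchmark large-effect threshold.
#' @return list with `d` (per participant, NA where excluded),
#'   `frac_large`, `n_excluded`, `sd_pre`.
#' @export
effect_sizes <- function(pre, post, benchmark = 0.8) {
  ok <- is.finite(pre) & is.finite(post)
  stop_ifnot(sum(ok) >= 2, "need >= 2 complete participant pairs")
  sd_pre <- stats::sd(pre[ok])
  stop_ifnot(sd_pre > 0, "constant premanipulation values")
  d <- rep(NA_real_, length(pre))
  d[ok] <- (pre[ok] - post[ok]) / sd_pre
  list(d = d, frac_large = mean(d[ok] > benchmark),
       n_excluded = sum(!ok), sd_pre = sd_pre)
}
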