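#' Per-participant affective indicator: right-amygdala contrast t
#'
#' Fits the GLM (Glover HRF + temporal derivative + DCT drift + constant)
#' to each participant's predicted right-amygdala BOLD during the
#' Emotional Faces task and returns the `face>shape` t-statistic, the
#' model's read-out of negative affective response strength.
#'
#' @param bold_list list of T x n_regions predicted BOLD matrices (one
#'   per participant, same time base).
#' @param events trial events covering the modeled window (local time).
#' @param region_labels region names; must contain `region`.
#' @param step_s sampling step (s).
#' @param region amygdala region label.
#' @param contrast contrast name.
#' @return object of class `functional_indicator` (numeric vector with
#'   `kind` attribute).
#' @export
affective_indicator <- function(bold_list, events, region_labels,
                                step_s = 0.08, region = "amygdala_R",
                                contrast = "face>shape") {
  stop_ifnot(region %in% region_labels,
             "region list does not contain %s", region)
  n_scans <- nrow(bold_list[[1]])
  design <- build_design(events, n_scans, step_s)
  ridx <- match(region, region_labels)
  vals <- vapply(bold_list, function(B) {
    fit_glm(design, B[, ridx])$t_by_contrast[[contrast]]
  }, 0)
  structure(vals, kind = "affective", class = "functional_indicator")
}

#' Per-participant cognitive indicator: mean reaction time (ms)
#'
#' Mean predicted reaction time, pooled over tasks as the unweighted mean
#' of per-task means.
#'
#' @param action_list per participant: named list of T x 3 predicted
#'   action probability matrices, one per task.
#' @param events_list named list of trial event tables, one per task
#'   (local time).
#' @param step_s sampling step (s).
#' @param threshold press detection threshold.
#' @return `functional_indicator` of mean RTs in ms (`NA` when a
#'   participant has no detected press in any task).
#' @export
cognitive_indicator <- function(action_list, events_list, step_s = 0.08,
                                threshold = 0.5) {
  vals <- vapply(action_list, function(acts) {
    task_means <- vapply(names(events_list), function(task) {
      rt <- extract_reaction_times(acts[[task]], events_list[[task]],
                                   step_s, threshold)
      mean(rt$rt_ms, na.rm = TRUE)
    }, 0)
    mean(task_means[is.finite(task_means)])
  }, 0)
  stop_ifnot(any(is.finite(vals)),
             "no participant produced a detectable press in any task")
  structure(vals, kind = "cognitive", class = "functional_indicator")
}

#' Partial-least-squares intervention direction over main-network parameters
#'
#' Standardizes the participant x parameter matrix `W` (columns) and the
#' indicator `s`, then computes the single-component direction
#' `v = W' s / ||W' s||` and the latent scores `z1 = W v` (standardized
#' `W`). Zero-variance parameter columns are dropped with a warning and
#' re-inserted as zeros in `v`. The standardization statistics and the
#' packing-layout hash travel with the result so that attribution and
#' intervention stay in a consistent coordinate system.
#'
#' @param W participants x n_params matrix (rows of packed main-network
#'   parameters; see [build_wmain()]).
#' @param s a `functional_indicator` or numeric vector, one value per row
#'   of `W`.
#' @param layout_hash layout identifier (from [main_param_layout()]);
#'   optional but required for [perturb_weights()].
#' @return object of class `pls_result`: `v` (unit vector), `z1`
#'   (per-participant scores), `col_mean`, `col_sd`, `s_mean`, `s_sd`,
#'   `kind`, `layout_hash`.
#' @export
pls_direction <- function(W, s, layout_hash = NULL) {
  W <- as.matrix(W)
  s <- as.numeric(s)
  stop_ifnot(nrow(W) >= 3, "need at least 3 participants")
  stop_ifnot(length(s) == nrow(W), "indicator length != participant count")
  s_sd <- stats::sd(s)
  stop_ifnot(is.finite(s_sd) && s_sd > 0, "constant functional indicator")
  col_mean <- colMeans(W)
  col_sd <- apply(W, 2, stats::sd)
  keep <- col_sd > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance parameter column(s)",
                    sum(!keep)))
  }
  Ws <- sweep(sweep(W[, keep, drop = FALSE], 2, col_mean[keep]), 2,
              col_sd[keep], "/")
  ss <- (s - mean(s)) / s_sd
  w <- drop(crossprod(Ws, ss))
  nrm <- sqrt(sum(w^2))
  stop_ifnot(nrm > 0, "degenerate direction: W's == 0")
  v <- numeric(ncol(W))
  v[keep] <- w / nrm
  z1 <- drop(Ws %*% v[keep])
  structure(list(v = v, z1 = z1, col_mean = col_mean, col_sd = col_sd,
                 s_mean = mean(s), s_sd = s_sd,
                 kind = attr(s, "kind") %||% "custom",
                 layout_hash = layout_hash),
            class = "pls_result")
}

#' Stack per-participant packed main-network parameters
#'
#' @param hp trained `hypernet_params`.
#' @param dataset a [twin_dataset()] (or list with per-participant `x`).
#' @return participants x n_params matrix.
#' @export
build_wmain <- function(hp, dataset) {
  parts <- if (inherits(dataset, "twin_dataset")) dataset$participants
           else dataset
  t(vapply(parts, function(part) hypernet_forward(part$x, hp)$packed,
           numeric(count_main_params(attr(hp, "config")))))
}

#' Pearson correlations of latent scores with external measures, FDR-adjusted
#'
#' Pairwise-complete Pearson correlation and two-sided p-value of `z1`
#' against every column of `measures`, with Benjamini-Hochberg adjustment
#' across the measures.
#'
#' @param z1 numeric latent scores (one per participant).
#' @param measures participants x m data frame/matrix (may contain NA).
#' @param min_pairs minimum complete pairs per measure.
#' @return data frame with `measure`, `n`, `r`, `p`, `p_adjusted`,
#'   ordered as given.
#' @export
correlate_with_measures <- function(z1, measures, min_pairs = 3L) {
  measures <- as.data.frame(measures)
  res <- lapply(names(measures), function(nm) {
    y <- as.numeric(measures[[nm]])
    ok <- is.finite(z1) & is.finite(y)
    stop_ifnot(sum(ok) >= min_pairs,
               "measure '%s' has fewer than %d complete pairs", nm, min_pairs)
    ct <- stats::cor.test(z1[ok], y[ok])
    data.frame(measure = nm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out
}
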