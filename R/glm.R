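#' Glover canonical hemodynamic response function
#'
#' Difference of two gamma densities with the conventional published
#' parameters (response peak 6 s, undershoot peak 12 s, dispersions 0.9 s,
#' undershoot ratio 0.35), sampled on `grid_s` and peak-normalized to 1.
#'
#' @param grid_s time grid in seconds starting at 0, uniform spacing.
#' @param peak_delay,under_delay gamma peak locations (s).
#' @param peak_disp,under_disp gamma dispersions (s).
#' @param ratio undershoot ratio.
#' @return numeric kernel, same length as `grid_s`, max value 1.
#' @export
#' @examples
#' k <- glover_hrf(seq(0, 32, by = 0.1))
#' k[1]                       # 0 at t = 0
#' seq(0, 32, by = 0.1)[which.max(k)]  # peak near 5-6 s
glover_hrf <- function(grid_s, peak_delay = 6, under_delay = 12,
                       peak_disp = 0.9, under_disp = 0.9, ratio = 0.35) {
  stop_ifnot(length(grid_s) > 0, "glover_hrf: empty time grid")
  stop_ifnot(abs(grid_s[1]) < 1e-12, "glover_hrf: grid must start at 0")
  k <- stats::dgamma(grid_s, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(grid_s, shape = under_delay / under_disp,
                          scale = under_disp)
  k / max(k)
}

# boxcar regressor convolved with a kernel, truncated to n_scans
convolve_boxcar <- function(onsets_s, durations_s, n_scans, step_s, kernel) {
  box <- numeric(n_scans)
  for (i in seq_along(onsets_s)) {
    a <- floor(onsets_s[i] / step_s) + 1
    b <- min(n_scans, floor((onsets_s[i] + durations_s[i]) / step_s))
    if (a <= n_scans && b >= a) box[a:b] <- box[a:b] + 1
  }
  full <- stats::convolve(box, rev(kernel), type = "open")
  full[seq_len(n_scans)]
}

# DCT-II drift basis: K columns, k = 1..K over n points
dct_basis <- function(n, K) {
  if (K <= 0) return(matrix(0, n, 0))
  sapply(seq_len(K), function(k) cos(pi * k * (seq_len(n) - 0.5) / n))
}

#' Build a GLM design matrix for a task run
#'
#' Per condition: a boxcar at trial stimulus onsets (duration = stimulus
#' window) convolved with the Glover HRF, plus the same boxcar convolved
#' with the HRF's first temporal derivative. Low-frequency drift is modeled
#' by `K = floor(2 * duration_s * dct_cutoff_hz)` discrete-cosine basis
#' functions (8 at ~400 s and 0.01 Hz), plus a constant baseline column.
#' All columns except the constant are mean-centered.
#'
#' @param events trial events data frame (see [generate_schedule()]); must
#'   contain `stim_onset_s`, `stim_s` and `condition`.
#' @param n_scans number of time points in the modeled signal.
#' @param step_s sampling interval (s).
#' @param dct_cutoff_hz drift cutoff frequency (default 0.01 Hz).
#' @param conditions condition labels in contrast order; default the sorted
#'   unique conditions present.
#' @param hrf_args optional list of overrides passed to [glover_hrf()].
#' @return object of class `glm_design`: list with `X`, `column_names`,
#'   `contrasts` (named list of vectors), `step_s`.
#' @export
build_design <- function(events, n_scans, step_s, dct_cutoff_hz = 0.01,
                         conditions = NULL, hrf_args = list()) {
  stop_ifnot(n_scans >= 2, "n_scans must be >= 2")
  if (is.null(conditions)) conditions <- sort(unique(as.character(events$condition)))
  dur_s <- n_scans * step_s
  kernel_grid <- seq(0, 32, by = step_s)
  kernel <- do.call(glover_hrf, c(list(grid_s = kernel_grid), hrf_args))
  dkernel <- c(diff(kernel), 0) / step_s
  cols <- list()
  nms <- character(0)
  for (cond in conditions) {
    ev <- events[as.character(events$condition) == cond, , drop = FALSE]
    cols[[length(cols) + 1]] <- convolve_boxcar(ev$stim_onset_s, ev$stim_s,
                                                n_scans, step_s, kernel)
    nms <- c(nms, paste0(cond, "_hrf"))
    cols[[length(cols) + 1]] <- convolve_boxcar(ev$stim_onset_s, ev$stim_s,
                                                n_scans, step_s, dkernel)
    nms <- c(nms, paste0(cond, "_deriv"))
  }
  K <- floor(2 * dur_s * dct_cutoff_hz)
  dct <- dct_basis(n_scans, K)
  if (K > 0) {
    for (k in seq_len(K)) cols[[length(cols) + 1]] <- dct[, k]
    nms <- c(nms, paste0("dct_", seq_len(K)))
  }
  X <- do.call(cbind, c(cols, list(rep(1, n_scans))))
  nms <- c(nms, "constant")
  colnames(X) <- nms
  keep <- nms == "constant"
  X[, !keep] <- sweep(X[, !keep, drop = FALSE], 2,
                      colMeans(X[, !keep, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- nms[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  contrasts <- list()
  if (length(conditions) == 2) {
    c12 <- numeric(ncol(X)); names(c12) <- nms
    c12[paste0(conditions[2], "_hrf")] <- 1
    c12[paste0(conditions[1], "_hrf")] <- -1
    contrasts[[paste0(conditions[2], ">", conditions[1])]] <- c12
    contrasts[[paste0(conditions[1], ">", conditions[2])]] <- -c12
  }
  structure(list(X = X, column_names = nms, contrasts = contrasts,
                 step_s = step_s),
            class = "glm_design")
}

#' Fit an ordinary-least-squares GLM to one region's signal
#'
#' @param design a `glm_design` (or a plain design matrix).
#' @param y numeric signal, length `nrow(X)`.
#' @param contrasts optional named list of contrast vectors; defaults to
#'   the design's contrasts.
#' @return object of class `glm_fit`: `beta`, `sigma2` (dof-corrected
#'   residual variance), `dof`, `t_by_contrast` (named; `Inf` flagged when
#'   the fit is exact).
#' @export
fit_glm <- function(design, y, contrasts = NULL) {
  X <- if (inherits(design, "glm_design")) design$X else as.matrix(design)
  if (is.null(contrasts) && inherits(design, "glm_design")) {
    contrasts <- design$contrasts
  }
  n <- nrow(X); p <- ncol(X)
  stop_ifnot(length(y) == n, "y length %d != %d rows of X", length(y), n)
  stop_ifnot(n > p, "need n_scans > p for residual dof")
  qrX <- qr(X)
  stop_ifnot(qrX$rank == p, "singular design matrix")
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  dof <- n - p
  sigma2 <- sum(res^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  t_by <- numeric(0)
  if (length(contrasts)) {
    t_by <- vapply(contrasts, function(cv) {
      se2 <- sigma2 * drop(t(cv) %*% XtXinv %*% cv)
      est <- sum(cv * beta)
      if (se2 <= .Machine$double.eps * max(1, est^2)) {
        # perfect fit: flag with signed infinity rather than dividing by ~0
        return(sign(est) * Inf)
      }
      est / sqrt(se2)
    }, 0)
  }
  structure(list(beta = beta, sigma2 = sigma2, dof = dof,
                 t_by_contrast = t_by),
            class = "glm_fit")
}

#' Contrast t-statistics across regions
#'
#' Fits the GLM independently per region (column of `bold`) and extracts
#' the named contrast's t-statistic. The default contrasts are
#' `face>shape` (Emotional Faces) and `incongruent>congruent` (Stroop).
#'
#' @param design a `glm_design`.
#' @param bold n_scans x n_regions matrix.
#' @param contrast contrast name present in the design.
#' @return named numeric vector, one t-statistic per region.
#' @export
contrast_tstats <- function(design, bold, contrast) {
  stop_ifnot(contrast %in% names(design$contrasts),
             "unknown contrast '%s' (available: %s)", contrast,
             paste(names(design$contrasts), collapse = ", "))
  bold <- as.matrix(bold)
  ts <- vapply(seq_len(ncol(bold)), function(j) {
    fit_glm(design, bold[, j])$t_by_contrast[[contrast]]
  }, 0)
  names(ts) <- colnames(bold)
  ts
}

#' Group-level one-sample t-test against zero
#'
#' @param values per-participant statistics (length >= 2, non-constant).
#' @return list with `t`, `p` (two-sided), `dof`, `mean`.
#' @export
group_ttest <- function(values) {
  values <- as.numeric(values)
  stop_ifnot(length(values) >= 2, "need at least 2 values")
  s <- stats::sd(values)
  stop_ifnot(s > 0, "zero variance across participants")
  n <- length(values)
  tval <- mean(values) / (s / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n - 1),
       dof = n - 1L, mean = mean(values))
}
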