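#' Construct a region-by-time series container
#'
#' @param values region x time numeric matrix.
#' @param step_s sampling interval in seconds.
#' @param region_labels character labels, one per row.
#' @return object of class `region_ts`.
#' @export
region_ts <- function(values, step_s, region_labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(region_labels)) {
    region_labels <- paste0("region_", seq_len(nrow(values)))
  }
  stop_ifnot(ncol(values) >= 2, "time axis must have length >= 2")
  stop_ifnot(!anyNA(values), "time series contains NA values")
  stop_ifnot(length(region_labels) == nrow(values),
             "need one label per region")
  structure(list(values = values, step_s = step_s,
                 region_labels = as.character(region_labels)),
            class = "region_ts")
}

# row-major upper-triangle (i < j, 0-based in exports) pair index
edge_index_pairs <- function(n) {
  do.call(rbind, lapply(seq_len(n - 1),
                        function(i) cbind(i = i, j = (i + 1):n)))
}

#' Resting-state functional connectivity vector (Fisher z)
#'
#' Pearson correlation per region pair, clipped to
#' `[-1 + clip_eps, 1 - clip_eps]` before the Fisher z-transform
#' (`atanh`), returned as the row-major upper triangle (i < j). For 446
#' regions this yields the canonical 99,235-element connectome vector.
#'
#' @param ts a [region_ts()] with >= 3 time points.
#' @param clip_eps clipping margin for degenerate correlations of +-1.
#' @return object of class `rsfcm`: list with `edges`, `n_regions`,
#'   `edge_index` (two-column matrix of 1-based region pairs),
#'   `region_labels`.
#' @export
compute_rsfcm <- function(ts, clip_eps = 1e-7) {
  stop_ifnot(inherits(ts, "region_ts"), "ts must be a region_ts")
  stop_ifnot(ncol(ts$values) >= 3, "need >= 3 time points")
  v <- apply(ts$values, 1, stats::var)
  if (any(v <= 0)) {
    stop(sprintf("zero-variance region(s): %s",
                 paste(ts$region_labels[v <= 0], collapse = ", ")),
         call. = FALSE)
  }
  R <- stats::cor(t(ts$values))
  R <- pmin(pmax(R, -1 + clip_eps), 1 - clip_eps)
  edges <- atanh(t(R)[lower.tri(R)])  # row-major upper triangle
  n <- nrow(ts$values)
  structure(list(edges = edges, n_regions = n,
                 edge_index = edge_index_pairs(n),
                 region_labels = ts$region_labels),
            class = "rsfcm")
}

#' Resample a region time series to a finer grid
#'
#' Interpolates each region's signal by an integer `factor` (10 for the
#' 0.8 s -> 0.08 s task-BOLD alignment), preserving values at the original
#' time points exactly; no extrapolation beyond the last sample, so the
#' new length is `(n - 1) * factor + 1`.
#'
#' @param ts a [region_ts()].
#' @param factor integer upsampling factor (>= 1).
#' @param method `"cubic"` (interpolating cubic spline, default) or
#'   `"linear"`.
#' @return a [region_ts()] with `step_s = ts$step_s / factor`.
#' @export
resample_series <- function(ts, factor, method = c("cubic", "linear")) {
  method <- match.arg(method)
  stop_ifnot(is.numeric(factor) && factor >= 1 && factor == round(factor),
             "factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(ts)
  n <- ncol(ts$values)
  t_old <- (seq_len(n) - 1) * ts$step_s
  t_new <- (seq_len((n - 1L) * factor + 1L) - 1) * ts$step_s / factor
  vals <- t(apply(ts$values, 1, function(yrow) {
    if (method == "cubic") {
      stats::spline(t_old, yrow, xout = t_new, method = "fmm")$y
    } else {
      stats::approx(t_old, yrow, xout = t_new)$y
    }
  }))
  region_ts(vals, ts$step_s / factor, ts$region_labels)
}

#' Fit per-region normalization statistics on a training pool
#'
#' Mean and SD per region across all participants and time steps of the
#' training data; the same statistics are then applied to test data.
#'
#' @param train list of [region_ts()] (or region x time matrices) sharing
#'   region order.
#' @return object of class `norm_stats`: `mean`, `sd` per region.
#' @export
fit_normalization <- function(train) {
  stop_ifnot(length(train) > 0, "training pool is empty")
  mats <- lapply(train, function(x) if (inherits(x, "region_ts")) x$values else as.matrix(x))
  pooled <- do.call(cbind, mats)
  m <- rowMeans(pooled)
  s <- apply(pooled, 1, stats::sd)
  if (any(s <= 0)) {
    stop(sprintf("zero-SD region at index %s",
                 paste(which(s <= 0), collapse = ", ")), call. = FALSE)
  }
  structure(list(mean = m, sd = s), class = "norm_stats")
}

#' Apply normalization statistics to a region time series
#'
#' @param ts a [region_ts()] or region x time matrix.
#' @param stats a [fit_normalization()] result.
#' @return same type as `ts`, z-scored per region with the training stats.
#' @export
apply_normalization <- function(ts, stats) {
  vals <- if (inherits(ts, "region_ts")) ts$values else as.matrix(ts)
  stop_ifnot(nrow(vals) == length(stats$mean),
             "region count mismatch: %d vs %d", nrow(vals), length(stats$mean))
  out <- (vals - stats$mean) / stats$sd
  if (inherits(ts, "region_ts")) region_ts(out, ts$step_s, ts$region_labels)
  else out
}

#' Serialize normalization statistics to JSON
#'
#' @param stats a [fit_normalization()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_norm_stats <- function(stats, path) {
  jsonlite::write_json(list(mean = stats$mean, sd = stats$sd), path,
                       digits = NA)
  invisible(path)
}

#' Read normalization statistics written by [write_norm_stats()]
#'
#' @param path JSON file.
#' @return a `norm_stats` object.
#' @export
read_norm_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(x$mean), sd = as.numeric(x$sd)),
            class = "norm_stats")
}

#' Split a multimodal sequence into contiguous train/test halves
#'
#' The first `train_duration_s` seconds become the training half and the
#' following `train_duration_s` seconds the test half (196.8 s each in the
#' reference setting). Each half keeps an absolute time offset
#' (`offset_s`) and the trial events whose stimulus onset falls inside it,
#' with onsets left in absolute time so they can be re-aligned.
#'
#' @param seq a `multimodal_sequence` (see [generate_cohort()]).
#' @param train_duration_s duration of the training half in seconds.
#' @return list with elements `train` and `test`, both
#'   `multimodal_sequence` objects.
#' @export
temporal_split <- function(seq, train_duration_s) {
  stop_ifnot(inherits(seq, "multimodal_sequence"),
             "seq must be a multimodal_sequence")
  n_half <- floor(train_duration_s / seq$step_s + 1e-9)
  stop_ifnot(n_half >= 1, "degenerate split: train duration < one step")
  Tn <- nrow(seq$sensory)
  stop_ifnot(Tn >= 2 * n_half,
             "sequence too short: %d steps, need >= %d", Tn, 2 * n_half)
  slice <- function(from, len, offset_s) {
    idx <- from:(from + len - 1)
    ev <- seq$events
    if (!is.null(ev) && nrow(ev)) {
      lo <- (from - 1) * seq$step_s
      hi <- lo + len * seq$step_s
      ev <- ev[ev$stim_onset_s >= lo & ev$stim_onset_s < hi, , drop = FALSE]
    }
    structure(list(sensory = seq$sensory[idx, , drop = FALSE],
                   condition = seq$condition[idx, , drop = FALSE],
                   action = seq$action[idx, , drop = FALSE],
                   bold = seq$bold[idx, , drop = FALSE],
                   step_s = seq$step_s, events = ev, task = seq$task,
                   region_labels = seq$region_labels,
                   offset_s = offset_s),
              class = "multimodal_sequence")
  }
  list(train = slice(1L, n_half, 0),
       test = slice(n_half + 1L, n_half, n_half * seq$step_s))
}
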