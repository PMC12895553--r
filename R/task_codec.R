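#' @name task_codec
#' @title Trial-event encoding and action decoding
#'
#' @description
#' Trials are rendered into the main network's channel layout at 80 ms
#' resolution: an 8-dimensional sensory channel, a constant 1-dimensional
#' task-condition channel (0 = Emotional Faces, 1 = Stroop) and a
#' 3-dimensional action channel. Dimension assignment (fixed here, since
#' only the roles are canonical):
#'
#' * Emotional Faces sensory: dims 1-2 cue indicators ("match faces" /
#'   "match shapes"); dims 3-8 the three probe positions (top, bottom
#'   left, bottom right) with 2 dims each. Face stimuli are 2-bit
#'   identity patterns whose bits are rendered as draws from U\[0, 0.1\]
#'   (bit 0) or U\[0.9, 1\] (bit 1); the matching probe duplicates the
#'   target's rendered pattern. Shape stimuli use exact 0/1 orientation
#'   codes. All six position dims are 0 when nothing is shown.
#' * Stroop sensory: dims 1-3 ink-color one-hot (red, green, blue), dims
#'   4-6 word-identity one-hot, dims 7-8 always 0.
#' * Action: Emotional Faces uses dims 1-2 (left/right press) with dim 3
#'   always 0; Stroop uses dims 1-3 (red/green/blue press). A press is a
#'   single active step at the response onset.
NULL

ef_buttons <- c("left", "right")
stroop_buttons <- c("red", "green", "blue")

# the four 2-bit identity patterns cycled over stimuli
ef_patterns <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))

step_of <- function(t_s, step_s) as.integer(floor(t_s / step_s + 1e-9)) + 1L

render_bits <- function(bits, face) {
  if (!face) return(as.numeric(bits))
  lo <- stats::runif(length(bits), 0, 0.1)
  hi <- stats::runif(length(bits), 0.9, 1.0)
  ifelse(bits == 1, hi, lo)
}

#' Encode Emotional Faces trials into sensory and action channels
#'
#' @param events trial events with responses (see [simulate_behavior()]).
#' @param n_steps total sequence length in steps.
#' @param step_s step size in seconds (0.08 in the reference setting).
#' @param seed seed for the face-value draws.
#' @param press_steps steps a button press stays active (default 3, i.e.
#'   240 ms; source data do not state press durations and a single 80 ms
#'   step starves the press-timing gradient at training time).
#' @return list with `sensory` (T x 8) and `action` (T x 3) matrices.
#' @export
encode_emotional_faces <- function(events, n_steps, step_s = 0.08, seed = 1L,
                                   press_steps = 3L) {
  sensory <- matrix(0, n_steps, 8)
  action <- matrix(0, n_steps, 3)
  if (!nrow(events)) return(list(sensory = sensory, action = action))
  stop_ifnot(all(events$condition %in% c("face", "shape")),
             "Emotional Faces events must use face/shape conditions")
  bad <- !is.na(events$response_choice) &
    !(events$response_choice %in% ef_buttons)
  stop_ifnot(!any(bad),
             "invalid response button for Emotional Faces: %s",
             paste(unique(events$response_choice[bad]), collapse = ", "))
  with_seed(seed, {
    for (k in seq_len(nrow(events))) {
      ev <- events[k, ]
      # cue period
      cue_a <- step_of(ev$onset_s, step_s)
      cue_b <- min(n_steps, step_of(ev$onset_s + ev$cue_s, step_s) - 1L)
      cue_dim <- if (ev$condition == "face") 1L else 2L
      if (cue_b >= cue_a && cue_a <= n_steps) sensory[cue_a:cue_b, cue_dim] <- 1
      # stimulus window: target top (dims 3-4), probes bottom left (5-6)
      # and bottom right (7-8); matching probe duplicates the target
      st_a <- step_of(ev$stim_onset_s, step_s)
      st_b <- min(n_steps, step_of(ev$stim_onset_s + ev$stim_s, step_s) - 1L)
      is_face <- ev$condition == "face"
      pat_target <- ef_patterns[(k - 1L) %% 4L + 1L, ]
      pat_foil <- ef_patterns[k %% 4L + 1L, ]
      target_vals <- render_bits(pat_target, is_face)
      foil_vals <- render_bits(pat_foil, is_face)
      left_vals <- if (ev$correct_choice == "left") target_vals else foil_vals
      right_vals <- if (ev$correct_choice == "right") target_vals else foil_vals
      if (st_b >= st_a && st_a <= n_steps) {
        rows <- st_a:st_b
        sensory[rows, 3:4] <- matrix(target_vals, length(rows), 2, byrow = TRUE)
        sensory[rows, 5:6] <- matrix(left_vals, length(rows), 2, byrow = TRUE)
        sensory[rows, 7:8] <- matrix(right_vals, length(rows), 2, byrow = TRUE)
      }
      if (!is.na(ev$response_choice)) {
        rs <- step_of(ev$response_onset_s, step_s)
        if (rs <= n_steps) {
          re <- min(n_steps, rs + press_steps - 1L)
          action[rs:re, match(ev$response_choice, ef_buttons)] <- 1
        }
      }
    }
  })
  list(sensory = sensory, action = action)
}

#' Encode Stroop trials into sensory and action channels
#'
#' @inheritParams encode_emotional_faces
#' @return list with `sensory` (T x 8) and `action` (T x 3) matrices.
#' @export
encode_stroop <- function(events, n_steps, step_s = 0.08, press_steps = 3L) {
  sensory <- matrix(0, n_steps, 8)
  action <- matrix(0, n_steps, 3)
  if (!nrow(events)) return(list(sensory = sensory, action = action))
  stop_ifnot(all(events$condition %in% c("congruent", "incongruent")),
             "Stroop events must use congruent/incongruent conditions")
  stop_ifnot(all(events$ink %in% stroop_buttons) &&
               all(events$word %in% stroop_buttons),
             "unknown ink or word color (must be red/green/blue)")
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    st_a <- step_of(ev$stim_onset_s, step_s)
    st_b <- min(n_steps, step_of(ev$stim_onset_s + ev$stim_s, step_s) - 1L)
    if (st_b >= st_a && st_a <= n_steps) {
      sensory[st_a:st_b, match(ev$ink, stroop_buttons)] <- 1
      sensory[st_a:st_b, 3L + match(ev$word, stroop_buttons)] <- 1
    }
    if (!is.na(ev$response_choice)) {
      stop_ifnot(ev$response_choice %in% stroop_buttons,
                 "unknown response color '%s'", ev$response_choice)
      rs <- step_of(ev$response_onset_s, step_s)
      if (rs <= n_steps) {
        re <- min(n_steps, rs + press_steps - 1L)
        action[rs:re, match(ev$response_choice, stroop_buttons)] <- 1
      }
    }
  }
  list(sensory = sensory, action = action)
}

#' Constant task-condition channel
#'
#' @param task `"emotional_faces"` (0) or `"stroop"` (1).
#' @param n_steps sequence length.
#' @return T x 1 matrix.
#' @export
encode_task_condition <- function(task, n_steps) {
  task <- match.arg(task, c("emotional_faces", "stroop"))
  matrix(if (task == "emotional_faces") 0 else 1, nrow = n_steps, ncol = 1)
}

task_button_labels <- function(task) {
  if (task == "stroop") stroop_buttons else c(ef_buttons, ".unused")
}

trial_windows <- function(events, n_steps, step_s) {
  on <- vapply(events$onset_s, step_of, 1L, step_s = step_s)
  nxt <- c(on[-1], n_steps + 1L)
  cbind(from = on, to = pmin(nxt - 1L, n_steps))
}

#' Decode per-trial button choices from predicted action activations
#'
#' Within each trial window (trial onset up to the next trial's onset),
#' the predicted choice is the action dimension whose peak activation is
#' largest, counted only if that peak reaches `threshold`; ties break
#' toward the lowest dimension index.
#'
#' @param pred_action T x 3 matrix of activations in \[0, 1\].
#' @param events trial events table.
#' @param task task name (maps dimensions to button labels).
#' @param step_s step size in seconds.
#' @param threshold detection threshold in (0, 1).
#' @return character vector of per-trial choices (`NA` if no press).
#' @export
decode_choices <- function(pred_action, events, task, step_s = 0.08,
                           threshold = 0.5) {
  stop_ifnot(threshold > 0 && threshold < 1, "threshold must be in (0,1)")
  if (!nrow(events)) return(character(0))
  labels <- task_button_labels(task)
  win <- trial_windows(events, nrow(pred_action), step_s)
  vapply(seq_len(nrow(events)), function(k) {
    rows <- win[k, "from"]:win[k, "to"]
    peaks <- apply(pred_action[rows, , drop = FALSE], 2, max)
    best <- which.max(peaks)  # which.max takes the lowest index on ties
    if (peaks[best] >= threshold) labels[best] else NA_character_
  }, "")
}

#' Extract reaction times from predicted action activations
#'
#' Reaction time is the interval from stimulus appearance to the first
#' step (within the trial window) at which any action dimension reaches
#' `threshold`, converted to milliseconds at 80 ms per step. Trials with
#' no threshold crossing are excluded and counted.
#'
#' @inheritParams decode_choices
#' @return list with `rt_ms` (per trial, `NA` when excluded) and
#'   `n_excluded`.
#' @export
extract_reaction_times <- function(pred_action, events, step_s = 0.08,
                                   threshold = 0.5) {
  stop_ifnot(threshold > 0 && threshold < 1, "threshold must be in (0,1)")
  if (!nrow(events)) return(list(rt_ms = numeric(0), n_excluded = 0L))
  win <- trial_windows(events, nrow(pred_action), step_s)
  rt <- vapply(seq_len(nrow(events)), function(k) {
    s0 <- step_of(events$stim_onset_s[k], step_s)
    rows <- max(win[k, "from"], s0):win[k, "to"]
    hit <- rows[apply(pred_action[rows, , drop = FALSE] >= threshold, 1, any)]
    if (!length(hit)) return(NA_real_)
    (hit[1] - s0) * step_s * 1000
  }, 0)
  list(rt_ms = rt, n_excluded = sum(is.na(rt)))
}

#' Concordance rate between predicted and observed choices
#'
#' Fraction of trials whose predicted choice matches the observed one;
#' trials with no predicted press (`NA`) count as mismatches.
#'
#' @param pred_choices,observed_choices character vectors, equal length.
#' @return scalar in \[0, 1\].
#' @export
concordance_rate <- function(pred_choices, observed_choices) {
  stop_ifnot(length(pred_choices) == length(observed_choices),
             "trial counts differ: %d vs %d",
             length(pred_choices), length(observed_choices))
  if (!length(pred_choices)) return(NaN)
  mean(!is.na(pred_choices) & pred_choices == observed_choices)
}
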