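#' @name synthetic_cohort
#' @title Synthetic cohort with planted traits
#'
#' @description
#' Generates virtual participants whose latent affective and cognitive
#' traits (i.i.d. standard normal) are planted both in the behavior/BOLD
#' they produce during the two tasks and, linearly, in their resting-state
#' connectomes. The cognitive trait controls response latency and error
#' rate; the affective trait controls the right amygdala's face-condition
#' response amplitude (negative slope by default: higher trait, weaker
#' response). Nuisance traits are embedded in the connectome but unrelated
#' to behavior. Every output is a deterministic function of the generator
#' configuration and seeds.
NULL

#' Default trial timing and schedule configuration
#'
#' Trial timing is a synthetic design choice (cue 2 s for Emotional Faces,
#' stimulus window 4 s, inter-trial interval 6 s, conditions blocked in
#' runs of 4 trials).
#'
#' @param task task name.
#' @return list of schedule parameters.
#' @export
default_schedule_cfg <- function(task = c("emotional_faces", "stroop")) {
  task <- match.arg(task)
  list(cue_s = if (task == "emotional_faces") 2 else 0,
       stim_s = 4, iti_s = 6, block_len = 4L)
}

#' Default behavioral generator configuration
#'
#' Latency = `base_latency_s + slope_s * cognitive + eps`, with `eps`
#' Gaussian (SD `noise_sd_s`) truncated at one 80 ms step; error
#' probability is `plogis(p0 + p1 * cognitive)`.
#'
#' @return list of behavioral parameters.
#' @export
default_beh_cfg <- function() {
  list(base_latency_s = 0.72, slope_s = 0.16, noise_sd_s = 0.04,
       p0 = stats::qlogis(0.05), p1 = 0.5)
}

#' Default BOLD generator configuration
#'
#' Region/condition response amplitudes drive Glover-HRF-convolved
#' boxcars plus AR(1) noise. The right-amygdala face amplitude is
#' `amyg_a0 + amyg_slope * affective` (negative slope: higher affective
#' trait, weaker amygdala response; the sign is recorded in the cohort's
#' generator parameters).
#'
#' @return list of BOLD parameters.
#' @export
default_bold_cfg <- function() {
  list(noise_sd = 0.2, ar_phi = 0.3,
       amyg_a0 = 0.8, amyg_slope = -0.35, amyg_shape_amp = 0.2,
       amp_base_mean = 0.5, amp_base_sd = 0.3)
}

#' Default connectome-embedding configuration
#' @return list of embedding parameters.
#' @export
default_embed_cfg <- function() {
  list(b0_sd = 0.3, load_sd = 0.15, noise_sd = 0.05, n_nuisance = 3L)
}

#' Region labels emulating the 20-region task-BOLD selection
#'
#' For `n = 20`, ten bilateral areas (anterior prefrontal, ventrolateral
#' prefrontal, premotor, primary motor, primary sensory, superior
#' parietal, auditory, higher visual, primary visual, amygdala).
#' Other sizes get generic labels with the last region named
#' `amygdala_R` so the affective indicator is always defined.
#'
#' @param n number of regions.
#' @return character vector of length `n`.
#' @export
default_region_labels <- function(n = 20L) {
  if (n == 20L) {
    areas <- c("aPFC", "VLPFC", "PMC", "M1", "S1", "SPC", "AUD", "HVC",
               "V1", "amygdala")
    return(as.vector(t(outer(areas, c("L", "R"), paste, sep = "_"))))
  }
  stop_ifnot(n >= 1, "need at least one region")
  labs <- sprintf("region_%03d", seq_len(n))
  labs[n] <- "amygdala_R"
  labs
}

task_durations <- function(task) {
  if (task == "emotional_faces") 394.6 else 407.2
}

#' Generate a trial schedule for one task
#'
#' Trials tile the run at a fixed length (cue + stimulus window +
#' inter-trial interval); conditions are blocked; onsets are aligned to
#' the step grid by flooring. Responses are left unfilled.
#'
#' @param task `"emotional_faces"` or `"stroop"`.
#' @param duration_s run duration in seconds (defaults: 394.6 for
#'   Emotional Faces, 407.2 for Stroop).
#' @param step_s time step (s).
#' @param trial_cfg see [default_schedule_cfg()].
#' @param seed seed for condition-independent draws (correct sides, ink
#'   and word colors).
#' @return data frame of trial events (one row per trial) with columns
#'   `onset_s`, `cue_s`, `stim_onset_s`, `stim_s`, `condition`,
#'   `correct_choice`, `ink`, `word` and empty response columns.
#' @export
generate_schedule <- function(task, duration_s = task_durations(task),
                              step_s = 0.08,
                              trial_cfg = default_schedule_cfg(task),
                              seed = 1L) {
  task <- match.arg(task, c("emotional_faces", "stroop"))
  stop_ifnot(duration_s >= 0, "duration_s must be >= 0")
  stop_ifnot(step_s > 0, "step_s must be > 0")
  trial_len <- trial_cfg$cue_s + trial_cfg$stim_s + trial_cfg$iti_s
  stop_ifnot(trial_cfg$cue_s >= 0 && trial_cfg$stim_s > 0 && trial_cfg$iti_s >= 0,
             "trial_cfg implies overlapping trials: cue %g s + stimulus %g s + iti %g s",
             trial_cfg$cue_s, trial_cfg$stim_s, trial_cfg$iti_s)
  n_trials <- floor(duration_s / trial_len + 1e-9)
  empty <- data.frame(onset_s = numeric(0), cue_s = numeric(0),
                      stim_onset_s = numeric(0), stim_s = numeric(0),
                      condition = character(0), correct_choice = character(0),
                      ink = character(0), word = character(0),
                      response_choice = character(0),
                      response_time_s = numeric(0),
                      response_onset_s = numeric(0))
  if (n_trials == 0) return(empty)
  floor_step <- function(t) floor(t / step_s + 1e-9) * step_s
  onsets <- floor_step((seq_len(n_trials) - 1) * trial_len)
  conds <- if (task == "emotional_faces") c("face", "shape")
           else c("congruent", "incongruent")
  block <- ((seq_len(n_trials) - 1) %/% trial_cfg$block_len) %% 2L
  condition <- conds[block + 1L]
  with_seed(seed, {
    if (task == "emotional_faces") {
      correct <- sample(ef_buttons, n_trials, replace = TRUE)
      ink <- word <- rep(NA_character_, n_trials)
    } else {
      ink <- sample(stroop_buttons, n_trials, replace = TRUE)
      word <- ink
      incon <- condition == "incongruent"
      word[incon] <- vapply(ink[incon], function(cl) {
        sample(setdiff(stroop_buttons, cl), 1L)
      }, "")
      correct <- ink
    }
    data.frame(onset_s = onsets, cue_s = trial_cfg$cue_s,
               stim_onset_s = floor_step(onsets + trial_cfg$cue_s),
               stim_s = trial_cfg$stim_s,
               condition = condition, correct_choice = correct,
               ink = ink, word = word,
               response_choice = NA_character_,
               response_time_s = NA_real_,
               response_onset_s = NA_real_,
               stringsAsFactors = FALSE)
  })
}

# inverse-CDF truncated normal: deterministic draw count under a seed
rtruncnorm01 <- function(n, sd, lim) {
  if (sd == 0) return(numeric(n))
  u <- stats::runif(n, stats::pnorm(-lim, 0, sd), stats::pnorm(lim, 0, sd))
  stats::qnorm(u, 0, sd)
}

#' Simulate trait-dependent responses for a trial schedule
#'
#' Response latency is `base_latency_s + slope_s * cognitive` plus
#' truncated Gaussian trial noise, clipped to at least one step and at
#' most one step before the stimulus window ends. The response is the
#' correct button with probability `1 - plogis(p0 + p1 * cognitive)`,
#' otherwise uniform over the task's alternative buttons.
#'
#' @param events a [generate_schedule()] table without responses.
#' @param traits list or one-row data frame with `cognitive` (and
#'   optionally other traits).
#' @param beh_cfg see [default_beh_cfg()].
#' @param seed participant-level seed.
#' @param step_s step size (s), also the truncation limit of the latency
#'   noise.
#' @return the events table with response columns filled.
#' @export
simulate_behavior <- function(events, traits, beh_cfg = default_beh_cfg(),
                              seed = 1L, step_s = 0.08) {
  stop_ifnot(beh_cfg$base_latency_s >= 0, "negative base_latency_s")
  stop_ifnot(all(is.na(events$response_choice)),
             "events already contain responses")
  n <- nrow(events)
  if (!n) return(events)
  is_stroop <- !is.na(events$ink[1])
  buttons <- if (is_stroop) stroop_buttons else ef_buttons
  with_seed(seed, {
    eps <- rtruncnorm01(n, beh_cfg$noise_sd_s, step_s)
    latency <- beh_cfg$base_latency_s + beh_cfg$slope_s * traits$cognitive + eps
    latency <- pmin(pmax(latency, step_s), events$stim_s - step_s)
    p_err <- stats::plogis(beh_cfg$p0 + beh_cfg$p1 * traits$cognitive)
    err <- stats::runif(n) < p_err
    choice <- events$correct_choice
    if (any(err)) {
      choice[err] <- vapply(events$correct_choice[err], function(cc) {
        alt <- setdiff(buttons, cc)
        if (length(alt) == 1) alt else sample(alt, 1L)
      }, "")
    }
    events$response_choice <- choice
    events$response_time_s <- latency
    events$response_onset_s <- events$stim_onset_s + latency
    events
  })
}

#' Simulate region-wise task BOLD signals
#'
#' Each region's signal is the sum over conditions of an amplitude times
#' the trial boxcar convolved with the Glover HRF, plus AR(1) noise with
#' stationary SD `noise_sd`. The right amygdala's face-condition
#' amplitude is `amyg_a0 + amyg_slope * affective`.
#'
#' @param events trial events (responses not required).
#' @param traits participant traits (`affective` used).
#' @param regions character vector of region labels; must contain
#'   `amygdala_R` when the events include a face condition.
#' @param n_steps sequence length in steps.
#' @param step_s step size (s).
#' @param bold_cfg see [default_bold_cfg()]; may carry a precomputed
#'   `amplitudes` matrix (regions x conditions) and `amp_seed`.
#' @param seed participant-level noise seed.
#' @return a [region_ts()] (regions x time).
#' @export
simulate_bold <- function(events, traits, regions, n_steps, step_s = 0.08,
                          bold_cfg = default_bold_cfg(), seed = 1L) {
  conds <- sort(unique(as.character(events$condition)))
  A <- bold_cfg$amplitudes
  if (is.null(A)) {
    A <- with_seed(bold_cfg$amp_seed %||% 1L,
      matrix(stats::rnorm(length(regions) * length(conds),
                          bold_cfg$amp_base_mean, bold_cfg$amp_base_sd),
             length(regions), length(conds),
             dimnames = list(regions, conds)))
  } else {
    A <- A[regions, conds, drop = FALSE]
  }
  if ("face" %in% conds) {
    stop_ifnot("amygdala_R" %in% regions,
               "region list must include amygdala_R for the face condition")
    A["amygdala_R", "face"] <- bold_cfg$amyg_a0 +
      bold_cfg$amyg_slope * traits$affective
    if ("shape" %in% conds) A["amygdala_R", "shape"] <- bold_cfg$amyg_shape_amp
  }
  kernel <- glover_hrf(seq(0, 32, by = step_s))
  reg_cond <- sapply(conds, function(cond) {
    ev <- events[as.character(events$condition) == cond, , drop = FALSE]
    convolve_boxcar(ev$stim_onset_s, ev$stim_s, n_steps, step_s, kernel)
  })  # n_steps x n_conds
  if (!is.matrix(reg_cond)) reg_cond <- matrix(reg_cond, n_steps, length(conds))
  signal <- A %*% t(reg_cond)  # regions x time
  noise <- with_seed(seed, {
    phi <- bold_cfg$ar_phi
    innov_sd <- bold_cfg$noise_sd * sqrt(1 - phi^2)
    t(vapply(seq_along(regions), function(r) {
      e <- stats::rnorm(n_steps, sd = innov_sd)
      if (phi != 0) e <- as.numeric(stats::filter(e, phi, method = "recursive"))
      e
    }, numeric(n_steps)))
  })
  region_ts(signal + noise, step_s, regions)
}

# draw the cohort-level symmetric loading matrices for the rsFCM embedding
draw_embed_bases <- function(n_regions, embed_cfg, cohort_seed) {
  sym <- function(sd) {
    M <- matrix(stats::rnorm(n_regions^2, sd = sd), n_regions)
    (M + t(M)) / sqrt(2)
  }
  with_seed(cohort_seed, {
    B <- list(B0 = sym(embed_cfg$b0_sd),
              B_a = sym(embed_cfg$load_sd),
              B_c = sym(embed_cfg$load_sd))
    B$B_nuis <- lapply(seq_len(embed_cfg$n_nuisance),
                       function(k) sym(embed_cfg$load_sd))
    B
  })
}

#' Embed traits linearly into a resting-state connectome
#'
#' Builds the symmetric matrix
#' `M = tanh(B0 + affective*B_a + cognitive*B_c + sum_k nuisance_k*B_k + E)`
#' (diagonal set to 1) and returns its Fisher-z upper-triangle vector.
#' Because `atanh(tanh(u)) = u`, the returned edges are exactly linear in
#' the traits plus noise: the simplest structure a two-hidden-layer MLP
#' can learn. This is a synthetic modeling assumption, not an empirical
#' claim about real connectomes.
#'
#' @param traits list with `affective`, `cognitive`, `nuisance` (vector).
#' @param n_regions number of regions (>= 2).
#' @param embed_cfg see [default_embed_cfg()]; may carry precomputed
#'   bases `B` and/or `cohort_seed` used to draw them.
#' @param seed participant-level seed for the edge noise `E`.
#' @return an `rsfcm` object.
#' @export
embed_rsfcm <- function(traits, n_regions, embed_cfg = default_embed_cfg(),
                        seed = 1L) {
  stop_ifnot(n_regions >= 2, "need n_regions >= 2")
  B <- embed_cfg$B %||%
    draw_embed_bases(n_regions, embed_cfg, embed_cfg$cohort_seed %||% 1L)
  U <- B$B0 + traits$affective * B$B_a + traits$cognitive * B$B_c
  nuis <- traits$nuisance %||% numeric(0)
  for (k in seq_along(nuis)) U <- U + nuis[[k]] * B$B_nuis[[k]]
  E <- with_seed(seed, {
    M <- matrix(stats::rnorm(n_regions^2, sd = embed_cfg$noise_sd), n_regions)
    (M + t(M)) / sqrt(2)
  })
  U <- U + E
  M <- tanh(U)
  diag(M) <- 1
  edges <- t(U)[lower.tri(U)]  # atanh(tanh(U)) == U off-diagonal
  structure(list(edges = edges, n_regions = as.integer(n_regions),
                 edge_index = edge_index_pairs(n_regions),
                 region_labels = default_region_labels(n_regions)),
            class = "rsfcm")
}

#' Generate a ground-truth synthetic cohort
#'
#' Draws participant traits, embeds them in connectomes, simulates the
#' two task sessions (trial schedule shared across participants, as in a
#' real experiment) with trait-dependent behavior and BOLD, and encodes
#' the multimodal channels.
#'
#' @param n_participants cohort size.
#' @param n_regions number of BOLD regions (also used for the synthetic
#'   connectome; the full-scale connectome uses 446 regions instead).
#' @param tasks tasks to simulate.
#' @param seed master cohort seed; all other seeds derive from it.
#' @param durations named run durations in seconds (defaults 394.6 /
#'   407.2).
#' @param schedule_cfg,beh_cfg,bold_cfg,embed_cfg generator settings.
#' @param step_s time step (s).
#' @return object of class `twin_cohort`: `traits` (data frame), `rsfcm`
#'   (list), `sessions` (per participant, per task
#'   `multimodal_sequence`), `schedules`, `region_labels`,
#'   `generator_params`.
#' @export
generate_cohort <- function(n_participants = 40L, n_regions = 20L,
                            tasks = c("emotional_faces", "stroop"),
                            seed = 1L,
                            durations = NULL,
                            schedule_cfg = NULL,
                            beh_cfg = default_beh_cfg(),
                            bold_cfg = default_bold_cfg(),
                            embed_cfg = default_embed_cfg(),
                            step_s = 0.08) {
  regions <- default_region_labels(n_regions)
  q <- embed_cfg$n_nuisance
  traits <- with_seed(derive_seed(seed, 1L), {
    df <- data.frame(affective = stats::rnorm(n_participants),
                     cognitive = stats::rnorm(n_participants))
    nuis <- matrix(stats::rnorm(n_participants * q), n_participants, q)
    colnames(nuis) <- paste0("nuisance_", seq_len(q))
    cbind(df, as.data.frame(nuis))
  })
  embed_cfg$B <- draw_embed_bases(n_regions, embed_cfg, derive_seed(seed, 2L))
  schedules <- list()
  amp <- list()
  for (ti in seq_along(tasks)) {
    task <- tasks[ti]
    dur <- durations[[task]] %||% task_durations(task)
    schedules[[task]] <- generate_schedule(task, dur, step_s,
                                           schedule_cfg %||% default_schedule_cfg(task),
                                           seed = derive_seed(seed, 10L + ti))
    conds <- sort(unique(schedules[[task]]$condition))
    amp[[task]] <- with_seed(derive_seed(seed, 20L + ti),
      matrix(stats::rnorm(length(regions) * length(conds),
                          bold_cfg$amp_base_mean, bold_cfg$amp_base_sd),
             length(regions), length(conds),
             dimnames = list(regions, conds)))
  }
  rsfcm <- vector("list", n_participants)
  sessions <- vector("list", n_participants)
  enc_seeds <- matrix(0L, n_participants, length(tasks),
                      dimnames = list(NULL, tasks))
  for (p in seq_len(n_participants)) {
    tr <- list(affective = traits$affective[p],
               cognitive = traits$cognitive[p],
               nuisance = as.numeric(traits[p, 2 + seq_len(q)]))
    rsfcm[[p]] <- embed_rsfcm(tr, n_regions, embed_cfg,
                              seed = derive_seed(seed, 1000L + p))
    sess <- list()
    for (ti in seq_along(tasks)) {
      task <- tasks[ti]
      sched <- schedules[[task]]
      n_steps <- floor((durations[[task]] %||% task_durations(task)) / step_s + 1e-9)
      ev <- simulate_behavior(sched, tr, beh_cfg,
                              seed = derive_seed(seed, 2000L + p * 10L + ti),
                              step_s = step_s)
      enc_seed <- derive_seed(seed, 3000L + p * 10L + ti)
      enc_seeds[p, task] <- enc_seed
      enc <- if (task == "emotional_faces") {
        encode_emotional_faces(ev, n_steps, step_s, seed = enc_seed)
      } else {
        encode_stroop(ev, n_steps, step_s)
      }
      bcfg <- bold_cfg
      bcfg$amplitudes <- amp[[task]]
      bold <- simulate_bold(ev, tr, regions, n_steps, step_s, bcfg,
                            seed = derive_seed(seed, 4000L + p * 10L + ti))
      sess[[task]] <- structure(list(
        sensory = enc$sensory,
        condition = encode_task_condition(task, n_steps),
        action = enc$action,
        bold = t(bold$values),
        step_s = step_s, events = ev, task = task,
        region_labels = regions, offset_s = 0
      ), class = "multimodal_sequence")
    }
    sessions[[p]] <- sess
  }
  structure(list(
    traits = traits, rsfcm = rsfcm, sessions = sessions,
    schedules = schedules, region_labels = regions, tasks = tasks,
    generator_params = list(
      seed = seed, n_participants = n_participants, n_regions = n_regions,
      step_s = step_s, durations = durations,
      schedule_cfg = schedule_cfg, beh_cfg = beh_cfg,
      bold_cfg = bold_cfg[setdiff(names(bold_cfg), "amplitudes")],
      embed_cfg = embed_cfg[setdiff(names(embed_cfg), "B")],
      amygdala_slope_sign = sign(bold_cfg$amyg_slope),
      enc_seeds = enc_seeds
    )
  ), class = "twin_cohort")
}

#' Write a cohort to disk as per-participant plain-text tables
#'
#' One directory per participant: `rsfcm.tsv` (labeled edge vector),
#' `{task}_events.tsv` (BIDS-style columns plus generator extras),
#' `{task}_bold.tsv` (regions x time) and a cohort-level `cohort.json`
#' holding the generator parameters, seeds and traits.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in seq_along(cohort$sessions)) {
    pdir <- file.path(dir, sprintf("sub-%03d", p))
    dir.create(pdir, showWarnings = FALSE)
    fc <- cohort$rsfcm[[p]]
    edge_df <- data.frame(i = fc$edge_index[, 1] - 1L,
                          j = fc$edge_index[, 2] - 1L,
                          region_i = fc$region_labels[fc$edge_index[, 1]],
                          region_j = fc$region_labels[fc$edge_index[, 2]],
                          z = fc$edges)
    utils::write.table(edge_df, file.path(pdir, "rsfcm.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (task in cohort$tasks) {
      ses <- cohort$sessions[[p]][[task]]
      ev <- ses$events
      bids <- data.frame(onset = ev$stim_onset_s, duration = ev$stim_s,
                         trial_type = ev$condition,
                         response = ev$response_choice,
                         response_time = ev$response_time_s,
                         trial_onset = ev$onset_s, cue_s = ev$cue_s,
                         correct = ev$correct_choice,
                         ink = ev$ink, word = ev$word)
      utils::write.table(bids, file.path(pdir, paste0(task, "_events.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      bold <- cbind(data.frame(region = ses$region_labels),
                    as.data.frame(t(ses$bold)))
      utils::write.table(bold, file.path(pdir, paste0(task, "_bold.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  gp <- cohort$generator_params
  gp$traits <- cohort$traits
  gp$tasks <- cohort$tasks
  gp$region_labels <- cohort$region_labels
  jsonlite::write_json(gp, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Sensory and action channels are re-encoded deterministically from the
#' stored events and encoding seeds, so a written-then-read cohort is
#' identical to the original.
#'
#' @param dir cohort directory.
#' @return a `twin_cohort`.
#' @export
read_cohort <- function(dir) {
  gp <- jsonlite::read_json(file.path(dir, "cohort.json"),
                            simplifyVector = TRUE)
  tasks <- gp$tasks
  step_s <- gp$step_s
  n <- gp$n_participants
  regions <- gp$region_labels
  sessions <- vector("list", n)
  rsfcm <- vector("list", n)
  for (p in seq_len(n)) {
    pdir <- file.path(dir, sprintf("sub-%03d", p))
    edge_df <- utils::read.delim(file.path(pdir, "rsfcm.tsv"))
    rsfcm[[p]] <- structure(list(edges = edge_df$z,
                                 n_regions = as.integer(gp$n_regions),
                                 edge_index = cbind(i = edge_df$i + 1L,
                                                    j = edge_df$j + 1L),
                                 region_labels = regions),
                            class = "rsfcm")
    sess <- list()
    for (task in tasks) {
      bids <- utils::read.delim(file.path(pdir, paste0(task, "_events.tsv")),
                                colClasses = NA, stringsAsFactors = FALSE)
      ev <- data.frame(onset_s = bids$trial_onset, cue_s = bids$cue_s,
                       stim_onset_s = bids$onset, stim_s = bids$duration,
                       condition = bids$trial_type,
                       correct_choice = bids$correct,
                       ink = if (all(is.na(bids$ink))) NA_character_ else bids$ink,
                       word = if (all(is.na(bids$word))) NA_character_ else bids$word,
                       response_choice = bids$response,
                       response_time_s = bids$response_time,
                       response_onset_s = bids$onset + bids$response_time,
                       stringsAsFactors = FALSE)
      bold_df <- utils::read.delim(file.path(pdir, paste0(task, "_bold.tsv")))
      bold <- t(as.matrix(bold_df[, -1]))
      n_steps <- nrow(bold)
      enc_seed <- gp$enc_seeds[p, match(task, tasks)]
      enc <- if (task == "emotional_faces") {
        encode_emotional_faces(ev, n_steps, step_s, seed = enc_seed)
      } else {
        encode_stroop(ev, n_steps, step_s)
      }
      sess[[task]] <- structure(list(
        sensory = enc$sensory,
        condition = encode_task_condition(task, n_steps),
        action = enc$action, bold = unname(bold),
        step_s = step_s, events = ev, task = task,
        region_labels = regions, offset_s = 0
      ), class = "multimodal_sequence")
    }
    sessions[[p]] <- sess
  }
  structure(list(traits = gp$traits, rsfcm = rsfcm, sessions = sessions,
                 schedules = NULL, region_labels = regions, tasks = tasks,
                 generator_params = gp),
            class = "twin_cohort")
}
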