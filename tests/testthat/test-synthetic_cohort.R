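test_that("generate_schedule fits the run and aligns to the grid", {
  ev <- generate_schedule("emotional_faces", 394.6, 0.08, seed = 1)
  expect_gt(nrow(ev), 0)
  # all events end inside the 4,932-step grid (floor(394.6 / 0.08))
  expect_lte(max(ev$stim_onset_s + ev$stim_s), floor(394.6 / 0.08) * 0.08)
  expect_true(all(abs(ev$onset_s / 0.08 - round(ev$onset_s / 0.08)) < 1e-9))
  expect_true(all(diff(ev$onset_s) > 0))
  expect_true(all(ev$condition %in% c("face", "shape")))
  # zero duration gives an empty list
  expect_identical(nrow(generate_schedule("stroop", 0, 0.08, seed = 0)), 0L)
  # determinism
  expect_identical(generate_schedule("stroop", 407.2, 0.08, seed = 3),
                   generate_schedule("stroop", 407.2, 0.08, seed = 3))
  # overlapping trials rejected
  bad <- default_schedule_cfg("stroop"); bad$stim_s <- -1
  expect_error(generate_schedule("stroop", 100, 0.08, bad, 1), "overlap")
})

test_that("simulate_behavior: degenerate configs and monotonicity", {
  sched <- generate_schedule("emotional_faces", 120, 0.08, seed = 2)
  cfg0 <- default_beh_cfg()
  cfg0$slope_s <- 0; cfg0$noise_sd_s <- 0
  ev <- simulate_behavior(sched, list(cognitive = 1.7), cfg0, seed = 1)
  expect_true(all(ev$response_time_s == cfg0$base_latency_s))
  # +-2 SD cognitive trait with positive slope: strictly slower mean latency
  cfg <- default_beh_cfg()
  ev_hi <- simulate_behavior(sched, list(cognitive = 2), cfg, seed = 1)
  ev_lo <- simulate_behavior(sched, list(cognitive = -2), cfg, seed = 1)
  expect_gt(mean(ev_hi$response_time_s), mean(ev_lo$response_time_s))
  # p0 = -Inf: no error trials
  cfgp <- default_beh_cfg(); cfgp$p0 <- -Inf
  evp <- simulate_behavior(sched, list(cognitive = 0), cfgp, seed = 3)
  expect_identical(evp$response_choice, evp$correct_choice)
  # responses already present / negative base latency rejected
  expect_error(simulate_behavior(ev, list(cognitive = 0)), "already")
  cfgn <- default_beh_cfg(); cfgn$base_latency_s <- -1
  expect_error(simulate_behavior(sched, list(cognitive = 0), cfgn), "negative")
})

test_that("planted monotonicity: cognitive trait vs mean RT at n = 100", {
  sched <- generate_schedule("stroop", 407.2, 0.08, seed = 4)
  cog <- with_seed(10, rnorm(100))
  mean_rt <- vapply(seq_len(100), function(p) {
    ev <- simulate_behavior(sched, list(cognitive = cog[p]), seed = 100 + p)
    mean(ev$response_time_s)
  }, 0)
  r <- cor(cog, mean_rt)
  expect_gt(r, 0.8)  # configured slope is positive
})

test_that("simulate_bold: degenerate limits and HRF-shape oracle", {
  sched <- generate_schedule("emotional_faces", 60, 0.08, seed = 5)
  ev <- sched[1, ]  # single face trial
  ev$condition <- "face"
  regions <- default_region_labels(4)
  n_steps <- 750
  cfg <- default_bold_cfg()
  cfg$noise_sd <- 0
  cfg$amplitudes <- matrix(0, 4, 2, dimnames = list(regions, c("face", "shape")))
  cfg$amyg_a0 <- 0; cfg$amyg_slope <- 0; cfg$amyg_shape_amp <- 0
  out <- simulate_bold(ev, list(affective = 0), regions, n_steps, 0.08, cfg, 1)
  expect_true(all(out$values == 0))
  # single trial, amplitude 1: signal equals boxcar (*) Glover kernel
  cfg$amyg_a0 <- 1
  out1 <- simulate_bold(ev, list(affective = 0), regions, n_steps, 0.08, cfg, 1)
  kernel <- glover_hrf(seq(0, 32, by = 0.08))
  box <- numeric(n_steps)
  a <- floor(ev$stim_onset_s / 0.08) + 1
  b <- floor((ev$stim_onset_s + ev$stim_s) / 0.08)
  box[a:b] <- 1
  oracle <- convolve(box, rev(kernel), type = "open")[1:n_steps]
  expect_equal(out1$values[match("amygdala_R", regions), ], oracle,
               tolerance = 1e-9)
  # AR(1) phi = 0: white noise with the configured SD
  cfgw <- cfg; cfgw$amyg_a0 <- 0; cfgw$noise_sd <- 0.5; cfgw$ar_phi <- 0
  nz <- simulate_bold(ev, list(affective = 0), regions, 20000, 0.08, cfgw, 2)
  expect_equal(sd(nz$values[1, ]), 0.5, tolerance = 0.02)
  expect_lt(abs(cor(nz$values[1, -1], nz$values[1, -20000])), 0.03)
})

test_that("embed_rsfcm: sizes, determinism, linear trait recovery", {
  tr0 <- list(affective = 0, cognitive = 0, nuisance = c(0, 0, 0))
  ecfg <- default_embed_cfg()
  ecfg$B <- twinbrain:::draw_embed_bases(10, ecfg, 1)
  fc <- embed_rsfcm(tr0, 10, ecfg, seed = 1)
  expect_identical(length(fc$edges), 45L)
  # zero noise + equal traits give identical vectors
  ecfg0 <- ecfg; ecfg0$noise_sd <- 0
  a <- embed_rsfcm(tr0, 10, ecfg0, seed = 1)
  b <- embed_rsfcm(tr0, 10, ecfg0, seed = 99)
  expect_identical(a$edges, b$edges)
  # 446 regions give the canonical 99,235-edge vector
  tr1 <- list(affective = 1, cognitive = -1, nuisance = numeric(0))
  ecfg446 <- default_embed_cfg(); ecfg446$n_nuisance <- 0L
  ecfg446$cohort_seed <- 2
  fc446 <- embed_rsfcm(tr1, 446, ecfg446, seed = 1)
  expect_identical(length(fc446$edges), 99235L)
})

test_that("affective trait is linearly recoverable from embedded rsFCMs", {
  ecfg <- default_embed_cfg()
  n_reg <- 12
  ecfg$B <- twinbrain:::draw_embed_bases(n_reg, ecfg, 3)
  set.seed(20)
  aff <- rnorm(200); cog <- rnorm(200)
  X <- t(vapply(1:200, function(p) {
    embed_rsfcm(list(affective = aff[p], cognitive = cog[p],
                     nuisance = rnorm(3)), n_reg, ecfg, seed = 500 + p)$edges
  }, numeric(n_reg * (n_reg - 1) / 2)))
  fit <- lm.fit(cbind(1, X), aff)
  r2 <- 1 - sum(fit$residuals^2) / sum((aff - mean(aff))^2)
  expect_gt(r2, 0.9)
})

test_that("cohorts regenerate byte-identically and round-trip through disk", {
  co1 <- generate_cohort(n_participants = 2, n_regions = 6, seed = 9,
                         durations = list(emotional_faces = 90, stroop = 90))
  co2 <- generate_cohort(n_participants = 2, n_regions = 6, seed = 9,
                         durations = list(emotional_faces = 90, stroop = 90))
  expect_identical(co1, co2)
  dir <- tempfile("cohort")
  write_cohort(co1, dir)
  co3 <- read_cohort(dir)
  for (p in 1:2) {
    expect_equal(co3$rsfcm[[p]]$edges, co1$rsfcm[[p]]$edges, tolerance = 1e-12)
    for (task in co1$tasks) {
      s1 <- co1$sessions[[p]][[task]]; s3 <- co3$sessions[[p]][[task]]
      expect_identical(s3$sensory, s1$sensory)
      expect_identical(s3$action, s1$action)
      expect_equal(s3$bold, unname(s1$bold), tolerance = 1e-10)
    }
  }
  expect_equal(co3$traits$cognitive, co1$traits$cognitive, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("GLM recovers planted amplitude ratios on noiseless BOLD", {
  sched <- generate_schedule("emotional_faces", 394.6, 0.08, seed = 6)
  regions <- default_region_labels(3)
  cfg <- default_bold_cfg()
  cfg$noise_sd <- 0
  cfg$amplitudes <- matrix(c(1.0, 0.25,   # region 1: face, then shape below
                             0.6, 0.3,
                             0.0, 0.0),
                           3, 2, byrow = TRUE,
                           dimnames = list(regions, c("face", "shape")))
  cfg$amyg_a0 <- 0.5; cfg$amyg_slope <- 0; cfg$amyg_shape_amp <- 0.25
  n_steps <- 4932
  out <- simulate_bold(sched, list(affective = 0), regions, n_steps, 0.08,
                       cfg, 1)
  des <- build_design(sched, n_steps, 0.08)
  for (r in 1:2) {
    fit <- fit_glm(des, out$values[r, ])
    b_face <- fit$beta[["face_hrf"]]
    b_shape <- fit$beta[["shape_hrf"]]
    truth <- cfg$amplitudes[r, "face"] / cfg$amplitudes[r, "shape"]
    expect_equal(b_face / b_shape, truth, tolerance = 0.01)
  }
})
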