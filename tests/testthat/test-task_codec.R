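ef_events <- function(n = 4, seed = 1) {
  sched <- generate_schedule("emotional_faces", n * 12, 0.08,
                             seed = seed)
  traits <- list(affective = 0, cognitive = 0)
  simulate_behavior(sched, traits, seed = seed)
}

stroop_events <- function(n = 4, seed = 2) {
  sched <- generate_schedule("stroop", n * 10, 0.08, seed = seed)
  simulate_behavior(sched, list(cognitive = 0), seed = seed)
}

test_that("Emotional Faces encoding respects the value ranges", {
  ev <- ef_events(8)
  enc <- encode_emotional_faces(ev, 1200, 0.08, seed = 3)
  expect_equal(dim(enc$sensory), c(1200, 8))
  # rows with no stimulus and no cue are all zero
  step0 <- floor(ev$onset_s[1] / 0.08)
  if (step0 >= 1) expect_true(all(enc$sensory[seq_len(step0), ] == 0))
  # inter-trial rows (after stimulus window, before next cue) are zero
  gap <- floor((ev$stim_onset_s[1] + ev$stim_s[1]) / 0.08) + 2
  expect_true(all(enc$sensory[gap, 3:8] == 0))
  # face values never fall inside (0.1, 0.9); shape values are exact bits
  for (k in seq_len(nrow(ev))) {
    rows <- (floor(ev$stim_onset_s[k] / 0.08) + 1):
            (floor((ev$stim_onset_s[k] + ev$stim_s[k]) / 0.08))
    vals <- enc$sensory[rows, 3:8]
    if (ev$condition[k] == "face") {
      expect_true(all(vals <= 0.1 | vals >= 0.9))
    } else {
      expect_true(all(vals %in% c(0, 1)))
    }
    # cue indicator matches the condition
    cue_rows <- (floor(ev$onset_s[k] / 0.08) + 1):
                (floor((ev$onset_s[k] + ev$cue_s[k]) / 0.08))
    dim_on <- if (ev$condition[k] == "face") 1 else 2
    expect_true(all(enc$sensory[cue_rows, dim_on] == 1))
    expect_true(all(enc$sensory[cue_rows, 3 - dim_on] == 0))
  }
  # the matching probe duplicates the target pattern
  k <- 1
  rows <- floor(ev$stim_onset_s[k] / 0.08) + 1
  side_dims <- if (ev$correct_choice[k] == "left") 5:6 else 7:8
  expect_equal(enc$sensory[rows, side_dims], enc$sensory[rows, 3:4])
  # action channel: one 3-step press per responded trial, third dim unused
  expect_equal(sum(enc$action), 3 * sum(!is.na(ev$response_choice)))
  expect_true(all(enc$action[, 3] == 0))
  enc1 <- encode_emotional_faces(ev, 1200, 0.08, seed = 3, press_steps = 1L)
  expect_equal(sum(enc1$action), sum(!is.na(ev$response_choice)))
  # third-button responses are rejected
  bad <- ev; bad$response_choice[1] <- "blue"
  expect_error(encode_emotional_faces(bad, 1200, 0.08, seed = 1), "button")
})

test_that("Stroop encoding uses ink/word one-hots and zero spare dims", {
  ev <- stroop_events(6)
  enc <- encode_stroop(ev, 800, 0.08)
  expect_true(all(enc$sensory[, 7:8] == 0))
  for (k in seq_len(nrow(ev))) {
    r <- floor(ev$stim_onset_s[k] / 0.08) + 1
    ink_hot <- as.numeric(c("red", "green", "blue") == ev$ink[k])
    word_hot <- as.numeric(c("red", "green", "blue") == ev$word[k])
    expect_equal(enc$sensory[r, 1:3], ink_hot)
    expect_equal(enc$sensory[r, 4:6], word_hot)
    if (ev$condition[k] == "incongruent") {
      expect_false(all(ink_hot == word_hot))
    } else {
      expect_equal(ink_hot, word_hot)
    }
  }
  # congruent red word in red ink -> (1,0,0,1,0,0,0,0)
  one <- ev[1, ]; one$condition <- "congruent"
  one$ink <- one$word <- "red"; one$correct_choice <- "red"
  enc1 <- encode_stroop(one, 200, 0.08)
  r <- floor(one$stim_onset_s / 0.08) + 1
  expect_equal(enc1$sensory[r, ], c(1, 0, 0, 1, 0, 0, 0, 0))
  # rows before the stimulus are zero
  expect_true(all(enc1$sensory[seq_len(r - 1), ] == 0))
  bad <- ev; bad$ink[1] <- "mauve"
  expect_error(encode_stroop(bad, 800, 0.08), "ink")
})

test_that("task-condition channel is the constant task flag", {
  expect_equal(encode_task_condition("emotional_faces", 5),
               matrix(0, 5, 1))
  expect_equal(encode_task_condition("stroop", 3), matrix(1, 3, 1))
  expect_equal(nrow(encode_task_condition("stroop", 0)), 0L)
})

test_that("decode_choices follows thresholded peak argmax per trial", {
  ev <- stroop_events(3)
  Tn <- 400
  # all zeros: no predicted press in any trial
  expect_true(all(is.na(decode_choices(matrix(0, Tn, 3), ev, "stroop"))))
  # single dim active above threshold
  act <- matrix(0, Tn, 3)
  r <- floor(ev$stim_onset_s[1] / 0.08) + 4
  act[r, 2] <- 0.9
  out <- decode_choices(act, ev, "stroop", threshold = 0.5)
  expect_identical(out[1], "green")
  # two dims: the higher peak wins (argmax oracle over the window)
  act[r + 1, 1] <- 0.8
  expect_identical(decode_choices(act, ev, "stroop")[1], "green")
  act[r + 1, 1] <- 0.95
  expect_identical(decode_choices(act, ev, "stroop")[1], "red")
  expect_error(decode_choices(act, ev, "stroop", threshold = 0), "threshold")
})

test_that("reaction times convert threshold crossings to ms", {
  ev <- ef_events(3)
  Tn <- 500
  act <- matrix(0, Tn, 3)
  s0 <- floor(ev$stim_onset_s[1] / 0.08) + 1
  act[s0, 1] <- 1  # press exactly at stimulus onset
  s1 <- floor(ev$stim_onset_s[2] / 0.08) + 1
  act[s1 + 10, 2] <- 0.8  # 10 steps after onset -> 800 ms
  rt <- extract_reaction_times(act, ev, 0.08, threshold = 0.5)
  expect_equal(rt$rt_ms[1], 0)
  expect_equal(rt$rt_ms[2], 800)
  expect_true(is.na(rt$rt_ms[3]))
  expect_identical(rt$n_excluded, 1L)
})

test_that("concordance counts matches; missing predictions are mismatches", {
  expect_equal(concordance_rate(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(concordance_rate(c("a", "b"), c("b", "a")), 0.0)
  expect_equal(concordance_rate(c("a", "b", "a", NA), c("a", "b", "b", "a")),
               0.5)
  expect_equal(concordance_rate(c("a", "a", "a", "b"), c("a", "a", "a", "a")),
               0.75)
  expect_error(concordance_rate("a", c("a", "b")), "counts differ")
})

test_that("Stroop encoding is event-lossless through decode", {
  ev <- stroop_events(8, seed = 9)
  enc <- encode_stroop(ev, 1100, 0.08)
  dec <- decode_choices(enc$action, ev, "stroop", threshold = 0.5)
  expect_identical(dec, ev$response_choice)
  rt <- extract_reaction_times(enc$action, ev, 0.08, threshold = 0.5)
  # recovered press steps equal the encoded response onsets
  expect_identical(rt$n_excluded, 0L)
  enc_steps <- floor(ev$response_onset_s / 0.08) - floor(ev$stim_onset_s / 0.08)
  expect_equal(rt$rt_ms, enc_steps * 80)
})
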