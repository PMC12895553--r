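#' Default run configuration for the toy end-to-end chain
#'
#' 20 regions, 40 participants and 32/32 hidden units: sized so that the
#' full simulate -> preprocess -> train -> evaluate -> pls -> intervene
#' chain completes in minutes on one CPU.
#'
#' @param seed global seed.
#' @return nested configuration list.
#' @export
toy_run_config <- function(seed = 1L) {
  list(
    seed = seed,
    synthetic = list(n_participants = 40L, n_regions = 20L),
    model = list(n_hidden_hyper = 32L, n_hidden_main = 32L, dropout = 0.1),
    train = list(segment_len = 262L, batch_size = 8L, lr = 1e-3,
                 max_epochs = 600L, early_stop_patience = 100L,
                 val_fraction = 0.1),
    loss = list(lambda_action = 1, lambda_bold = 1),
    split = list(train_duration_s = 196.8),
    pls = list(threshold = 0.5),
    intervention = list(alpha_sd = 2, sd_threshold = 2.5,
                        smoothgrad_samples = 100L, noise_level = 0.1,
                        threshold = 0.5)
  )
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` (requires the yaml package)
#'   or `.json`.
#' @return configuration list, merged over [toy_run_config()] defaults.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    stop_ifnot(requireNamespace("yaml", quietly = TRUE),
               "yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- toy_run_config(raw$seed %||% 1L)
  merge2 <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge2(base, raw)
}

write_manifest <- function(out_dir, phase, config, inputs = character(0)) {
  # no timestamps or absolute paths: repeated runs under one config
  # yield byte-identical manifests
  hashes <- as.list(unname(tools::md5sum(inputs)))
  names(hashes) <- basename(inputs)
  man <- list(phase = phase,
              config_hash = digest::digest(config),
              seed = config$seed,
              inputs = hashes)
  jsonlite::write_json(man, file.path(out_dir, paste0(phase, "_manifest.json")),
                       auto_unbox = TRUE)
}

need_artifact <- function(path, producer) {
  stop_ifnot(file.exists(path),
             "missing artifact '%s'; run phase '%s' first", path, producer)
  path
}

#' Run one phase of the analysis pipeline
#'
#' Phases chain through artifacts in `out_dir`:
#' `simulate_cohort` -> `preprocess` -> `train` -> `evaluate` / `glm` ->
#' `pls` -> `intervene`. Each phase writes a manifest recording the
#' configuration hash, the seed and the md5 of its inputs, so every
#' artifact is reproducible from its manifest.
#'
#' @param phase one of `simulate_cohort`, `preprocess`, `train`,
#'   `evaluate`, `glm`, `pls`, `intervene`.
#' @param config nested configuration (see [toy_run_config()]).
#' @param out_dir artifact directory.
#' @param verbose print progress.
#' @return invisibly, the main artifact path of the phase.
#' @export
run_phase <- function(phase, config = toy_run_config(), out_dir = "twin_out",
                      verbose = TRUE) {
  phase <- match.arg(phase, c("simulate_cohort", "preprocess", "train",
                              "evaluate", "glm", "pls", "intervene"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed %||% 1L
  cohort_dir <- file.path(out_dir, "cohort")
  ds_path <- file.path(out_dir, "dataset.rds")
  ck_path <- file.path(out_dir, "checkpoint.rds")
  pls_path <- file.path(out_dir, "pls.rds")

  model_cfg_for <- function(dataset) {
    twin_config(n_in = length(dataset$participants[[1]]$x),
                n_hidden_hyper = config$model$n_hidden_hyper,
                dropout = config$model$dropout,
                n_hidden_main = config$model$n_hidden_main,
                n_bold = length(dataset$region_labels))
  }

  if (phase == "simulate_cohort") {
    say("simulating cohort (%d participants, %d regions)",
        config$synthetic$n_participants, config$synthetic$n_regions)
    cohort <- generate_cohort(config$synthetic$n_participants,
                              config$synthetic$n_regions, seed = seed)
    write_cohort(cohort, cohort_dir)
    write_manifest(out_dir, phase, config)
    return(invisible(cohort_dir))
  }

  if (phase == "preprocess") {
    need_artifact(file.path(cohort_dir, "cohort.json"), "simulate_cohort")
    cohort <- read_cohort(cohort_dir)
    dataset <- twin_dataset(cohort, config$split$train_duration_s,
                            config$train$segment_len,
                            config$train$val_fraction)
    saveRDS(dataset, ds_path)
    write_manifest(out_dir, phase, config,
                   file.path(cohort_dir, "cohort.json"))
    return(invisible(ds_path))
  }

  dataset <- readRDS(need_artifact(ds_path, "preprocess"))
  cfg <- model_cfg_for(dataset)

  if (phase == "train") {
    tc <- train_config(segment_len = config$train$segment_len,
                       batch_size = config$train$batch_size,
                       lr = config$train$lr,
                       max_epochs = config$train$max_epochs,
                       early_stop_patience = config$train$early_stop_patience,
                       val_fraction = config$train$val_fraction,
                       seed = seed)
    lc <- loss_config(config$loss$lambda_action, config$loss$lambda_bold)
    say("training (%d epochs max)", tc$max_epochs)
    fit <- train_twin(dataset, cfg, lc, tc, verbose = verbose)
    # wall time is reported but not persisted, keeping the artifact
    # byte-reproducible under a fixed config
    saveRDS(fit[setdiff(names(fit), "wall_time_s")], ck_path)
    utils::write.csv(fit$log, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, phase, config, ds_path)
    return(invisible(ck_path))
  }

  if (phase == "glm") {
    # group GLM on the observed (synthetic) BOLD, per task and region
    rows <- list()
    for (task in dataset$tasks) {
      contrast <- if (task == "emotional_faces") "face>shape"
                  else "incongruent>congruent"
      tmat <- sapply(dataset$participants, function(part) {
        half <- part$tasks[[task]]$test
        design <- build_design(local_events(half), nrow(half$B),
                               half$step_s)
        contrast_tstats(design, half$B, contrast)
      })
      for (r in seq_len(nrow(tmat))) {
        gt <- group_ttest(tmat[r, ])
        rows[[length(rows) + 1]] <- data.frame(
          task = task, region = dataset$region_labels[r],
          contrast = contrast, mean_t = gt$mean, group_t = gt$t, p = gt$p)
      }
    }
    out <- do.call(rbind, rows)
    path <- file.path(out_dir, "glm_group.tsv")
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(out_dir, phase, config, ds_path)
    return(invisible(path))
  }

  fit <- readRDS(need_artifact(ck_path, "train"))

  if (phase == "evaluate") {
    ev <- evaluate_twin(fit$hp, dataset, cfg)
    path <- file.path(out_dir, "metrics.tsv")
    utils::write.table(ev$per_participant, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    summ <- list(rt_cor = as.list(ev$rt_cor), bold_cor = ev$bold_cor,
                 concordance = as.list(ev$concordance))
    jsonlite::write_json(summ, file.path(out_dir, "metrics_summary.json"),
                         auto_unbox = TRUE)
    write_manifest(out_dir, phase, config, c(ds_path, ck_path))
    return(invisible(path))
  }

  if (phase == "pls") {
    ev <- evaluate_twin(fit$hp, dataset, cfg)
    ind <- list()
    for (kind in c("affective", "cognitive")) {
      ind[[kind]] <- tryCatch(
        twin_indicators(ev, dataset, kinds = kind,
                        threshold = config$pls$threshold %||% 0.5)[[kind]],
        error = function(e) {
          warning(sprintf("skipping %s indicator: %s", kind,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
    }
    ind <- Filter(Negate(is.null), ind)
    W <- build_wmain(fit$hp, dataset)
    lay <- main_param_layout(cfg)
    pls <- list()
    for (kind in names(ind)) {
      pls[[kind]] <- tryCatch(pls_direction(W, ind[[kind]], lay$hash),
                              error = function(e) {
        warning(sprintf("skipping %s vector: %s", kind, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    }
    pls <- Filter(Negate(is.null), pls)
    stop_ifnot(length(pls) > 0, "no usable functional indicator")
    saveRDS(list(pls = pls, indicators = ind), pls_path)
    z1 <- data.frame(participant = seq_along(pls[[1]]$z1))
    for (kind in names(pls)) z1[[paste0("z1_", kind)]] <- pls[[kind]]$z1
    utils::write.table(z1, file.path(out_dir, "latent_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(out_dir, phase, config, c(ds_path, ck_path))
    return(invisible(pls_path))
  }

  # intervene
  plsfit <- readRDS(need_artifact(pls_path, "pls"))$pls
  icfg <- config$intervention
  results <- list()
  for (kind in names(plsfit)) {
    pls <- plsfit[[kind]]
    spec <- intervention_spec(pls, alpha = icfg$alpha_sd * stats::sd(pls$z1))
    sgc <- smoothgrad_config(icfg$smoothgrad_samples, icfg$noise_level,
                             seed = derive_seed(seed, 7L))
    map <- smoothgrad_cohort(fit$hp, dataset, pls, sgc)
    n_reg <- length(dataset$region_labels)
    edges <- select_top_edges(map, icfg$sd_threshold,
                              edge_index_pairs(n_reg),
                              dataset$region_labels)
    utils::write.table(edges,
                       file.path(out_dir, paste0("targets_", kind, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    sim <- simulate_intervention(fit$hp, dataset, cfg, spec,
                                 threshold = icfg$threshold %||% 0.5)
    col <- paste0(c("pre_", "post_"), kind)
    es <- effect_sizes(sim[[col[1]]], sim[[col[2]]])
    sim$effect_size <- es$d
    utils::write.table(sim,
                       file.path(out_dir, paste0("intervention_", kind, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results[[kind]] <- list(frac_large = es$frac_large,
                            n_excluded = es$n_excluded,
                            alpha = spec$alpha)
  }
  jsonlite::write_json(results, file.path(out_dir, "intervention_summary.json"),
                       auto_unbox = TRUE)
  write_manifest(out_dir, phase, config, c(ds_path, ck_path, pls_path))
  invisible(file.path(out_dir, "intervention_summary.json"))
}

#' Compute both functional indicators from an evaluation result
#'
#' @param ev an [evaluate_twin()] result.
#' @param dataset the matching [twin_dataset()].
#' @param split which half the evaluation used.
#' @param threshold press detection threshold.
#' @param kinds which indicators to compute.
#' @return list with `affective` and/or `cognitive`
#'   `functional_indicator`s.
#' @export
twin_indicators <- function(ev, dataset, split = "test", threshold = 0.5,
                            kinds = c("affective", "cognitive")) {
  events_list <- lapply(dataset$tasks, function(task) {
    local_events(dataset$participants[[1]]$tasks[[task]][[split]])
  })
  names(events_list) <- dataset$tasks
  out <- list()
  if ("affective" %in% kinds) {
    bold_list <- lapply(ev$predictions, function(pr) {
      pr$emotional_faces$bold_pred
    })
    out$affective <- affective_indicator(bold_list,
                                         events_list$emotional_faces,
                                         dataset$region_labels,
                                         dataset$step_s)
  }
  if ("cognitive" %in% kinds) {
    action_list <- lapply(ev$predictions, function(pr) {
      lapply(pr, function(x) x$action_prob)
    })
    out$cognitive <- cognitive_indicator(action_list, events_list,
                                         dataset$step_s, threshold)
  }
  out
}
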