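# Shared toy world: 40 participants, 20 regions, 32/32 hidden units.
# Built lazily and cached for the whole test run; the trained twin is the
# most expensive fixture and is reused by the acceptance and training
# suites.
.toy <- new.env(parent = emptyenv())

toy_cohort <- function() {
  if (is.null(.toy$cohort)) {
    .toy$cohort <- generate_cohort(n_participants = 40, n_regions = 20,
                                   seed = 1)
  }
  .toy$cohort
}

toy_dataset <- function() {
  if (is.null(.toy$dataset)) {
    .toy$dataset <- twin_dataset(toy_cohort())
  }
  .toy$dataset
}

toy_model_cfg <- function() {
  ds <- toy_dataset()
  twin_config(n_in = length(ds$participants[[1]]$x),
              n_hidden_hyper = 32, n_hidden_main = 32, n_bold = 20)
}

toy_fit <- function() {
  if (is.null(.toy$fit)) {
    .toy$fit <- train_twin(toy_dataset(), toy_model_cfg(),
                           train_cfg = train_config(lr = 1e-3,
                                                    batch_size = 8,
                                                    max_epochs = 600,
                                                    early_stop_patience = 100,
                                                    seed = 1))
  }
  .toy$fit
}

toy_eval <- function() {
  if (is.null(.toy$eval)) {
    .toy$eval <- evaluate_twin(toy_fit()$hp, toy_dataset(), toy_model_cfg())
  }
  .toy$eval
}
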