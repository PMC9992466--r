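# Shared study configuration for the analysis scripts.
#
# One synthetic study population stands in for the restricted hospital
# data: 2,500 patients over 2009-2016 with leaf-level coding drift
# (stationary AR(1) log-frequency mixing plus sibling replacement) and an
# ontology-invariant outcome signal. All scripts derive their randomness
# from ROOT_SEED.

suppressMessages({
  library(ehrshift)
  library(data.table)
})

ROOT_SEED <- 20260924L
RESULTS_DIR <- file.path("results")

study_generator <- function(drift = TRUE) {
  generator_config(
    n_patients = 2500,
    year_range = c(2009, 2016),
    ontology = make_synthetic_ontology(2, 6), # 8 parent concepts, 48 leaves
    drift_magnitude = if (drift) 0.3 else 0,
    code_replacement_rate = if (drift) 0.1 else 0,
    seed = ROOT_SEED
  )
}

study_encoder <- function(architecture = "gru") {
  pretrain_config(
    architecture = architecture,
    code_embed_dim = 24, hidden_dim = 32, representation_dim = 48,
    max_epochs = 10, max_sequence_days = 20, batch_size = 16
  )
}

study_config <- function(tasks = c("long_los", "icu", "mortality",
                                   "readmission"),
                         ..., seed = ROOT_SEED) {
  experiment_config(
    generator = study_generator(),
    id_years = c(2009, 2012),
    ood_year_groups = list(c(2013, 2016)),
    split_fractions = c(train = 0.65, val = 0.15, test = 0.2),
    pretrain_cap = 800L,
    encoder = study_encoder(),
    architectures = "gru",
    tasks = tasks,
    n_boot = 1000L,
    min_count = 10L,
    seed = seed,
    ...
  )
}
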