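# Shared, lazily-computed model ensembles for the acceptance-level tests.
# All use the default-parameter network (N = 500) at desk-scale factor 100
# with 10-seed ensembles; several criteria read the same ensemble, so runs
# are cached for the duration of the test session.

acc_cache <- new.env(parent = emptyenv())

# NOTE: formals avoid any name a model_config argument could partially match
# (e.g. `k` would partially match a formal named `key`).
acc_cached <- function(cache_key, maker) {
  stopifnot(is.character(cache_key), length(cache_key) == 1L)
  if (is.null(acc_cache[[cache_key]])) acc_cache[[cache_key]] <- maker()
  acc_cache[[cache_key]]
}

ACC_SEED <- 2024L
ACC_SCALE <- 100L
ACC_ENSEMBLE <- 10L

acc_config <- function(seed_offset = 0L, ...) {
  rescale_for_desk(model_config(seed = ACC_SEED + seed_offset, ...),
                   ACC_SCALE)
}

acc_baseline_ensemble <- function(cache_key, n_days, seed_offset = 0L, ...) {
  acc_cached(cache_key, function() {
    run_protocol(acc_config(seed_offset, ...),
                 protocol_spec(list(baseline_phase(n_days)),
                               measure_every = 20L,
                               ensemble_size = ACC_ENSEMBLE))
  })
}

acc_deprivation_ensemble <- function(cache_key, seed_offset = 0L, ...) {
  acc_cached(cache_key, function() {
    run_protocol(acc_config(seed_offset, ...),
                 protocol_spec(list(deprivation_phase(28L)),
                               measure_every = 28L,
                               ensemble_size = ACC_ENSEMBLE))
  })
}

# ensemble summaries
ens_drift_at <- function(ens, day) {
  vapply(ens$runs, function(tr) {
    i <- match(day, tr$days)
    median(orientation_distance(tr$po[i, ], tr$po[1, ]))
  }, numeric(1))
}

ens_median_convergence <- function(ens) {
  vapply(ens$runs, function(tr)
    deprivation_analysis(tr)$median_convergence, numeric(1))
}

ens_spearman <- function(ens) {
  vapply(ens$runs, function(tr)
    as.numeric(deprivation_analysis(tr)$spearman), numeric(1))
}

# "moderate SNR" imaging conditions used by the estimator-recovery checks:
# peak response 0.6 dF/F against 0.2 dF/F frame noise (SNR 3).
acc_imaging_config <- function(n_neurons, seed, ...) {
  synthetic_config(n_neurons = n_neurons, session_days = 0L,
                   response_amplitude = 0.6, noise_sd = 0.2,
                   fraction_untuned = 0, frame_rate = 5,
                   seed = seed, ...)
}
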