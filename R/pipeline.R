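# End-to-end orchestration: YAML config -> validated configs -> staged runs
# (simulate imaging -> tuning analysis -> drift statistics; model simulation
# -> model analysis) with a reproducibility manifest per output directory.
# Tables are CSV (RFC 4180, '.' decimal), summaries JSON, angles degrees in
# [-90, 90) and 180-degree periodic.

pipeline_stages <- c("simulate-imaging", "analyze-tuning", "drift-stats",
                     "simulate-model", "model-analysis")

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent nested list) with sections
#' `imaging`, `analysis`, `drift`, `model`, `protocol`, checks every field
#' against the domain constructors, rejects unknown keys, and returns the
#' fully-constructed configuration objects with defaults filled. All
#' violations are reported together.
#'
#' @param config path to a YAML file, or a nested list.
#' @return list: `imaging` ([synthetic_config()]), `analysis` (list:
#'   `n_boot`, `alpha`, `contamination`), `drift` (list: `experienced`,
#'   `n_shuffle`), `model` ([model_config()], desk-rescaled when a `scale`
#'   key is present), `protocol` ([protocol_spec()]).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' does not exist", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  known_sections <- c("imaging", "analysis", "drift", "model", "protocol")
  unknown <- setdiff(names(config), known_sections)
  if (length(unknown) > 0)
    note(sprintf("unknown section(s): %s", paste(unknown, collapse = ", ")))

  build <- function(section, constructor, extra_keys = character()) {
    args <- config[[section]]
    if (is.null(args)) args <- list()
    allowed <- setdiff(names(formals(constructor)), "...")
    bad <- setdiff(names(args), c(allowed, extra_keys))
    if (length(bad) > 0) {
      note(sprintf("section '%s': unknown key(s): %s", section,
                   paste(bad, collapse = ", ")))
      return(NULL)
    }
    tryCatch(do.call(constructor, args[setdiff(names(args), extra_keys)]),
             error = function(e)
               note(sprintf("section '%s': %s", section,
                            conditionMessage(e))))
  }

  imaging <- build("imaging", synthetic_config)

  analysis <- config$analysis
  if (is.null(analysis)) analysis <- list()
  bad <- setdiff(names(analysis), c("n_boot", "alpha", "contamination"))
  if (length(bad) > 0)
    note(sprintf("section 'analysis': unknown key(s): %s",
                 paste(bad, collapse = ", ")))
  analysis <- list(
    n_boot = if (is.null(analysis$n_boot)) 1000L else as.integer(analysis$n_boot),
    alpha = if (is.null(analysis$alpha)) 0.05 else analysis$alpha,
    contamination = if (is.null(analysis$contamination)) 0.7
                    else analysis$contamination)
  if (analysis$n_boot < 100L) note("section 'analysis': n_boot must be >= 100")
  if (analysis$alpha <= 0 || analysis$alpha >= 1)
    note("section 'analysis': alpha must lie in (0, 1)")

  drift <- config$drift
  if (is.null(drift)) drift <- list()
  bad <- setdiff(names(drift), c("experienced", "n_shuffle"))
  if (length(bad) > 0)
    note(sprintf("section 'drift': unknown key(s): %s",
                 paste(bad, collapse = ", ")))
  drift <- list(
    experienced = drift$experienced,
    n_shuffle = if (is.null(drift$n_shuffle)) 1000L
                else as.integer(drift$n_shuffle))

  model <- build("model", model_config, extra_keys = "scale")
  if (!is.null(model) && !is.null(config$model$scale)) {
    model <- tryCatch(rescale_for_desk(model, config$model$scale),
                      error = function(e)
                        note(sprintf("section 'model': %s",
                                     conditionMessage(e))))
  }

  prot <- config$protocol
  if (is.null(prot)) prot <- list()
  bad <- setdiff(names(prot), c("type", "n_days", "theta_hat", "period_days",
                                "exposure_stimuli", "measure_every",
                                "ensemble_size"))
  if (length(bad) > 0)
    note(sprintf("section 'protocol': unknown key(s): %s",
                 paste(bad, collapse = ", ")))
  protocol <- tryCatch({
    type <- if (is.null(prot$type)) "baseline" else prot$type
    n_days <- if (is.null(prot$n_days)) 20L else as.integer(prot$n_days)
    phase <- switch(type,
      baseline = baseline_phase(n_days),
      deprivation = deprivation_phase(n_days, prot$theta_hat),
      interrupted_deprivation = interrupted_deprivation_phase(
        n_days, prot$theta_hat,
        if (is.null(prot$period_days)) 7L else prot$period_days,
        prot$exposure_stimuli),
      stop(sprintf("unknown protocol type '%s'", type)))
    protocol_spec(list(phase),
      measure_every = if (is.null(prot$measure_every)) 7L
                      else prot$measure_every,
      ensemble_size = if (is.null(prot$ensemble_size)) 1L
                      else prot$ensemble_size)
  }, error = function(e) note(sprintf("section 'protocol': %s",
                                      conditionMessage(e))))

  if (length(errors) > 0)
    stop("invalid pipeline config:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  list(imaging = imaging, analysis = analysis, drift = drift,
       model = model, protocol = protocol)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' `simulate-imaging` -> `analyze-tuning` -> `drift-stats` for the imaging
#' arm, `simulate-model` -> `model-analysis` for the model arm. Each stage
#' writes CSV/JSON artifacts into `out_dir`; a single `manifest.json`
#' (command, config hash, seeds, outputs, package version, timestamp) makes
#' runs reproducible — identical config and seed give identical tables.
#' A missing upstream artifact raises a dependency error.
#'
#' @param config path to a YAML config or a nested list (see
#'   [validate_config()]).
#' @param stages subset of
#'   `c("simulate-imaging", "analyze-tuning", "drift-stats",
#'   "simulate-model", "model-analysis")`.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the seeds in the config.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the manifest and per-stage summaries.
#' @export
run_pipeline <- function(config, stages = pipeline_stages,
                         out_dir = "podrift-out", seed = NULL,
                         quiet = FALSE) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]  # dependency order
  cfg <- validate_config(config)
  if (!is.null(seed)) {
    cfg$imaging$seed <- as.integer(seed)
    cfg$model$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  need <- function(f, from) {
    if (!file.exists(path(f)))
      stop(sprintf("dependency error: '%s' not found; run stage '%s' first",
                   f, from), call. = FALSE)
    path(f)
  }
  summaries <- list()

  for (stage in stages) {
    t0 <- Sys.time()
    if (stage == "simulate-imaging") {
      exp <- generate_experiment(cfg$imaging)
      saveRDS(exp$sessions, path("sessions.rds"))
      gt <- cfg$imaging
      tp <- exp$ground_truth$true_po
      write.csv(data.frame(
        neuron = rep(seq_len(nrow(tp)), ncol(tp)),
        day = rep(gt$session_days, each = nrow(tp)),
        true_po_deg = as.vector(tp),
        true_width_deg = rep(exp$ground_truth$true_width, ncol(tp)),
        tuned = rep(exp$ground_truth$tuned_mask, ncol(tp))),
        path("ground_truth.csv"), row.names = FALSE)
      write.csv(exp$ground_truth$behavior, path("behavior.csv"),
                row.names = FALSE)
      summaries[[stage]] <- list(n_neurons = nrow(tp),
                                 n_sessions = ncol(tp))
    } else if (stage == "analyze-tuning") {
      sessions <- readRDS(need("sessions.rds", "simulate-imaging"))
      tuning <- analyze_tuning(sessions, n_boot = cfg$analysis$n_boot,
                               alpha = cfg$analysis$alpha,
                               contamination = cfg$analysis$contamination,
                               seed = cfg$imaging$seed)
      write.csv(tuning, path("tuning.csv"), row.names = FALSE)
      summaries[[stage]] <- list(
        n_tuned = sum(tuning$tuned),
        frac_responsive = mean(tuning$responsive))
    } else if (stage == "drift-stats") {
      tuning <- read.csv(need("tuning.csv", "analyze-tuning"))
      recs <- make_drift_records(tuning, experienced = cfg$drift$experienced)
      write.csv(recs, path("drift_records.csv"), row.names = FALSE)
      summ <- list(n_records = nrow(recs),
                   median_drift_magnitude = median(recs$drift_magnitude))
      if (!is.null(cfg$drift$experienced) && nrow(recs) > 0) {
        cs <- with_seed(cfg$imaging$seed, convergence_summary(recs))
        sh_m <- with_seed(cfg$imaging$seed + 1L,
                          shuffle_test(recs, "magnitude",
                                       cfg$drift$n_shuffle))
        sh_d <- with_seed(cfg$imaging$seed + 2L,
                          shuffle_test(recs, "direction",
                                       cfg$drift$n_shuffle))
        summ$convergence <- cs
        summ$shuffle_magnitude_ci <- c(sh_m$ci_low, sh_m$ci_high)
        summ$shuffle_direction_ci <- c(sh_d$ci_low, sh_d$ci_high)
      }
      jsonlite::write_json(summ, path("drift_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      summaries[[stage]] <- summ
    } else if (stage == "simulate-model") {
      traj <- run_protocol(cfg$model, cfg$protocol)
      saveRDS(traj, path("model_traj.rds"))
      first <- if (inherits(traj, "drift_ensemble")) traj$runs[[1]] else traj
      write.csv(data.frame(
        day = rep(first$days, ncol(first$po)),
        neuron = rep(seq_len(ncol(first$po)), each = nrow(first$po)),
        po_deg = as.vector(first$po)),
        path("model_po.csv"), row.names = FALSE)
      summaries[[stage]] <- list(
        days = max(first$days),
        conservation_max = first$conservation_max)
    } else if (stage == "model-analysis") {
      traj <- readRDS(need("model_traj.rds", "simulate-model"))
      runs <- if (inherits(traj, "drift_ensemble")) traj$runs else list(traj)
      has_depr <- any(vapply(runs[[1]]$theta_hat,
                             Negate(is.null), logical(1)))
      summ <- list(
        n_runs = length(runs),
        median_drift_magnitude = mean(vapply(runs, function(r)
          utils::tail(trajectory_drift_magnitude(r)$median_drift, 1),
          numeric(1))))
      if (has_depr) {
        das <- lapply(runs, deprivation_analysis)
        summ$median_convergence <- mean(vapply(das, function(d)
          d$median_convergence, numeric(1)))
        summ$spearman_initial_rpo_vs_drift <- mean(vapply(das, function(d)
          as.numeric(d$spearman), numeric(1)))
        sh <- with_seed(cfg$model$seed, list(
          magnitude = shuffle_test(das[[1]]$records, "magnitude",
                                   cfg$drift$n_shuffle),
          direction = shuffle_test(das[[1]]$records, "direction",
                                   cfg$drift$n_shuffle)))
        summ$shuffle_magnitude_ci <- c(sh$magnitude$ci_low,
                                       sh$magnitude$ci_high)
        summ$shuffle_direction_ci <- c(sh$direction$ci_low,
                                       sh$direction$ci_high)
      }
      jsonlite::write_json(summ, path("model_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      summaries[[stage]] <- summ
    }
    pipeline_log(quiet, "stage %-16s done in %.1fs", stage,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(config_fingerprint(cfg), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    command = "run_pipeline", stages = stages,
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = if (is.null(seed)) cfg$imaging$seed else as.integer(seed),
    out_dir = normalizePath(out_dir),
    package_version = as.character(utils::packageVersion("podrift")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  unlink(cfg_json)
  invisible(list(manifest = manifest, summaries = summaries))
}

# Stable, serializable view of the validated config for hashing.
config_fingerprint <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}
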