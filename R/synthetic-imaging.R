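# Synthetic trial-structured calcium-imaging experiments with known ground
# truth. The generator emulates a chronic drifting-grating protocol: gratings
# moving in n_directions directions (default 12, tiling 360 deg), stim_duration
# s of stimulus separated by isi_duration s of gray screen, n_reps repetitions
# per direction per session, sessions on given day indices. Neurons carry a
# circular-Gaussian orientation tuning curve (period 180 deg) whose preferred
# orientation may drift across days.

#' Configuration for a synthetic imaging experiment
#'
#' Builds and validates the parameter set consumed by
#' [generate_experiment()]. Defaults mirror a typical chronic two-photon
#' protocol: 12 drifting-grating directions, 32 repetitions, 5 s stimulus,
#' 6 s inter-stimulus interval.
#'
#' @param n_neurons number of neurons.
#' @param session_days integer day indices of the sessions, strictly
#'   increasing. Length defines the number of sessions.
#' @param n_directions number of grating directions, even and >= 4, tiling
#'   360 degrees uniformly.
#' @param n_reps repetitions per direction per session.
#' @param frame_rate imaging frame rate, Hz.
#' @param stim_duration,isi_duration stimulus and inter-stimulus durations, s.
#'   The trial window keeps 2 s of the ISI before stimulus onset; the final
#'   1 s of it is the pre-stimulus baseline window.
#' @param tuning_width_log_mean,tuning_width_log_sd meanlog/sdlog (log-degrees)
#'   of the log-normal tuning-width distribution.
#' @param response_amplitude peak stimulus response of a tuned neuron, dF/F
#'   units.
#' @param noise_sd additive frame noise, dF/F units. Also scales the shared
#'   neuropil fluctuation, so `noise_sd = 0` yields an exactly invertible
#'   noiseless experiment.
#' @param neuropil_contamination fraction of the neuropil signal mixed into the
#'   somatic trace; keep at 0.7 to match the analysis-side correction.
#' @param drift_model list describing how the true preferred orientation
#'   evolves per day: `list(type = "none")`,
#'   `list(type = "random_walk", step_sd = )`, or
#'   `list(type = "biased_walk", step_sd = , target_orientation = ,
#'   bias_strength = )`.
#' @param fraction_untuned fraction of neurons with zero stimulus response.
#' @param behavior_gain multiplicative response-gain modulation by the
#'   (log, z-scored) running speed; 0 disables behavioral modulation. The gain
#'   is preferred-orientation preserving.
#' @param baseline_f mean somatic baseline fluorescence, arbitrary units.
#' @param seed integer seed; identical seeds give bit-identical experiments.
#' @return a validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_neurons = 100L,
                             session_days = c(0L, 20L),
                             n_directions = 12L,
                             n_reps = 32L,
                             frame_rate = 10,
                             stim_duration = 5,
                             isi_duration = 6,
                             tuning_width_log_mean = log(25),
                             tuning_width_log_sd = 0.25,
                             response_amplitude = 1,
                             noise_sd = 0.2,
                             neuropil_contamination = 0.7,
                             drift_model = list(type = "none"),
                             fraction_untuned = 0.2,
                             behavior_gain = 0.2,
                             baseline_f = 100,
                             seed = 1L) {
  cfg <- list(
    n_neurons = as.integer(n_neurons), session_days = as.integer(session_days),
    n_directions = as.integer(n_directions), n_reps = as.integer(n_reps),
    frame_rate = frame_rate, stim_duration = stim_duration,
    isi_duration = isi_duration,
    tuning_width_log_mean = tuning_width_log_mean,
    tuning_width_log_sd = tuning_width_log_sd,
    response_amplitude = response_amplitude, noise_sd = noise_sd,
    neuropil_contamination = neuropil_contamination,
    drift_model = drift_model, fraction_untuned = fraction_untuned,
    behavior_gain = behavior_gain, baseline_f = baseline_f,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid synthetic_config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (cfg$n_neurons < 1L) fail("n_neurons", "must be >= 1")
  if (length(cfg$session_days) < 1L) fail("session_days", "must be non-empty")
  if (is.unsorted(cfg$session_days, strictly = TRUE))
    fail("session_days", "must be strictly increasing")
  if (cfg$n_directions < 4L || cfg$n_directions %% 2L != 0L)
    fail("n_directions", "must be even and >= 4")
  if (cfg$n_reps < 1L) fail("n_reps", "must be >= 1")
  for (f in c("frame_rate", "stim_duration", "isi_duration",
              "tuning_width_log_sd", "response_amplitude", "baseline_f")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      fail(f, "must be a single strictly positive number")
  }
  if (cfg$isi_duration < 1) fail("isi_duration", "must be >= 1 s (baseline window)")
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  for (f in c("neuropil_contamination", "fraction_untuned")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must lie in [0, 1]")
  }
  dm <- cfg$drift_model
  if (!is.list(dm) || is.null(dm$type) ||
      !dm$type %in% c("none", "random_walk", "biased_walk"))
    fail("drift_model", "type must be one of none, random_walk, biased_walk")
  if (dm$type != "none" && (is.null(dm$step_sd) || dm$step_sd < 0))
    fail("drift_model", "needs step_sd >= 0")
  if (dm$type == "biased_walk" &&
      (is.null(dm$target_orientation) || is.null(dm$bias_strength) ||
       dm$bias_strength < 0))
    fail("drift_model", "biased_walk needs target_orientation and bias_strength >= 0")
  invisible(cfg)
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' One step of a (possibly biased) orientation random walk
#'
#' Advances a preferred orientation by one day: a Gaussian step of sd
#' `step_sd` whose mean is `bias_strength` times the signed circular distance
#' from `po` toward `target`. With `bias_strength = 0` this is a pure random
#' walk; at `po == target` the expected step is zero.
#'
#' @param po current orientations, degrees.
#' @param target target orientation, degrees.
#' @param step_sd per-day step standard deviation, degrees.
#' @param bias_strength fraction (>= 0) of the remaining distance covered per
#'   day in expectation.
#' @return updated orientations wrapped to \[-90, 90). Uses the current R RNG
#'   stream.
#' @export
biased_walk_step <- function(po, target, step_sd, bias_strength) {
  if (bias_strength < 0) stop("bias_strength must be >= 0", call. = FALSE)
  drift <- bias_strength * orientation_diff(target, po)
  step <- if (step_sd > 0) rnorm(length(po), 0, step_sd) else 0
  wrap_orientation(po + drift + step)
}

# Evolve true POs across sessions; one step per elapsed day.
evolve_pos <- function(po0, session_days, drift_model) {
  n_sessions <- length(session_days)
  pos <- matrix(NA_real_, length(po0), n_sessions)
  pos[, 1] <- po0
  if (n_sessions == 1L || drift_model$type == "none") {
    pos[] <- po0
    return(pos)
  }
  cur <- po0
  for (s in 2:n_sessions) {
    for (d in seq_len(session_days[s] - session_days[s - 1])) {
      cur <- switch(drift_model$type,
        random_walk = wrap_orientation(cur + rnorm(length(cur), 0, drift_model$step_sd)),
        biased_walk = biased_walk_step(cur, drift_model$target_orientation,
                                       drift_model$step_sd, drift_model$bias_strength)
      )
    }
    pos[, s] <- cur
  }
  pos
}

# Circular-Gaussian orientation tuning curve, period 180 deg, peak 1.
tuning_curve <- function(theta, po, width) {
  d <- orientation_distance(theta, po)
  exp(-d^2 / (2 * width^2))
}

#' Generate a synthetic chronic imaging experiment
#'
#' Simulates per-session trial tensors (raw somatic and neuropil fluorescence,
#' neuron x trial x frame) plus the generating ground truth. Tuned neurons
#' respond with a circular-Gaussian orientation tuning curve atop a baseline;
#' the shared neuropil signal is mixed into the somatic trace with the
#' configured contamination fraction; frame noise is additive Gaussian.
#' Running speed modulates response gain multiplicatively
#' (preferred-orientation preserving). Identical configs (same seed) give
#' bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return list with elements
#'   \describe{
#'     \item{sessions}{list of `"trial_tensor"` objects, one per session, with
#'       fields `raw_f`, `neuropil_f` (neuron x trial x frame), `stim_label`
#'       (direction, degrees in \[0, 360)), `pre_window`, `stim_window` (frame
#'       indices), `day`, `frame_rate`. Neuron ordering is identical across
#'       sessions.}
#'     \item{ground_truth}{list with `true_po` (neuron x session matrix,
#'       degrees in \[-90, 90)), `true_width`, `tuned_mask`, `baseline_f`, and
#'       `behavior` (data.frame: session, trial, running, pupil, gain).}
#'   }
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_experiment_impl(config))
}

generate_experiment_impl <- function(cfg) {
  n <- cfg$n_neurons
  n_sessions <- length(cfg$session_days)
  directions <- seq(0, 360 - 360 / cfg$n_directions,
                    by = 360 / cfg$n_directions)
  n_trials <- cfg$n_directions * cfg$n_reps

  # frames: 2 s of ISI kept before onset; last 1 s is the baseline window
  pre_seg <- round(min(2, cfg$isi_duration) * cfg$frame_rate)
  base_fr <- round(1 * cfg$frame_rate)
  stim_fr <- round(cfg$stim_duration * cfg$frame_rate)
  n_frames <- pre_seg + stim_fr
  pre_window <- (pre_seg - base_fr + 1L):pre_seg
  stim_window <- (pre_seg + 1L):n_frames

  # ground truth
  po0 <- runif(n, -90, 90)
  true_width <- rlnorm(n, cfg$tuning_width_log_mean, cfg$tuning_width_log_sd)
  tuned_mask <- runif(n) >= cfg$fraction_untuned
  true_po <- evolve_pos(po0, cfg$session_days, cfg$drift_model)
  f0 <- cfg$baseline_f * rlnorm(n, 0, 0.2)
  amp <- ifelse(tuned_mask, cfg$response_amplitude, 0)

  stim_ind <- c(rep(0, pre_seg), rep(1, stim_fr))
  np0 <- 0.3 * cfg$baseline_f

  sessions <- vector("list", n_sessions)
  behavior <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    stim_label <- sample(rep(directions, cfg$n_reps))

    running <- rlnorm(n_trials, log(5), 0.6)
    z_run <- as.numeric(scale(log(running)))
    pupil <- 1.5 + 0.2 * z_run + rnorm(n_trials, 0, 0.15)
    gain <- exp(cfg$behavior_gain * z_run)
    behavior[[s]] <- data.frame(session = s, trial = seq_len(n_trials),
                                running = running, pupil = pupil, gain = gain)

    # per-trial tuned response (dF/F peak units)
    resp <- (amp * t(tuning_curve(
      matrix(stim_label, n_trials, n, byrow = FALSE),
      matrix(true_po[, s], n_trials, n, byrow = TRUE),
      matrix(true_width, n_trials, n, byrow = TRUE)
    ))) * rep(gain, each = n)  # n x n_trials

    # shared neuropil: slow oscillation + white noise, both scaled by noise_sd
    tt <- seq_len(n_trials * n_frames) / cfg$frame_rate
    np_fluct <- cfg$noise_sd * np0 *
      (0.5 * sin(2 * pi * tt / 300) +
         (if (cfg$noise_sd > 0) 0.5 * rnorm(length(tt)) else 0))
    np_mat <- matrix(np0 + np_fluct, n_trials, n_frames, byrow = TRUE)

    # somatic trace, neuron x (trial*frame), frame fastest
    tr_of_col <- rep(seq_len(n_trials), each = n_frames)
    fr_of_col <- rep(seq_len(n_frames), n_trials)
    sig <- resp[, tr_of_col, drop = FALSE] *
      rep(stim_ind[fr_of_col], each = n)
    raw <- f0 * (1 + sig)
    np_row <- as.numeric(t(np_mat))  # trial-major, frame fastest
    raw <- raw + cfg$neuropil_contamination *
      rep(np_row - np0, each = n)
    if (cfg$noise_sd > 0) {
      raw <- raw + f0 * cfg$noise_sd * matrix(rnorm(length(raw)), nrow = n)
    }
    np_full <- matrix(np_row, n, length(np_row), byrow = TRUE)

    to_tensor <- function(m) {
      aperm(array(m, c(n, n_frames, n_trials)), c(1, 3, 2))
    }
    sessions[[s]] <- structure(list(
      raw_f = to_tensor(raw), neuropil_f = to_tensor(np_full),
      stim_label = stim_label, pre_window = pre_window,
      stim_window = stim_window, day = cfg$session_days[s],
      frame_rate = cfg$frame_rate
    ), class = "trial_tensor")
  }

  list(
    sessions = sessions,
    ground_truth = list(
      true_po = true_po, true_width = true_width, tuned_mask = tuned_mask,
      baseline_f = f0, behavior = do.call(rbind, behavior)
    )
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$raw_f)
  cat(sprintf(
    "<trial_tensor> day %d: %d neurons, %d trials, %d frames (%.1f Hz)\n",
    x$day, d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}
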