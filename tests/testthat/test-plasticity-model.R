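# Small-scale configs: n = 100 neurons and 30 stimuli/day (desk factor 1440)
# keep the qualitative property runs fast; quantitative claims about the
# default-scale model live in the acceptance tests.
small_cfg <- function(seed = 1L, n = 100L, c = 1440L, ...) {
  rescale_for_desk(model_config(n = n, seed = seed, ...), c)
}

test_that("model config validation names the offending field", {
  expect_error(model_config(epsilon = -1), "epsilon")
  expect_error(model_config(k = 1.5), "k")
  expect_error(model_config(n = 1), "'n'")
  expect_error(model_config(noise_sd = -0.1), "noise_sd")
  expect_error(model_config(stimuli_per_day = 0), "stimuli_per_day")
})

test_that("default protocol constants match the experiment they emulate", {
  cfg <- model_config()
  # one stimulus per second for 12 waking hours
  expect_identical(cfg$stimuli_per_day, 60L * 60L * 12L)
  expect_identical(cfg$stimuli_per_day, 43200L)
  expect_equal(cfg$epsilon, 1e-4)
  expect_equal(cfg$n, 500L)
  expect_equal(cfg$propensity_gain, 10)
})

test_that("desk rescaling preserves per-day Hebbian and diffusion scales", {
  cfg <- model_config()
  expect_identical(rescale_for_desk(cfg, 1L), cfg)
  r <- rescale_for_desk(cfg, 100L)
  expect_equal(r$epsilon * r$stimuli_per_day,
               cfg$epsilon * cfg$stimuli_per_day)
  expect_equal(r$epsilon * r$noise_sd * sqrt(r$stimuli_per_day),
               cfg$epsilon * cfg$noise_sd * sqrt(cfg$stimuli_per_day))
  expect_equal(r$parity_sd, cfg$parity_sd)  # calibration target untouched
  expect_error(rescale_for_desk(cfg, 7L), "divide")
})

test_that("presynaptic tuning curves peak at their centers and tile uniformly", {
  cfg <- podrift:::resolve_calibration(model_config(n = 500L))
  ctr <- podrift:::presyn_centers(500L)
  u <- presyn_response(ctr[250], cfg)
  expect_equal(which.max(u), 250L)
  expect_equal(max(u), cfg$presyn_offset + cfg$presyn_amplitude)
  # symmetry around the stimulated orientation
  u2 <- presyn_response(10, cfg)
  d <- orientation_distance(10, ctr)
  expect_equal(u2[order(d)][1:20], sort(u2, decreasing = TRUE)[1:20])
  # translation invariance of the population rate (< 1% ripple)
  sums <- vapply(seq(-90, 89, by = 7.7),
                 function(th) sum(presyn_response(th, cfg)), numeric(1))
  expect_lt(diff(range(sums)) / mean(sums), 0.01)
})

test_that("forward response matches a double-loop oracle", {
  cfg <- podrift:::resolve_calibration(model_config(n = 6L, seed = 2L))
  state <- init_network(cfg)
  expect_equal(forward(state, rep(0, 6)), rep(0, 6))
  w <- matrix(0, 6, 6); w[3, 5] <- 1
  state$w <- w
  u <- runif(6)
  expect_equal(forward(state, u)[5], u[3])
  set.seed(3)
  state$w <- matrix(runif(36, 0, 0.1), 6)
  u <- runif(6)
  v <- forward(state, u)
  for (i in 1:6) {
    s <- 0
    for (j in 1:6) s <- s + state$w[j, i] * u[j]
    expect_equal(v[i], s, tolerance = 1e-12)
  }
})

test_that("plasticity step follows the learning rule exactly (scalar oracle)", {
  cfg <- model_config(n = 2L, noise_sd = 0, parity_sd = 1,
                      presyn_amplitude = 2, presyn_offset = 0.5,
                      epsilon = 1e-4, seed = 4L)
  state <- init_network(cfg)
  state$w <- matrix(c(0.5, 0.2, 0.1, 0.7), 2)
  theta <- 17
  u <- presyn_response(theta, state)
  v <- as.numeric(t(state$w) %*% u)
  after <- plasticity_step(state, theta)
  for (j in 1:2) for (i in 1:2) {
    dw <- 1e-4 * tanh(10 * state$w[j, i]) * (u[j] * v[i])
    expect_equal(after$w[j, i], state$w[j, i] + dw, tolerance = 1e-14)
  }
  # single-synapse magnitude check against a hand-evaluated number:
  # w = 0.5, u = 2, v = 3, xi = 0.1 => dw = 1e-4 * tanh(5) * 6.1
  # tanh(5) = 0.9999092042625951, so dw = 6.0994461460018303e-4
  expect_equal(1e-4 * tanh(10 * 0.5) * (2 * 3 + 0.1),
               6.0994461460018303e-4, tolerance = 1e-15)
})

test_that("zero weights and disabled terms are exact fixed points", {
  cfg <- model_config(n = 4L, noise_sd = 1, parity_sd = 1,
                      presyn_amplitude = 1, presyn_offset = 0.1, seed = 5L)
  state <- init_network(cfg)
  state$w <- matrix(0, 4, 4)  # rho(0) = 0: frozen regardless of H and xi
  after <- podrift:::with_seed(1, plasticity_step(state, 0))
  expect_identical(after$w, state$w)
  # k = 0 and noise_sd = 0: nothing drives the weights
  cfg2 <- model_config(n = 4L, k = 0, noise_sd = 0, parity_sd = 1,
                       presyn_amplitude = 1, presyn_offset = 0.1, seed = 5L)
  st2 <- init_network(cfg2)
  expect_equal(plasticity_step(st2, 30)$w, st2$w)
})

test_that("divisive normalization: exact sums, idempotence, dead-neuron error", {
  cfg <- podrift:::resolve_calibration(model_config(n = 30L, seed = 6L))
  state <- init_network(cfg)
  set.seed(7)
  state$w <- matrix(runif(900, 0.01, 1), 30)
  norm1 <- normalize_incoming(state)
  expect_equal(colSums(norm1$w), rep(1, 30), tolerance = 1e-12)
  norm2 <- normalize_incoming(norm1)
  expect_equal(norm2$w, norm1$w, tolerance = 1e-15)
  # one incoming weight per neuron: becomes exactly 1
  state$w <- diag(0.37, 30)
  expect_equal(normalize_incoming(state)$w, diag(1, 30))
  state$w[, 4] <- 0
  expect_error(normalize_incoming(state), "4")
})

test_that("initialization: equal widths option, unit sums, PO = assigned center", {
  cfg0 <- podrift:::resolve_calibration(
    model_config(n = 80L, width_log_sd = 0, seed = 8L))
  st <- init_network(cfg0)
  expect_equal(sd(st$widths), 0)
  expect_equal(colSums(st$w), rep(1, 80), tolerance = 1e-12)
  expect_equal(measure_pos(st), st$assigned)
  # log-normal widths vary neuron to neuron
  st2 <- init_network(podrift:::resolve_calibration(
    model_config(n = 80L, seed = 8L)))
  expect_gt(sd(st2$widths), 0)
  expect_equal(measure_pos(st2), st2$assigned)
})

test_that("PO measurement is frozen, deterministic, and ties break to the smaller angle", {
  cfg <- podrift:::resolve_calibration(model_config(n = 40L, seed = 9L))
  st <- init_network(cfg)
  rng_before <- .Random.seed
  p1 <- measure_pos(st)
  p2 <- measure_pos(st)
  expect_identical(p1, p2)
  expect_identical(rng_before, .Random.seed)  # no RNG consumption
  # two equal-height weight peaks: argmax returns the smaller angle
  st$w[] <- 0
  i45 <- which.min(abs(st$presyn_centers - 45))
  im30 <- which.min(abs(st$presyn_centers + 30))
  st$w[i45, 1] <- 0.5; st$w[im30, 1] <- 0.5
  st$w[2:40, 2:40] <- diag(1, 39)  # keep other columns alive
  expect_equal(measure_pos(st)[1], st$presyn_centers[im30])
  expect_lt(st$presyn_centers[im30], 0)
})

test_that("compiled day kernel agrees with the R reference path when deterministic", {
  cfg <- small_cfg(seed = 10L, n = 40L, noise_sd = 0)
  cfg <- podrift:::resolve_calibration(cfg)
  state <- init_network(cfg)
  set.seed(11)
  thetas <- runif(60, -90, 90)
  w_cpp <- podrift:::.sim_day(state$w, state$presyn_centers, thetas,
                              cfg$presyn_amplitude, cfg$presyn_offset,
                              cfg$presyn_sigma, cfg$epsilon, cfg$k, 0,
                              cfg$propensity_gain, TRUE, 10, 0)
  st_ref <- state
  for (th in thetas) st_ref <- plasticity_step(st_ref, th)
  expect_equal(max(abs(w_cpp - st_ref$w)), 0, tolerance = 1e-9)
})

test_that("kernel noise stream is standard normal and seed-stable", {
  z <- podrift:::.kernel_normal_sample(200000L, 123)
  expect_identical(z, podrift:::.kernel_normal_sample(200000L, 123))
  expect_false(identical(z[1:10],
                         podrift:::.kernel_normal_sample(10L, 124)))
  expect_lt(abs(mean(z)), 0.01)
  expect_equal(sd(z), 1, tolerance = 0.01)
  expect_lt(abs(mean(z^3)), 0.03)              # skewness
  expect_equal(mean(z^4), 3, tolerance = 0.1)  # kurtosis
  expect_gt(suppressWarnings(stats::ks.test(z, "pnorm")$p.value), 1e-4)
})

test_that("kernel propensity table matches tanh to interpolation accuracy", {
  x <- c(seq(0, 25, length.out = 100000), 5, 1e-8, 1e8)
  expect_lt(max(abs(podrift:::.rho_table(x) - tanh(x))), 1e-8)
  expect_equal(podrift:::.rho_table(-2), -tanh(2), tolerance = 1e-8)
})

test_that("kernel applies N(0, noise_sd^2) volatility through the propensity", {
  n <- 150L
  w0 <- matrix(0.4, n, n)  # large enough that clipping never triggers
  ctr <- podrift:::presyn_centers(n)
  w1 <- podrift:::.sim_day(w0, ctr, 0, 1, 0.1, 8, 1e-3, 0, 0.5, 10, TRUE,
                           77, 0)
  z <- (w1 - w0) / (1e-3 * tanh(10 * 0.4))
  expect_equal(sd(z), 0.5, tolerance = 0.02)
  expect_lt(abs(mean(z)), 0.01)
})

test_that("parity calibration is closed-form, homogeneous, and guards sd = 0", {
  cfg <- model_config(n = 100L, seed = 12L)
  cal <- calibrate_hebbian_noise_parity(cfg)
  expect_equal(cal$measured_ratio, 1, tolerance = 1e-10)
  expect_equal(cal$presyn_offset / cal$presyn_amplitude, cfg$offset_ratio)
  # doubling the volatility sd doubles the Hebbian magnitude (amp x sqrt(2))
  cal2 <- calibrate_hebbian_noise_parity(model_config(n = 100L, seed = 12L,
                                                      noise_sd = 2))
  expect_equal(cal2$presyn_amplitude / cal$presyn_amplitude, sqrt(2),
               tolerance = 1e-10)
  expect_error(
    calibrate_hebbian_noise_parity(model_config(n = 100L, noise_sd = 0)),
    "parity")
  # step-horizon target is sqrt(N_theta) larger than the day horizon
  cal_s <- calibrate_hebbian_noise_parity(cfg, horizon = "step")
  expect_equal(cal_s$presyn_amplitude / cal$presyn_amplitude,
               43200^0.25, tolerance = 1e-8)
})

test_that("protocols: frozen dynamics without drives, determinism, conservation", {
  prot <- protocol_spec(list(baseline_phase(4L)), measure_every = 2L)
  cfg <- small_cfg(seed = 13L, k = 0, noise_sd = 0, parity_sd = 1)
  tr <- run_protocol(cfg, prot)
  expect_s3_class(tr, "drift_trajectory")
  expect_equal(tr$days, c(0L, 2L, 4L))
  # k = 0 and noise_sd = 0: POs constant over any protocol
  expect_equal(tr$po[1, ], tr$po[2, ])
  expect_equal(tr$po[1, ], tr$po[3, ])
  # identical config twice: identical trajectory; conservation at 1e-12
  cfg2 <- small_cfg(seed = 14L)
  t1 <- run_protocol(cfg2, prot)
  t2 <- run_protocol(cfg2, prot)
  expect_identical(t1$po, t2$po)
  expect_lt(t1$conservation_max, 1e-12)
  expect_true(all(t1$state$w >= 0))
})

test_that("ensembles carry one independent trajectory per seed", {
  prot <- protocol_spec(list(baseline_phase(2L)), measure_every = 2L,
                        ensemble_size = 3L)
  ens <- run_protocol(small_cfg(seed = 15L), prot)
  expect_s3_class(ens, "drift_ensemble")
  expect_length(ens$runs, 3L)
  expect_false(identical(ens$runs[[1]]$po, ens$runs[[2]]$po))
  # member 1 equals a single run at the same seed
  single <- run_protocol(small_cfg(seed = 15L),
                         protocol_spec(list(baseline_phase(2L)),
                                       measure_every = 2L))
  expect_identical(ens$runs[[1]]$po, single$po)
})

test_that("volatility-only drift grows with interval and does not converge", {
  cfg <- small_cfg(seed = 16L, k = 0)
  tr <- run_protocol(cfg, protocol_spec(list(baseline_phase(24L)),
                                        measure_every = 8L))
  dm <- trajectory_drift_magnitude(tr)
  expect_true(all(diff(dm$median_drift) >= 0) ||
              dm$median_drift[4] > dm$median_drift[2])
  expect_gt(dm$median_drift[4], 0)
  da <- deprivation_analysis(tr, theta_hat = 20)
  expect_lt(abs(da$median_convergence), 5)
})

test_that("Hebbian-only deprivation converges toward the experienced orientation", {
  cfg <- small_cfg(seed = 17L, noise_sd = 0, parity_sd = 1)
  tr <- run_protocol(cfg, protocol_spec(
    list(deprivation_phase(60L, theta_hat = 20)), measure_every = 30L))
  da <- deprivation_analysis(tr)
  expect_gt(da$median_convergence, 1)
  # baseline drift without volatility stays near the measurement grid
  trb <- run_protocol(cfg, protocol_spec(list(baseline_phase(20L)),
                                         measure_every = 20L))
  expect_lt(trajectory_drift_magnitude(trb)$median_drift[2], 2)
})

test_that("interrupted deprivation converges more slowly than uninterrupted", {
  # noise-free Hebbian transport with a fine measurement grid isolates the
  # protocol effect; interruption days replace deprivation with a full day
  # of uniformly drawn (plasticity-active) stimuli
  conv <- sapply(18:20, function(s) {
    cfg <- small_cfg(seed = s, noise_sd = 0, parity_sd = 1, grid_step = 0.2)
    un <- run_protocol(cfg, protocol_spec(
      list(deprivation_phase(28L, theta_hat = 10)), measure_every = 28L))
    int <- run_protocol(cfg, protocol_spec(
      list(interrupted_deprivation_phase(28L, theta_hat = 10,
                                         period_days = 7L,
                                         exposure_stimuli = 30L)),
      measure_every = 28L))
    c(deprivation_analysis(un, 10)$median_convergence,
      deprivation_analysis(int, 10)$median_convergence)
  })
  expect_true(all(conv[1, ] > conv[2, ]))
})

test_that("recovery after deprivation is incomplete", {
  seeds <- 23:27
  resid <- sapply(seeds, function(s) {
    tr <- run_protocol(small_cfg(seed = s), protocol_spec(list(
      deprivation_phase(28L, theta_hat = 0), baseline_phase(28L)),
      measure_every = 28L))
    rpo0 <- orientation_distance(tr$po[1, ], 0)
    rpo_end <- orientation_distance(tr$po[nrow(tr$po), ], 0)
    median(rpo0) - median(rpo_end)
  })
  # residual attraction toward the deprived orientation persists
  expect_gt(mean(resid), 0)
})

test_that("baseline drift rate is stationary across days", {
  cfg <- small_cfg(seed = 28L, n = 150L)
  tr <- run_protocol(cfg, protocol_spec(list(baseline_phase(15L)),
                                        measure_every = 1L))
  dr <- trajectory_drift_rate(tr)
  fit <- stats::lm(mean_rate ~ day, data = dr)
  slope <- summary(fit)$coefficients["day", ]
  # slope indistinguishable from zero at the 99% level
  expect_gt(2 * stats::pt(-abs(slope["t value"]), df = nrow(dr) - 2), 0.01)
})

test_that("deprivation analysis handles degenerate and perfectly-correlated cases", {
  po0 <- seq(-80, 80, length.out = 30)
  traj <- structure(list(
    po = rbind(po0, wrap_orientation(po0 + 5)),
    days = c(0L, 28L), phase_of_day = c("warmup_end", "deprivation"),
    theta_hat = list(0), conservation_max = 0,
    state = NULL, config = NULL, protocol = NULL),
    class = "drift_trajectory")
  da <- deprivation_analysis(traj)
  expect_equal(attr(da$spearman, "flag"), "degenerate_ranks")
  expect_equal(as.numeric(da$spearman), 0)
  # drift magnitude exactly equal to initial |rPO|: Spearman 1
  po_start <- runif(30, 10, 80)
  traj2 <- traj
  traj2$po <- rbind(po_start, wrap_orientation(po_start - po_start / 2))
  # drift = po_start/2, monotone in rpo_pre = po_start
  da2 <- deprivation_analysis(traj2, theta_hat = 0)
  expect_equal(as.numeric(da2$spearman), 1)
})
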