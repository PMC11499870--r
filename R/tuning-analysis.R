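# From trial-structured fluorescence to per-session preferred-orientation
# (PO) estimates. Pipeline: neuropil-corrected dF/F -> per-trial window means
# (response matrix) -> rank-sum responsiveness test -> vector-sum PO with a
# bootstrap confidence interval and the tuned/untuned criterion.

#' Neuropil-corrected Delta F / F
#'
#' Computes
#' `(F(t) - c*(Fnp(t) - median(Fnp)) - F_base) / F_base`
#' where `F_base` is the median of the neuropil-corrected trace over the
#' concatenated 1 s pre-stimulus windows. Accepts a single trace (vector) or
#' one trace per row (matrix, neurons x time); `neuropil` must match.
#'
#' @param raw,neuropil fluorescence traces (vector or neurons x time matrix).
#' @param pre_index integer indices (into time) of the concatenated
#'   pre-stimulus baseline frames.
#' @param contamination neuropil contamination coefficient (default 0.7).
#' @return dF/F with the same shape as `raw`.
#' @export
compute_dff <- function(raw, neuropil, pre_index, contamination = 0.7) {
  vec <- is.null(dim(raw))
  if (vec) {
    raw <- matrix(raw, 1L)
    neuropil <- matrix(neuropil, 1L)
  }
  stopifnot(all(dim(raw) == dim(neuropil)))
  if (length(pre_index) < 1L)
    stop("at least one pre-stimulus frame is required", call. = FALSE)
  np_med <- apply(neuropil, 1L, median)
  corrected <- raw - contamination * (neuropil - np_med)
  base <- apply(corrected[, pre_index, drop = FALSE], 1L, median)
  if (any(base <= 0))
    stop(sprintf("degenerate baseline: non-positive median in %d trace(s)",
                 sum(base <= 0)), call. = FALSE)
  out <- (corrected - base) / base
  if (vec) as.numeric(out) else out
}

# dF/F for a whole trial_tensor: traces are concatenated trial-major so the
# baseline median pools every trial's pre-stimulus window of the session.
dff_tensor <- function(tt, contamination = 0.7) {
  d <- dim(tt$raw_f)
  n <- d[1]; n_trials <- d[2]; n_frames <- d[3]
  flat <- function(a) {
    dim(a) <- c(n, n_trials * n_frames)  # after aperm: frame fastest
    a
  }
  raw <- flat(aperm(tt$raw_f, c(1, 3, 2)))
  np <- flat(aperm(tt$neuropil_f, c(1, 3, 2)))
  pre_index <- as.integer(outer(tt$pre_window,
                                (seq_len(n_trials) - 1L) * n_frames, "+"))
  dff <- compute_dff(raw, np, pre_index, contamination)
  aperm(array(dff, c(n, n_frames, n_trials)), c(1, 3, 2))
}

#' Per-trial window means organised by direction and repetition
#'
#' Averages dF/F over the stimulus window (and the pre-stimulus window) of
#' every trial and arranges the result as neuron x direction x repetition
#' arrays, the shape consumed by the PO estimator.
#'
#' @param trials a `"trial_tensor"` (see [generate_experiment()]).
#' @param dff dF/F array of the same shape as `trials$raw_f`; computed from
#'   the tensor when omitted.
#' @param contamination passed to [compute_dff()] when `dff` is missing.
#' @return object of class `"response_matrix"`: list with `r` and `prestim`
#'   (neuron x n_stim x n_rep), `directions` (degrees), `n_stim`, `n_rep`.
#' @export
build_response_matrix <- function(trials, dff = NULL, contamination = 0.7) {
  stopifnot(inherits(trials, "trial_tensor"))
  if (is.null(dff)) dff <- dff_tensor(trials, contamination)
  stopifnot(all(dim(dff) == dim(trials$raw_f)))
  directions <- sort(unique(trials$stim_label))
  lab <- match(trials$stim_label, directions)
  if (anyNA(lab)) stop("trial with missing direction label", call. = FALSE)
  counts <- tabulate(lab, length(directions))
  if (length(unique(counts)) != 1L)
    stop("unequal repetition counts across directions", call. = FALSE)
  n_rep <- counts[1]
  n <- dim(dff)[1]

  stim_mean <- rowMeans(dff[, , trials$stim_window, drop = FALSE], dims = 2L)
  pre_mean <- rowMeans(dff[, , trials$pre_window, drop = FALSE], dims = 2L)

  r <- array(NA_real_, c(n, length(directions), n_rep))
  p <- array(NA_real_, c(n, length(directions), n_rep))
  for (s in seq_along(directions)) {
    idx <- which(lab == s)  # repetition order = order of occurrence
    r[, s, ] <- stim_mean[, idx, drop = FALSE]
    p[, s, ] <- pre_mean[, idx, drop = FALSE]
  }
  structure(list(r = r, prestim = p, directions = directions,
                 n_stim = length(directions), n_rep = n_rep),
            class = "response_matrix")
}

#' Visual responsiveness by rank-sum test
#'
#' For each neuron and direction, a two-sample Wilcoxon rank-sum test (normal
#' approximation with tie correction) compares stimulus-window means against
#' pre-stimulus-window means. A neuron is responsive if, for any direction,
#' the test is significant at `alpha / n_stim` (Bonferroni) and the
#' stimulus-window median exceeds the pre-stimulus median (responses must be
#' above baseline, not below).
#'
#' @param rm a `"response_matrix"`.
#' @param alpha family-wise significance level (default 0.05).
#' @return logical vector, one entry per neuron.
#' @export
responsiveness_test <- function(rm, alpha = 0.05) {
  stopifnot(inherits(rm, "response_matrix"))
  if (rm$n_rep < 2L)
    stop("responsiveness test needs at least 2 repetitions per direction",
         call. = FALSE)
  n <- dim(rm$r)[1]
  thr <- alpha / rm$n_stim
  out <- logical(n)
  for (i in seq_len(n)) {
    for (s in seq_len(rm$n_stim)) {
      x <- rm$r[i, s, ]; y <- rm$prestim[i, s, ]
      if (median(x) <= median(y)) next
      p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
      if (is.finite(p) && p < thr) { out[i] <- TRUE; break }
    }
  }
  out
}

#' Vector-sum preferred orientation
#'
#' The PO is half the angle of the response-weighted mean vector of the
#' doubled stimulus angles: with responses `R` and angles `theta` over all
#' direction x repetition entries,
#' `X = mean(R cos 2theta)`, `Y = mean(R sin 2theta)`,
#' `PO = atan2(Y, X) / 2`, wrapped to \[-90, 90). The two-argument
#' arctangent keeps the quadrant. Returns `NA` when `X = Y = 0` (perfectly
#' symmetric responses; no defined PO).
#'
#' @param rm a `"response_matrix"`.
#' @param neuron neuron index.
#' @return PO in degrees in \[-90, 90), or `NA`.
#' @export
vector_sum_po <- function(rm, neuron) {
  stopifnot(inherits(rm, "response_matrix"))
  R <- rm$r[neuron, , ]
  th <- 2 * rm$directions * pi / 180
  X <- mean(R * cos(th))
  Y <- mean(R * sin(th))
  # resultant indistinguishable from zero at floating precision (relative to
  # the response scale): perfectly symmetric responses, no defined PO
  if (sqrt(X^2 + Y^2) <= 1e-12 * max(mean(abs(R)), .Machine$double.xmin))
    return(NA_real_)
  wrap_orientation(atan2(Y, X) / 2 * 180 / pi)
}

#' Bootstrap PO estimate with circular confidence interval
#'
#' Repetitions are resampled with replacement (`n_boot` times, jointly across
#' directions); each resample yields a vector-sum PO. The point estimate is
#' the circular mean (period 180 deg) of the bootstrap distribution. For the
#' 95% interval, bootstrap angles are doubled, centered on the doubled
#' circular mean, percentiled at 2.5/97.5, and halved back, which avoids
#' branch-cut artifacts near +-90 deg. A neuron is orientation-tuned when the
#' interval width is at most 90 deg.
#'
#' @param rm a `"response_matrix"`.
#' @param neuron neuron index.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param resample `"joint"` (default) draws one set of repetition indices
#'   shared by all directions; `"per_direction"` draws independently per
#'   direction.
#' @return list of class `"tuning_result"`: `po`, `ci_low`, `ci_high`,
#'   `ci_width` (degrees), `tuned`, `n_boot`, `n_undefined` (resamples with no
#'   defined PO; if more than half, `po` is `NA` and `tuned` is `FALSE`).
#'   Uses the current R RNG stream; seed externally for reproducibility.
#' @export
estimate_po <- function(rm, neuron, n_boot = 1000L,
                        resample = c("joint", "per_direction")) {
  stopifnot(inherits(rm, "response_matrix"))
  resample <- match.arg(resample)
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  R <- matrix(rm$r[neuron, , ], rm$n_stim, rm$n_rep)
  th <- 2 * rm$directions * pi / 180
  cs <- colSums(R * cos(th))  # per-repetition partial sums
  sn <- colSums(R * sin(th))
  if (resample == "joint") {
    idx <- matrix(sample.int(rm$n_rep, n_boot * rm$n_rep, replace = TRUE),
                  n_boot, rm$n_rep)
    X <- rowSums(matrix(cs[idx], n_boot, rm$n_rep)) / length(R)
    Y <- rowSums(matrix(sn[idx], n_boot, rm$n_rep)) / length(R)
  } else {
    X <- numeric(n_boot); Y <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      Rb <- matrix(NA_real_, rm$n_stim, rm$n_rep)
      for (s in seq_len(rm$n_stim))
        Rb[s, ] <- R[s, sample.int(rm$n_rep, rm$n_rep, replace = TRUE)]
      X[b] <- mean(Rb * cos(th)); Y[b] <- mean(Rb * sin(th))
    }
  }
  ok <- sqrt(X^2 + Y^2) > 1e-12 * max(mean(abs(R)), .Machine$double.xmin)
  n_undef <- sum(!ok)  # resamples with no defined PO (symmetric responses)
  po_b <- atan2(Y[ok], X[ok]) / 2 * 180 / pi  # orientation degrees

  if (n_undef > n_boot / 2 || sum(ok) == 0L) {
    out <- list(po = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                ci_width = 180, tuned = FALSE, n_boot = n_boot,
                n_undefined = n_undef)
    class(out) <- "tuning_result"
    return(out)
  }
  po <- circular_mean_orientation(po_b)
  if (is.na(po)) po <- po_b[1]
  centered <- ((2 * (po_b - po) + 180) %% 360) - 180  # doubled, centered
  q <- quantile(centered, c(0.025, 0.975), names = FALSE)
  ci_width <- (q[2] - q[1]) / 2
  out <- list(po = po,
              ci_low = wrap_orientation(po + q[1] / 2),
              ci_high = wrap_orientation(po + q[2] / 2),
              ci_width = ci_width,
              tuned = ci_width <= 90,
              n_boot = n_boot, n_undefined = n_undef)
  class(out) <- "tuning_result"
  out
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> PO %.2f deg, 95%% CI [%.2f, %.2f] (width %.2f), %s\n",
              x$po, x$ci_low, x$ci_high, x$ci_width,
              if (isTRUE(x$tuned)) "tuned" else "not tuned"))
  invisible(x)
}

#' Per-session tuning table for a whole experiment
#'
#' Runs the full estimation chain (dF/F, response matrix, responsiveness,
#' bootstrap PO) on each session of an experiment and stacks the results.
#'
#' @param sessions list of `"trial_tensor"` objects (or the `sessions`
#'   element of [generate_experiment()] output).
#' @param n_boot bootstrap resamples per neuron.
#' @param alpha responsiveness significance level.
#' @param contamination neuropil correction coefficient.
#' @param seed optional integer; when given, results are reproducible.
#' @return data.frame with columns `neuron`, `day`, `po`, `ci_low`, `ci_high`,
#'   `ci_width`, `responsive`, `tuned` (tuned requires responsive and CI width
#'   <= 90 deg).
#' @export
analyze_tuning <- function(sessions, n_boot = 1000L, alpha = 0.05,
                           contamination = 0.7, seed = NULL) {
  if (inherits(sessions, "trial_tensor")) sessions <- list(sessions)
  run <- function() {
    out <- lapply(sessions, function(tt) {
      rm_ <- build_response_matrix(tt, contamination = contamination)
      resp <- responsiveness_test(rm_, alpha)
      n <- dim(rm_$r)[1]
      res <- lapply(seq_len(n), function(i) estimate_po(rm_, i, n_boot))
      data.frame(
        neuron = seq_len(n), day = tt$day,
        po = vapply(res, `[[`, numeric(1), "po"),
        ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
        ci_high = vapply(res, `[[`, numeric(1), "ci_high"),
        ci_width = vapply(res, `[[`, numeric(1), "ci_width"),
        responsive = resp,
        tuned = resp & vapply(res, `[[`, logical(1), "tuned")
      )
    })
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
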