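# Drift and convergence statistics across session pairs: per-neuron PO-change
# records, median convergence with bootstrap CIs, magnitude/direction shuffle
# nulls, pairwise-signal-correlation similarity decay, and behavioral
# (running/arousal) modulation filters.

# Is orientation x inside the circular interval [lo, hi] surrounding center?
# Valid while the interval spans < 180 deg, which holds for tuned neurons.
inside_ci_circular <- function(x, center, lo, hi) {
  d <- orientation_diff(x, center)
  dlo <- orientation_diff(lo, center)
  dhi <- orientation_diff(hi, center)
  d >= dlo & d <= dhi
}

#' Per-neuron drift records across session pairs
#'
#' For every pair of sessions and every concurrently tuned neuron (responsive
#' and tuned on both days), computes the signed PO change, its magnitude
#' |dPO|, and whether the change is significant: the PO of each day must lie
#' outside the other day's 95% CI (both tested circularly). When an
#' experienced orientation is supplied, also fills the distance from it
#' (`rpo_pre`, `rpo_post`, both in \[0, 90\]) and the convergence
#' `rpo_pre - rpo_post` (positive = drift toward the experienced orientation).
#'
#' @param tuning tuning table from [analyze_tuning()] (columns `neuron`,
#'   `day`, `po`, `ci_low`, `ci_high`, `ci_width`, `responsive`, `tuned`).
#' @param experienced experienced orientation in degrees, or `NULL`.
#' @return data.frame of class `"drift_records"` with columns `neuron`,
#'   `day_pre`, `day_post`, `interval`, `po_pre`, `po_post`, `delta_po`,
#'   `drift_magnitude`, `significant`, and (when `experienced` is given)
#'   `rpo_pre`, `rpo_post`, `convergence`.
#' @export
make_drift_records <- function(tuning, experienced = NULL) {
  days <- sort(unique(tuning$day))
  if (length(days) < 2L) stop("need at least 2 sessions", call. = FALSE)
  out <- list()
  for (i in seq_len(length(days) - 1L)) {
    for (j in (i + 1L):length(days)) {
      a <- tuning[tuning$day == days[i] & tuning$tuned, , drop = FALSE]
      b <- tuning[tuning$day == days[j] & tuning$tuned, , drop = FALSE]
      common <- intersect(a$neuron, b$neuron)
      if (length(common) == 0L) next
      a <- a[match(common, a$neuron), ]
      b <- b[match(common, b$neuron), ]
      delta <- orientation_diff(b$po, a$po)
      sig <- !inside_ci_circular(b$po, a$po, a$ci_low, a$ci_high) &
             !inside_ci_circular(a$po, b$po, b$ci_low, b$ci_high)
      rec <- data.frame(
        neuron = common, day_pre = days[i], day_post = days[j],
        interval = days[j] - days[i],
        po_pre = a$po, po_post = b$po,
        delta_po = delta, drift_magnitude = abs(delta),
        significant = sig
      )
      if (!is.null(experienced)) {
        rec$rpo_pre <- orientation_distance(a$po, experienced)
        rec$rpo_post <- orientation_distance(b$po, experienced)
        rec$convergence <- rec$rpo_pre - rec$rpo_post
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  if (length(out) == 0L) {
    warning("no concurrently tuned neurons in any session pair")
    res <- data.frame(neuron = integer(), day_pre = integer(),
                      day_post = integer(), interval = integer(),
                      po_pre = numeric(), po_post = numeric(),
                      delta_po = numeric(), drift_magnitude = numeric(),
                      significant = logical())
  } else {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
  }
  class(res) <- c("drift_records", "data.frame")
  res
}

#' Median convergence with a bootstrap confidence interval
#'
#' @param x drift records (uses the `convergence` column) or a numeric vector
#'   of convergence values, degrees.
#' @param n_boot bootstrap resamples of the records (default 10000).
#' @return list: `median`, `ci_low`, `ci_high` (95% percentile bootstrap of
#'   the median), `n`. Uses the current R RNG stream.
#' @export
convergence_summary <- function(x, n_boot = 10000L) {
  v <- if (is.data.frame(x)) x$convergence else x
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no convergence values", call. = FALSE)
  idx <- matrix(sample.int(length(v), n_boot * length(v), replace = TRUE),
                n_boot)
  meds <- apply(matrix(v[idx], n_boot), 1L, median)
  ci <- quantile(meds, c(0.025, 0.975), names = FALSE)
  list(median = median(v), ci_low = ci[1], ci_high = ci[2], n = length(v))
}

#' Shuffle nulls for population convergence
#'
#' Tests whether population convergence toward an experienced orientation is
#' carried by drift magnitudes or drift directions.
#' \describe{
#'   \item{`magnitude`}{permutes drift magnitudes across neurons while each
#'     neuron keeps its drift direction (toward/away).}
#'   \item{`direction`}{assigns each neuron a random direction (toward or away
#'     from the experienced orientation with equal probability) while keeping
#'     its magnitude.}
#'   \item{`direction_permute`}{permutes the observed directions across
#'     neurons (an alternative direction null preserving the toward/away
#'     ratio).}
#' }
#' After each shuffle, `rpo_post` is re-derived from `rpo_pre`, the assigned
#' direction and the magnitude, clipped to \[0, 90\], and the median
#' convergence is recomputed.
#'
#' @param records drift records with `rpo_pre` and `convergence` columns.
#' @param mode one of `"magnitude"`, `"direction"`, `"direction_permute"`.
#' @param n_shuffle number of shuffles.
#' @return list of class `"shuffle_test"`: `observed_median`,
#'   `shuffle_medians` (length `n_shuffle`), `ci_low`/`ci_high` (2.5/97.5
#'   percentiles of the shuffle medians), `mode`.
#' @export
shuffle_test <- function(records, mode = c("magnitude", "direction",
                                           "direction_permute"),
                         n_shuffle = 1000L) {
  mode <- match.arg(mode)
  conv <- records$convergence
  rpo_pre <- records$rpo_pre
  keep <- !is.na(conv) & !is.na(rpo_pre)
  conv <- conv[keep]; rpo_pre <- rpo_pre[keep]
  n <- length(conv)
  if (n < 1L) stop("no usable records", call. = FALSE)
  mag <- abs(conv)
  dir <- ifelse(conv >= 0, 1, -1)  # +1 = toward the experienced orientation
  meds <- numeric(n_shuffle)
  for (k in seq_len(n_shuffle)) {
    if (mode == "magnitude") {
      m <- mag[sample.int(n)]; d <- dir
    } else if (mode == "direction") {
      m <- mag; d <- sample(c(-1, 1), n, replace = TRUE)
    } else {
      m <- mag; d <- dir[sample.int(n)]
    }
    rpo_post <- pmin(90, pmax(0, rpo_pre - d * m))
    meds[k] <- median(rpo_pre - rpo_post)
  }
  ci <- quantile(meds, c(0.025, 0.975), names = FALSE)
  structure(list(observed_median = median(conv), shuffle_medians = meds,
                 ci_low = ci[1], ci_high = ci[2], mode = mode,
                 n_records = n),
            class = "shuffle_test")
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf(
    "<shuffle_test mode=%s> observed median %.3f deg; shuffle 95%% [%.3f, %.3f] (%d shuffles, %d records)\n",
    x$mode, x$observed_median, x$ci_low, x$ci_high,
    length(x$shuffle_medians), x$n_records))
  invisible(x)
}

#' Pairwise signal correlation (PSC) matrix
#'
#' Pearson correlation between the trial-averaged tuning curves (mean
#' response per direction) of every pair of neurons. Neurons with
#' zero-variance tuning curves get `NA` rows/columns.
#'
#' @param rm a `"response_matrix"`.
#' @return neuron x neuron correlation matrix.
#' @export
psc_matrix <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  tc <- rowMeans(rm$r, dims = 2L)  # neuron x direction
  if (nrow(tc) < 2L) stop("need at least 2 neurons", call. = FALSE)
  flat <- apply(tc, 1L, sd) == 0
  out <- suppressWarnings(cor(t(tc)))
  out[flat, ] <- NA_real_
  out[, flat] <- NA_real_
  out
}

#' Across-day PSC similarity and its exponential decay
#'
#' Vectorizes each day's PSC matrix (strict upper triangle), correlates every
#' day pair, and fits `y = a + b * exp(-c * x)` to similarity versus interval
#' by nonlinear least squares (Levenberg-Marquardt, `c` constrained
#' non-negative, initialized at `(min(y), max(y) - min(y), 0.1)`).
#'
#' @param psc_by_day list of PSC matrices, one per day.
#' @param day_labels numeric day indices, same length.
#' @return list: `day_corr` (day x day similarity matrix), `points`
#'   (data.frame `interval`, `similarity`), `fit` (named vector `a`, `b`,
#'   `c`), `model` (the `nls` object).
#' @export
psc_similarity_decay <- function(psc_by_day, day_labels) {
  stopifnot(length(psc_by_day) == length(day_labels))
  nd <- length(psc_by_day)
  vecs <- lapply(psc_by_day, function(m) m[upper.tri(m)])
  D <- matrix(NA_real_, nd, nd)
  for (i in seq_len(nd)) for (j in seq_len(nd))
    D[i, j] <- suppressWarnings(
      cor(vecs[[i]], vecs[[j]], use = "complete.obs"))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  pts <- data.frame(interval = day_labels[pairs[, 2]] - day_labels[pairs[, 1]],
                    similarity = D[pairs])
  pts <- pts[is.finite(pts$similarity), ]
  if (length(unique(pts$interval)) < 3L)
    stop("need >= 3 distinct intervals to fit the decay", call. = FALSE)
  fit <- fit_exp_decay(pts$interval, pts$similarity)
  list(day_corr = D, points = pts, fit = coef(fit), model = fit)
}

#' Three-parameter exponential decay fit
#'
#' Least-squares fit of `y = a + b * exp(-c * x)` with `c >= 0`.
#'
#' @param x,y data vectors.
#' @return an `nls`-class model object (see [minpack.lm::nlsLM]).
#' @export
fit_exp_decay <- function(x, y) {
  start <- list(a = min(y), b = max(y) - min(y), c = 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(-c * x), start = start,
                      lower = c(-Inf, -Inf, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "exponential decay fit failed: %s (n = %d points, y range [%.3g, %.3g])",
      conditionMessage(e), length(y), min(y), max(y)), call. = FALSE))
  fit
}

#' Behavioral modulation of a PO change
#'
#' The correlation between per-trial stimulus-response amplitudes and a
#' behavioral covariate (running speed or pupil diameter), multiplied by the
#' average change of that covariate across the two sessions of the PO change.
#' Either factor being zero makes the modulation zero; a zero-variance
#' covariate returns 0 with attribute `flag = "zero_variance"`.
#'
#' @param amplitudes per-trial stimulus-window response amplitudes.
#' @param behavior per-trial behavioral covariate, same length (>= 3).
#' @param session_change mean across-session change of the covariate.
#' @return modulation value (covariate units).
#' @export
behavioral_modulation <- function(amplitudes, behavior, session_change) {
  if (length(amplitudes) != length(behavior) || length(amplitudes) < 3L)
    stop("need >= 3 paired trials", call. = FALSE)
  if (sd(behavior) == 0 || sd(amplitudes) == 0) {
    out <- 0
    attr(out, "flag") <- "zero_variance"
    return(out)
  }
  cor(amplitudes, behavior) * session_change
}

#' Drop the drift records most affected by behavioral state changes
#'
#' Removes the `drop_fraction` of records with the largest absolute
#' modulation. Ties at the cut are broken deterministically: among equal
#' |modulation|, records with larger neuron id are dropped first.
#'
#' @param records drift records (must have a `neuron` column).
#' @param modulation numeric vector, one modulation value per record.
#' @param drop_fraction fraction in \[0, 1) to drop; the number dropped is
#'   `floor(drop_fraction * n)`.
#' @return the surviving subset of `records`.
#' @export
filter_by_modulation <- function(records, modulation, drop_fraction) {
  stopifnot(length(modulation) == nrow(records))
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)", call. = FALSE)
  n_drop <- floor(drop_fraction * nrow(records))
  if (n_drop == 0L) return(records)
  ord <- order(-abs(modulation), -records$neuron)
  keep <- sort(ord[-seq_len(n_drop)])
  records[keep, , drop = FALSE]
}
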