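# Partial-noise/resample class-recovery experiments and the desk-scale
# distribution-fidelity metrics shared across modules.

# mean Euclidean distance between all row pairs of a and b, computed in
# chunks so the full cross-distance matrix is never materialized
mean_cross_dist <- function(a, b, chunk = 2000L) {
  a <- as.matrix(a); b <- as.matrix(b)
  bb <- rowSums(b^2)
  total <- 0
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(a))
    ai <- a[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(ai^2), bb, "+") - 2 * tcrossprod(ai, b)
    total <- total + sum(sqrt(pmax(d2, 0)))
  }
  total / (nrow(a) * nrow(b))
}

#' Energy distance between two samples
#'
#' The V-statistic estimator
#' \eqn{2\,\mathbb{E}\|X-Y\| - \mathbb{E}\|X-X'\| - \mathbb{E}\|Y-Y'\|},
#' zero in expectation iff the two distributions coincide.  Used as the
#' desk-scale distribution-fidelity metric throughout the package.
#'
#' @param sample_a,sample_b Matrices (rows = observations) with equal column
#'   count.
#' @return A non-negative scalar (up to Monte Carlo fluctuation).
#' @export
energy_distance <- function(sample_a, sample_b) {
  a <- as.matrix(sample_a); b <- as.matrix(sample_b)
  stopifnot(ncol(a) == ncol(b))
  2 * mean_cross_dist(a, b) - mean_cross_dist(a, a) - mean_cross_dist(b, b)
}

#' Fraction of samples near each basin center
#'
#' @param samples n x d matrix.
#' @param basin_centers K x d matrix of centers.
#' @param radius Inclusion radius (same units as the data).
#' @param period Optional period for angular data (e.g. 360 for degrees);
#'   distances are then computed on the torus, componentwise.
#' @return Length-K vector of occupancy fractions.
#' @export
basin_occupancy <- function(samples, basin_centers, radius, period = NULL) {
  x <- as.matrix(samples)
  centers <- as.matrix(basin_centers)
  vapply(seq_len(nrow(centers)), function(k) {
    delta <- abs(sweep(x, 2, centers[k, ], "-"))
    if (!is.null(period)) {
      delta <- delta %% period
      delta <- pmin(delta, period - delta)
    }
    mean(sqrt(rowSums(delta^2)) <= radius)
  }, numeric(1))
}

# uniform random permutation of the eta components within each sample;
# destroys the x-eta alignment while preserving the eta marginal
shuffle_eta_rows <- function(eta) {
  d <- ncol(eta)
  if (d == 1L) return(eta)
  t(apply(eta, 1, function(r) r[sample.int(d)]))
}

#' Partial noising followed by reverse resampling
#'
#' Forward-noises each sample exactly to time `tf`, optionally scrambles the
#' active degrees of freedom within each sample, reverse-integrates back to
#' `t = 0` with the supplied score provider, and classifies the result.  The
#' eta-shuffle control tests whether the active coordinates carry class
#' information: destroying their alignment with x should pull active recovery
#' toward the passive level.
#'
#' @param x n x d matrix of clean samples.
#' @param score_provider A `score_provider` for the matching process.
#' @param params Process parameters.
#' @param tf Forward diffusion time (must not exceed the provider's trained
#'   horizon when one is recorded).
#' @param shuffle_eta Permute the d eta components within each sample before
#'   the reverse pass (active process only; a no-op for d = 1).
#' @param classifier Function mapping an n x d matrix to class labels.
#' @param n_steps Reverse integration steps over `[0, tf]`.
#' @param seed Optional integer seed.
#' @return A list with `labels` (predicted classes), `x0` (the regenerated
#'   samples) and `noised` (the partially noised ensemble).
#' @export
partial_noise_resample <- function(x, score_provider, params, tf,
                                   shuffle_eta = FALSE, classifier,
                                   n_steps = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(score_provider$tf_max) && tf > score_provider$tf_max) {
    stop("partial_noise_resample: tf exceeds the provider's trained horizon")
  }
  if (tf <= 0) {
    return(list(labels = classifier(x), x0 = x, noised = NULL))
  }
  active <- is_active(params)
  ens <- if (active) sample_forward(params, x, tf)
         else sample_forward_passive(params, x, tf)
  if (shuffle_eta) {
    if (!active) stop("shuffle_eta requires an active process")
    ens$eta <- shuffle_eta_rows(ens$eta)
  }
  sched <- reverse_schedule(tf = tf, n_steps = n_steps)
  out <- generate(score_provider, params, sched, start = ens)
  list(labels = classifier(out$x), x0 = out$x, noised = ens)
}

#' Class-recovery curves over a forward-time grid
#'
#' Runs [partial_noise_resample()] for every condition at every grid time and
#' records the fraction of samples whose recovered class matches the true
#' label, with binomial standard errors.
#'
#' @param x n x d matrix of clean samples.
#' @param labels True class labels aligned with the rows of `x`.
#' @param conditions Named list; each element a list with `params`,
#'   `provider`, and optionally `shuffle_eta` (default `FALSE`).
#' @param tf_grid Vector of forward times.
#' @param classifier Function mapping samples to labels.
#' @param n_steps Reverse steps per unit time are `n_steps / tf`;
#'   interpreted as the step count at each `tf` (default 100).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `tf`, `condition`, `fraction`, `se`,
#'   `n`.
#' @export
recovery_curve <- function(x, labels, conditions, tf_grid, classifier,
                           n_steps = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (cname in names(conditions)) {
    cond <- conditions[[cname]]
    for (tf in tf_grid) {
      res <- partial_noise_resample(
        x, cond$provider, cond$params, tf,
        shuffle_eta = isTRUE(cond$shuffle_eta),
        classifier = classifier, n_steps = n_steps)
      frac <- mean(res$labels == labels)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, condition = cname, fraction = frac,
        se = sqrt(frac * (1 - frac) / length(labels)), n = length(labels))
    }
  }
  do.call(rbind, rows)
}
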