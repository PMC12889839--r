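#' Diagonal-covariance Gaussian mixture
#'
#' The analytic-score workhorse: a mixture
#' \deqn{P_0(x) = \sum_\alpha p_\alpha \prod_i N(x_i;\, \mu_{\alpha i},
#'   h_{\alpha i})}
#' with weights on the probability simplex and strictly positive diagonal
#' variances.
#'
#' @param weights Length-K vector of positive weights (normalized to sum 1).
#' @param means K x d matrix of component means.
#' @param variances K x d matrix of per-dimension variances (recycled from a
#'   scalar or length-K vector).
#' @return An object of class `gaussian_mixture`.
#' @export
#' @examples
#' gaussian_mixture(c(0.5, 0.5), rbind(-2, 2), 0.1)
gaussian_mixture <- function(weights, means, variances) {
  means <- as.matrix(means)
  K <- nrow(means); d <- ncol(means)
  stopifnot(length(weights) == K, all(weights > 0))
  if (length(variances) == 1L) variances <- matrix(variances, K, d)
  if (is.vector(variances) && length(variances) == K)
    variances <- matrix(variances, K, d)
  variances <- as.matrix(variances)
  stopifnot(identical(dim(variances), dim(means)), all(variances > 0))
  structure(list(weights = weights / sum(weights), means = means,
                 variances = variances),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("gaussian mixture: %d components in %d dimensions\n",
              nrow(x$means), ncol(x$means)))
  invisible(x)
}

#' Draw labelled samples from a Gaussian mixture
#'
#' @param gmm A [gaussian_mixture()].
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return A list with `x` (n x d matrix) and `labels` (component index of
#'   each row).
#' @export
sample_gmm <- function(gmm, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(gmm$means); d <- ncol(gmm$means)
  labels <- sample.int(K, n, replace = TRUE, prob = gmm$weights)
  z <- matrix(stats::rnorm(n * d), n, d)
  x <- gmm$means[labels, , drop = FALSE] +
    sqrt(gmm$variances)[labels, , drop = FALSE] * z
  list(x = x, labels = labels)
}

#' Serialize a Gaussian mixture to/from JSON
#'
#' Layout: `{"weights":[...], "means":[[...]], "variances":[[...]]}` with one
#' row per component.
#'
#' @param gmm A [gaussian_mixture()].
#' @param path File path.
#' @return `path` / a `gaussian_mixture`.
#' @export
write_gmm <- function(gmm, path) {
  jsonlite::write_json(list(weights = gmm$weights,
                            means = apply(gmm$means, 1, identity,
                                          simplify = FALSE),
                            variances = apply(gmm$variances, 1, identity,
                                              simplify = FALSE)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_rows <- function(m) {
    if (is.list(m)) m <- do.call(rbind, m)
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    as.matrix(m)
  }
  gaussian_mixture(obj$weights, as_rows(obj$means), as_rows(obj$variances))
}

#' Pushforward of a Gaussian mixture through the forward process
#'
#' Because the forward SDE is linear with Gaussian noise, each mixture
#' component stays Gaussian: weights are preserved and the per-component,
#' per-dimension moments follow from the propagator and covariance.  For the
#' passive process the component laws are
#' \eqn{N(\mu e^{-kt},\, h e^{-2kt} + \Delta_t)}.  For the active process the
#' joint \eqn{(x_i, \eta_i)} component covariance is
#' \eqn{\Sigma = e^{Mt}\,\mathrm{diag}(h, S_{\eta_0})\,e^{M^\top t} + C_t},
#' where \eqn{S_{\eta_0}} is `Ta/tau` under the stationary eta policy and 0
#' under the zero policy.  Only the xx entry of \eqn{\Sigma} depends on the
#' component.
#'
#' @param gmm A [gaussian_mixture()].
#' @param params `passive_params` or `active_params`.
#' @param t Forward time (>= 0).
#' @param eta0_policy Initial eta policy, as in [sample_forward()].
#' @return An object of class `noised_mixture`.  `t = 0` with the `zero`
#'   policy is degenerate for the active joint law and is rejected.
#' @export
noised_mixture <- function(gmm, params, t,
                           eta0_policy = c("stationary", "zero")) {
  eta0_policy <- match.arg(eta0_policy)
  stopifnot(t >= 0)
  tm <- transition_moments(params, t)
  if (!is_active(params)) {
    a <- tm$propagator[1, 1]
    return(structure(list(process = "passive", weights = gmm$weights,
                          means = gmm$means * a,
                          vars = gmm$variances * a^2 + tm$covariance[1, 1],
                          t = t, params = params),
                     class = "noised_mixture"))
  }
  s_eta0 <- if (eta0_policy == "stationary") params$Ta / params$tau else 0
  G <- tm$propagator; C <- tm$covariance
  sxx <- gmm$variances * G[1, 1]^2 + s_eta0 * G[1, 2]^2 + C[1, 1]  # K x d
  sxe <- s_eta0 * G[1, 2] * G[2, 2] + C[1, 2]                      # scalar
  see <- s_eta0 * G[2, 2]^2 + C[2, 2]                              # scalar
  if (see <= 0 || any(sxx * see - sxe^2 <= 0)) {
    stop("noised_mixture: degenerate joint covariance (t = 0 with zero-eta ",
         "policy and/or zero component variance)")
  }
  structure(list(process = "active", weights = gmm$weights,
                 means = gmm$means * G[1, 1], sxx = sxx, sxe = sxe, see = see,
                 t = t, params = params, eta0_policy = eta0_policy),
            class = "noised_mixture")
}

#' @export
print.noised_mixture <- function(x, ...) {
  cat(sprintf("noised mixture (%s) at t = %g: %d components x %d dims\n",
              x$process, x$t, length(x$weights), ncol(x$means)))
  invisible(x)
}

# log responsibilities (n x K) and per-component Gaussian parameters are
# computed in log space throughout; well-separated components (the diamond
# target) underflow otherwise.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# per-component joint log-likelihoods for an active noised mixture
active_component_loglik <- function(nm, x, eta) {
  n <- nrow(x); K <- length(nm$weights)
  ll <- matrix(0, n, K)
  for (a in seq_len(K)) {
    dx <- x - matrix(nm$means[a, ], n, ncol(x), byrow = TRUE)
    sxx <- matrix(nm$sxx[a, ], n, ncol(x), byrow = TRUE)
    det <- sxx * nm$see - nm$sxe^2
    q <- (nm$see * dx^2 - 2 * nm$sxe * dx * eta + sxx * eta^2) / det
    ll[, a] <- log(nm$weights[a]) +
      rowSums(-0.5 * (q + log(det)) - log(2 * pi))
  }
  ll
}

#' Analytic score of a noised Gaussian mixture (passive process)
#'
#' Evaluates \eqn{\mathcal{F}(x;t) = \nabla_x \log P(x,t)} exactly: the
#' responsibility-weighted sum of per-component Gaussian scores of the
#' pushforward mixture.  Stable for well-separated components (log-sum-exp).
#'
#' @param gmm A [gaussian_mixture()].
#' @param params `passive_params`.
#' @param t Forward time (>= 0).
#' @param x n x d matrix (or length-d vector) of evaluation points.
#' @return n x d matrix of score values.
#' @export
passive_score <- function(gmm, params, t, x) {
  stopifnot(inherits(params, "passive_params"))
  nm <- noised_mixture(gmm, params, t)
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  n <- nrow(x); d <- ncol(x); K <- length(nm$weights)
  ll <- matrix(0, n, K)
  for (a in seq_len(K)) {
    m <- matrix(nm$means[a, ], n, d, byrow = TRUE)
    v <- matrix(nm$vars[a, ], n, d, byrow = TRUE)
    ll[, a] <- log(nm$weights[a]) +
      rowSums(-0.5 * ((x - m)^2 / v + log(2 * pi * v)))
  }
  r <- exp(ll - logsumexp_rows(ll))
  s <- matrix(0, n, d)
  for (a in seq_len(K)) {
    m <- matrix(nm$means[a, ], n, d, byrow = TRUE)
    v <- matrix(nm$vars[a, ], n, d, byrow = TRUE)
    s <- s + r[, a] * (-(x - m) / v)
  }
  s
}

#' Analytic joint score of a noised Gaussian mixture (active process)
#'
#' Evaluates both gradients of the joint log density,
#' \eqn{\mathcal{F}_x = \nabla_x \log P(x,\eta;t)} and
#' \eqn{\mathcal{F}_\eta = \nabla_\eta \log P(x,\eta;t)}, from the exact
#' linear-Gaussian pushforward of the mixture.
#'
#' @inheritParams passive_score
#' @param params `active_params`.
#' @param eta n x d matrix (or vector) of active coordinates.
#' @param eta0_policy Initial eta policy used by the forward process.
#' @return A list with n x d matrices `x` and `eta`.
#' @export
active_score <- function(gmm, params, t, x, eta,
                         eta0_policy = c("stationary", "zero")) {
  stopifnot(is_active(params))
  nm <- noised_mixture(gmm, params, t, eta0_policy = match.arg(eta0_policy))
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  eta <- if (is.null(dim(eta))) matrix(eta, 1) else as.matrix(eta)
  stopifnot(identical(dim(x), dim(eta)))
  n <- nrow(x); d <- ncol(x); K <- length(nm$weights)
  ll <- active_component_loglik(nm, x, eta)
  r <- exp(ll - logsumexp_rows(ll))
  fx <- matrix(0, n, d); fe <- matrix(0, n, d)
  for (a in seq_len(K)) {
    dx <- x - matrix(nm$means[a, ], n, d, byrow = TRUE)
    sxx <- matrix(nm$sxx[a, ], n, d, byrow = TRUE)
    det <- sxx * nm$see - nm$sxe^2
    fx <- fx + r[, a] * (-(nm$see * dx - nm$sxe * eta) / det)
    fe <- fe + r[, a] * (-(sxx * eta - nm$sxe * dx) / det)
  }
  list(x = fx, eta = fe)
}

#' Log density of a noised mixture
#'
#' @param nm A [noised_mixture()].
#' @param x n x d matrix of data coordinates.
#' @param eta n x d matrix of active coordinates (active process only).
#' @return Length-n vector of joint (active) or marginal (passive) log
#'   densities.
#' @export
noised_mixture_logpdf <- function(nm, x, eta = NULL) {
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  n <- nrow(x); d <- ncol(x); K <- length(nm$weights)
  if (nm$process == "passive") {
    ll <- matrix(0, n, K)
    for (a in seq_len(K)) {
      m <- matrix(nm$means[a, ], n, d, byrow = TRUE)
      v <- matrix(nm$vars[a, ], n, d, byrow = TRUE)
      ll[, a] <- log(nm$weights[a]) +
        rowSums(-0.5 * ((x - m)^2 / v + log(2 * pi * v)))
    }
    return(logsumexp_rows(ll))
  }
  eta <- if (is.null(dim(eta))) matrix(eta, 1) else as.matrix(eta)
  logsumexp_rows(active_component_loglik(nm, x, eta))
}

#' Denoising regression target (conditional score)
#'
#' The per-sample target whose conditional expectation over the posterior of
#' the clean state given the noised state equals the true score.  Passive:
#' \eqn{-(x_t - x_0 e^{-kt})/\Delta_t}.  Active: the joint Gaussian-channel
#' residual \eqn{-C_t^{-1}(z_t - e^{Mt} z_0)} per dimension, for
#' \eqn{z = (x, \eta)}.
#'
#' @param params `passive_params` or `active_params`.
#' @param t Forward time, strictly positive (the channel variance vanishes at
#'   `t = 0`).
#' @param x_t,x0 Matrices of noised/clean data coordinates (same shape).
#' @param eta_t,eta0 Matrices of noised/initial active coordinates (active
#'   process only).
#' @return For the passive process an n x d matrix; for the active process a
#'   list with matrices `x` and `eta`.
#' @export
conditional_score_target <- function(params, t, x_t, x0, eta_t = NULL,
                                     eta0 = NULL) {
  if (t <= 0) stop("conditional_score_target: t must be > 0")
  tm <- transition_moments(params, t)
  if (!is_active(params)) {
    return(-(x_t - x0 * tm$propagator[1, 1]) / tm$covariance[1, 1])
  }
  stopifnot(!is.null(eta_t), !is.null(eta0))
  G <- tm$propagator; C <- tm$covariance
  rx <- x_t - (G[1, 1] * x0 + G[1, 2] * eta0)
  re <- eta_t - G[2, 2] * eta0
  det <- C[1, 1] * C[2, 2] - C[1, 2]^2
  list(x = -(C[2, 2] * rx - C[1, 2] * re) / det,
       eta = -(C[1, 1] * re - C[1, 2] * rx) / det)
}

#' Maximum-posterior (Bayes) classification under a Gaussian mixture
#'
#' Assigns each row of `x` to the mixture component with the largest
#' posterior responsibility; with equal weights and variances this is the
#' nearest-mean rule.
#'
#' @param gmm A [gaussian_mixture()].
#' @param x n x d matrix of points.
#' @return Integer vector of component indices.
#' @export
bayes_classify <- function(gmm, x) {
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  n <- nrow(x); d <- ncol(x); K <- nrow(gmm$means)
  ll <- matrix(0, n, K)
  for (a in seq_len(K)) {
    m <- matrix(gmm$means[a, ], n, d, byrow = TRUE)
    v <- matrix(gmm$variances[a, ], n, d, byrow = TRUE)
    ll[, a] <- log(gmm$weights[a]) +
      rowSums(-0.5 * ((x - m)^2 / v + log(2 * pi * v)))
  }
  max.col(ll, ties.method = "first")
}

#' Exact draws from a noised mixture
#'
#' Samples the pushforward mixture directly (component choice, then the
#' per-dimension Gaussian), e.g. to initialize the reverse process from the
#' exact forward marginal at `t = tf` instead of the stationary law.
#'
#' @param nm A [noised_mixture()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return An [aug_ensemble()] at time `nm$t` (passive: `eta = NULL`).
#' @export
sample_noised_mixture <- function(nm, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(nm$weights); d <- ncol(nm$means)
  lab <- sample.int(K, n, replace = TRUE, prob = nm$weights)
  m <- nm$means[lab, , drop = FALSE]
  if (nm$process == "passive") {
    x <- m + sqrt(nm$vars)[lab, , drop = FALSE] * matrix(stats::rnorm(n * d), n, d)
    return(aug_ensemble(x, NULL, t = nm$t, params = nm$params,
                        seed_record = if (is.null(seed)) NA else seed))
  }
  sxx <- nm$sxx[lab, , drop = FALSE]
  l11 <- sqrt(sxx)
  l21 <- nm$sxe / l11
  l22 <- sqrt(pmax(nm$see - l21^2, 0))
  w1 <- matrix(stats::rnorm(n * d), n, d)
  w2 <- matrix(stats::rnorm(n * d), n, d)
  aug_ensemble(m + l11 * w1, l21 * w1 + l22 * w2, t = nm$t,
               params = nm$params,
               seed_record = if (is.null(seed)) NA else seed)
}
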