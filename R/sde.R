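#' Per-dimension drift matrix of the active forward process
#'
#' The augmented state \eqn{(x_i, \eta_i)} of each data dimension evolves
#' under the linear drift
#' \deqn{M = \begin{pmatrix} -k & 1 \\ 0 & -1/\tau \end{pmatrix},}
#' identically and independently across dimensions, so the full 2d-dimensional
#' drift is block-diagonal with this 2x2 block and is never materialized.
#'
#' @param params An `active_params` object.
#' @return A 2x2 numeric matrix.
#' @export
#' @examples
#' drift_matrix(active_params(k = 1, Tp = 0, Ta = 1, tau = 1))
drift_matrix <- function(params) {
  stopifnot(is_active(params))
  matrix(c(-params$k, 0, 1, -1 / params$tau), 2, 2)
}

# Noise intensity matrix D with <xi xi'> = 2 D delta(t - t')
diffusion_matrix <- function(params) {
  diag(c(params$Tp, params$Ta / params$tau^2))
}

# relative thresholds below which the confluent (k ~ 1/tau) closed forms are
# used: tight for the propagator (error eps/|a-b|), much wider for the
# covariance integrals (error eps/|a-b|^2)
DEGENERATE_TOL <- 1e-8
DEGENERATE_COV_TOL <- 1e-5

#' Exact transition moments of the forward process
#'
#' For the linear forward SDE the conditional law of the state at time `t`
#' given the state at time 0 is Gaussian with mean `propagator %*% z0` and
#' covariance `covariance`, per dimension.  Both are returned in closed form:
#' the propagator is \eqn{e^{Mt}} and the covariance solves the finite-time
#' Lyapunov integral \eqn{C_t = \int_0^t e^{Mu} 2D e^{M^\top u}\,du}.
#'
#' The active propagator has distinct eigenvalues \eqn{-k} and \eqn{-1/\tau};
#' the degenerate case \eqn{k = 1/\tau} (within a relative tolerance of
#' 1e-8) is handled by the confluent \eqn{t e^{-kt}} forms to avoid
#' catastrophic cancellation.  The passive case returns the 1x1 "matrices"
#' \eqn{e^{-kt}} and \eqn{\Delta_t = (T/k)(1 - e^{-2kt})}.
#'
#' @param params `active_params` or `passive_params`.
#' @param t Time, non-negative scalar.
#' @return A list of class `transition_moments` with elements `propagator`
#'   (2x2 active, 1x1 passive), `covariance` (same shape), and `t`.
#' @export
#' @examples
#' transition_moments(passive_params(k = 1, T = 1), 0.5)$covariance  # 1 - e^-1
transition_moments <- function(params, t) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  if (t < 0) stop("transition_moments: t must be non-negative")
  if (!is_active(params)) {
    k <- params$k
    G <- matrix(exp(-k * t), 1, 1)
    C <- matrix((params$T / k) * (1 - exp(-2 * k * t)), 1, 1)
    return(structure(list(propagator = G, covariance = C, t = t),
                     class = "transition_moments"))
  }
  a <- params$k
  b <- 1 / params$tau
  ea <- exp(-a * t)
  eb <- exp(-b * t)
  degenerate <- abs(a - b) < DEGENERATE_TOL * a
  g <- if (degenerate) t * ea else (eb - ea) / (a - b)
  G <- matrix(c(ea, 0, g, eb), 2, 2)

  Dx <- params$Tp
  De <- params$Ta / params$tau^2
  # the Lyapunov integrals divide by (a-b)^2, so their cancellation error is
  # eps/(a-b)^2: switch to the confluent forms much earlier than the
  # propagator does (relative error of the confluent approximation there is
  # O(|a-b| t), i.e. <= ~1e-4 on any time scale of interest)
  if (abs(a - b) < DEGENERATE_COV_TOL * a) {
    # g(u) = u e^{-au}: confluent Lyapunov integrals
    c2 <- 2 * a
    e2 <- exp(-c2 * t)
    i_gg <- (2 - e2 * (c2^2 * t^2 + 2 * c2 * t + 2)) / c2^3
    i_gb <- (1 - e2 * (1 + c2 * t)) / c2^2
  } else {
    f2a <- (1 - exp(-2 * a * t)) / (2 * a)
    f2b <- (1 - exp(-2 * b * t)) / (2 * b)
    fab <- (1 - exp(-(a + b) * t)) / (a + b)
    i_gg <- (f2b + f2a - 2 * fab) / (a - b)^2
    i_gb <- (f2b - fab) / (a - b)
  }
  Cxx <- 2 * Dx * (1 - ea^2) / (2 * a) + 2 * De * i_gg
  Cxe <- 2 * De * i_gb
  Cee <- 2 * De * (1 - eb^2) / (2 * b)
  C <- matrix(c(Cxx, Cxe, Cxe, Cee), 2, 2)
  structure(list(propagator = G, covariance = C, t = t),
            class = "transition_moments")
}

#' @export
print.transition_moments <- function(x, ...) {
  cat(sprintf("transition moments at t = %g\n", x$t))
  cat("propagator:\n"); print(x$propagator)
  cat("covariance:\n"); print(x$covariance)
  invisible(x)
}

#' Stationary covariance of the forward process
#'
#' Solves the stationary Lyapunov equation \eqn{M\Sigma + \Sigma M^\top + 2D
#' = 0} in closed form.  For the active process, per dimension,
#' \deqn{\mathrm{Var}(\eta) = T_a/\tau,\quad \mathrm{Cov}(x,\eta) =
#'   T_a/(1+k\tau),\quad \mathrm{Var}(x) = T_p/k + T_a/(k(1+k\tau)).}
#' For a passive process the 1x1 matrix \eqn{T/k} is returned.
#'
#' @param params `active_params` or `passive_params`.
#' @return Per-dimension stationary covariance matrix (2x2 active, 1x1
#'   passive).
#' @export
stationary_moments <- function(params) {
  if (!is_active(params)) {
    return(matrix(params$T / params$k, 1, 1))
  }
  k <- params$k; tau <- params$tau
  See <- params$Ta / tau
  Sxe <- params$Ta / (1 + k * tau)
  Sxx <- params$Tp / k + params$Ta / (k * (1 + k * tau))
  matrix(c(Sxx, Sxe, Sxe, See), 2, 2)
}

# lower Cholesky factor of a 2x2 PSD matrix, tolerating zero blocks
chol2_lower <- function(S) {
  l11 <- sqrt(max(S[1, 1], 0))
  l21 <- if (l11 > 0) S[2, 1] / l11 else 0
  l22 <- sqrt(max(S[2, 2] - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2, 2)
}

#' Augmented ensemble container
#'
#' Holds a batch of augmented states \eqn{(x, \eta)} at a common process time,
#' together with RNG provenance.  Passive ensembles carry `eta = NULL`.
#'
#' @param x n x d matrix of data coordinates.
#' @param eta n x d matrix of active coordinates, or `NULL`.
#' @param t Process time (>= 0).
#' @param params The process parameters the ensemble was produced with.
#' @param seed_record Seed (or `NA`) used to produce the ensemble.
#' @return An object of class `aug_ensemble`.
#' @export
aug_ensemble <- function(x, eta = NULL, t = 0, params = NULL,
                         seed_record = NA) {
  x <- as.matrix(x)
  if (!is.null(eta)) {
    eta <- as.matrix(eta)
    stopifnot(identical(dim(x), dim(eta)))
  }
  stopifnot(t >= 0)
  structure(list(x = x, eta = eta, t = t, params = params,
                 seed_record = seed_record),
            class = "aug_ensemble")
}

#' @export
print.aug_ensemble <- function(x, ...) {
  cat(sprintf("ensemble: n = %d, d = %d, t = %g, %s, seed = %s\n",
              nrow(x$x), ncol(x$x),
              x$t, if (is.null(x$eta)) "passive (x only)" else "active (x, eta)",
              format(x$seed_record)))
  invisible(x)
}

#' Exact forward sampling of the active process
#'
#' Draws \eqn{(x_t, \eta_t)} given the rows of `x0` in one shot from the exact
#' Gaussian transition law (no time-stepping error): \eqn{\eta_0} is drawn per
#' `eta0_policy`, then \eqn{z_t = e^{Mt} z_0 + L w} with \eqn{LL^\top = C_t}.
#'
#' @param params `active_params`.
#' @param x0 n x d matrix (or vector) of initial data coordinates; must be
#'   finite.
#' @param t Forward time (>= 0).
#' @param eta0_policy Either `"stationary"` (\eqn{\eta_0 \sim N(0, T_a/\tau)},
#'   the default, which makes the joint process time-homogeneous) or `"zero"`
#'   (\eqn{\eta_0 = 0}).
#' @param seed Optional integer seed; recorded in the result.
#' @return An [aug_ensemble()] at time `t`.
#' @export
sample_forward <- function(params, x0, t, eta0_policy = c("stationary", "zero"),
                           seed = NULL) {
  stopifnot(is_active(params))
  eta0_policy <- match.arg(eta0_policy)
  x0 <- as.matrix(x0)
  if (!all(is.finite(x0))) stop("sample_forward: x0 must be finite")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x0); d <- ncol(x0)
  eta0 <- if (eta0_policy == "stationary") {
    matrix(stats::rnorm(n * d, sd = sqrt(params$Ta / params$tau)), n, d)
  } else {
    matrix(0, n, d)
  }
  tm <- transition_moments(params, t)
  G <- tm$propagator
  L <- chol2_lower(tm$covariance)
  w1 <- matrix(stats::rnorm(n * d), n, d)
  w2 <- matrix(stats::rnorm(n * d), n, d)
  x <- G[1, 1] * x0 + G[1, 2] * eta0 + L[1, 1] * w1
  eta <- G[2, 2] * eta0 + L[2, 1] * w1 + L[2, 2] * w2
  aug_ensemble(x, eta, t = t, params = params,
               seed_record = if (is.null(seed)) NA else seed)
}

#' Exact forward sampling of the passive process
#'
#' \eqn{x_t \sim N(x_0 e^{-kt}, \Delta_t)} with
#' \eqn{\Delta_t = (T/k)(1-e^{-2kt})}, applied independently per coordinate.
#'
#' @inheritParams sample_forward
#' @param params `passive_params`.
#' @return An [aug_ensemble()] with `eta = NULL`.
#' @export
sample_forward_passive <- function(params, x0, t, seed = NULL) {
  stopifnot(inherits(params, "passive_params"))
  x0 <- as.matrix(x0)
  if (!all(is.finite(x0))) stop("sample_forward_passive: x0 must be finite")
  if (!is.null(seed)) set.seed(seed)
  tm <- transition_moments(params, t)
  x <- tm$propagator[1, 1] * x0 +
    sqrt(tm$covariance[1, 1]) * matrix(stats::rnorm(length(x0)), nrow(x0))
  aug_ensemble(x, NULL, t = t, params = params,
               seed_record = if (is.null(seed)) NA else seed)
}

#' Read/write ensembles as delimited text
#'
#' The ensemble is written as CSV with columns `x_1..x_d[,eta_1..eta_d]` and a
#' header row; a JSON sidecar `<path>.json` records the process parameters,
#' time stamp and seed.
#'
#' @param ens An [aug_ensemble()].
#' @param path CSV file path.
#' @return `path` ([write_ensemble()]) or an `aug_ensemble`
#'   ([read_ensemble()]).
#' @export
write_ensemble <- function(ens, path) {
  d <- ncol(ens$x)
  df <- as.data.frame(ens$x)
  names(df) <- paste0("x_", seq_len(d))
  if (!is.null(ens$eta)) {
    eta <- as.data.frame(ens$eta)
    names(eta) <- paste0("eta_", seq_len(d))
    df <- cbind(df, eta)
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(t = ens$t, seed = ens$seed_record,
               params = if (is.null(ens$params)) NULL else unclass(ens$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- utils::read.csv(path)
  xc <- grepl("^x_", names(df))
  ec <- grepl("^eta_", names(df))
  meta_path <- paste0(path, ".json")
  t <- 0; seed <- NA; params <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    t <- meta$t %||% 0
    seed <- meta$seed %||% NA
    if (!is.null(meta$params)) {
      params <- if (!is.null(meta$params$tau)) {
        active_params(meta$params$k, meta$params$Tp, meta$params$Ta,
                      meta$params$tau)
      } else {
        passive_params(meta$params$k, meta$params$T)
      }
    }
  }
  aug_ensemble(as.matrix(df[, xc, drop = FALSE]),
               if (any(ec)) as.matrix(df[, ec, drop = FALSE]) else NULL,
               t = t, params = params, seed_record = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
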