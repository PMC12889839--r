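#' Uniform reverse-integration schedule
#'
#' The reverse-time SDE is integrated by Euler-Maruyama on a uniform grid
#' running from `tf` down to 0 with step `dt = tf / n_steps`; the score is
#' queried at the current state and time of each step.
#'
#' @param tf Total trajectory time (> 0); the toy experiments use `tf = 1`.
#' @param n_steps Number of steps (>= 1).
#' @param denoise_last `NULL` (process default: on for passive, off for
#'   active) or logical.  When on, the final update keeps only the drift term
#'   and sets the noise to zero; for the active process the denoising applies
#'   to the eta dimension and leaves x unchanged in that step.
#' @return An object of class `reverse_schedule` with fields `tf`, `n_steps`,
#'   `dt`, `denoise_last`.
#' @export
reverse_schedule <- function(tf = 1, n_steps = 500, denoise_last = NULL) {
  stopifnot(tf > 0, n_steps >= 1)
  structure(list(tf = tf, n_steps = as.integer(n_steps), dt = tf / n_steps,
                 denoise_last = denoise_last),
            class = "reverse_schedule")
}

#' One Euler-Maruyama step of the passive reverse-time SDE
#'
#' The time reversal of \eqn{\dot x = -kx + \xi} has backward drift
#' \eqn{+kx + 2T\,\mathcal{F}(x,t)} and noise variance \eqn{2T\,dt} per step,
#' which preserves a stationary Gaussian under its exact score.
#'
#' @param x n x d matrix, current state.
#' @param score_value n x d matrix, score evaluated at `(x, t)`.
#' @param params `passive_params`.
#' @param dt Step size (> 0).
#' @param noise n x d matrix of standard normal draws (ignored when
#'   `drift_only`).
#' @param drift_only If `TRUE`, apply only the drift term (final denoising
#'   step).
#' @return Updated n x d matrix.
#' @export
reverse_step_passive <- function(x, score_value, params, dt, noise,
                                 drift_only = FALSE) {
  stopifnot(dt > 0)
  out <- x + dt * (params$k * x + 2 * params$T * score_value)
  if (!drift_only) out <- out + sqrt(2 * params$T * dt) * noise
  out
}

#' One Euler-Maruyama step of the active reverse-time SDE
#'
#' Coupled update of the augmented state: the backward x-drift is
#' \eqn{kx - \eta + 2T_p\mathcal{F}_x} with noise variance \eqn{2T_p dt}, and
#' the backward eta-drift is \eqn{\eta/\tau + (2T_a/\tau^2)\mathcal{F}_\eta}
#' with noise variance \eqn{(2T_a/\tau^2) dt}.  With `Tp = 0` the x-update is
#' deterministic given eta and the x-score is never needed.
#'
#' @param x,eta n x d matrices, current augmented state.
#' @param fx n x d matrix of x-scores, or `NULL` when `Tp = 0`.
#' @param feta n x d matrix of eta-scores.
#' @param params `active_params`.
#' @param dt Step size (> 0).
#' @param noise_x,noise_eta n x d matrices of standard normal draws.
#' @param denoise_eta If `TRUE`, this is the final denoising step: eta is
#'   updated with drift only and x is left unchanged.
#' @return A list with updated matrices `x` and `eta`.
#' @export
reverse_step_active <- function(x, eta, fx, feta, params, dt,
                                noise_x, noise_eta, denoise_eta = FALSE) {
  stopifnot(dt > 0)
  if (denoise_eta) {
    eta_new <- eta + dt * (eta / params$tau +
                             (2 * params$Ta / params$tau^2) * feta)
    return(list(x = x, eta = eta_new))
  }
  xdrift <- params$k * x - eta
  if (params$Tp > 0) {
    stopifnot(!is.null(fx))
    xdrift <- xdrift + 2 * params$Tp * fx
  }
  x_new <- x + dt * xdrift
  if (params$Tp > 0) x_new <- x_new + sqrt(2 * params$Tp * dt) * noise_x
  eta_new <- eta + dt * (eta / params$tau +
                           (2 * params$Ta / params$tau^2) * feta) +
    sqrt(2 * params$Ta * dt) / params$tau * noise_eta
  list(x = x_new, eta = eta_new)
}

#' Analytic score provider for a Gaussian-mixture target
#'
#' Wraps [passive_score()] / [active_score()] into the provider interface
#' consumed by [generate()]: an object with a `$score(x, eta, t)` method
#' returning `list(x = , eta = )` (eta `NULL` for passive processes).
#'
#' @param gmm A [gaussian_mixture()].
#' @param params Process parameters.
#' @param eta0_policy Forward eta initialization assumed by the score.
#' @return An object of class `score_provider`.
#' @export
score_provider_analytic <- function(gmm, params,
                                    eta0_policy = c("stationary", "zero")) {
  eta0_policy <- match.arg(eta0_policy)
  if (is_active(params)) {
    fn <- function(x, eta, t) {
      active_score(gmm, params, t, x, eta, eta0_policy = eta0_policy)
    }
  } else {
    fn <- function(x, eta, t) list(x = passive_score(gmm, params, t, x),
                                   eta = NULL)
  }
  structure(list(process = if (is_active(params)) "active" else "passive",
                 score = fn, kind = "analytic"),
            class = "score_provider")
}

#' @export
print.score_provider <- function(x, ...) {
  cat(sprintf("score provider: %s (%s)\n", x$process, x$kind))
  invisible(x)
}

#' Generate samples by reverse-time integration
#'
#' Initializes walkers from the exact stationary law of the forward process
#' (passive: \eqn{N(0, T/k)}; active: the joint stationary covariance), or
#' from a supplied ensemble at `t = tf`, and integrates the reverse-time SDE
#' to `t = 0` on the uniform grid of `schedule`.
#'
#' @param score_provider A `score_provider` (analytic or trained).
#' @param params Process parameters.
#' @param schedule A [reverse_schedule()].
#' @param n_samples Number of walkers (ignored when `start` is supplied).
#' @param d Data dimension (ignored when `start` is supplied).
#' @param seed Optional integer seed.
#' @param start Optional [aug_ensemble()] at time `tf` to start from (used by
#'   the partial-noise/resample experiments).
#' @return An [aug_ensemble()] at `t = 0`.
#' @export
generate <- function(score_provider, params, schedule, n_samples = NULL,
                     d = NULL, seed = NULL, start = NULL) {
  stopifnot(inherits(schedule, "reverse_schedule"))
  if (!is.null(seed)) set.seed(seed)
  active <- is_active(params)
  denoise <- schedule$denoise_last
  if (is.null(denoise)) denoise <- !active
  dt <- schedule$dt
  if (is.null(start)) {
    stopifnot(!is.null(n_samples), !is.null(d))
    n <- n_samples
    if (active) {
      S <- stationary_moments(params)
      L <- chol2_lower(S)
      w1 <- matrix(stats::rnorm(n * d), n, d)
      w2 <- matrix(stats::rnorm(n * d), n, d)
      x <- L[1, 1] * w1
      eta <- L[2, 1] * w1 + L[2, 2] * w2
    } else {
      x <- matrix(stats::rnorm(n * d, sd = sqrt(params$T / params$k)), n, d)
      eta <- NULL
    }
  } else {
    stopifnot(inherits(start, "aug_ensemble"))
    x <- start$x
    eta <- start$eta
    n <- nrow(x); d <- ncol(x)
    if (active && is.null(eta)) stop("generate: active start needs eta")
  }
  for (j in seq_len(schedule$n_steps)) {
    t_cur <- schedule$tf - (j - 1) * dt
    last <- j == schedule$n_steps
    sc <- tryCatch(score_provider$score(x, eta, t_cur),
                   error = function(e) {
                     stop(sprintf("score provider failed at grid time %g: %s",
                                  t_cur, conditionMessage(e)), call. = FALSE)
                   })
    if (active) {
      st <- reverse_step_active(x, eta, sc$x, sc$eta, params, dt,
                                matrix(stats::rnorm(n * d), n, d),
                                matrix(stats::rnorm(n * d), n, d),
                                denoise_eta = last && denoise)
      x <- st$x; eta <- st$eta
    } else {
      x <- reverse_step_passive(x, sc$x, params, dt,
                                matrix(stats::rnorm(n * d), n, d),
                                drift_only = last && denoise)
    }
  }
  aug_ensemble(x, eta, t = 0, params = params,
               seed_record = if (is.null(seed)) NA else seed)
}
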