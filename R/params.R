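#' Passive (white-noise) forward-process parameters
#'
#' The passive forward process is overdamped Brownian motion in a harmonic
#' trap, \eqn{\dot x = -k x + \xi(t)} with \eqn{\langle\xi_i(t)\xi_j(t')\rangle
#' = 2T\,\delta_{ij}\delta(t-t')}.  Its stationary law is an isotropic
#' Gaussian with mean 0 and variance \eqn{T/k} per dimension.
#'
#' @param k Trap stiffness (1/time), strictly positive.
#' @param T Temperature (data units squared), strictly positive.
#' @return An object of class `passive_params`.
#' @seealso [active_params()]
#' @export
#' @examples
#' p <- passive_params(k = 1, T = 1)
#' stationary_moments(p)  # T/k
passive_params <- function(k, T) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0)
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T), T > 0)
  structure(list(k = as.numeric(k), T = as.numeric(T)),
            class = "passive_params")
}

#' Active (Ornstein-Uhlenbeck noise) forward-process parameters
#'
#' Each data coordinate \eqn{x_i} is driven by a persistent auxiliary noise
#' coordinate \eqn{\eta_i}:
#' \deqn{\dot x = -k x + \eta + \xi_1, \qquad \dot\eta = -\eta/\tau + \xi_2,}
#' with white-noise intensities \eqn{2 T_p} for \eqn{\xi_1} and
#' \eqn{2 T_a/\tau^2} for \eqn{\xi_2}.  The persistence time `tau` sets the
#' correlation time of the active forcing; `tau -> 0` recovers a passive
#' process with temperature `Tp + Ta`.
#'
#' `Tp = 0` is allowed: the forward x-equation then carries no white noise of
#' its own, and the reverse-time x-equation becomes deterministic given
#' \eqn{\eta} (its score term and noise both carry a factor \eqn{2T_p}).
#'
#' @param k Trap stiffness (> 0).
#' @param Tp Passive temperature (>= 0).
#' @param Ta Active temperature (> 0).
#' @param tau Persistence time of the active noise (> 0).
#' @return An object of class `active_params`.
#' @export
#' @examples
#' active_params(k = 1, Tp = 1e-3, Ta = 1, tau = 0.5)
active_params <- function(k, Tp, Ta, tau) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0)
  stopifnot(is.numeric(Tp), length(Tp) == 1L, is.finite(Tp), Tp >= 0)
  stopifnot(is.numeric(Ta), length(Ta) == 1L, is.finite(Ta), Ta > 0)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0)
  structure(list(k = as.numeric(k), Tp = as.numeric(Tp),
                 Ta = as.numeric(Ta), tau = as.numeric(tau)),
            class = "active_params")
}

#' @export
print.passive_params <- function(x, ...) {
  cat(sprintf("passive process: k = %g, T = %g (stationary var %g)\n",
              x$k, x$T, x$T / x$k))
  invisible(x)
}

#' @export
print.active_params <- function(x, ...) {
  cat(sprintf("active process: k = %g, Tp = %g, Ta = %g, tau = %g\n",
              x$k, x$Tp, x$Ta, x$tau))
  cat(sprintf("  stationary Var(x) = %g, Var(eta) = %g, Cov(x,eta) = %g\n",
              x$Tp / x$k + x$Ta / (x$k * (1 + x$k * x$tau)),
              x$Ta / x$tau, x$Ta / (1 + x$k * x$tau)))
  invisible(x)
}

is_active <- function(params) inherits(params, "active_params")

#' Serialize process parameters to JSON
#'
#' Passive parameters use keys `{"k","T"}`, active parameters
#' `{"k","Tp","Ta","tau"}`; [read_params()] dispatches on the keys present.
#'
#' @param params A `passive_params` or `active_params` object.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$tau)) {
    active_params(k = obj$k, Tp = obj$Tp, Ta = obj$Ta, tau = obj$tau)
  } else {
    passive_params(k = obj$k, T = obj$T)
  }
}
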