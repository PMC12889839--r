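#' Fisher memory matrix of the forward process
#'
#' For the linear forward SDE with Jacobian \eqn{M} and time-`t` covariance
#' \eqn{C_t}, the KL divergence between the conditionals started at
#' \eqn{X_0 + \delta X_0} and \eqn{X_0} is the quadratic form
#' \eqn{\tfrac12\,\delta X_0^\top F_t\, \delta X_0} with
#' \eqn{F_t = e^{M^\top t} C_t^{-1} e^{M t}} — independent of the base input
#' \eqn{X_0}.  The dynamics are dimension-wise independent, so the 2d x 2d
#' matrix is block diagonal and only the per-dimension block is returned
#' (2x2 active, 1x1 passive).
#'
#' With `Tp = 0` the xx-block of \eqn{C_t} is \eqn{O(t^3)} at small `t`;
#' inversion falls back to a relative ridge of 1e-12 when the covariance is
#' numerically singular, rather than inventing noise.
#'
#' @param params `active_params` or `passive_params`.
#' @param t Time, strictly positive.
#' @return Per-dimension Fisher memory matrix.
#' @export
fisher_memory_matrix <- function(params, t) {
  if (t <= 0) stop("fisher_memory_matrix: t must be > 0")
  tm <- transition_moments(params, t)
  G <- tm$propagator
  C <- tm$covariance
  if (nrow(C) == 1L) {
    if (C[1, 1] <= 0) stop("fisher_memory_matrix: singular covariance")
    return(matrix(G[1, 1]^2 / C[1, 1], 1, 1))
  }
  det <- C[1, 1] * C[2, 2] - C[1, 2]^2
  scale <- max(C[1, 1], C[2, 2])
  if (!is.finite(det) || det <= 1e-300) {
    if (scale <= 0) stop("fisher_memory_matrix: singular covariance")
    C <- C + diag(1e-12 * scale, 2)
    det <- C[1, 1] * C[2, 2] - C[1, 2]^2
  }
  Cinv <- matrix(c(C[2, 2], -C[1, 2], -C[1, 2], C[1, 1]), 2, 2) / det
  t(G) %*% Cinv %*% G
}

#' Fisher memory curve
#'
#' The trace of the Fisher memory matrix over all state indices, normalized
#' by the data dimension.  Block-diagonality across dimensions makes this the
#' trace of the per-dimension block: \eqn{\mathrm{FMC}(t)/d =
#' \mathrm{tr}\,F_t^{(2\times2)}} for the active process and the scalar
#' \eqn{e^{-2kt} k / (T(1-e^{-2kt}))} for the passive one.  Larger
#' persistence times `tau` slow the decay of this curve.
#'
#' @param params Process parameters.
#' @param times Strictly positive, strictly increasing time grid.
#' @return An object of class `fisher_memory_curve` with fields `times`,
#'   `values` (FMC per data dimension), `params`.
#' @export
fmc_curve <- function(params, times) {
  stopifnot(all(times > 0), !is.unsorted(times, strictly = TRUE))
  values <- vapply(times,
                   function(t) sum(diag(fisher_memory_matrix(params, t))),
                   numeric(1))
  structure(list(times = times, values = values, params = params),
            class = "fisher_memory_curve")
}

#' @export
print.fisher_memory_curve <- function(x, ...) {
  cat(sprintf("Fisher memory curve on %d times in [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Speciation time of the active reverse process
#'
#' The forward-process time (measured from the data distribution at t = 0) at
#' which reverse trajectories commit to a mode:
#' \deqn{t_s^a = \tfrac12 \log\!\big(\max\lambda(C_0)\,(1+\tau)/T_a\big),}
#' where \eqn{\max\lambda(C_0)} is the largest eigenvalue of the data
#' covariance.  Implemented exactly as printed (stiffness absorbed into the
#' time unit).
#'
#' @param lambda_max Largest eigenvalue of the data covariance (> 0).
#' @param Ta Active temperature (> 0).
#' @param tau Persistence time (>= 0; 0 gives the passive expression with
#'   `Tp = Ta`).
#' @return Speciation time (may be negative if the data variance is small
#'   relative to the temperature, as the formula dictates).
#' @export
speciation_time_active <- function(lambda_max, Ta, tau) {
  stopifnot(lambda_max > 0, Ta > 0, tau >= 0)
  0.5 * log(lambda_max * (1 + tau) / Ta)
}

#' Speciation time of the passive reverse process
#'
#' \deqn{t_s^p = \tfrac12 \log\!\big(\max\lambda(C_0)/T_p\big).}
#' For equal temperatures `Ta = Tp` and any data covariance,
#' \eqn{t_s^a - t_s^p = \tfrac12\log(1+\tau) > 0}: the active process
#' speciates at a larger forward time, i.e. earlier in the reverse process.
#'
#' @param lambda_max Largest eigenvalue of the data covariance (> 0).
#' @param Tp Passive temperature (> 0).
#' @return Speciation time.
#' @export
speciation_time_passive <- function(lambda_max, Tp) {
  stopifnot(lambda_max > 0, Tp > 0)
  0.5 * log(lambda_max / Tp)
}

#' Equivalent passive temperature of an active process
#'
#' The white-noise temperature whose stationary data variance matches the
#' active process's: \eqn{T = T_p + T_a/(1 + k\tau)}, i.e.
#' \eqn{T/k = \mathrm{Var}_\infty(x)}.
#'
#' @param params `active_params`.
#' @return Temperature (scalar).
#' @export
#' @examples
#' equivalent_passive_temperature(active_params(1, 0, 1, 2))  # 1/3
equivalent_passive_temperature <- function(params) {
  stopifnot(is_active(params))
  params$Tp + params$Ta / (1 + params$k * params$tau)
}
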