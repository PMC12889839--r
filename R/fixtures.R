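# Synthetic target distributions for the toy experiments.  The exact
# generating law is returned alongside the samples wherever one exists, so
# analytic scores and Bayes classification are available downstream.

#' Nine-Gaussian "diamond" mixture in 2D
#'
#' Nine equal-weight isotropic components on the diamond lattice
#' `{(0,0), (+-s,0), (0,+-s), (+-s/2,+-s/2)}`, rescaled so the mixture has
#' unit variance per dimension.  Used as the analytic-score benchmark target.
#'
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @param spacing Lattice scale `s` before rescaling (default 2).
#' @param sigma Component standard deviation before rescaling (default 0.1).
#' @return A list with `x` (n x 2), `labels` (component of each sample) and
#'   `gmm` (the exact [gaussian_mixture()]).
#' @export
diamond_gmm <- function(n, seed = NULL, spacing = 2, sigma = 0.1) {
  s <- spacing
  means <- rbind(c(0, 0), c(s, 0), c(-s, 0), c(0, s), c(0, -s),
                 c(s / 2, s / 2), c(s / 2, -s / 2),
                 c(-s / 2, s / 2), c(-s / 2, -s / 2))
  # per-dimension variance of the lattice is s^2/3; rescale to unit variance
  scl <- 1 / sqrt(s^2 / 3 + sigma^2)
  gmm <- gaussian_mixture(rep(1 / 9, 9), means * scl, (sigma * scl)^2)
  smp <- sample_gmm(gmm, n, seed = seed)
  list(x = smp$x, labels = smp$labels, gmm = gmm)
}

#' Overlapping Swiss rolls in 2D
#'
#' `n_rolls` Archimedean spirals with offset centers chosen so neighbouring
#' rolls overlap; the target has structure at two length scales (roll
#' placement and interior winding).
#'
#' @param n Total number of samples (split evenly across rolls).
#' @param n_rolls Number of rolls (default 2).
#' @param seed Optional integer seed.
#' @param noise Gaussian jitter standard deviation around the spiral
#'   (default 0.05).
#' @return A list with `x` (n x 2) and `labels` (roll index).
#' @export
swiss_rolls <- function(n, n_rolls = 2, seed = NULL, noise = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  per <- diff(round(seq(0, n, length.out = n_rolls + 1)))
  centers <- cbind(0.9 * (seq_len(n_rolls) - (n_rolls + 1) / 2), 0)
  xs <- vector("list", n_rolls)
  for (j in seq_len(n_rolls)) {
    m <- per[j]
    theta <- stats::runif(m, 1.5 * pi, 4.5 * pi)
    r <- theta / (4.5 * pi)  # radius grows to 1 at the outer edge
    pts <- cbind(r * cos(theta), r * sin(theta)) +
      matrix(stats::rnorm(2 * m, sd = noise), m, 2)
    xs[[j]] <- sweep(pts, 2, centers[j, ], "+")
  }
  list(x = do.call(rbind, xs),
       labels = rep(seq_len(n_rolls), per))
}

#' One-dimensional multi-peak landscapes
#'
#' `coarse3`: three equal-weight, essentially non-overlapping peaks.
#' `fine5`: one dominant peak plus four minor closely overlapping peaks
#' (weights 0.8 and 4 x 0.05).
#'
#' @param kind `"coarse3"` or `"fine5"`.
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return A list with `x` (n x 1), `labels` and `gmm`.
#' @export
multi_peak_1d <- function(kind = c("coarse3", "fine5"), n, seed = NULL) {
  kind <- match.arg(kind)
  gmm <- if (kind == "coarse3") {
    gaussian_mixture(rep(1 / 3, 3), cbind(c(-3, 0, 3)), 0.3^2)
  } else {
    gaussian_mixture(c(0.8, rep(0.05, 4)),
                     cbind(c(0, -1.6, -0.8, 0.8, 1.6)),
                     cbind(c(1, 0.3, 0.3, 0.3, 0.3)^2))
  }
  smp <- sample_gmm(gmm, n, seed = seed)
  list(x = smp$x, labels = smp$labels, gmm = gmm)
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution,
# vectorized; mu and the result are in radians.
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    m <- length(todo)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    ce <- kappa * (r - f)
    ok <- (ce * (2 - ce) - u2 > 0) | (log(ce / u2) + 1 - ce >= 0)
    out[todo[ok]] <- sign(u3[ok] - 0.5) * acos(pmax(pmin(f[ok], 1), -1)) + mu
    todo <- todo[!ok]
  }
  out
}

# wrap angles in degrees to the half-open Ramachandran range [-180, 180)
wrap_degrees <- function(x) ((x + 180) %% 360) - 180

#' Dihedral-angle proxy: a von Mises mixture on the Ramachandran torus
#'
#' Stands in for alanine-dipeptide (phi, psi) sampling: three basins at the
#' conformations alphaR (-60, -45), PII (-75, 145) and C5 (-180, 180)
#' degrees, sampled from independent von Mises laws per angle and wrapped to
#' the half-open square [-180, 180)^2.
#'
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @param weights Basin weights (alphaR, PII, C5); default `c(0.5, 0.35,
#'   0.15)`.
#' @param kappa von Mises concentration per angle (default 8, circular sd of
#'   roughly 20 degrees).
#' @return A list with `x` (n x 2, degrees), `labels`, `centers` (3 x 2
#'   matrix of basin centers in degrees) and `weights`.
#' @export
dihedral_proxy <- function(n, seed = NULL, weights = c(0.5, 0.35, 0.15),
                           kappa = 8) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(weights) == 3, all(weights > 0))
  weights <- weights / sum(weights)
  centers <- rbind(alphaR = c(-60, -45), PII = c(-75, 145), C5 = c(-180, 180))
  labels <- sample.int(3, n, replace = TRUE, prob = weights)
  x <- matrix(NA_real_, n, 2)
  for (b in 1:3) {
    idx <- which(labels == b)
    if (!length(idx)) next
    for (j in 1:2) {
      x[idx, j] <- wrap_degrees(
        rvonmises(length(idx), centers[b, j] * pi / 180, kappa) * 180 / pi)
    }
  }
  colnames(x) <- c("phi", "psi")
  list(x = x, labels = labels, centers = centers, weights = weights)
}

#' Three-class well-separated 2D Gaussian mixture
#'
#' Equal-weight isotropic components at the vertices of an equilateral
#' triangle, rescaled to approximately unit variance per dimension; the
#' labelled target for the partial-noise/resample class-recovery experiments.
#'
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @param radius Circumradius of the triangle before rescaling (default 2).
#' @param sigma Component standard deviation before rescaling (default 0.25).
#' @return A list with `x`, `labels` and `gmm`.
#' @export
triangle_gmm <- function(n, seed = NULL, radius = 2, sigma = 0.25) {
  ang <- c(90, 210, 330) * pi / 180
  means <- radius * cbind(cos(ang), sin(ang))
  scl <- 1 / sqrt(radius^2 / 2 + sigma^2)
  gmm <- gaussian_mixture(rep(1 / 3, 3), means * scl, (sigma * scl)^2)
  smp <- sample_gmm(gmm, n, seed = seed)
  list(x = smp$x, labels = smp$labels, gmm = gmm)
}
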