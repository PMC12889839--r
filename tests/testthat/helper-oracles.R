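# Independent oracles used across the suite.  These deliberately avoid the
# package's closed-form code paths: brute-force Euler-Maruyama integration,
# central finite differences, quadrature, and exhaustive enumeration.

# Euler-Maruyama integration of the active forward SDE (Tp/Ta intensities),
# z0 an n x 2 matrix of (x, eta) initial conditions
em_forward_active <- function(params, z0, t, dt = 1e-3) {
  n <- nrow(z0)
  x <- z0[, 1]
  e <- z0[, 2]
  n_steps <- round(t / dt)
  for (i in seq_len(n_steps)) {
    x_new <- x + dt * (-params$k * x + e) +
      sqrt(2 * params$Tp * dt) * stats::rnorm(n)
    e <- e + dt * (-e / params$tau) +
      sqrt(2 * params$Ta * dt) / params$tau * stats::rnorm(n)
    x <- x_new
  }
  cbind(x, e)
}

em_forward_passive <- function(params, x0, t, dt = 1e-3) {
  x <- x0
  for (i in seq_len(round(t / dt))) {
    x <- x + dt * (-params$k * x) +
      sqrt(2 * params$T * dt) * stats::rnorm(length(x))
  }
  x
}

# central finite difference of the log noised-mixture density
fd_passive_score <- function(gmm, params, t, x, h = 1e-5) {
  nm <- noised_mixture(gmm, params, t)
  vapply(seq_along(x), function(j) {
    u <- x; v <- x
    u[j] <- u[j] + h; v[j] <- v[j] - h
    (noised_mixture_logpdf(nm, u) - noised_mixture_logpdf(nm, v)) / (2 * h)
  }, numeric(1))
}

fd_active_score <- function(gmm, params, t, x, eta, h = 1e-5) {
  nm <- noised_mixture(gmm, params, t)
  fx <- vapply(seq_along(x), function(j) {
    u <- x; v <- x
    u[j] <- u[j] + h; v[j] <- v[j] - h
    (noised_mixture_logpdf(nm, u, eta) -
       noised_mixture_logpdf(nm, v, eta)) / (2 * h)
  }, numeric(1))
  fe <- vapply(seq_along(eta), function(j) {
    u <- eta; v <- eta
    u[j] <- u[j] + h; v[j] <- v[j] - h
    (noised_mixture_logpdf(nm, x, u) -
       noised_mixture_logpdf(nm, x, v)) / (2 * h)
  }, numeric(1))
  list(x = fx, eta = fe)
}

# KL divergence between two Gaussians with means m1, m0 and common 2x2
# covariance C, via the standard formula (solve(), not the package inverse)
gaussian_kl_shifted <- function(m1, m0, C) {
  d <- m1 - m0
  as.numeric(0.5 * t(d) %*% solve(C, d))
}

# exhaustive-enumeration root posterior for tiny grammars: sums the channel
# likelihood over every root symbol and every combination of rule choices
enum_root_posterior <- function(noised, grammar, params,
                                marginal = FALSE) {
  p <- grammar$params
  v <- p$v
  ch_loglik <- function(leaves) {
    tm <- transition_moments(params, noised$t)
    ll <- 0
    for (i in seq_along(leaves)) {
      for (w in seq_len(v)) {
        x0 <- as.numeric(leaves[i] == w)
        if (is_active(params)) {
          G <- tm$propagator
          s0 <- params$Ta / params$tau
          S <- G %*% diag(c(0, s0)) %*% t(G) + tm$covariance
          z <- c(noised$x[i, w], noised$eta[i, w])
          m <- c(G[1, 1] * x0, 0)
          if (marginal) {
            ll <- ll + stats::dnorm(z[1], m[1], sqrt(S[1, 1]), log = TRUE)
          } else {
            dz <- z - m
            ll <- ll - 0.5 * (t(dz) %*% solve(S, dz) +
                                determinant(S)$modulus + 2 * log(2 * pi))
          }
        } else {
          ll <- ll + stats::dnorm(noised$x[i, w],
                                  tm$propagator[1, 1] * x0,
                                  sqrt(tm$covariance[1, 1]), log = TRUE)
        }
      }
    }
    as.numeric(ll)
  }
  # expand a root through every combination of rule choices
  expand_all <- function(syms, level) {
    if (level > p$L) return(list(syms))
    out <- list()
    n_nodes <- length(syms)
    rule_grid <- as.matrix(expand.grid(rep(list(seq_len(p$m)), n_nodes)))
    for (g in seq_len(nrow(rule_grid))) {
      child <- integer(0)
      for (j in seq_len(n_nodes)) {
        child <- c(child, grammar$prod[[level]][syms[j], rule_grid[g, j], ])
      }
      out <- c(out, expand_all(child, level + 1L))
    }
    out
  }
  logpost <- vapply(seq_len(v), function(root) {
    leaves_set <- expand_all(root, 1L)
    lls <- vapply(leaves_set, ch_loglik, numeric(1))
    mx <- max(lls)
    mx + log(mean(exp(lls - mx)))  # uniform rule prior
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w / sum(w)
}

# smallest nontrivial fixtures shared by several files
toy_gmm_1d <- function() {
  gaussian_mixture(c(0.6, 0.4), rbind(-1, 1.3), cbind(c(0.08, 0.15)))
}

toy_gmm_2d <- function() diamond_gmm(10, seed = 1)$gmm
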