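test_that("gaussian_mixture validates and normalizes", {
  g <- gaussian_mixture(c(2, 2), rbind(-1, 1), 0.1)
  expect_equal(g$weights, c(0.5, 0.5))
  expect_error(gaussian_mixture(c(0.5, -0.5), rbind(-1, 1), 0.1))
  expect_error(gaussian_mixture(c(0.5, 0.5), rbind(-1, 1), 0))
  js <- tempfile(fileext = ".json")
  write_gmm(toy_gmm_1d(), js)
  expect_equal(read_gmm(js), toy_gmm_1d())
})

test_that("noised mixture: t = 0 passive identity and long-time limit", {
  g <- toy_gmm_1d()
  p <- passive_params(1, 0.8)
  nm0 <- noised_mixture(g, p, 0)
  expect_equal(nm0$means, g$means)
  expect_equal(nm0$vars, g$variances)
  nm_inf <- noised_mixture(gaussian_mixture(1, matrix(3), matrix(0.1)), p, 40)
  expect_equal(nm_inf$means[1, 1], 0, tolerance = 1e-12)
  expect_equal(nm_inf$vars[1, 1], 0.8)  # T/k
  # degenerate active joint at t = 0 with the zero-eta policy is rejected
  expect_error(noised_mixture(g, active_params(1, 0, 1, 1), 0,
                              eta0_policy = "zero"), "degenerate")
})

test_that("noised-mixture x-marginal matches exact forward sampling (KS)", {
  g <- toy_gmm_1d()
  p <- active_params(1, 0.01, 1, 0.5)
  t <- 0.7
  smp <- sample_gmm(g, 20000, seed = 21)
  ens <- sample_forward(p, smp$x, t, seed = 22)
  nm <- noised_mixture(g, p, t)
  marg_cdf <- function(q) {
    sapply(q, function(qi) {
      sum(nm$weights * pnorm(qi, nm$means[, 1], sqrt(nm$sxx[, 1])))
    })
  }
  ks <- suppressWarnings(ks.test(as.vector(ens$x), marg_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("passive score: closed form, symmetry, finite differences", {
  p <- passive_params(1, 1)
  g1 <- gaussian_mixture(1, matrix(0.7), matrix(0.2))
  t <- 0.4
  a <- exp(-t); Dt <- 1 - exp(-2 * t)
  x <- 0.3
  expect_equal(passive_score(g1, p, t, x)[1, 1],
               -(x - 0.7 * a) / (0.2 * a^2 + Dt))
  gs <- gaussian_mixture(c(0.5, 0.5), rbind(-1, 1), 0.1)
  expect_equal(passive_score(gs, p, 0.3, 0)[1, 1], 0)
  dm <- toy_gmm_2d()
  x <- c(0.5, -0.2)
  expect_equal(as.vector(passive_score(dm, p, 0.3, x)),
               fd_passive_score(dm, p, 0.3, x), tolerance = 1e-6)
})

test_that("active score: stationary linear form, symmetry, FD property", {
  p <- active_params(1, 0.1, 1, 0.5)
  # single zero-mean component, t large: joint is the stationary Gaussian
  g1 <- gaussian_mixture(1, matrix(0), matrix(0.3))
  S <- stationary_moments(p)
  z <- c(0.4, -0.8)
  sc <- active_score(g1, p, 25, z[1], z[2])
  lin <- -solve(S, z)
  expect_equal(c(sc$x[1, 1], sc$eta[1, 1]), lin, tolerance = 1e-6)
  # symmetric mixture at the origin
  gs <- gaussian_mixture(c(0.5, 0.5), rbind(-1, 1), 0.1)
  sc0 <- active_score(gs, p, 0.5, 0, 0)
  expect_equal(sc0$x[1, 1], 0)
  expect_equal(sc0$eta[1, 1], 0)
  # property-based finite-difference agreement over (x, eta, t)
  set.seed(31)
  g3 <- gaussian_mixture(c(0.2, 0.5, 0.3), rbind(-1.5, 0, 1), 0.1)
  for (rep in 1:8) {
    t <- runif(1, 0.05, 2)
    x <- rnorm(1, sd = 1.5); eta <- rnorm(1, sd = 1.5)
    sc <- active_score(g3, p, t, x, eta)
    fd <- fd_active_score(g3, p, t, x, eta)
    expect_equal(sc$x[1, 1], fd$x, tolerance = 1e-6)
    expect_equal(sc$eta[1, 1], fd$eta, tolerance = 1e-6)
  }
  # 2D mixture, both gradients
  dm <- toy_gmm_2d()
  x <- c(0.4, -0.3); eta <- c(-0.6, 0.2)
  sc <- active_score(dm, p, 0.5, x, eta)
  fd <- fd_active_score(dm, p, 0.5, x, eta)
  expect_equal(as.vector(sc$x), fd$x, tolerance = 1e-6)
  expect_equal(as.vector(sc$eta), fd$eta, tolerance = 1e-6)
})

test_that("score integrates to zero against the noised density", {
  g <- gaussian_mixture(c(0.3, 0.7), rbind(-1, 0.8), cbind(c(0.1, 0.2)))
  p <- passive_params(1, 1)
  xs <- seq(-8, 8, length.out = 4001)
  nm <- noised_mixture(g, p, 0.4)
  dens <- exp(noised_mixture_logpdf(nm, matrix(xs)))
  sc <- passive_score(g, p, 0.4, matrix(xs))[, 1]
  expect_lt(abs(sum(dens * sc) * diff(xs[1:2])), 1e-8)
  # active joint in (x, eta) by 2D quadrature
  pa <- active_params(1, 0.1, 1, 0.5)
  gr <- expand.grid(x = seq(-6, 6, length.out = 241),
                    e = seq(-8, 8, length.out = 241))
  nma <- noised_mixture(g, pa, 0.6)
  da <- exp(noised_mixture_logpdf(nma, matrix(gr$x), matrix(gr$e)))
  sca <- active_score(g, pa, 0.6, matrix(gr$x), matrix(gr$e))
  cell <- diff(seq(-6, 6, length.out = 241)[1:2]) *
    diff(seq(-8, 8, length.out = 241)[1:2])
  expect_lt(abs(sum(da * sca$x[, 1]) * cell), 1e-6)
  expect_lt(abs(sum(da * sca$eta[, 1]) * cell), 1e-6)
})

test_that("tau -> 0: active x-marginal score matches passive score", {
  g <- toy_gmm_1d()
  pa <- active_params(1, 0.4, 0.6, 1e-4)
  pp <- passive_params(1, 1)
  t <- 0.5
  nma <- noised_mixture(g, pa, t)
  xs <- matrix(seq(-2, 2, length.out = 21))
  # marginal score from the x-block of the joint component moments
  marg <- sapply(seq_len(nrow(xs)), function(i) {
    ll <- log(nma$weights) +
      dnorm(xs[i], nma$means[, 1], sqrt(nma$sxx[, 1]), log = TRUE)
    r <- exp(ll - max(ll)); r <- r / sum(r)
    sum(r * (-(xs[i] - nma$means[, 1]) / nma$sxx[, 1]))
  })
  expect_equal(marg, as.vector(passive_score(g, pp, t, xs)),
               tolerance = 1e-2)
})

test_that("conditional score targets: closed forms and MC identity", {
  p <- passive_params(1, 1)
  expect_error(conditional_score_target(p, 0, 1, 1), "t must be > 0")
  a <- exp(-0.5)
  expect_equal(conditional_score_target(p, 0.5, matrix(a), matrix(1))[1, 1],
               0)
  expect_equal(conditional_score_target(p, 0.5, matrix(0), matrix(1))[1, 1],
               a / (1 - exp(-1)))
  # averaging targets over the posterior reproduces the score at an x_t bin
  g <- toy_gmm_1d()
  set.seed(41)
  n <- 200000
  x0 <- sample_gmm(g, n)$x
  t <- 0.5
  Dt <- 1 - exp(-2 * t)
  x_t <- x0 * a + sqrt(Dt) * matrix(rnorm(n))
  tgt <- conditional_score_target(p, t, x_t, x0)
  bin <- abs(x_t - 0.3) < 0.02
  mc <- mean(tgt[bin])
  se <- sd(tgt[bin]) / sqrt(sum(bin))
  truth <- passive_score(g, p, t, 0.3)[1, 1]
  expect_lt(abs(mc - truth), 3 * se + 0.02)
  # active target equals -C^{-1} (z_t - G z0) by definition
  pa <- active_params(1, 0.2, 1, 0.5)
  tm <- transition_moments(pa, 0.7)
  z0 <- c(0.5, -1); zt <- c(0.2, 0.4)
  resid <- zt - as.vector(tm$propagator %*% z0)
  want <- -solve(tm$covariance, resid)
  got <- conditional_score_target(pa, 0.7, matrix(zt[1]), matrix(z0[1]),
                                  matrix(zt[2]), matrix(z0[2]))
  expect_equal(c(got$x[1, 1], got$eta[1, 1]), want, tolerance = 1e-12)
})

test_that("sample_noised_mixture draws from the pushforward law", {
  g <- toy_gmm_1d()
  pa <- active_params(1, 0.1, 1, 0.5)
  nm <- noised_mixture(g, pa, 0.6)
  ens <- sample_noised_mixture(nm, 20000, seed = 51)
  ref <- sample_forward(pa, sample_gmm(g, 20000, seed = 52)$x, 0.6, seed = 53)
  expect_lt(energy_distance(cbind(ens$x, ens$eta), cbind(ref$x, ref$eta)),
            0.01)
})
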