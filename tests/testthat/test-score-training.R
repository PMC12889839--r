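# Training tests run at deliberately reduced desk-scale budgets (smaller
# nets / fewer iterations than the package defaults) so the whole suite
# stays within a CPU-minutes budget; the protocols are documented in the
# methods vignette.

test_that("DSM losses: validation, determinism, Tp = 0 reduction", {
  pp <- passive_params(1, 1)
  pa0 <- active_params(1, 0, 1, 0.5)
  x0 <- matrix(rnorm(64), 32, 2)
  z <- matrix(rnorm(64), 32, 2)
  t <- runif(32, 0.1, 1)
  expect_error(dsm_loss_passive(function(x, t) 0 * x, x0, c(0, t[-1]), z, pp),
               "positive")
  l1 <- dsm_loss_passive(function(x, t) 0 * x, x0, t, z, pp)
  expect_identical(dsm_loss_passive(function(x, t) 0 * x, x0, t, z, pp), l1)
  # with Tp = 0 the x-term is absent: swapping the x-model changes nothing
  eta0 <- matrix(rnorm(64), 32, 2)
  w1 <- matrix(rnorm(64), 32, 2); w2 <- matrix(rnorm(64), 32, 2)
  zero_model <- function(x, eta, t) 0 * x
  wild_model <- function(x, eta, t) x * 1e6
  la <- dsm_loss_active(list(eta = zero_model, x = zero_model),
                        x0, eta0, t, w1, w2, pa0)
  lb <- dsm_loss_active(list(eta = zero_model, x = wild_model),
                        x0, eta0, t, w1, w2, pa0)
  expect_identical(la, lb)
  # with Tp > 0 the x-term is formed and does change the loss
  pa <- active_params(1, 0.3, 1, 0.5)
  expect_gt(dsm_loss_active(list(eta = zero_model, x = wild_model),
                            x0, eta0, t, w1, w2, pa),
            dsm_loss_active(list(eta = zero_model, x = zero_model),
                            x0, eta0, t, w1, w2, pa))
})

test_that("the true score attains the analytic conditional-variance floor", {
  # passive single Gaussian: the DSM loss of the exact score equals
  # a^2 h / (Dt (Dt + a^2 h)) per dimension, not zero
  p <- passive_params(1, 1)
  mu <- 0.4; h <- 0.3; t0 <- 0.5
  g <- gaussian_mixture(1, matrix(mu), matrix(h))
  set.seed(301)
  n <- 60000
  x0 <- matrix(rnorm(n, mu, sqrt(h)))
  z <- matrix(rnorm(n))
  truth <- function(x, t) passive_score(g, p, t0, x)
  loss <- dsm_loss_passive(truth, x0, rep(t0, n), z, p)
  a <- exp(-t0); Dt <- 1 - exp(-2 * t0)
  floor <- a^2 * h / (Dt * (Dt + a^2 * h))
  expect_gt(floor, 0)
  expect_lt(abs(loss - floor) / floor, 0.05)
})

test_that("training is bitwise reproducible under a fixed seed", {
  g <- toy_gmm_1d()
  smp <- sample_gmm(g, 600, seed = 302)
  pp <- passive_params(1, 1)
  spec <- score_model_spec(1, "passive", hidden = c(16, 16), n_iter = 150,
                           batch = 64, seed = 303)
  f1 <- train_score_model(smp$x, pp, spec)
  f2 <- train_score_model(smp$x, pp, spec)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$models$score$net$W, f2$models$score$net$W)
})

test_that("smoothed training loss decreases on a toy fixture", {
  g <- toy_gmm_1d()
  smp <- sample_gmm(g, 2000, seed = 304)
  pp <- passive_params(1, 1)
  # t_min = 0.25: at smaller times the irreducible conditional-variance
  # floor (~1/Delta_t) swamps the reducible part of the unweighted loss
  spec <- score_model_spec(1, "passive", hidden = c(32, 32), n_iter = 1500,
                           batch = 128, t_min = 0.25, seed = 305)
  fit <- train_score_model(smp$x, pp, spec)
  ema <- stats::filter(fit$log$loss, rep(1 / 100, 100), sides = 1)
  ema <- ema[!is.na(ema)]
  checkpoints <- ema[round(seq(1, length(ema), length.out = 5))]
  expect_true(all(diff(checkpoints) < 0.02 * (checkpoints[1] -
                                                min(checkpoints))))
  expect_lt(ema[length(ema)], ema[1])
})

test_that("the empirical DSM minimizer approaches the known linear score", {
  # single-Gaussian dataset: the true score is linear in x; RMSE on
  # in-distribution points shrinks with the iteration budget
  g <- gaussian_mixture(1, matrix(0.5), matrix(0.3))
  smp <- sample_gmm(g, 3000, seed = 306)
  pp <- passive_params(1, 1)
  rmse_at <- function(iters) {
    spec <- score_model_spec(1, "passive", hidden = c(32, 32),
                            n_iter = iters, batch = 128, seed = 307)
    fit <- train_score_model(smp$x, pp, spec)
    err <- sapply(c(0.3, 0.6, 0.9), function(t) {
      xt <- sample_forward_passive(pp, sample_gmm(g, 400, seed = 308)$x, t,
                                   seed = 309)$x
      sqrt(mean((fit$provider$score(xt, NULL, t)$x -
                   passive_score(g, pp, t, xt))^2))
    })
    sqrt(mean(err^2))
  }
  early <- rmse_at(200)
  late <- rmse_at(2500)
  expect_lt(late, early)
  expect_lt(late, 0.15)
})

test_that("trained eta-score matches the analytic score (documented
           protocol)", {
  # 2-component 1D mixture, Tp = 0; documented budget: 3x64 tanh MLP,
  # 10000 Adam iterations, batch 256, lr 1e-3 decaying to 1e-4; RMSE on
  # in-distribution test points across t in [0.15, 0.95]
  g <- gaussian_mixture(c(0.5, 0.5), rbind(-1.2, 1.2), 0.05)
  pa <- active_params(1, 0, 1, 0.5)
  smp <- sample_gmm(g, 4000, seed = 1)
  spec <- score_model_spec(1, "active", hidden = c(64, 64, 64),
                          n_iter = 10000, batch = 256, seed = 2)
  fit <- train_score_model(smp$x, pa, spec)
  rms <- sapply(seq(0.15, 0.95, by = 0.1), function(t) {
    ens <- sample_forward(pa, sample_gmm(g, 400, seed = 100)$x, t, seed = 99)
    truth <- active_score(g, pa, t, ens$x, ens$eta)$eta
    pred <- fit$provider$score(ens$x, ens$eta, t)$eta
    sqrt(mean((pred - truth)^2))
  })
  expect_lt(sqrt(mean(rms^2)), 0.1)
})

test_that("trained passive model generates the diamond within 2x of the
           analytic-score baseline", {
  dm <- diamond_gmm(4000, seed = 310)
  ref <- diamond_gmm(2500, seed = 311)$x
  pp <- passive_params(1, 1)
  sched <- reverse_schedule(tf = 1, n_steps = 100)  # dt = 0.01
  base <- generate(score_provider_analytic(dm$gmm, pp), pp, sched, 2500, 2,
                   seed = 312)
  ed_base <- energy_distance(base$x, ref)
  spec <- score_model_spec(2, "passive", n_iter = 10000, batch = 256,
                          seed = 313)
  fit <- train_score_model(dm$x, pp, spec)
  gen <- generate(fit$provider, pp, sched, 2500, 2, seed = 314)
  ed_train <- energy_distance(gen$x, ref)
  expect_lt(ed_train, 2 * max(ed_base, 0.005))
})

test_that("swiss rolls: learned active beats learned passive at coarse dt", {
  # the multi-scale regime: dt = 0.1 (10 reverse steps), equal training
  # budgets; median over 3 seeds (scaled down from 5 for CPU budget)
  sw <- swiss_rolls(4000, seed = 1)
  ref <- swiss_rolls(3000, seed = 2)$x
  pp <- passive_params(1, 1)
  pa <- active_params(1, 0, 1, 0.5)
  eds <- sapply(3:5, function(sd) {
    fp <- train_score_model(sw$x, pp,
                            score_model_spec(2, "passive",
                                             hidden = c(64, 64, 64),
                                             n_iter = 4000, batch = 256,
                                             seed = sd))
    fa <- train_score_model(sw$x, pa,
                            score_model_spec(2, "active",
                                             hidden = c(64, 64, 64),
                                             n_iter = 4000, batch = 256,
                                             seed = sd))
    sch <- reverse_schedule(1, 10)
    c(passive = energy_distance(
        generate(fp$provider, pp, sch, 2000, 2, seed = sd + 10)$x, ref),
      active = energy_distance(
        generate(fa$provider, pa, sch, 2000, 2, seed = sd + 20)$x, ref))
  })
  expect_lte(median(eds["active", ]), median(eds["passive", ]))
})

test_that("dihedral proxy: active generation occupies all three basins", {
  dp <- dihedral_proxy(4000, seed = 315)
  scale <- 90  # degrees per data unit; angles live in [-2, 2)
  pa <- active_params(1, 0, 1, 0.5)
  spec <- score_model_spec(2, "active", hidden = c(64, 64, 64),
                          n_iter = 4000, batch = 256, seed = 316)
  fit <- train_score_model(dp$x / scale, pa, spec)
  gen <- generate(fit$provider, pa, reverse_schedule(1, 50), 3000, 2,
                  seed = 317)
  ang <- activediff:::wrap_degrees(gen$x * scale)
  occ <- basin_occupancy(ang, dp$centers, 45, period = 360)
  expect_true(all(occ > 0.01))
})

test_that("score model checkpoints round-trip through JSON", {
  g <- toy_gmm_1d()
  smp <- sample_gmm(g, 600, seed = 318)
  pa <- active_params(1, 0, 1, 0.5)
  spec <- score_model_spec(1, "active", hidden = c(8, 8), n_iter = 50,
                          batch = 64, seed = 319)
  fit <- train_score_model(smp$x, pa, spec)
  path <- tempfile(fileext = ".json")
  write_score_model(fit, spec, path)
  back <- read_score_model(path, pa)
  x <- matrix(c(0.1, -0.5)); eta <- matrix(c(0.3, 0.2))
  expect_equal(back$provider$score(x, eta, 0.5),
               fit$provider$score(x, eta, 0.5), tolerance = 1e-12)
})
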