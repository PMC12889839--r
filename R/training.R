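# Denoising score matching on toy datasets.  The score approximator is a
# small multilayer perceptron with tanh activations and a sinusoidal time
# embedding, trained with Adam on the conditional-target regression; the
# function-space minimizer of that regression is the true score.

# vectorized active transition moments over a vector of times; the
# degenerate k ~ 1/tau branch depends on params only, not t
tm_vectorized <- function(params, t) {
  a <- params$k; b <- 1 / params$tau
  ea <- exp(-a * t); eb <- exp(-b * t)
  degenerate <- abs(a - b) < DEGENERATE_COV_TOL * a
  De <- params$Ta / params$tau^2
  if (degenerate) {
    g <- t * ea
    c2 <- 2 * a; e2 <- exp(-c2 * t)
    i_gg <- (2 - e2 * (c2^2 * t^2 + 2 * c2 * t + 2)) / c2^3
    i_gb <- (1 - e2 * (1 + c2 * t)) / c2^2
  } else {
    g <- (eb - ea) / (a - b)
    f2a <- (1 - ea^2) / (2 * a)
    f2b <- (1 - eb^2) / (2 * b)
    fab <- (1 - exp(-(a + b) * t)) / (a + b)
    i_gg <- (f2b + f2a - 2 * fab) / (a - b)^2
    i_gb <- (f2b - fab) / (a - b)
  }
  list(ea = ea, g = g, eb = eb,
       cxx = 2 * params$Tp * (1 - ea^2) / (2 * a) + 2 * De * i_gg,
       cxe = 2 * De * i_gb,
       cee = 2 * De * (1 - eb^2) / (2 * b))
}

# sinusoidal time embedding: raw t plus 4 sin/cos pairs on dyadic
# frequencies scaled to the training horizon
embed_time <- function(t, tf) {
  w <- 2^(0:3) * pi / tf
  cbind(t, sapply(w, function(wj) sin(wj * t)),
        sapply(w, function(wj) cos(wj * t)))
}

N_TIME_FEATURES <- 9L

mlp_init <- function(sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = 1 / sqrt(sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(sizes = sizes, W = W, b = b)
}

mlp_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  acts <- if (keep) vector("list", L + 1L)
  A <- X
  if (keep) acts[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- sweep(A %*% net$W[[l]], 2, net$b[[l]], "+")
    A <- if (l < L) tanh(Z) else Z
    if (keep) acts[[l + 1L]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

# gradient of sum-of-squares style losses: dOut is dLoss/dOutput
mlp_backward <- function(net, acts, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - acts[[l]]^2)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  zeros <- function(p) if (is.matrix(p)) p * 0 else numeric(length(p))
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros), t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

#' Score-model training specification
#'
#' @param d Data dimension.
#' @param process `"passive"` or `"active"`.
#' @param hidden Hidden layer sizes (default `c(128, 128, 128)`).
#' @param n_iter Number of Adam iterations (default 4000).
#' @param batch Batch size (default 128).
#' @param lr Learning rate (default 1e-3).
#' @param tf Training horizon: times are sampled uniformly on
#'   `[t_min, tf]`.
#' @param t_min Lower time cutoff (default 1e-3; the conditional-target
#'   variance diverges as `t -> 0`).
#' @param lr_final_frac The learning rate decays exponentially to
#'   `lr * lr_final_frac` over the run (default 0.1; set to 1 for a constant
#'   rate).
#' @param train_x For active processes with `Tp > 0`, also train an x-score
#'   network (default `FALSE`: the x-score is irrelevant for the reverse
#'   process when `Tp` is zero or negligible).
#' @param seed Integer seed for initialization and batch sampling.
#' @return An object of class `score_model_spec`.
#' @export
score_model_spec <- function(d, process = c("passive", "active"),
                             hidden = c(128, 128, 128), n_iter = 4000L,
                             batch = 128L, lr = 1e-3, tf = 1, t_min = 1e-3,
                             train_x = FALSE, lr_final_frac = 0.1,
                             seed = 1L) {
  process <- match.arg(process)
  stopifnot(d >= 1, n_iter >= 1, batch >= 1, lr > 0, tf > t_min, t_min > 0,
            lr_final_frac > 0, lr_final_frac <= 1)
  structure(list(d = as.integer(d), process = process, hidden = hidden,
                 n_iter = as.integer(n_iter), batch = as.integer(batch),
                 lr = lr, tf = tf, t_min = t_min, train_x = train_x,
                 lr_final_frac = lr_final_frac, seed = as.integer(seed)),
            class = "score_model_spec")
}

# evaluate a "model" that may be a raw function(inputs...) or an mlp net
eval_passive_model <- function(model, x_t, t, tf) {
  if (is.function(model)) return(model(x_t, t))
  mlp_forward(model$net, cbind(x_t, embed_time(t, tf)))
}

eval_active_model <- function(model, x_t, eta_t, t, tf) {
  if (is.function(model)) return(model(x_t, eta_t, t))
  mlp_forward(model$net, cbind(x_t, eta_t, embed_time(t, tf)))
}

#' Denoising score-matching loss, passive process
#'
#' Mean (over the batch) of the summed squared error between the model output
#' at the noised points and the conditional targets
#' \eqn{-(x_t - x_0 e^{-kt})/\Delta_t}, with the noised points built from the
#' supplied standard-normal draws: \eqn{x_t = x_0 e^{-kt} + \sqrt{\Delta_t} z}.
#'
#' @param model A trained model (as in [train_score_model()]) or a function
#'   `(x_t, t) -> score matrix` (e.g. the analytic score, for computing the
#'   loss floor).
#' @param x0 n x d batch of clean samples.
#' @param t Length-n vector of times in `(0, tf]`.
#' @param z n x d matrix of standard normal draws.
#' @param params `passive_params`.
#' @param tf Time horizon used for the time embedding (default `max(t)`).
#' @return Scalar loss.
#' @export
dsm_loss_passive <- function(model, x0, t, z, params, tf = max(t)) {
  if (any(t <= 0)) stop("dsm_loss_passive: t must be positive")
  a <- exp(-params$k * t)
  Dt <- (params$T / params$k) * (1 - a^2)
  x_t <- x0 * a + sqrt(Dt) * z
  target <- -z / sqrt(Dt)
  S <- eval_passive_model(model, x_t, t, tf)
  mean(rowSums((S - target)^2))
}

#' Denoising score-matching loss, active process
#'
#' Sum of the two mean-squared terms of the joint objective, built from the
#' exact Gaussian channel: \eqn{z_t = e^{Mt} z_0 + L w} with
#' \eqn{LL^\top = C_t}, targets \eqn{-C_t^{-1} L w} (x- and eta-components).
#' When `Tp = 0`, or when no x-model is supplied, only the eta-term is
#' formed, matching the reduction used for the reverse process.
#'
#' @param models List with elements `eta` (required) and optionally `x`;
#'   each a trained model or a function `(x_t, eta_t, t) -> matrix`.
#' @param x0,eta0 n x d clean data and initial eta draws.
#' @param t Length-n vector of times in `(0, tf]`.
#' @param w1,w2 n x d standard normal matrices driving the channel.
#' @param params `active_params`.
#' @param tf Time horizon for the embedding (default `max(t)`).
#' @return Scalar loss.
#' @export
dsm_loss_active <- function(models, x0, eta0, t, w1, w2, params,
                            tf = max(t)) {
  if (any(t <= 0)) stop("dsm_loss_active: t must be positive")
  ch <- active_channel(params, x0, eta0, t, w1, w2)
  loss <- mean(rowSums(
    (eval_active_model(models$eta, ch$x_t, ch$eta_t, t, tf) - ch$target_eta)^2))
  if (params$Tp > 0 && !is.null(models$x)) {
    loss <- loss + mean(rowSums(
      (eval_active_model(models$x, ch$x_t, ch$eta_t, t, tf) - ch$target_x)^2))
  }
  loss
}

# exact active forward channel for a batch with per-sample times:
# noised states plus the conditional score targets -C^{-1} L w
active_channel <- function(params, x0, eta0, t, w1, w2) {
  tm <- tm_vectorized(params, t)
  l11 <- sqrt(tm$cxx)
  l21 <- tm$cxe / l11
  l22 <- sqrt(pmax(tm$cee - l21^2, 0))
  rx <- l11 * w1
  re <- l21 * w1 + l22 * w2
  det <- tm$cxx * tm$cee - tm$cxe^2
  list(x_t = tm$ea * x0 + tm$g * eta0 + rx,
       eta_t = tm$eb * eta0 + re,
       target_x = -(tm$cee * rx - tm$cxe * re) / det,
       target_eta = -(tm$cxx * re - tm$cxe * rx) / det)
}

#' Train a score model by denoising score matching
#'
#' Draws minibatches from `x0`, samples times uniformly on
#' `[t_min, tf]`, forms the exact conditional targets, and minimizes the
#' unweighted mean-squared objective with Adam.  For active processes the
#' eta-score network is always trained; an x-score network is trained only if
#' `spec$train_x` and `Tp > 0` (otherwise the x-score enters the reverse
#' dynamics with weight `2 Tp ~ 0` and is replaced by zero).
#'
#' @param x0 n x d matrix of training samples (finite; `n >= spec$batch`).
#' @param params Process parameters matching `spec$process`.
#' @param spec A [score_model_spec()].
#' @return A list with `provider` (usable by [generate()]), `models`, and
#'   `log` (data.frame with `iter`, `loss`).  Training aborts with a
#'   diagnostic if the loss diverges to NaN.
#' @export
train_score_model <- function(x0, params, spec) {
  x0 <- as.matrix(x0)
  stopifnot(all(is.finite(x0)), nrow(x0) >= spec$batch,
            ncol(x0) == spec$d)
  active <- is_active(params)
  stopifnot(identical(spec$process, if (active) "active" else "passive"))
  set.seed(spec$seed)
  d <- spec$d
  in_dim <- (if (active) 2L * d else d) + N_TIME_FEATURES
  sizes <- c(in_dim, spec$hidden, d)
  net_eta <- mlp_init(sizes)
  st_eta <- adam_init(net_eta)
  with_x <- active && spec$train_x && params$Tp > 0
  if (with_x) { net_x <- mlp_init(sizes); st_x <- adam_init(net_x) }
  s_eta0 <- if (active) sqrt(params$Ta / params$tau)
  log_it <- integer(spec$n_iter); log_loss <- numeric(spec$n_iter)
  B <- spec$batch
  decay <- spec$lr_final_frac^(1 / max(spec$n_iter - 1L, 1L))
  lr_it <- spec$lr
  for (it in seq_len(spec$n_iter)) {
    idx <- sample.int(nrow(x0), B, replace = TRUE)
    xb <- x0[idx, , drop = FALSE]
    t <- stats::runif(B, spec$t_min, spec$tf)
    if (active) {
      eta0 <- matrix(stats::rnorm(B * d, sd = s_eta0), B, d)
      w1 <- matrix(stats::rnorm(B * d), B, d)
      w2 <- matrix(stats::rnorm(B * d), B, d)
      ch <- active_channel(params, xb, eta0, t, w1, w2)
      inputs <- cbind(ch$x_t, ch$eta_t, embed_time(t, spec$tf))
      fw <- mlp_forward(net_eta, inputs, keep = TRUE)
      resid <- fw$out - ch$target_eta
      loss <- mean(rowSums(resid^2))
      gr <- mlp_backward(net_eta, fw$acts, 2 * resid / B)
      upd <- adam_step(net_eta, gr, st_eta, lr_it)
      net_eta <- upd$net; st_eta <- upd$state
      if (with_x) {
        fwx <- mlp_forward(net_x, inputs, keep = TRUE)
        residx <- fwx$out - ch$target_x
        loss <- loss + mean(rowSums(residx^2))
        grx <- mlp_backward(net_x, fwx$acts, 2 * residx / B)
        updx <- adam_step(net_x, grx, st_x, lr_it)
        net_x <- updx$net; st_x <- updx$state
      }
    } else {
      a <- exp(-params$k * t)
      Dt <- (params$T / params$k) * (1 - a^2)
      z <- matrix(stats::rnorm(B * d), B, d)
      x_t <- xb * a + sqrt(Dt) * z
      target <- -z / sqrt(Dt)
      inputs <- cbind(x_t, embed_time(t, spec$tf))
      fw <- mlp_forward(net_eta, inputs, keep = TRUE)
      resid <- fw$out - target
      loss <- mean(rowSums(resid^2))
      gr <- mlp_backward(net_eta, fw$acts, 2 * resid / B)
      upd <- adam_step(net_eta, gr, st_eta, lr_it)
      net_eta <- upd$net; st_eta <- upd$state
    }
    lr_it <- lr_it * decay
    if (!is.finite(loss)) {
      stop(sprintf("train_score_model: loss diverged (iteration %d)", it))
    }
    log_it[it] <- it; log_loss[it] <- loss
  }
  models <- if (active) {
    list(eta = list(net = net_eta, tf = spec$tf),
         x = if (with_x) list(net = net_x, tf = spec$tf))
  } else {
    list(score = list(net = net_eta, tf = spec$tf))
  }
  provider <- score_provider_trained(models, params, spec)
  list(provider = provider, models = models,
       log = data.frame(iter = log_it, loss = log_loss))
}

#' Score provider backed by trained networks
#'
#' For active processes without an x-network, the x-score is reported as zero
#' (its reverse-dynamics weight `2 Tp` is zero or negligible in that regime).
#'
#' @param models As returned by [train_score_model()].
#' @param params Process parameters.
#' @param spec The training [score_model_spec()] (provides `tf` as the
#'   trained horizon).
#' @return A `score_provider` with `tf_max = spec$tf`.
#' @export
score_provider_trained <- function(models, params, spec) {
  tf <- spec$tf
  if (is_active(params)) {
    fn <- function(x, eta, t) {
      tt <- rep(t, length.out = nrow(x))
      fe <- eval_active_model(models$eta, x, eta, tt, tf)
      fx <- if (!is.null(models$x)) {
        eval_active_model(models$x, x, eta, tt, tf)
      } else {
        matrix(0, nrow(x), ncol(x))
      }
      list(x = fx, eta = fe)
    }
  } else {
    fn <- function(x, eta, t) {
      tt <- rep(t, length.out = nrow(x))
      list(x = eval_passive_model(models$score, x, tt, tf), eta = NULL)
    }
  }
  structure(list(process = if (is_active(params)) "active" else "passive",
                 score = fn, kind = "trained", tf_max = tf),
            class = "score_provider")
}

#' Save / load a trained score model as JSON
#'
#' Weights and the spec sidecar are stored together in one JSON document
#' (plain text; adequate for the MLP sizes used here).
#'
#' @param fit Result of [train_score_model()].
#' @param spec The [score_model_spec()] used.
#' @param path Output path.
#' @param params Process parameters (needed on load to rebuild the provider).
#' @return `path` / a list like the result of [train_score_model()] (without
#'   the training log).
#' @export
write_score_model <- function(fit, spec, path) {
  ser_net <- function(m) {
    if (is.null(m)) return(NULL)
    list(sizes = m$net$sizes, tf = m$tf,
         W = lapply(m$net$W, function(w) as.vector(w)),
         b = m$net$b)
  }
  jsonlite::write_json(list(spec = unclass(spec),
                            models = lapply(fit$models, ser_net)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path, params) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$spec
  spec <- score_model_spec(d = sp$d, process = sp$process, hidden = sp$hidden,
                           n_iter = sp$n_iter, batch = sp$batch, lr = sp$lr,
                           tf = sp$tf, t_min = sp$t_min,
                           train_x = isTRUE(sp$train_x), seed = sp$seed)
  de_net <- function(m) {
    if (is.null(m) || is.null(m$sizes)) return(NULL)
    sizes <- m$sizes
    W <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(m$W[[l]], sizes[l], sizes[l + 1])
    }
    list(net = list(sizes = sizes, W = W, b = m$b), tf = m$tf)
  }
  models <- lapply(obj$models, de_net)
  models <- models[!vapply(models, is.null, logical(1))]
  list(provider = score_provider_trained(models, params, spec),
       models = models)
}
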