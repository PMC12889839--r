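# Random-hierarchy data model: a depth-L grammar whose root symbol plays the
# role of class identity and whose s^L leaves play the role of observed data.
# Leaves are one-hot embedded, noised through the forward process, and the
# root class is inferred by exact sum-product belief propagation; the grammar
# is unambiguous by construction, which makes BP exact on the tree.

#' Hierarchy model parameters
#'
#' @param L Tree depth (number of production levels).
#' @param s Branching factor (children per node).
#' @param m Productions per symbol.
#' @param v Vocabulary size per level.
#' @return An object of class `hierarchy_params`.  Requires `m * v <= v^s` so
#'   that `m` distinct s-tuples can be assigned to every symbol without
#'   ambiguity.
#' @export
hierarchy_params <- function(L = 10L, s = 2L, m = 8L, v = 32L) {
  stopifnot(L >= 1, s >= 1, m >= 1, v >= 1)
  if (m * v > v^s) {
    stop("hierarchy_params: infeasible (m * v > v^s); cannot draw distinct ",
         "productions")
  }
  structure(list(L = as.integer(L), s = as.integer(s), m = as.integer(m),
                 v = as.integer(v)),
            class = "hierarchy_params")
}

#' Sample an unambiguous random grammar
#'
#' For each level and each of the `v` symbols, `m` ordered s-tuples of child
#' symbols are drawn uniformly without replacement from the tuples not yet
#' used at that level, so every tuple is produced by at most one
#' (symbol, rule) pair — the condition under which sum-product inference of
#' the root is exact.
#'
#' @param params A [hierarchy_params()].
#' @param seed Optional integer seed.
#' @return An object of class `hierarchy_grammar` with per-level production
#'   arrays `prod[[l]][symbol, rule, child]`.
#' @export
sample_grammar <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- params$v; m <- params$m; s <- params$s
  n_tuples <- v^s
  prod <- vector("list", params$L)
  for (l in seq_len(params$L)) {
    idx <- sample.int(n_tuples, m * v) - 1L
    tab <- array(0L, dim = c(v, m, s))
    for (cc in seq_len(s)) {
      tab[, , cc] <- as.integer(idx %% v) + 1L
      idx <- idx %/% v
    }
    prod[[l]] <- tab
  }
  structure(list(params = params, prod = prod,
                 seed = if (is.null(seed)) NA else seed),
            class = "hierarchy_grammar")
}

#' @export
print.hierarchy_grammar <- function(x, ...) {
  p <- x$params
  cat(sprintf("hierarchy grammar: L = %d, s = %d, m = %d, v = %d (%d leaves)\n",
              p$L, p$s, p$m, p$v, p$s^p$L))
  invisible(x)
}

# sample symbols for a batch of trees at once; roots is an integer vector,
# returns leaves as an n x s^L matrix plus the full per-level symbol tables
sample_tree_batch <- function(grammar, roots) {
  p <- grammar$params
  n <- length(roots)
  levels <- vector("list", p$L + 1L)
  syms <- matrix(as.integer(roots), n, 1L)
  levels[[1L]] <- syms
  for (l in seq_len(p$L)) {
    K <- ncol(syms)
    rule <- matrix(sample.int(p$m, n * K, replace = TRUE), n, K)
    child <- matrix(0L, n, K * p$s)
    for (cc in seq_len(p$s)) {
      child[, p$s * (seq_len(K) - 1L) + cc] <-
        grammar$prod[[l]][cbind(as.vector(syms), as.vector(rule), cc)]
    }
    syms <- child
    levels[[l + 1L]] <- syms
  }
  list(leaves = syms, levels = levels)
}

#' Sample one datum from the grammar
#'
#' Starting from the given root symbol, one of the `m` productions is chosen
#' uniformly at each internal node.
#'
#' @param grammar A [sample_grammar()] result.
#' @param root_class Root symbol in `1..v`.
#' @param seed Optional integer seed.
#' @return A list with `leaves` (integer vector of length `s^L`) and `tree`
#'   (list of per-level symbol vectors, root first).
#' @export
sample_datum <- function(grammar, root_class, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(root_class >= 1, root_class <= grammar$params$v)
  out <- sample_tree_batch(grammar, as.integer(root_class))
  list(leaves = as.integer(out$leaves[1L, ]),
       tree = lapply(out$levels, function(m) as.integer(m[1L, ])))
}

# per-coordinate channel second moments of (x_t, eta_t) given x0, with the
# stationary eta0 policy marginalized in
hierarchy_channel <- function(params, t, eta0_policy = "stationary") {
  tm <- transition_moments(params, t)
  if (!is_active(params)) {
    return(list(process = "passive", a = tm$propagator[1, 1],
                var = tm$covariance[1, 1]))
  }
  s0 <- if (eta0_policy == "stationary") params$Ta / params$tau else 0
  G <- tm$propagator; C <- tm$covariance
  list(process = "active", a = G[1, 1], g = G[1, 2], eb = G[2, 2], s0 = s0,
       sxx = s0 * G[1, 2]^2 + C[1, 1],
       sxe = s0 * G[1, 2] * G[2, 2] + C[1, 2],
       see = s0 * G[2, 2]^2 + C[2, 2])
}

# internal worker shared by noise_leaves() and the recovery loops: noise a
# batch of leaf strings (n x n_leaf matrix of symbols) into x (and eta)
# matrices of shape (n * n_leaf) x v, rows ordered trial-major then leaf
noise_leaves_matrix <- function(leaves_rows, v, params, t,
                                eta0_policy = "stationary") {
  nr <- nrow(leaves_rows) * ncol(leaves_rows)
  rows <- nr  # one row per leaf occurrence
  sym <- as.vector(t(leaves_rows))  # trial-major, leaf-minor
  ch <- hierarchy_channel(params, t, eta0_policy)
  hot <- cbind(seq_len(rows), sym)
  if (ch$process == "passive") {
    x <- matrix(stats::rnorm(rows * v, sd = sqrt(ch$var)), rows, v)
    x[hot] <- x[hot] + ch$a
    return(list(x = x, eta = NULL, t = t, process = "passive"))
  }
  tm <- transition_moments(params, t)
  L <- chol2_lower(tm$covariance)
  eta0 <- matrix(stats::rnorm(rows * v, sd = sqrt(ch$s0)), rows, v)
  w1 <- matrix(stats::rnorm(rows * v), rows, v)
  w2 <- matrix(stats::rnorm(rows * v), rows, v)
  x <- ch$g * eta0 + L[1, 1] * w1
  x[hot] <- x[hot] + ch$a
  eta <- ch$eb * eta0 + L[2, 1] * w1 + L[2, 2] * w2
  list(x = x, eta = eta, t = t, process = "active")
}

#' Noise the one-hot leaf encoding of a datum
#'
#' Each leaf symbol is embedded as a one-hot vector in `R^v` and every
#' coordinate is pushed through the forward process for time `t` (exact
#' sampling; eta initialized per policy for active processes).
#'
#' @param leaves Integer vector of leaf symbols (length `s^L`).
#' @param v Vocabulary size (number of embedding coordinates).
#' @param params Process parameters (`passive_params` or `active_params`; use
#'   [equivalent_passive_temperature()] to build the equivalent-passive
#'   comparator).
#' @param t Forward noising time (>= 0).
#' @param eta0_policy Initial eta policy.
#' @param seed Optional integer seed.
#' @return A list with `x` (`s^L` x `v` matrix), `eta` (same shape or
#'   `NULL`), `t`, `process`.
#' @export
noise_leaves <- function(leaves, v, params, t, eta0_policy = "stationary",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(leaves >= 1), all(leaves <= v))
  noise_leaves_matrix(matrix(as.integer(leaves), 1L), v, params, t,
                      eta0_policy)
}

# leaf log-messages over candidate symbols: the channel is linear-Gaussian,
# so log P(y_leaf | symbol = w) differs from the symbol-independent baseline
# only through the coordinate w, linearly in the observation there
leaf_log_messages <- function(noised, params, eta0_policy = "stationary",
                              marginal = FALSE) {
  if (noised$t == 0) {
    # zero channel variance: the encoding is observed exactly
    return(log(1 * (noised$x > 0.5)))
  }
  ch <- hierarchy_channel(params, noised$t, eta0_policy)
  if (ch$process == "passive") {
    return(ch$a * noised$x / ch$var - ch$a^2 / (2 * ch$var))
  }
  if (marginal) {
    return(ch$a * noised$x / ch$sxx - ch$a^2 / (2 * ch$sxx))
  }
  det <- ch$sxx * ch$see - ch$sxe^2
  wx <- ch$see * ch$a / det
  we <- -ch$sxe * ch$a / det
  wx * noised$x + we * noised$eta - ch$a * wx / 2
}

# exact sum-product upward pass for a batch; msg rows ordered trial-major,
# node-minor; returns the root posterior matrix (n x v)
bp_upward <- function(log_msg, grammar, n_trials) {
  p <- grammar$params
  mx <- apply(log_msg, 1, max)
  M <- exp(log_msg - mx)
  M <- M / rowSums(M)
  for (l in rev(seq_len(p$L))) {
    Kp <- p$s^(l - 1L)  # nodes at the parent level
    off <- rep((seq_len(n_trials) - 1L) * (Kp * p$s), each = Kp)
    children <- vector("list", p$s)
    for (cc in seq_len(p$s)) {
      children[[cc]] <- M[off + p$s * (rep(seq_len(Kp), n_trials) - 1L) + cc,
                          , drop = FALSE]
    }
    P <- matrix(0, n_trials * Kp, p$v)
    tab <- grammar$prod[[l]]
    for (a in seq_len(p$v)) {
      acc <- 0
      for (r in seq_len(p$m)) {
        term <- children[[1L]][, tab[a, r, 1L]]
        if (p$s > 1L) {
          for (cc in 2:p$s) term <- term * children[[cc]][, tab[a, r, cc]]
        }
        acc <- acc + term
      }
      P[, a] <- acc
    }
    M <- P / rowSums(P)
  }
  M
}

#' Belief-propagation posterior over the root class
#'
#' Exact sum-product on the (unambiguous) grammar tree: Gaussian channel
#' likelihoods at the leaves (the joint `(x, eta)` likelihood for active
#' processes, or the x-marginal when `marginal = TRUE`), uniform priors over
#' root symbols and production rules, messages normalized level by level.
#'
#' @param noised Output of [noise_leaves()].
#' @param grammar The generating [sample_grammar()].
#' @param params The noising process parameters.
#' @param marginal Use only the data coordinates (ignore eta) in the leaf
#'   likelihoods; demonstrates the information stored in the active
#'   coordinates.
#' @param eta0_policy Initial eta policy assumed by the channel.
#' @return Probability vector of length `v` (sums to 1).
#' @export
bp_root_posterior <- function(noised, grammar, params, marginal = FALSE,
                              eta0_policy = "stationary") {
  lm <- leaf_log_messages(noised, params, eta0_policy, marginal = marginal)
  as.vector(bp_upward(lm, grammar, 1L))
}

#' Class-recovery curves in the hierarchical model
#'
#' For each noising time and process, draws trials (uniform random root,
#' random tree, noised one-hot leaves), infers the root by exact BP, and
#' records the fraction of trials whose maximum-posterior root (ties broken
#' uniformly at random) matches the truth.
#'
#' @param grammar A [sample_grammar()].
#' @param processes Named list; each element a list with `params` and
#'   optionally `marginal = TRUE` (active x-only inference).
#' @param t_grid Vector of noising times.
#' @param n_trials Trials per (time, process) point.
#' @param seed Optional integer seed.
#' @param chunk Trials processed per batch (memory control).
#' @return A data.frame with columns `t`, `process`, `fraction`, `se`, `n`.
#' @export
class_recovery_curve <- function(grammar, processes, t_grid, n_trials = 500L,
                                 seed = NULL, chunk = 100L) {
  if (!is.null(seed)) set.seed(seed)
  v <- grammar$params$v
  rows <- list()
  for (pname in names(processes)) {
    proc <- processes[[pname]]
    for (t in t_grid) {
      correct <- 0L
      done <- 0L
      while (done < n_trials) {
        nb <- min(chunk, n_trials - done)
        roots <- sample.int(v, nb, replace = TRUE)
        tree <- sample_tree_batch(grammar, roots)
        noised <- noise_leaves_matrix(tree$leaves, v, proc$params, t)
        lm <- leaf_log_messages(noised, proc$params,
                                marginal = isTRUE(proc$marginal))
        post <- bp_upward(lm, grammar, nb)
        pred <- max.col(post, ties.method = "random")
        correct <- correct + sum(pred == roots)
        done <- done + nb
      }
      frac <- correct / n_trials
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, process = pname, fraction = frac,
        se = sqrt(frac * (1 - frac) / n_trials), n = n_trials)
    }
  }
  do.call(rbind, rows)
}

#' Joint versus marginal root recovery on identical noised data
#'
#' Runs active noising once per trial and infers the root twice from the very
#' same draws: with the joint `(x, eta)` leaf likelihood and with the x-only
#' marginal likelihood.  The gap measures the class information stored in the
#' active coordinates.
#'
#' @param grammar A [sample_grammar()].
#' @param params `active_params`.
#' @param t_grid Vector of noising times.
#' @param n_trials Trials per time point.
#' @param seed Optional integer seed.
#' @param chunk Trials per batch.
#' @return A data.frame with columns `t`, `joint`, `marginal`, `se`, `n`.
#' @export
marginal_vs_joint_recovery <- function(grammar, params, t_grid,
                                       n_trials = 500L, seed = NULL,
                                       chunk = 100L) {
  stopifnot(is_active(params))
  if (!is.null(seed)) set.seed(seed)
  v <- grammar$params$v
  rows <- list()
  for (t in t_grid) {
    cj <- 0L; cm <- 0L; done <- 0L
    while (done < n_trials) {
      nb <- min(chunk, n_trials - done)
      roots <- sample.int(v, nb, replace = TRUE)
      tree <- sample_tree_batch(grammar, roots)
      noised <- noise_leaves_matrix(tree$leaves, v, params, t)
      pj <- bp_upward(leaf_log_messages(noised, params), grammar, nb)
      pm <- bp_upward(leaf_log_messages(noised, params, marginal = TRUE),
                      grammar, nb)
      cj <- cj + sum(max.col(pj, ties.method = "random") == roots)
      cm <- cm + sum(max.col(pm, ties.method = "random") == roots)
      done <- done + nb
    }
    rows[[length(rows) + 1L]] <- data.frame(
      t = t, joint = cj / n_trials, marginal = cm / n_trials,
      se = sqrt(0.25 / n_trials), n = n_trials)
  }
  do.call(rbind, rows)
}
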