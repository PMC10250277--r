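# Softmax observation model: the likelihood of a click sequence given a
# strategy. Each strategy is represented by a weight vector over the
# feature bank; the propensity of an action is exp(w'f(b, c) / tau),
# normalised over all available actions (clicks and termination).
#
# Weights are fitted once per strategy at tau = 1 by maximum likelihood on
# trials simulated from the strategy's generative policy (a convex
# multinomial-logit problem, with a small L2 ridge for identifiability of
# collinear features). The inference-time temperature tau of the
# observation model then rescales all strategies' propensities jointly.

#' Log-probability of one action under a weight vector
#'
#' @param w feature weight vector (manifest order).
#' @param tau softmax temperature (> 0).
#' @param belief a `belief_state`.
#' @param action node id or [TERMINATE]; must be available.
#' @param env the `mdp_env`.
#' @return log P(action | belief), normalised over all available actions.
#' @export
action_log_prob <- function(w, tau, belief, action, env) {
  if (tau <= 0) stop("temperature tau must be positive", call. = FALSE)
  avail <- available_actions(belief, env)
  i <- match(as.integer(action), avail)
  if (is.na(i)) stop("action ", action, " is not available", call. = FALSE)
  u <- as.vector(feature_matrix(belief, env) %*% w) / tau
  u[i] - logsumexp(u)
}

# ---------------------------------------------------------------------------
# Stacked per-step representation of a set of trials.
#
# Every step of every trial contributes one block of rows (one row per
# available action) to a single feature matrix X. `group` indexes the step a
# row belongs to, `chosen` the row of the action actually taken, `trial` the
# trial a step belongs to. IDX pads the row indices of each step into a
# G x Kmax matrix (0 rows map to -Inf) so that per-step log-sum-exp reduces
# to vectorised row operations.
stack_trials <- function(trials, env) {
  Xs <- list(); chosen <- integer(0); group <- integer(0)
  trial_of_group <- integer(0)
  nrow_total <- 0L; gid <- 0L
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    belief <- new_belief(env)
    actions <- c(tr$clicks, TERMINATE)
    for (a in actions) {
      gid <- gid + 1L
      X <- feature_matrix(belief, env)
      cand <- which(is.na(unclass(belief)[-1L]))
      avail <- c(as.integer(cand), TERMINATE)
      i <- match(as.integer(a), avail)
      if (is.na(i)) stop("invalid trial: action ", a, " unavailable", call. = FALSE)
      Xs[[gid]] <- X
      chosen <- c(chosen, nrow_total + i)
      group <- c(group, rep.int(gid, nrow(X)))
      trial_of_group <- c(trial_of_group, ti)
      nrow_total <- nrow_total + nrow(X)
      if (a != TERMINATE) belief <- apply_click(belief, a, tr$ground_truth)
    }
  }
  X <- do.call(rbind, Xs)
  rows_of_group <- split(seq_len(nrow(X)), group)
  K <- max(lengths(rows_of_group))
  IDX <- matrix(nrow(X) + 1L, length(rows_of_group), K)
  for (g in seq_along(rows_of_group)) {
    r <- rows_of_group[[g]]
    IDX[g, seq_along(r)] <- r
  }
  list(X = X, group = group, chosen = chosen, IDX = IDX,
       trial_of_group = trial_of_group, n_trials = length(trials),
       n_groups = length(rows_of_group))
}

# Per-step log-sum-exp of a utility vector u (one value per stacked row).
# Returns a vector of length n_groups.
group_lse <- function(u, IDX) {
  U <- matrix(c(u, -Inf)[IDX], nrow(IDX), ncol(IDX))
  m <- U[, 1L]
  if (ncol(U) > 1L) for (k in 2:ncol(U)) m <- pmax(m, U[, k])
  m + log(rowSums(exp(U - m)))
}

# Negative penalised log-likelihood and gradient of the multinomial logit.
logit_nll <- function(w, st, ridge) {
  u <- as.vector(st$X %*% w)
  lse <- group_lse(u, st$IDX)
  -(sum(u[st$chosen]) - sum(lse)) + ridge * sum(w^2)
}

logit_grad <- function(w, st, ridge) {
  u <- as.vector(st$X %*% w)
  lse <- group_lse(u, st$IDX)
  p <- exp(u - lse[st$group])
  -(colSums(st$X[st$chosen, , drop = FALSE]) - as.vector(crossprod(st$X, p))) +
    2 * ridge * w
}

#' Fit a strategy's observation-model weights
#'
#' Simulates trials from the strategy's generative policy and fits the
#' softmax weight vector by maximum likelihood at tau = 1.
#'
#' @param strategy a `planning_strategy`.
#' @param env the `mdp_env`.
#' @param n_sim number of simulated trials used for fitting.
#' @param seed integer seed for the simulations.
#' @param ridge L2 penalty weight (identifiability of collinear features).
#' @param maxit BFGS iteration cap.
#' @return list with `weights` (named vector), `convergence`, `logLik`,
#'   `n_sim`.
#' @export
fit_strategy_weights <- function(strategy, env, n_sim = 400, seed = 1,
                                 ridge = 1e-4, maxit = 250) {
  stopifnot(n_sim >= 1)
  trials <- lapply(seq_len(n_sim), function(i)
    simulate_trial(strategy, env, seed = derive_seed(seed, i), t = i))
  st <- stack_trials(trials, env)
  w0 <- numeric(ncol(st$X))
  fit <- stats::optim(w0, fn = logit_nll, gr = logit_grad, st = st,
                      ridge = ridge, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (!fit$convergence %in% c(0L, 1L)) {
    warning("weight fitting for '", strategy$name, "' did not converge (code ",
            fit$convergence, ", value ", signif(fit$value, 6), ")")
  }
  list(weights = stats::setNames(fit$par, colnames(st$X)),
       convergence = fit$convergence, logLik = -fit$value, n_sim = n_sim)
}

#' Fit the observation model for a whole strategy set
#'
#' @param set a `strategy_set`.
#' @param env the `mdp_env`.
#' @param n_sim simulated trials per strategy.
#' @param seed master seed; each strategy gets a derived sub-seed.
#' @param ... passed to [fit_strategy_weights()].
#' @return an `obs_model`: weight matrix (features x strategies), the
#'   strategy and feature manifests, and their hashes.
#' @export
fit_observation_model <- function(set, env, n_sim = 400, seed = 1, ...) {
  man <- default_feature_manifest()
  W <- matrix(0, nrow(man), length(set),
              dimnames = list(man$name, names(set)))
  conv <- integer(length(set))
  for (i in seq_along(set)) {
    f <- fit_strategy_weights(set[[i]], env, n_sim = n_sim,
                              seed = derive_seed(seed, 1000L + i), ...)
    W[, i] <- f$weights
    conv[i] <- f$convergence
  }
  sm <- strategy_manifest(set)
  m <- list(weights = W, env_name = env$name, n_sim = n_sim,
            strategies = sm, feature_manifest = man,
            feature_hash = manifest_hash(man),
            strategy_hash = manifest_hash(sm),
            convergence = conv)
  class(m) <- "obs_model"
  m
}

#' @export
print.obs_model <- function(x, ...) {
  cat("Softmax observation model for", ncol(x$weights), "strategies x",
      nrow(x$weights), "features\n")
  cat("  environment:", x$env_name, "  fitted from", x$n_sim,
      "simulated trials per strategy\n")
  cat("  feature manifest", x$feature_hash, " strategy manifest",
      x$strategy_hash, "\n")
  invisible(x)
}

#' Log-likelihood of one trial under a strategy
#'
#' Sum of the per-action log-probabilities under the evolving belief state,
#' including the terminal stop action.
#'
#' @param obs_model an `obs_model` (or a bare weight vector).
#' @param strategy strategy id or name (ignored when a weight vector is
#'   passed directly).
#' @param trial a trial record (see [simulate_trial()]).
#' @param env the `mdp_env`.
#' @param tau softmax temperature.
#' @return log P(trial | strategy).
#' @export
trial_log_likelihood <- function(obs_model, strategy, trial, env, tau = 1) {
  w <- if (inherits(obs_model, "obs_model")) {
    obs_model$weights[, strategy]
  } else {
    obs_model
  }
  if (tau <= 0) stop("temperature tau must be positive", call. = FALSE)
  st <- stack_trials(list(trial), env)
  u <- as.vector(st$X %*% w) / tau
  sum(u[st$chosen]) - sum(group_lse(u, st$IDX))
}

#' Simulate a trial from a fitted observation model
#'
#' Samples clicks from the softmax model itself (rather than from the
#' underlying generative policy), which is how simulated validation data
#' are produced.
#'
#' @param obs_model an `obs_model` or weight vector.
#' @param strategy strategy id or name.
#' @param env the `mdp_env`.
#' @param tau generation temperature.
#' @param seed optional seed.
#' @param truth optional pre-drawn ground truth.
#' @param t trial index.
#' @return a trial record.
#' @export
sample_trial_from_model <- function(obs_model, strategy, env, tau = 1,
                                    seed = NULL, truth = NULL, t = 1L) {
  w <- if (inherits(obs_model, "obs_model")) obs_model$weights[, strategy] else obs_model
  run <- function() {
    gt <- if (is.null(truth)) sample_ground_truth(env) else truth
    belief <- new_belief(env)
    clicks <- integer(0); values <- numeric(0)
    repeat {
      X <- feature_matrix(belief, env)
      cand <- which(is.na(unclass(belief)[-1L]))
      avail <- c(as.integer(cand), TERMINATE)
      u <- as.vector(X %*% w) / tau
      p <- exp(u - logsumexp(u))
      a <- avail[sample.int(length(avail), 1L, prob = p)]
      if (a == TERMINATE) break
      belief <- apply_click(belief, a, gt)
      clicks <- c(clicks, a)
      values <- c(values, gt[a + 1L])
    }
    finish_trial(belief, env, gt, clicks, values, t)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Average per-click likelihood of a strategy assignment
#'
#' Diagnostic comparing how well assigned strategies predict each recorded
#' action, reported both as the arithmetic and the geometric mean of the
#' per-action probabilities.
#'
#' @param obs_model an `obs_model`.
#' @param trials list of trial records.
#' @param assignment integer vector of strategy ids, one per trial.
#' @param env the `mdp_env`.
#' @param tau softmax temperature.
#' @return list with `arithmetic`, `geometric`, and `n_actions`.
#' @export
average_click_likelihood <- function(obs_model, trials, assignment, env, tau = 1) {
  stopifnot(length(trials) == length(assignment))
  probs <- numeric(0)
  for (i in seq_along(trials)) {
    st <- stack_trials(list(trials[[i]]), env)
    u <- as.vector(st$X %*% obs_model$weights[, assignment[i]]) / tau
    lse <- group_lse(u, st$IDX)
    probs <- c(probs, exp(u[st$chosen] - lse))
  }
  list(arithmetic = mean(probs), geometric = exp(mean(log(probs))),
       n_actions = length(probs))
}
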