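# Hidden-Markov strategy-sequence model and its inversion.
#
# The latent state on trial t is the strategy S_t; the emission is that
# trial's click sequence under the softmax observation model. The initial
# distribution is uniform over strategies. The transition prior is either
# "abrupt" (repeat with probability p_stay, otherwise jump uniformly) or a
# distance-based "gradual" variant. The MAP strategy sequence is computed
# with the Viterbi algorithm; p_stay is fitted by grid search (resolution
# 0.02) and the temperature tau by a derivative-free search with a
# 50-evaluation budget, both maximising the joint probability of the MAP
# sequence.

#' Transition prior
#'
#' @param kind `"abrupt"` or `"gradual"`.
#' @param p_stay self-transition probability (abrupt prior).
#' @param bandwidth kernel bandwidth over strategy distances (gradual prior).
#' @param distances symmetric strategy distance matrix (gradual prior).
#' @return a `transition_prior` object.
#' @export
transition_prior <- function(kind = c("abrupt", "gradual"), p_stay = 0.5,
                             bandwidth = 1, distances = NULL) {
  kind <- match.arg(kind)
  if (kind == "abrupt" && (p_stay < 0 || p_stay > 1)) {
    stop("p_stay must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "gradual" && is.null(distances)) {
    stop("the gradual prior needs a strategy distance matrix", call. = FALSE)
  }
  structure(list(kind = kind, p_stay = p_stay, bandwidth = bandwidth,
                 distances = distances),
            class = "transition_prior")
}

#' Transition matrix of a prior
#'
#' @param prior a `transition_prior`.
#' @param n_strategies number of strategies (>= 2).
#' @return n x n row-stochastic matrix; for the abrupt prior the diagonal is
#'   `p_stay` and off-diagonal entries `(1 - p_stay) / (n - 1)`.
#' @export
transition_matrix <- function(prior, n_strategies) {
  stopifnot(n_strategies >= 2)
  n <- n_strategies
  if (prior$kind == "abrupt") {
    p <- prior$p_stay
    if (p < 0 || p > 1) stop("p_stay must lie in [0, 1]", call. = FALSE)
    M <- matrix((1 - p) / (n - 1), n, n)
    diag(M) <- p
  } else {
    D <- prior$distances[seq_len(n), seq_len(n)]
    K <- exp(-D / prior$bandwidth)
    M <- K / rowSums(K)
  }
  M
}

# ---------------------------------------------------------------------------
# Per-participant likelihood cache: one stacked pass over all trials gives
# the utility of every available action under every strategy at tau = 1;
# the trial-by-strategy log-likelihood matrix at any tau is then a cheap
# rescale + grouped log-sum-exp.
participant_cache <- function(trials, obs_model, env) {
  st <- stack_trials(trials, env)
  U <- st$X %*% obs_model$weights            # rows x strategies
  list(U = U, chosen = st$chosen, IDX = st$IDX, group = st$group,
       trial_of_group = st$trial_of_group, n_trials = st$n_trials,
       n_strategies = ncol(U))
}

# Trial x strategy log-likelihood matrix at temperature tau.
loglik_matrix <- function(cache, tau) {
  if (tau <= 0) stop("temperature tau must be positive", call. = FALSE)
  S <- cache$n_strategies
  G <- nrow(cache$IDX)
  term <- matrix(0, G, S)
  for (s in seq_len(S)) {
    u <- cache$U[, s] / tau
    term[, s] <- u[cache$chosen] - group_lse(u, cache$IDX)
  }
  rowsum(term, cache$trial_of_group)
}

#' Joint log-probability of a strategy sequence
#'
#' log P(sequence, data) = log(1/|S|) + sum of transition log-probabilities
#' + sum of per-trial click log-likelihoods.
#'
#' @param sequence integer strategy ids, one per trial.
#' @param L trial x strategy log-likelihood matrix (see
#'   [infer_strategies()]), or a list of trials together with `obs_model`
#'   and `env`.
#' @param prior a `transition_prior`.
#' @param obs_model,env,tau used only when `L` is a list of trials.
#' @return the joint log-probability.
#' @export
joint_log_prob <- function(sequence, L, prior, obs_model = NULL, env = NULL,
                           tau = 1) {
  if (!is.matrix(L)) {
    L <- loglik_matrix(participant_cache(L, obs_model, env), tau)
  }
  T_ <- nrow(L)
  if (length(sequence) != T_) stop("sequence length must equal the number of trials",
                                   call. = FALSE)
  S <- ncol(L)
  logA <- log(transition_matrix(prior, S))
  lp <- -log(S) + L[1L, sequence[1L]]
  if (T_ > 1L) {
    for (t in 2:T_) lp <- lp + logA[sequence[t - 1L], sequence[t]] + L[t, sequence[t]]
  }
  lp
}

#' Viterbi MAP decoding of the strategy sequence
#'
#' @param L trial x strategy log-likelihood matrix.
#' @param prior a `transition_prior`.
#' @return list with `sequence` (MAP strategy ids; ties broken toward the
#'   lowest id) and `log_prob` (joint log-probability of the MAP sequence).
#' @export
viterbi_map <- function(L, prior) {
  T_ <- nrow(L); S <- ncol(L)
  logA <- log(transition_matrix(prior, S))
  delta <- -log(S) + L[1L, ]
  back <- matrix(0L, T_, S)
  if (T_ > 1L) {
    for (t in 2:T_) {
      M <- delta + logA                       # M[i, j]: from i to j
      bi <- max.col(t(M), ties.method = "first")
      delta <- M[cbind(bi, seq_len(S))] + L[t, ]
      back[t, ] <- bi
    }
  }
  seq_ <- integer(T_)
  seq_[T_] <- which.max(delta)
  if (T_ > 1L) for (t in (T_ - 1L):1L) seq_[t] <- back[t + 1L, seq_[t + 1L]]
  list(sequence = seq_, log_prob = max(delta))
}

#' Fit the self-transition probability p_stay
#'
#' Grid search over \{0, 0.02, ..., 1\} (51 values), maximising the joint
#' log-probability of the Viterbi MAP sequence; ties resolve to the
#' smallest value.
#'
#' @param L trial x strategy log-likelihood matrix, or a participant cache.
#' @param tau temperature at which `L` was computed (only used when a cache
#'   is passed).
#' @param resolution grid resolution.
#' @return list with `p_stay`, `log_prob`, and the searched `grid`.
#' @export
fit_p_stay <- function(L, tau = 1, resolution = 0.02) {
  if (!is.matrix(L)) L <- loglik_matrix(L, tau)
  grid <- seq(0, 1, by = resolution)
  lp <- vapply(grid, function(p)
    viterbi_map(L, transition_prior("abrupt", p_stay = p))$log_prob, numeric(1))
  best <- which(lp >= max(lp) - 1e-9)[1L]
  list(p_stay = grid[best], log_prob = lp[best], grid = grid)
}

#' Fit the softmax temperature tau
#'
#' Derivative-free maximisation of the joint log-probability of the MAP
#' sequence over a log-spaced temperature range, with a fixed evaluation
#' budget: a coarse log-grid scan followed by golden-section refinement
#' around the best grid point. Deterministic given the data.
#'
#' @param cache participant cache (internal) or list of trials with
#'   `obs_model` and `env` supplied.
#' @param prior a `transition_prior` (fixed during the search).
#' @param obs_model,env used when `cache` is a list of trials.
#' @param range temperature search range.
#' @param budget total number of objective evaluations.
#' @return list with `tau`, `log_prob`, `evals`.
#' @export
fit_temperature <- function(cache, prior, obs_model = NULL, env = NULL,
                            range = c(1e-2, 1e2), budget = 50) {
  if (!is.null(obs_model)) cache <- participant_cache(cache, obs_model, env)
  obj <- function(lt) {
    viterbi_map(loglik_matrix(cache, exp(lt)), prior)$log_prob
  }
  n_grid <- ceiling(budget / 2)
  lts <- seq(log(range[1L]), log(range[2L]), length.out = n_grid)
  vals <- vapply(lts, obj, numeric(1))
  evals <- n_grid
  i <- which.max(vals)
  lo <- lts[max(i - 1L, 1L)]; hi <- lts[min(i + 1L, n_grid)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- obj(x1); f2 <- obj(x2); evals <- evals + 2L
  while (evals < budget) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- obj(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- obj(x1)
    }
    evals <- evals + 1L
  }
  cands <- c(lts[i], x1, x2)
  cvals <- c(vals[i], f1, f2)
  k <- which.max(cvals)
  list(tau = exp(cands[k]), log_prob = cvals[k], evals = evals)
}

#' Infer a participant's strategy sequence
#'
#' Full per-participant pipeline: fit tau at p_stay = 0.5, fit p_stay at
#' that tau, refit tau, then decode the MAP strategy sequence.
#'
#' @param trials list of trial records for one participant, in trial order.
#' @param obs_model an `obs_model`.
#' @param env the `mdp_env`.
#' @param tau fixed temperature; fitted when `NULL`.
#' @param p_stay fixed self-transition probability; fitted when `NULL`.
#' @param tau_budget evaluation budget for the temperature search.
#' @return an `inference_result`: MAP `sequence` (ids), `strategy_names`,
#'   `type_labels`, fitted `p_stay` and `tau`, and the MAP `log_prob`.
#' @export
infer_strategies <- function(trials, obs_model, env, tau = NULL, p_stay = NULL,
                             tau_budget = 50) {
  cache <- participant_cache(trials, obs_model, env)
  fit_tau <- is.null(tau); fit_ps <- is.null(p_stay)
  if (fit_ps) p_stay <- 0.5
  if (fit_tau) {
    tau <- fit_temperature(cache, transition_prior("abrupt", p_stay = p_stay),
                           budget = tau_budget)$tau
  }
  if (fit_ps) {
    p_stay <- fit_p_stay(loglik_matrix(cache, tau))$p_stay
  }
  if (fit_tau && fit_ps) {
    tau <- fit_temperature(cache, transition_prior("abrupt", p_stay = p_stay),
                           budget = tau_budget)$tau
  }
  L <- loglik_matrix(cache, tau)
  vit <- viterbi_map(L, transition_prior("abrupt", p_stay = p_stay))
  sm <- obs_model$strategies
  res <- list(sequence = vit$sequence,
              strategy_names = sm$name[vit$sequence],
              type_labels = sm$type_label[vit$sequence],
              p_stay = p_stay, tau = tau, log_prob = vit$log_prob,
              n_trials = length(trials))
  class(res) <- "inference_result"
  res
}

#' @export
print.inference_result <- function(x, ...) {
  cat("MAP strategy sequence over", x$n_trials, "trials",
      sprintf("(p_stay = %.2f, tau = %.3g, log P = %.2f)\n",
              x$p_stay, x$tau, x$log_prob))
  cat(" ", paste(x$sequence, collapse = " "), "\n")
  invisible(x)
}

#' Infer strategy sequences for a whole dataset
#'
#' @param dataset a `ps_dataset` (see [read_dataset()] / [simulate_dataset()]).
#' @param obs_model an `obs_model`.
#' @param env the `mdp_env`; defaults to the dataset's environment preset.
#' @param shared_hyperparameters if `TRUE`, tau and p_stay are fitted once
#'   on the pooled data and reused for every participant; otherwise (the
#'   default) they are fitted per participant.
#' @param ... passed to [infer_strategies()].
#' @return list of `inference_result`s, named by participant id.
#' @export
infer_dataset <- function(dataset, obs_model, env = NULL,
                          shared_hyperparameters = FALSE, ...) {
  if (is.null(env)) env <- build_environment(dataset$env)
  out <- vector("list", length(dataset$participants))
  names(out) <- vapply(dataset$participants, `[[`, character(1), "id")
  if (shared_hyperparameters) {
    pooled <- unlist(lapply(dataset$participants, `[[`, "trials"),
                     recursive = FALSE)
    h <- infer_strategies(pooled, obs_model, env, ...)
    for (i in seq_along(out)) {
      out[[i]] <- infer_strategies(dataset$participants[[i]]$trials, obs_model,
                                   env, tau = h$tau, p_stay = h$p_stay)
    }
  } else {
    for (i in seq_along(out)) {
      out[[i]] <- infer_strategies(dataset$participants[[i]]$trials, obs_model,
                                   env, ...)
    }
  }
  out
}

#' Compare transition priors by AIC and BIC
#'
#' Fits each candidate prior's hyperparameters on the data, scores it by
#' the joint log-probability of its MAP sequence, and ranks the priors by
#' information criteria. The parameter count is the number of fitted
#' hyperparameters (transition parameter + temperature); n is the number
#' of trials.
#'
#' @param trials list of trial records.
#' @param obs_model an `obs_model`.
#' @param env the `mdp_env`.
#' @param priors character vector of prior kinds to compare.
#' @param distances strategy distance matrix (needed for `"gradual"`).
#' @param tau temperature; fitted once at p_stay = 0.5 when `NULL`.
#' @param bandwidth_grid candidate bandwidths for the gradual prior.
#' @return data.frame ranked by BIC (ascending) with columns `prior`,
#'   `log_lik`, `k`, `AIC`, `BIC`, and the fitted hyperparameter.
#' @export
compare_priors <- function(trials, obs_model, env,
                           priors = c("abrupt", "gradual"), distances = NULL,
                           tau = NULL, bandwidth_grid = NULL) {
  cache <- participant_cache(trials, obs_model, env)
  if (is.null(tau)) {
    tau <- fit_temperature(cache, transition_prior("abrupt", p_stay = 0.5))$tau
  }
  L <- loglik_matrix(cache, tau)
  n <- nrow(L)
  rows <- lapply(priors, function(kind) {
    if (kind == "abrupt") {
      f <- fit_p_stay(L)
      list(prior = "abrupt", log_lik = f$log_prob, k = 2,
           parameter = f$p_stay)
    } else {
      if (is.null(distances)) stop("gradual prior needs 'distances'", call. = FALSE)
      bw <- bandwidth_grid %||% stats::quantile(distances[upper.tri(distances)],
                                                c(.1, .25, .5, .75, .9, 1))
      lp <- vapply(bw, function(b)
        viterbi_map(L, transition_prior("gradual", bandwidth = b,
                                        distances = distances))$log_prob,
        numeric(1))
      best <- which.max(lp)
      list(prior = "gradual", log_lik = lp[best], k = 2,
           parameter = unname(bw[best]))
    }
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$AIC <- 2 * out$k - 2 * out$log_lik
  out$BIC <- out$k * log(n) - 2 * out$log_lik
  out[order(out$BIC), , drop = FALSE]
}
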