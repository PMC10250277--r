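# Shared fixtures, built once per test run.
#
# The observation model and the Monte-Carlo distance matrix are the most
# expensive objects in the suite; every test file reuses these instances.

ps_env3 <- build_environment("increasing_variance_3step")
ps_env5 <- build_environment("increasing_variance_5step")
ps_strats <- default_strategies()
ps_om <- fit_observation_model(ps_strats, ps_env3, n_sim = 400, seed = 1)
ps_dist <- strategy_distance_matrix(ps_om, ps_env3, n_mc = 300, seed = 11)

# Independent reference decoder: exhaustive maximisation of the joint
# log-probability over all strategy sequences, with the same tie rule as
# Viterbi backtracking (lowest id at the last trial, then at each earlier
# trial given the fixed suffix).
brute_force_map <- function(L, p_stay) {
  T_ <- nrow(L); S <- ncol(L)
  logA <- log(transition_matrix(transition_prior("abrupt", p_stay = p_stay), S))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  lp <- -log(S) + L[cbind(1L, seqs[, 1L])]
  if (T_ > 1L) for (t in 2:T_) {
    lp <- lp + logA[cbind(seqs[, t - 1L], seqs[, t])] + L[cbind(t, seqs[, t])]
  }
  best <- max(lp)
  cand <- seqs[lp >= best - 1e-12, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cand[, T_:1, drop = FALSE]))
  list(sequence = unname(cand[ord[1L], ]), log_prob = best)
}

# A belief state with a random number of random clicks revealed.
random_belief <- function(env, seed) {
  planscope:::with_seed(seed, {
    gt <- sample_ground_truth(env)
    k <- sample.int(env$n_nodes - 1L, 1L) - 1L
    b <- new_belief(env)
    for (v in sample(seq_len(env$n_nodes - 1L), k)) b <- apply_click(b, v, gt)
    b
  })
}

# Restrict an observation model to a subset of strategy columns (optionally
# renaming them), keeping the class contract intact.
subset_obs_model <- function(om, cols, new_names = NULL) {
  W <- om$weights[, cols, drop = FALSE]
  sm <- om$strategies[match(colnames(W), om$strategies$name), , drop = FALSE]
  if (!is.null(new_names)) {
    colnames(W) <- new_names
    sm$name <- new_names
  }
  sm$id <- seq_len(nrow(sm))
  rownames(sm) <- NULL
  m <- om
  m$weights <- W
  m$strategies <- sm
  m
}
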