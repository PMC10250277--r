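# Softmax likelihood, MLE weight fitting, click-likelihood diagnostics.

nF <- nrow(default_feature_manifest())

test_that("zero weights give a uniform softmax over the 13 actions", {
  b <- new_belief(ps_env3)
  w0 <- numeric(nF)
  for (a in available_actions(b, ps_env3)) {
    expect_equal(action_log_prob(w0, 1, b, a, ps_env3), log(1 / 13))
  }
  expect_error(action_log_prob(w0, 0, b, TERMINATE, ps_env3), "positive")
})

test_that("a single binary feature reproduces the closed-form softmax", {
  # 13 actions of which 3 carry the feature: P(feature action) = e/(3e + 10)
  b <- new_belief(ps_env3)
  w <- numeric(nF); names(w) <- default_feature_manifest()$name
  w["is_immediate"] <- 1
  depth1 <- which(ps_env3$depth == 1L) - 1L
  p1 <- exp(action_log_prob(w, 1, b, depth1[1L], ps_env3))
  expect_equal(p1, exp(1) / (3 * exp(1) + 10), tolerance = 1e-12)
  # tau -> 0 concentrates all mass on the argmax set
  p_small_tau <- sum(vapply(depth1, function(v)
    exp(action_log_prob(w, 0.01, b, v, ps_env3)), numeric(1)))
  expect_equal(p_small_tau, 1, tolerance = 1e-9)
})

test_that("per-step probabilities normalise for random weights and beliefs", {
  for (i in 1:40) {
    b <- random_belief(ps_env3, seed = 700 + i)
    w <- planscope:::with_seed(i, stats::rnorm(nF))
    tot <- sum(vapply(available_actions(b, ps_env3), function(a)
      exp(action_log_prob(w, 1.3, b, a, ps_env3)), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("trial likelihoods track the shrinking action set", {
  w0 <- numeric(nF)
  gt <- sample_ground_truth(ps_env3, seed = 4)
  term_only <- list(t = 1L, clicks = integer(0), values = numeric(0),
                    path = ps_env3$paths[[1L]], ground_truth = gt)
  expect_equal(trial_log_likelihood(w0, 1, term_only, ps_env3), log(1 / 13))
  two <- list(t = 1L, clicks = c(2L, 7L), values = gt[c(3L, 8L)],
              path = ps_env3$paths[[1L]], ground_truth = gt)
  expect_equal(trial_log_likelihood(w0, 1, two, ps_env3),
               log(1 / 13) + log(1 / 12) + log(1 / 11))
})

test_that("trial likelihood equals a step-by-step re-evaluation oracle", {
  w <- planscope:::with_seed(8, stats::rnorm(nF, sd = 0.7))
  for (sname in c("best_first", "myopic_satisficing", "local_search")) {
    tr <- simulate_trial(ps_strats[[sname]], ps_env3, seed = 21)
    # independent oracle: walk the trial, normalising propensities manually
    belief <- new_belief(ps_env3)
    ll <- 0
    for (a in c(tr$clicks, TERMINATE)) {
      avail <- available_actions(belief, ps_env3)
      u <- vapply(avail, function(x)
        sum(w * compute_features(belief, x, ps_env3)), numeric(1)) / 1.7
      ll <- ll + (u[match(a, avail)] - log(sum(exp(u - max(u)))) - max(u))
      if (a != TERMINATE) belief <- apply_click(belief, a, tr$ground_truth)
    }
    expect_equal(trial_log_likelihood(w, 1, tr, ps_env3, tau = 1.7),
                 unname(ll), tolerance = 1e-9)
  }
})

test_that("reordering clicks changes the likelihood of belief-dependent models", {
  w <- numeric(nF); names(w) <- default_feature_manifest()$name
  w["ancestor_observed"] <- 2
  gt <- sample_ground_truth(ps_env3, seed = 6)
  fwd <- list(t = 1L, clicks = c(1L, 2L), values = gt[c(2L, 3L)],
              path = ps_env3$paths[[1L]], ground_truth = gt)
  rev_ <- list(t = 1L, clicks = c(2L, 1L), values = gt[c(3L, 2L)],
               path = ps_env3$paths[[1L]], ground_truth = gt)
  expect_false(isTRUE(all.equal(trial_log_likelihood(w, 1, fwd, ps_env3),
                                trial_log_likelihood(w, 1, rev_, ps_env3))))
})

test_that("MLE recovers the action distributions of a known softmax policy", {
  w_true <- numeric(nF); names(w_true) <- default_feature_manifest()$name
  w_true[c("is_leaf", "is_terminate", "best_leaf_found")] <- c(1.5, -0.5, 3)
  trials <- lapply(1:2000, function(i)
    sample_trial_from_model(w_true, NULL, ps_env3, tau = 1,
                            seed = planscope:::derive_seed(31L, i), t = i))
  st <- planscope:::stack_trials(trials, ps_env3)
  fit <- stats::optim(numeric(nF), fn = planscope:::logit_nll,
                      gr = planscope:::logit_grad, st = st, ridge = 1e-4,
                      method = "BFGS", control = list(maxit = 250))
  # compare predicted distributions, not raw weights (likelihood-equivalent
  # directions exist)
  for (i in 1:30) {
    b <- random_belief(ps_env3, seed = 900 + i)
    X <- feature_matrix(b, ps_env3)
    p_true <- exp(X %*% w_true); p_true <- p_true / sum(p_true)
    p_fit <- exp(X %*% fit$par); p_fit <- p_fit / sum(p_fit)
    expect_lt(max(abs(p_true - p_fit)), 0.06)
  }
})

test_that("the fitted no-planning model terminates immediately", {
  b <- new_belief(ps_env3)
  p_term <- exp(action_log_prob(ps_om$weights[, "no_planning"], 1, b,
                                TERMINATE, ps_env3))
  expect_gte(p_term, 0.95)
})

test_that("fitted strategies beat the uniform baseline on held-out trials", {
  w0 <- numeric(nF)
  for (sname in names(ps_strats)) {
    held <- lapply(1:25, function(i)
      simulate_trial(ps_strats[[sname]], ps_env3, seed = 5000L + i, t = i))
    ll_fit <- sum(vapply(held, function(tr)
      trial_log_likelihood(ps_om, sname, tr, ps_env3), numeric(1)))
    ll_unif <- sum(vapply(held, function(tr)
      trial_log_likelihood(w0, 1, tr, ps_env3), numeric(1)))
    if (sname == "random_search") {
      expect_gte(ll_fit, ll_unif - 5)   # the random strategy IS the baseline
    } else {
      expect_gt(ll_fit, ll_unif)
    }
  }
})

test_that("average click likelihood behaves as a diagnostic should", {
  gt <- sample_ground_truth(ps_env3, seed = 10)
  term_trials <- lapply(1:5, function(i)
    list(t = i, clicks = integer(0), values = numeric(0),
         path = ps_env3$paths[[1L]], ground_truth = gt))
  acl <- average_click_likelihood(ps_om, term_trials,
                                  rep(which(names(ps_strats) == "random_search"), 5),
                                  ps_env3)
  expect_lt(abs(acl$arithmetic - 1 / 13), 0.015)
  # the generating strategy predicts its own clicks better than random
  sim <- lapply(1:15, function(i)
    simulate_trial(ps_strats$goal_setting_satisficing, ps_env3, seed = 60 + i))
  id_gs <- which(names(ps_strats) == "goal_setting_satisficing")
  id_rand <- which(names(ps_strats) == "random_search")
  a_gs <- average_click_likelihood(ps_om, sim, rep(id_gs, 15), ps_env3)
  a_rand <- average_click_likelihood(ps_om, sim, rep(id_rand, 15), ps_env3)
  expect_gt(a_gs$arithmetic, a_rand$arithmetic)
  expect_gt(a_gs$geometric, a_rand$geometric)
})
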