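# HMM transition priors, Viterbi decoding, hyperparameter fitting.
# (brute_force_map, the exhaustive reference decoder, lives in the helper.)

test_that("the abrupt transition matrix follows its defining formula", {
  M <- transition_matrix(transition_prior("abrupt", p_stay = 0.6), 79)
  expect_equal(unique(diag(M)), 0.6)
  expect_equal(unique(M[row(M) != col(M)]), 0.4 / 78)
  expect_equal(rowSums(M), rep(1, 79))
  expect_equal(transition_matrix(transition_prior("abrupt", p_stay = 1), 5),
               diag(5))
  expect_equal(transition_matrix(transition_prior("abrupt", p_stay = 1 / 7), 7),
               matrix(1 / 7, 7, 7))
  expect_error(transition_prior("abrupt", p_stay = 1.2), "0, 1")
})

test_that("joint log-probability matches term-by-term recomputation", {
  set.seed(40)
  L <- matrix(stats::rnorm(5 * 4), 5, 4)
  prior <- transition_prior("abrupt", p_stay = 0.7)
  s <- c(2L, 2L, 4L, 1L, 1L)
  # independent recomputation
  A <- transition_matrix(prior, 4)
  manual <- log(1 / 4) + L[1, 2] +
    sum(vapply(2:5, function(t) log(A[s[t - 1], s[t]]) + L[t, s[t]], numeric(1)))
  expect_equal(joint_log_prob(s, L, prior), manual)
  # T = 1: no transition terms
  expect_equal(joint_log_prob(3L, L[1, , drop = FALSE], prior),
               log(1 / 4) + L[1, 3])
  # constant sequence under p_stay = 1 has zero-cost transitions
  expect_equal(joint_log_prob(rep(2L, 5), L, transition_prior("abrupt", p_stay = 1)),
               log(1 / 4) + sum(L[, 2]))
  expect_error(joint_log_prob(c(1L, 2L), L, prior), "length")
})

test_that("Viterbi equals exhaustive enumeration, ties included", {
  for (i in 1:60) {
    set.seed(1200 + i)
    S <- sample(2:5, 1); T_ <- sample(1:5, 1)
    L <- matrix(stats::rnorm(T_ * S), T_, S)
    if (i %% 3 == 0) L[, 1L] <- L[, 2L]  # force exact ties
    p <- stats::runif(1)
    v <- viterbi_map(L, transition_prior("abrupt", p_stay = p))
    bf <- brute_force_map(L, p)
    expect_equal(v$log_prob, bf$log_prob, tolerance = 1e-10)
    expect_equal(v$sequence, bf$sequence)
    # the MAP sequence scores at least as high as any other sequence
    expect_gte(v$log_prob + 1e-10,
               joint_log_prob(rep(1L, T_), L, transition_prior("abrupt", p_stay = p)))
  }
})

test_that("a flat prior decouples Viterbi into per-trial argmaxes", {
  set.seed(3)
  L <- matrix(stats::rnorm(8 * 6), 8, 6)
  v <- viterbi_map(L, transition_prior("abrupt", p_stay = 1 / 6))
  expect_equal(v$sequence, apply(L, 1, which.max))
})

test_that("p_stay grid search has 51 candidates and resolves ties downward", {
  f <- fit_p_stay(matrix(0, 1, 4))
  expect_equal(length(f$grid), 51L)
  expect_equal(f$p_stay, 0)          # single trial: all grid values tie
  # sticky data pushes the fitted p_stay up
  Ls <- matrix(-5, 10, 3); Ls[, 2] <- -1
  fs <- fit_p_stay(Ls)
  expect_gte(fs$p_stay, 0.9)
})

test_that("temperature fitting is deterministic and beats the range endpoints", {
  gen <- generate_participants("abrupt_markov", ps_om, ps_env3, n = 1,
                               n_trials = 25, seed = 91)
  cache <- planscope:::participant_cache(gen$dataset$participants[[1]]$trials,
                                         ps_om, ps_env3)
  prior <- transition_prior("abrupt", p_stay = 0.8)
  f1 <- fit_temperature(cache, prior)
  f2 <- fit_temperature(cache, prior)
  expect_identical(f1, f2)
  obj <- function(tau) viterbi_map(planscope:::loglik_matrix(cache, tau),
                                   prior)$log_prob
  expect_gte(f1$log_prob, obj(1e-2))
  expect_gte(f1$log_prob, obj(1e2))
  expect_lte(f1$evals, 50L)
  # data generated at tau = 1 should be fitted in a sane band
  expect_gt(f1$tau, 0.4); expect_lt(f1$tau, 2.5)
})

test_that("the full pipeline returns a coherent inference result", {
  gen <- generate_participants("abrupt_markov", ps_om, ps_env3, n = 2,
                               n_trials = 12, seed = 17)
  res <- infer_strategies(gen$dataset$participants[[1]]$trials, ps_om, ps_env3)
  expect_s3_class(res, "inference_result")
  expect_equal(length(res$sequence), 12L)
  expect_true(all(res$sequence %in% seq_len(ncol(ps_om$weights))))
  expect_identical(res$strategy_names, ps_om$strategies$name[res$sequence])
  expect_identical(res$type_labels, ps_om$strategies$type_label[res$sequence])
  # the MAP sequence is at least as probable as the generating sequence
  L <- planscope:::loglik_matrix(
    planscope:::participant_cache(gen$dataset$participants[[1]]$trials,
                                  ps_om, ps_env3), res$tau)
  expect_gte(res$log_prob + 1e-9,
             joint_log_prob(gen$sequences[1, ], L,
                            transition_prior("abrupt", p_stay = res$p_stay)))
})

test_that("information criteria are computed by their definitions", {
  gen <- generate_participants("abrupt_markov", ps_om, ps_env3, n = 1,
                               n_trials = 15, seed = 23)
  trials <- gen$dataset$participants[[1]]$trials
  cp <- compare_priors(trials, ps_om, ps_env3, priors = c("abrupt", "abrupt"),
                       tau = 1)
  expect_equal(cp$AIC[1], cp$AIC[2])
  expect_equal(cp$BIC[1], cp$BIC[2])
  expect_equal(cp$AIC, 2 * cp$k - 2 * cp$log_lik)
  expect_equal(cp$BIC, cp$k * log(15) - 2 * cp$log_lik)
  cp2 <- compare_priors(trials, ps_om, ps_env3, distances = ps_dist$D, tau = 1)
  expect_setequal(cp2$prior, c("abrupt", "gradual"))
  expect_equal(cp2$BIC, sort(cp2$BIC))
})

test_that("decoding cost scales quadratically in the strategy count", {
  set.seed(77)
  L40 <- matrix(stats::rnorm(50 * 40), 50, 40)
  tm <- system.time(
    for (k in 1:20) viterbi_map(L40, transition_prior("abrupt", 0.7)))["elapsed"]
  expect_lt(tm, 5)  # smoke bound: 20 decodes of T=50, S=40 stay fast
})
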