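# Strategy distances, clustering, decision-system influence, time courses,
# performance scores.

test_that("strategy distances are symmetric with an exactly zero diagonal", {
  expect_equal(strategy_distance(ps_om, "myopic_all", "myopic_all", ps_env3,
                                 n_mc = 100), 0)
  d_ab <- strategy_distance(ps_om, "no_planning", "breadth_first", ps_env3,
                            n_mc = 120, seed = 2)
  d_ba <- strategy_distance(ps_om, "breadth_first", "no_planning", ps_env3,
                            n_mc = 120, seed = 2)
  expect_identical(d_ab, d_ba)
  expect_true(all(diag(ps_dist$D) == 0))
  expect_identical(ps_dist$D, t(ps_dist$D))
  expect_true(all(ps_dist$D >= 0))
  # grossly different strategies sit far apart, near-variants close by
  expect_gt(ps_dist$D["no_planning", "breadth_first"],
            ps_dist$D["best_first", "satisficing_best_first_after_sweep"])
})

test_that("Ward clustering handles the degenerate cuts and plants", {
  S <- nrow(ps_dist$D)
  cl_all <- cluster_strategies(ps_dist, n_clusters = S)
  expect_equal(length(unique(cl_all$assignment)), S)
  cl_one <- cluster_strategies(ps_dist, n_clusters = 1)
  expect_equal(unique(cl_one$assignment), 1L)
  expect_error(cluster_strategies(matrix(c(0, 1, 2, 0), 2, 2), 2), "symmetric")

  # planted partition: three strategies duplicated with small weight noise
  # must co-cluster at k = 3
  base <- c("no_planning", "breadth_first", "goal_setting_satisficing")
  om6 <- subset_obs_model(ps_om, rep(base, each = 2),
                          new_names = paste0(rep(base, each = 2), c("_a", "_b")))
  om6$weights <- om6$weights +
    planscope:::with_seed(5, matrix(stats::rnorm(length(om6$weights), sd = 0.02),
                                    nrow(om6$weights)))
  D6 <- strategy_distance_matrix(om6, ps_env3, n_mc = 150, seed = 3)
  cl <- cluster_strategies(D6, n_clusters = 3)
  a <- cl$assignment
  expect_equal(unname(a[c(1, 3, 5)]), unname(a[c(2, 4, 6)]))
  expect_equal(length(unique(a)), 3L)
})

test_that("relative influence follows the signed-sum formula", {
  man <- default_feature_manifest()
  w <- stats::setNames(numeric(nrow(man)), man$name)
  # category totals (+2, -1, +1, 0, 0) -> RI (0.5, 0.25, 0.25, 0, 0)
  w["path_value_through"] <- 2      # pavlovian, sign +1
  w["depth"] <- -1                  # model-free, sign +1
  w["myopic_voi"] <- 1              # metareasoning, sign +1
  ri <- relative_influence(w, man)
  expect_equal(unname(ri), c(0.5, 0.25, 0.25, 0, 0))
  expect_equal(sum(ri), 1)
  # the manifest sign flips a feature's contribution
  w2 <- w; w2["ancestor_loss"] <- 2   # pavlovian, sign -1: cancels +2
  ri2 <- relative_influence(w2, man)
  expect_equal(unname(ri2["pavlovian"]), 0)
  # all mass on one system
  w3 <- 0 * w; w3["is_terminate"] <- 4
  expect_equal(unname(relative_influence(w3, man)["mental_effort_avoidance"]), 1)
  expect_warning(ri0 <- relative_influence(0 * w, man), "uniform")
  expect_equal(as.numeric(ri0), rep(0.2, 5))
})

test_that("influence profiles of all fitted strategies are proper", {
  RI <- influence_profiles(ps_om)
  expect_equal(unname(rowSums(RI)), rep(1, nrow(RI)), tolerance = 1e-9)
  expect_true(all(RI >= 0))
})

test_that("time courses aggregate to proper per-trial frequencies", {
  mk <- function(ids) {
    r <- list(sequence = ids, strategy_names = ps_om$strategies$name[ids],
              type_labels = ps_om$strategies$type_label[ids],
              p_stay = 0.5, tau = 1, log_prob = 0, n_trials = length(ids))
    class(r) <- "inference_result"
    r
  }
  one <- mk(rep(3L, 6))
  tc1 <- time_course(list(one), level = "strategy")
  expect_equal(tc1$myopic_all, rep(1, 6))
  two <- list(mk(rep(1L, 6)), mk(rep(5L, 6)))
  tc2 <- time_course(two, level = "strategy")
  expect_equal(tc2$no_planning, rep(0.5, 6))
  expect_equal(tc2$breadth_first, rep(0.5, 6))
  expect_equal(unname(rowSums(tc2[, -1])), rep(1, 6))
  tct <- time_course(two, level = "type")
  expect_equal(unname(rowSums(tct[, -1])), rep(1, 6))
  tci <- time_course(two, level = "influence", obs_model = ps_om)
  expect_true(all(tci[, -1] >= 0 & tci[, -1] <= 1))
  expect_equal(unname(rowSums(tci[, -1])), rep(1, 6), tolerance = 1e-9)
})

test_that("performance scores normalise to [0, 1] with sane ordering", {
  picks <- c("no_planning", "myopic_all", "goal_setting_satisficing",
             "maximizing_goal_setting_backward")
  scores <- vapply(picks, function(nm)
    strategy_performance(ps_strats[[nm]], ps_env3, n_sims = 1500, seed = 9),
    numeric(1))
  r <- relative_scores(scores)
  expect_equal(max(r), 1); expect_equal(min(r), 0)
  expect_true(all(r >= 0 & r <= 1))
  # zero-mean rewards: not planning at all earns ~0 on average
  se <- sqrt(10 + 40 + 1440) / sqrt(1500)
  expect_lt(abs(scores["no_planning"]), 3 * se)
  # goal-setting exploits the increasing-variance structure; myopic does not
  expect_gt(scores["goal_setting_satisficing"], scores["myopic_all"])
  expect_warning(relative_scores(c(a = 1, b = 1)), "identically")
})
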