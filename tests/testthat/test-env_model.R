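# Environment construction, path enumeration, ground truth, beliefs, scoring.

test_that("presets match their stated layouts and reward sets", {
  expect_equal(length(enumerate_paths(ps_env3)), 6L)
  expect_equal(ps_env3$n_nodes, 13L)

  cv <- build_environment("constant_variance_3step")
  for (d in 1:3) {
    expect_equal(sort(cv$reward_model[[d]]$values), c(-10, -5, 5, 10))
  }
  dv <- build_environment("decreasing_variance_3step")
  expect_equal(sort(dv$reward_model[[1]]$values), c(-48, -24, 24, 48))
  expect_equal(sort(dv$reward_model[[3]]$values), c(-4, -2, 2, 4))
  expect_equal(sort(ps_env3$reward_model[[3]]$values), c(-48, -24, 24, 48))

  expect_equal(vapply(1:5, function(d) ps_env5$reward_model[[d]]$sd, numeric(1)),
               c(1, 2, 4, 8, 32))
})

test_that("path enumeration agrees with an independent graph traversal", {
  # brute-force oracle: count leaves reachable from the root
  count_paths <- function(children, v = 0L) {
    ks <- children[[v + 1L]]
    if (!length(ks)) return(1L)
    sum(vapply(ks, function(k) count_paths(children, k), integer(1)))
  }
  expect_equal(length(enumerate_paths(ps_env5)), count_paths(ps_env5$children))
  expect_equal(length(enumerate_paths(ps_env3)), count_paths(ps_env3$children))

  chain <- build_environment(list(
    name = "chain", children = list(1L, 2L, integer()),
    reward_model = rep(list(list(kind = "discrete", values = c(-1, 1))), 2)))
  expect_equal(length(enumerate_paths(chain)), 1L)
  # every path runs parent -> child from the start to a leaf
  for (p in enumerate_paths(ps_env5)) {
    expect_identical(ps_env5$parent[p[-1L] + 1L], p[-length(p)])
    expect_equal(length(ps_env5$children[[p[length(p)] + 1L]]), 0L)
  }
})

test_that("malformed environment specs are rejected with a named violation", {
  rm2 <- rep(list(list(kind = "discrete", values = c(-1, 1))), 2)
  expect_error(build_environment(list(children = list(c(1L), c(1L), integer()),
                                      reward_model = rm2)),
               "cycle")
  expect_error(build_environment(list(children = list(c(1L, 2L), c(2L), integer()),
                                      reward_model = rm2)),
               "more than one parent")
  expect_error(build_environment(list(children = list(1L, integer(), integer()),
                                      reward_model = rm2)),
               "orphan")
  expect_error(build_environment(list(children = list(1L, 2L, integer()),
                                      reward_model = rm2[1])),
               "reward_model")
})

test_that("ground truth draws follow the per-depth distributions", {
  g <- sample_ground_truth(ps_env3, seed = 5)
  expect_identical(g, sample_ground_truth(ps_env3, seed = 5))
  dv <- build_environment("decreasing_variance_3step")
  draws <- lapply(1:400, function(i) sample_ground_truth(dv, seed = i))
  d1 <- unlist(lapply(draws, function(g) g[which(dv$depth == 1L)]))
  expect_true(all(d1 %in% c(-48, -24, 24, 48)))
  # zero-mean symmetry: per-depth sample means within 3 MC standard errors
  for (d in 1:3) {
    x <- unlist(lapply(draws, function(g) g[which(dv$depth == d)]))
    expect_lt(abs(mean(x)), 3 * stats::sd(x) / sqrt(length(x)))
  }
})

test_that("clicks accumulate monotonically and invalid clicks error", {
  gt <- sample_ground_truth(ps_env3, seed = 2)
  b <- new_belief(ps_env3)
  b <- apply_click(b, 5L, gt)
  expect_equal(unclass(b)[6L], unname(gt[6L]))
  expect_error(apply_click(b, 5L, gt), "already")
  expect_error(apply_click(b, 0L, gt), "start node")
  for (v in setdiff(1:12, 5L)) b <- apply_click(b, v, gt)
  expect_equal(sum(!is.na(unclass(b))), 12L)

  # final belief is order-insensitive
  b1 <- new_belief(ps_env3); b2 <- new_belief(ps_env3)
  for (v in c(3L, 7L, 1L)) b1 <- apply_click(b1, v, gt)
  for (v in c(1L, 3L, 7L)) b2 <- apply_click(b2, v, gt)
  expect_equal(unclass(b1), unclass(b2))
})

test_that("expected path values mix observed rewards and zero means", {
  dv <- build_environment("decreasing_variance_3step")
  path <- enumerate_paths(dv)[[1L]]
  b <- new_belief(dv)
  expect_equal(expected_path_value(b, path, dv), 0)
  gt <- rep(NA_real_, dv$n_nodes)
  gt[path[2L] + 1L] <- 48; gt[path[3L] + 1L] <- -4
  b <- apply_click(b, path[2L], gt)
  b <- apply_click(b, path[3L], gt)
  expect_equal(expected_path_value(b, path, dv), 44)
  gt[path[4L] + 1L] <- 2
  b <- apply_click(b, path[4L], gt)
  expect_equal(expected_path_value(b, path, dv), 46)
})

test_that("trial scores are path return minus click fees", {
  path <- enumerate_paths(ps_env3)[[1L]]
  gt <- rep(0, ps_env3$n_nodes); gt[1L] <- NA
  gt[path[-1L] + 1L] <- c(2, 8, 48)
  expect_equal(trial_score(path, gt, 3L, ps_env3), 55)
  gt[path[-1L] + 1L] <- 0
  expect_equal(trial_score(path, gt, 0L, ps_env3), 0)
  gt[path[-1L] + 1L] <- c(10, 0, 0)
  expect_equal(trial_score(path, gt, 12L, ps_env3), -2)
})
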