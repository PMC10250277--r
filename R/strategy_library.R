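# Planning strategies as stochastic generative click policies.
#
# Each strategy maps a belief state to a distribution over the available
# planning operations: clicking one of the still-concealed nodes, or
# terminating planning and acting. Strategies spread probability uniformly
# over all clicks they treat as functionally equivalent at the current step.

#' Termination pseudo-action
#'
#' The decision to stop gathering information and act. Represented as the
#' integer -1 so that action vectors stay integer node ids.
#' @export
TERMINATE <- -1L

#' Actions available in a belief state
#'
#' @param belief a `belief_state`.
#' @param env the `mdp_env`.
#' @return integer vector: all unclicked non-start nodes in increasing id
#'   order, followed by [TERMINATE]. Never empty.
#' @export
available_actions <- function(belief, env) {
  b <- unclass(belief)
  cand <- which(is.na(b[-1L])) # positions 2..n -> node ids
  c(as.integer(cand), TERMINATE)
}

# Quantities most policies condition on, computed once per step.
policy_context <- function(belief, env) {
  b <- unclass(belief)
  obs_mask <- !is.na(b)
  cand <- which(is.na(b[-1L]))
  pv <- all_path_values(belief, env)
  plen <- env$path_len
  oc <- as.vector(env$path_inc %*% ifelse(obs_mask, 1, 0))
  leaf_obs <- b[env$leaves + 1L]
  list(b = b, obs_mask = obs_mask, cand = as.integer(cand), pv = pv,
       complete_pos = any(oc == plen & pv > 0),
       leaf_obs = leaf_obs[!is.na(leaf_obs)],
       cand_leaves = intersect(cand, env$leaves),
       cand_depth = env$depth[cand + 1L])
}

# A policy step: uniform probability (1 - term) over `nodes`, `term` on stop.
pstep <- function(nodes = integer(), term = 0) list(nodes = as.integer(nodes), term = term)

frontier_of <- function(ctx, env) {
  par <- env$parent[ctx$cand + 1L]
  ctx$cand[par == 0L | ctx$obs_mask[par + 1L]]
}

best_first_pick <- function(ctx, env) {
  fr <- frontier_of(ctx, env)
  if (!length(fr)) return(ctx$cand)
  sc <- vapply(fr, function(v) max(ctx$pv[env$paths_through[[v + 1L]]]), numeric(1))
  fr[sc >= max(sc) - 1e-12]
}

builtin_policies <- function() list(
  no_planning = function(ctx, env) pstep(term = 1),

  random_search = function(ctx, env) {
    k <- length(ctx$cand)
    pstep(ctx$cand, term = 1 / (k + 1))
  },

  myopic_all = function(ctx, env) {
    u <- ctx$cand[ctx$cand_depth == 1L]
    if (!length(u)) pstep(term = 1) else pstep(u)
  },

  myopic_satisficing = function(ctx, env) {
    u <- ctx$cand[ctx$cand_depth == 1L]
    seen1 <- ctx$b[which(env$depth == 1L)]
    if (!length(u) || any(seen1 > 0, na.rm = TRUE)) pstep(term = 1) else pstep(u)
  },

  breadth_first = function(ctx, env) {
    if (!length(ctx$cand)) return(pstep(term = 1))
    pstep(ctx$cand[ctx$cand_depth == min(ctx$cand_depth)])
  },

  satisficing_depth_first = function(ctx, env) {
    if (ctx$complete_pos || !length(ctx$cand)) return(pstep(term = 1))
    par <- env$parent[ctx$cand + 1L]
    deep <- ctx$cand[par != 0L & ctx$obs_mask[par + 1L]]
    if (length(deep)) {
      pd <- env$depth[env$parent[deep + 1L] + 1L]
      pstep(deep[pd == max(pd)])
    } else {
      pstep(ctx$cand[ctx$cand_depth == 1L])
    }
  },

  best_first = function(ctx, env) {
    if (!length(ctx$cand) || max(ctx$pv) >= env$aspiration) return(pstep(term = 1))
    pstep(best_first_pick(ctx, env))
  },

  best_first_no_stop = function(ctx, env) {
    if (!length(ctx$cand)) return(pstep(term = 1))
    pstep(best_first_pick(ctx, env))
  },

  satisficing_best_first_after_sweep = function(ctx, env) {
    u <- ctx$cand[ctx$cand_depth == 1L]
    if (length(u)) return(pstep(u))
    if (!length(ctx$cand) || max(ctx$pv) >= env$aspiration) return(pstep(term = 1))
    pstep(best_first_pick(ctx, env))
  },

  goal_setting_satisficing = function(ctx, env) {
    if (any(ctx$leaf_obs >= env$leaf_goal) || !length(ctx$cand_leaves)) {
      pstep(term = 1)
    } else pstep(ctx$cand_leaves)
  },

  maximizing_goal_setting_backward = function(ctx, env) {
    found <- any(ctx$leaf_obs >= env$leaf_goal)
    if (!found && length(ctx$cand_leaves)) return(pstep(ctx$cand_leaves))
    lo <- ctx$b[env$leaves + 1L]
    if (all(is.na(lo))) return(pstep(term = 1))
    best <- env$leaves[which(lo >= max(lo, na.rm = TRUE) - 1e-12)]
    pn <- setdiff(unique(unlist(env$ancestors[best + 1L])), integer(0))
    pn <- intersect(pn, ctx$cand)
    if (length(pn)) pstep(pn) else pstep(term = 1)
  },

  goal_setting_exhaustive_backward = function(ctx, env) {
    if (length(ctx$cand_leaves)) return(pstep(ctx$cand_leaves))
    if (!length(ctx$cand)) return(pstep(term = 1))
    lo <- ifelse(is.na(ctx$b[env$leaves + 1L]), -Inf, ctx$b[env$leaves + 1L])
    leaf_of_path <- vapply(env$paths, function(p) p[length(p)], integer(1))
    path_leaf_val <- lo[match(leaf_of_path, env$leaves)]
    sc <- vapply(ctx$cand, function(v)
      max(path_leaf_val[env$paths_through[[v + 1L]]]), numeric(1))
    pstep(ctx$cand[sc >= max(sc) - 1e-12])
  },

  frugal_goal_setting = function(ctx, env) {
    if (any(ctx$leaf_obs > 0) || !length(ctx$cand_leaves)) pstep(term = 1)
    else pstep(ctx$cand_leaves)
  },

  consecutive_second_maximum = function(ctx, env) {
    if (sum(ctx$leaf_obs >= env$leaf_goal2) >= 2L || !length(ctx$cand_leaves)) {
      pstep(term = 1)
    } else pstep(ctx$cand_leaves)
  },

  local_search = function(ctx, env) {
    if (ctx$complete_pos || !length(ctx$cand)) return(pstep(term = 1))
    if (!any(ctx$obs_mask)) return(pstep(ctx$cand))
    adj <- ctx$cand[vapply(ctx$cand, function(v) {
      p <- env$parent[v + 1L]
      (p != 0L && ctx$obs_mask[p + 1L]) ||
        any(ctx$obs_mask[env$children[[v + 1L]] + 1L]) ||
        any(ctx$obs_mask[env$siblings[[v + 1L]] + 1L])
    }, logical(1))]
    if (!length(adj)) pstep(term = 1) else pstep(adj)
  },

  middle_out = function(ctx, env) {
    if (!length(ctx$cand)) return(pstep(term = 1))
    m <- (env$max_depth + 1) / 2
    ord <- unique(ctx$cand_depth[order(abs(ctx$cand_depth - m), ctx$cand_depth)])
    pstep(ctx$cand[ctx$cand_depth == ord[1L]])
  }
)

builtin_types <- function() c(
  no_planning = "frugal_planning",
  random_search = "miscellaneous",
  myopic_all = "myopic_planning",
  myopic_satisficing = "myopic_planning",
  breadth_first = "forward_planning_breadth_first",
  satisficing_depth_first = "local_search",
  best_first = "forward_planning_best_first",
  best_first_no_stop = "forward_planning_best_first",
  satisficing_best_first_after_sweep = "forward_planning_best_first",
  goal_setting_satisficing = "maximizing_goal_setting",
  maximizing_goal_setting_backward = "maximizing_goal_setting",
  goal_setting_exhaustive_backward = "exhaustive_goal_setting",
  frugal_goal_setting = "frugal_goal_setting",
  consecutive_second_maximum = "maximizing_goal_setting",
  local_search = "local_search",
  middle_out = "middle_out"
)

#' Built-in strategy set
#'
#' The library of generative planning strategies shipped with the package.
#' It covers every behaviour named in the strategy taxonomy the package
#' implements: no planning, random clicking, myopic strategies (exhaustive
#' and satisficing), breadth-first, satisficing depth-first, best-first
#' (terminating, non-terminating, and after an immediate sweep),
#' goal-setting strategies (satisficing search over final outcomes,
#' maximizing goal-setting with limited backward planning, exhaustive
#' backward planning, frugal goal-setting, consecutive second maximum),
#' local search, and middle-out planning. Further strategies can be added
#' with [register_strategy()].
#'
#' @return a `strategy_set`: an ordered list of strategies, each with an
#'   integer `id` (the index space used by all downstream tables), `name`,
#'   `type_label`, and a `policy` function.
#' @export
default_strategies <- function() {
  pols <- builtin_policies()
  types <- builtin_types()
  set <- lapply(seq_along(pols), function(i) {
    s <- list(id = i, name = names(pols)[i],
              type_label = unname(types[names(pols)[i]]),
              policy = pols[[i]])
    class(s) <- "planning_strategy"
    s
  })
  names(set) <- names(pols)
  class(set) <- "strategy_set"
  set
}

#' Register an additional strategy
#'
#' @param set a `strategy_set`.
#' @param name unique strategy name.
#' @param type_label strategy-type label used for type-level analyses.
#' @param policy function `(ctx, env)` returning a policy step: use
#'   [policy_step()] to build it from a click set and a stop probability.
#' @return the extended `strategy_set`; the new strategy gets the next id.
#' @export
register_strategy <- function(set, name, type_label, policy) {
  stopifnot(inherits(set, "strategy_set"), is.function(policy))
  if (name %in% names(set)) {
    stop("a strategy named '", name, "' is already registered", call. = FALSE)
  }
  s <- list(id = length(set) + 1L, name = name, type_label = type_label,
            policy = policy)
  class(s) <- "planning_strategy"
  set[[name]] <- s
  class(set) <- "strategy_set"
  set
}

#' Build a policy step for a custom strategy
#'
#' @param nodes nodes treated as functionally equivalent clicks at this step.
#' @param term probability of terminating planning at this step.
#' @return internal policy-step structure.
#' @export
policy_step <- function(nodes = integer(), term = 0) pstep(nodes, term)

get_strategy <- function(set, id_or_name) {
  s <- if (is.character(id_or_name)) set[[id_or_name]] else set[[as.integer(id_or_name)]]
  if (is.null(s)) stop("unknown strategy: ", id_or_name, call. = FALSE)
  s
}

#' Action distribution of a strategy in a belief state
#'
#' @param strategy a `planning_strategy` (element of a strategy set), or a
#'   strategy id/name together with `set`.
#' @param belief a `belief_state`.
#' @param env the `mdp_env`.
#' @param set optional `strategy_set` used to resolve `strategy` by id/name.
#' @return numeric probability vector aligned with
#'   [available_actions()]`(belief, env)` (termination last); sums to 1.
#' @export
strategy_policy <- function(strategy, belief, env, set = NULL) {
  if (!inherits(strategy, "planning_strategy")) {
    if (is.null(set)) stop("pass a strategy object or a strategy set", call. = FALSE)
    strategy <- get_strategy(set, strategy)
  }
  ctx <- policy_context(belief, env)
  st <- strategy$policy(ctx, env)
  avail <- c(ctx$cand, TERMINATE)
  p <- numeric(length(avail))
  names(p) <- avail
  p[length(p)] <- st$term
  if (length(st$nodes)) {
    p[match(st$nodes, avail)] <- (1 - st$term) / length(st$nodes)
  }
  p
}

#' Simulate one Mouselab-MDP trial from a generative strategy
#'
#' Samples clicks sequentially from the strategy's policy until it
#' terminates (or nothing is left to click), then selects the path with the
#' highest expected value under the final belief, breaking ties uniformly
#' at random.
#'
#' @param strategy a `planning_strategy`.
#' @param env the `mdp_env`.
#' @param seed optional integer seed.
#' @param truth optional pre-drawn `ground_truth`; sampled if missing.
#' @param t trial index stored in the record.
#' @return a trial record: list with `clicks` (ordered node ids), `values`
#'   (revealed rewards), `path`, `ground_truth`, `score`, `env_name`, `t`.
#' @export
simulate_trial <- function(strategy, env, seed = NULL, truth = NULL, t = 1L) {
  run <- function() {
    gt <- if (is.null(truth)) sample_ground_truth(env) else truth
    belief <- new_belief(env)
    clicks <- integer(0); values <- numeric(0)
    repeat {
      ctx <- policy_context(belief, env)
      st <- strategy$policy(ctx, env)
      acts <- c(st$nodes, TERMINATE)
      pr <- c(rep((1 - st$term) / max(length(st$nodes), 1L), length(st$nodes)), st$term)
      a <- if (length(acts) == 1L) acts else acts[sample.int(length(acts), 1L, prob = pr)]
      if (a == TERMINATE) break
      belief <- apply_click(belief, a, gt)
      clicks <- c(clicks, a)
      values <- c(values, gt[a + 1L])
    }
    finish_trial(belief, env, gt, clicks, values, t)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Greedy path choice under the final belief, uniform tie-breaking.
finish_trial <- function(belief, env, gt, clicks, values, t) {
  pv <- all_path_values(belief, env)
  best <- which(pv >= max(pv) - 1e-12)
  pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  path <- env$paths[[pick]]
  list(t = as.integer(t), clicks = clicks, values = values, path = path,
       ground_truth = gt,
       score = trial_score(path, gt, length(clicks), env),
       env_name = env$name)
}

#' @export
print.strategy_set <- function(x, ...) {
  cat("Strategy set with", length(x), "strategies:\n")
  for (s in x) cat(sprintf("  %2d %-36s [%s]\n", s$id, s$name, s$type_label))
  invisible(x)
}

# Ordered manifest of a strategy set; its hash stamps downstream tables.
strategy_manifest <- function(set) {
  data.frame(id = vapply(set, `[[`, integer(1), "id"),
             name = vapply(set, `[[`, character(1), "name"),
             type_label = vapply(set, `[[`, character(1), "type_label"),
             stringsAsFactors = FALSE)
}
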