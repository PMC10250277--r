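# Feature bank: the vector f(b, c) describing a candidate planning
# operation c in belief state b. Every feature belongs to exactly one of
# five decision-system categories, with a sign saying whether a larger
# value reflects more (+1) or less (-1) influence of that system.
#
# Click-specific features evaluate to 0 on the termination row, and
# stopping/termination features evaluate to 0 on click rows, so that all
# actions share one feature space.

FEATURE_CATEGORIES <- c("pavlovian", "model_free_values_heuristics",
                        "model_based_metareasoning", "mental_effort_avoidance",
                        "satisficing_stopping")

#' Feature manifest
#'
#' The ordered list of features used by the softmax observation model.
#' The row order defines the global feature ordering that every weight
#' vector refers to; the manifest hash is stamped on all weight tables.
#'
#' @return data.frame with columns `name`, `category`, `sign`.
#' @export
default_feature_manifest <- function() {
  f <- function(name, category, sign = 1) list(name, category, sign)
  rows <- list(
    # --- click features: structural and relational heuristics -----------
    f("depth",                   "model_free_values_heuristics"),
    f("is_immediate",            "model_free_values_heuristics"),
    f("is_middle",               "model_free_values_heuristics"),
    f("is_leaf",                 "model_free_values_heuristics"),
    f("parent_observed",         "model_free_values_heuristics"),
    f("ancestor_observed",       "model_free_values_heuristics"),
    f("n_ancestors_observed",    "model_free_values_heuristics"),
    f("descendant_observed",     "model_free_values_heuristics"),
    f("sibling_observed",        "model_free_values_heuristics"),
    f("adjacent_observed",       "model_free_values_heuristics"),
    f("n_observed_on_path",      "model_free_values_heuristics"),
    f("on_best_path",            "model_free_values_heuristics"),
    f("on_path_to_best_leaf",    "model_free_values_heuristics"),
    # --- Pavlovian attraction/repulsion: rewards on the node's own paths -
    f("path_value_through",      "pavlovian"),
    f("best_observed_ancestor",  "pavlovian"),
    f("ancestor_loss",           "pavlovian", -1),
    f("best_observed_successor", "pavlovian"),
    f("successor_loss",          "pavlovian", -1),
    # --- model-based metareasoning ---------------------------------------
    f("node_uncertainty",        "model_based_metareasoning"),
    f("myopic_voi",              "model_based_metareasoning"),
    # --- mental effort avoidance -----------------------------------------
    f("is_terminate",            "mental_effort_avoidance"),
    f("clicks_made",             "mental_effort_avoidance"),
    # --- satisficing and stopping criteria -------------------------------
    f("aspiration_met",          "satisficing_stopping"),
    f("term_best_path_value",    "satisficing_stopping"),
    f("positive_path_complete",  "satisficing_stopping"),
    f("frac_observed",           "satisficing_stopping"),
    f("all_immediate_observed",  "satisficing_stopping"),
    f("all_leaves_observed",     "satisficing_stopping"),
    f("best_leaf_found",         "satisficing_stopping")
  )
  data.frame(name = vapply(rows, `[[`, character(1), 1),
             category = vapply(rows, `[[`, character(1), 2),
             sign = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
             stringsAsFactors = FALSE)
}

# Manifest is fixed within a session; cache it (feature_matrix is hot).
feature_manifest_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_feature_manifest()
    m
  }
})

#' Feature-to-decision-system mapping
#'
#' @param manifest a feature manifest, by default [default_feature_manifest()].
#' @return named character vector mapping each feature name to its category;
#'   every feature appears exactly once.
#' @export
category_map <- function(manifest = default_feature_manifest()) {
  stats::setNames(manifest$category, manifest$name)
}

#' Feature matrix for all available actions
#'
#' Computes the full feature vector for every available action (all
#' unclicked nodes plus termination) in one call.
#'
#' @param belief a `belief_state`.
#' @param env the `mdp_env`.
#' @return numeric matrix, one row per action in [available_actions()]
#'   order (termination last), one column per manifest feature.
#' @export
feature_matrix <- function(belief, env) {
  man <- feature_manifest_cached()
  b <- unclass(belief)
  obs_mask <- !is.na(b)
  cand <- which(is.na(b[-1L]))
  nc <- length(cand)
  pv <- all_path_values(belief, env)
  oc <- as.vector(env$path_inc %*% ifelse(obs_mask, 1, 0))
  plen <- env$path_len %||% rowSums(env$path_inc)
  best_pv <- max(pv)
  n_obs <- sum(obs_mask)
  md <- env$max_depth

  lo <- b[env$leaves + 1L]
  best_leaf_paths <- integer(0)
  if (any(!is.na(lo))) {
    best_leaf_nodes <- env$leaves[which(lo >= max(lo, na.rm = TRUE) - 1e-12)]
    best_leaf_paths <- unique(unlist(env$paths_through[best_leaf_nodes + 1L]))
  }

  X <- matrix(0, nc + 1L, nrow(man))
  colnames(X) <- man$name

  if (nc) {
    d <- env$depth[cand + 1L]
    par <- env$parent[cand + 1L]
    anc_obs <- num <- anc_loss <- best_anc <- best_des <- des_obs <-
      des_loss <- sib_obs <- adj_obs <- n_on_path <- on_best <- on_best_leaf <-
      pv_through <- voi <- numeric(nc)
    for (j in seq_len(nc)) {
      v <- cand[j]
      anc <- env$ancestors[[v + 1L]]
      des <- env$descendants[[v + 1L]]
      sib <- env$siblings[[v + 1L]]
      anc_v <- b[anc + 1L]; anc_v <- anc_v[!is.na(anc_v)]
      des_v <- b[des + 1L]; des_v <- des_v[!is.na(des_v)]
      anc_obs[j] <- length(anc_v) > 0
      num[j] <- length(anc_v)
      anc_loss[j] <- any(anc_v < 0)
      best_anc[j] <- if (length(anc_v)) max(anc_v) else 0
      des_obs[j] <- length(des_v) > 0
      des_loss[j] <- any(des_v < 0)
      best_des[j] <- if (length(des_v)) max(des_v) else 0
      sib_obs[j] <- any(obs_mask[sib + 1L])
      adj_obs[j] <- (par[j] != 0L && obs_mask[par[j] + 1L]) ||
        any(obs_mask[env$children[[v + 1L]] + 1L]) || sib_obs[j]
      through <- env$paths_through[[v + 1L]]
      pvt <- pv[through]
      n_on_path[j] <- max(oc[through])
      pv_through[j] <- max(pvt)
      on_best[j] <- pv_through[j] >= best_pv - 1e-12
      on_best_leaf[j] <- length(best_leaf_paths) > 0 &&
        any(through %in% best_leaf_paths)
      # myopic value of information, exact over the node's reward support
      sup <- env$support[[d[j]]]
      delta <- sup$values - env$depth_means[d[j]]
      m_out <- if (length(through) < length(pv)) max(pv[-through]) else -Inf
      voi[j] <- sum(sup$probs * pmax(m_out, pv_through[j] + delta)) - best_pv
    }
    ji <- seq_len(nc)
    X[ji, 1L] <- d
    X[ji, 2L] <- d == 1L
    X[ji, 3L] <- d > 1L & d < md
    X[ji, 4L] <- d == md
    X[ji, 5L] <- par == 0L | obs_mask[par + 1L]
    X[ji, 6L] <- anc_obs
    X[ji, 7L] <- num
    X[ji, 8L] <- des_obs
    X[ji, 9L] <- sib_obs
    X[ji, 10L] <- adj_obs
    X[ji, 11L] <- n_on_path
    X[ji, 12L] <- on_best
    X[ji, 13L] <- on_best_leaf
    X[ji, 14L] <- pv_through
    X[ji, 15L] <- best_anc
    X[ji, 16L] <- anc_loss
    X[ji, 17L] <- best_des
    X[ji, 18L] <- des_loss
    X[ji, 19L] <- env$depth_sds[d]
    X[ji, 20L] <- pmax(voi, 0)
  }

  ti <- nc + 1L
  X[ti, 21L] <- 1                                        # is_terminate
  X[ti, 22L] <- n_obs                                    # clicks_made
  X[ti, 23L] <- best_pv >= env$aspiration                # aspiration_met
  X[ti, 24L] <- best_pv                                  # term_best_path_value
  X[ti, 25L] <- any(oc == plen & pv > 0)                 # positive_path_complete
  X[ti, 26L] <- n_obs / (env$n_nodes - 1L)               # frac_observed
  X[ti, 27L] <- all(obs_mask[which(env$depth == 1L)])    # all_immediate_observed
  X[ti, 28L] <- all(obs_mask[env$leaves + 1L])           # all_leaves_observed
  X[ti, 29L] <- any(lo >= env$leaf_goal, na.rm = TRUE)   # best_leaf_found
  X
}

#' Feature vector of a single action
#'
#' @param belief a `belief_state`.
#' @param action a node id, or [TERMINATE].
#' @param env the `mdp_env`.
#' @return named numeric vector in manifest order.
#' @export
compute_features <- function(belief, action, env) {
  avail <- available_actions(belief, env)
  i <- match(as.integer(action), avail)
  if (is.na(i)) stop("action ", action, " is not available in this belief state",
                     call. = FALSE)
  X <- feature_matrix(belief, env)
  stats::setNames(X[i, ], colnames(X))
}

#' Myopic value of information of inspecting a node
#'
#' Expected improvement in the maximum expected path value from revealing
#' the node's reward, with the expectation taken over the node's reward
#' distribution. Always non-negative.
#'
#' @param belief a `belief_state`.
#' @param node 0-based id of an unclicked non-start node.
#' @param env the `mdp_env`.
#' @return the myopic VOI in the task currency.
#' @export
myopic_voi <- function(belief, node, env) {
  b <- unclass(belief)
  if (!is.na(b[node + 1L])) stop("node ", node, " is already observed", call. = FALSE)
  pv <- all_path_values(belief, env)
  d <- env$depth[node + 1L]
  sup <- env$support[[d]]
  through <- env$paths_through[[node + 1L]]
  m_in <- max(pv[through])
  m_out <- if (length(through) < length(pv)) max(pv[-through]) else -Inf
  delta <- sup$values - env$depth_means[d]
  max(0, sum(sup$probs * pmax(m_out, m_in + delta)) - max(pv))
}
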