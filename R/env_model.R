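# Mouselab-MDP planning environments: rooted out-trees whose non-start nodes
# hide stochastic rewards that are revealed one click at a time.

GH_POINTS <- 15L  # Gauss-Hermite order used to discretise normal rewards

#' Build a Mouselab-MDP planning environment
#'
#' Constructs a planning environment as a rooted out-tree with concealed
#' per-node rewards. Node ids are 0-based with the start node fixed at 0;
#' rewards are attached to every non-start node and drawn per depth from
#' either a discrete uniform distribution over a finite integer set or a
#' zero-mean normal distribution.
#'
#' Four presets are available:
#' \describe{
#'   \item{`increasing_variance_3step`}{Three first moves, one forced second
#'     move each, two final moves each (13 nodes, 6 paths). Reward sets
#'     \{-4,-2,+2,+4\}, \{-8,-4,+4,+8\}, \{-48,-24,+24,+48\} at depths 1-3,
#'     so long-term outcomes matter most.}
#'   \item{`decreasing_variance_3step`}{Same tree, reward sets mirrored:
#'     \{-48,-24,+24,+48\}, \{-8,-4,+4,+8\}, \{-4,-2,+2,+4\}.}
#'   \item{`constant_variance_3step`}{Same tree, all depths uniform over
#'     \{-10,-5,+5,+10\}.}
#'   \item{`increasing_variance_5step`}{Three-branch trunk with binary splits
#'     at the last two steps (28 nodes, 12 paths); rewards normal with
#'     sd = 1, 2, 4, 8, 32 at depths 1-5.}
#' }
#'
#' @param preset preset name, or a list with fields `name`, `children`
#'   (list of integer child-id vectors, one per node, 0-based ids, element
#'   `i + 1` belongs to node `i`), `reward_model` (list per depth, each
#'   either `list(kind = "discrete", values = ...)` or
#'   `list(kind = "normal", sd = ...)`), and optional `click_cost`.
#' @param click_cost fee charged per click, in the task currency. Default $1.
#' @param aspiration satisficing aspiration level used by stopping rules and
#'   the satisficing feature. Defaults to $48 where the environment can pay
#'   at least that much on one path, otherwise to the maximum path value.
#' @return an object of class `mdp_env`.
#' @examples
#' env <- build_environment("increasing_variance_3step")
#' length(enumerate_paths(env))  # 6
#' @export
build_environment <- function(preset = "increasing_variance_3step",
                              click_cost = 1, aspiration = NULL) {
  spec <- if (is.character(preset)) env_preset_spec(preset) else preset
  if (is.null(spec$click_cost)) spec$click_cost <- click_cost
  validate_env_spec(spec)
  finalize_env(spec, aspiration = aspiration)
}

env_preset_spec <- function(name) {
  tree3 <- list(
    c(1L, 5L, 9L), c(2L), c(3L, 4L), integer(), integer(),
    c(6L), c(7L, 8L), integer(), integer(),
    c(10L), c(11L, 12L), integer(), integer()
  )
  disc <- function(v) list(kind = "discrete", values = v)
  norm <- function(s) list(kind = "normal", sd = s)
  specs <- list(
    increasing_variance_3step = list(
      children = tree3,
      reward_model = list(disc(c(-4, -2, 2, 4)), disc(c(-8, -4, 4, 8)),
                          disc(c(-48, -24, 24, 48)))
    ),
    decreasing_variance_3step = list(
      children = tree3,
      reward_model = list(disc(c(-48, -24, 24, 48)), disc(c(-8, -4, 4, 8)),
                          disc(c(-4, -2, 2, 4)))
    ),
    constant_variance_3step = list(
      children = tree3,
      reward_model = rep(list(disc(c(-10, -5, 5, 10))), 3)
    ),
    increasing_variance_5step = list(
      children = local({
        # trunk: 0 -> {1, 10, 19}; each branch a chain of 3, then two
        # binary splits (depths 4 and 5): 1 + 3 * 9 = 28 nodes, 12 paths
        branch <- function(b) {
          o <- 1L + 9L * b  # first node id of branch b (0-based branches)
          list(c(o + 1L), c(o + 2L), c(o + 3L, o + 6L),
               c(o + 4L, o + 5L), integer(), integer(),
               c(o + 7L, o + 8L), integer(), integer())
        }
        c(list(c(1L, 10L, 19L)), branch(0L), branch(1L), branch(2L))
      }),
      reward_model = list(norm(1), norm(2), norm(4), norm(8), norm(32))
    )
  )
  if (!name %in% names(specs)) {
    stop("unknown environment preset '", name, "'; available: ",
         paste(names(specs), collapse = ", "), call. = FALSE)
  }
  spec <- specs[[name]]
  spec$name <- name
  spec
}

validate_env_spec <- function(spec) {
  ch <- spec$children
  if (is.null(ch) || !is.list(ch) || length(ch) < 2) {
    stop("environment spec needs a 'children' list with at least 2 nodes",
         call. = FALSE)
  }
  n <- length(ch)
  ids <- 0:(n - 1L)
  kids <- unlist(ch, use.names = FALSE)
  if (length(kids) && (any(kids < 0) || any(kids >= n))) {
    stop("child ids must be existing 0-based node ids", call. = FALSE)
  }
  for (i in seq_len(n)) {
    if ((i - 1L) %in% ch[[i]]) {
      stop("invalid tree: node ", i - 1L, " lists itself as a child (cycle)",
           call. = FALSE)
    }
  }
  if (anyDuplicated(kids)) {
    stop("invalid tree: some node has more than one parent", call. = FALSE)
  }
  if (0L %in% kids) stop("invalid tree: the start node cannot be a child",
                         call. = FALSE)
  orphans <- setdiff(ids[-1L], kids)
  if (length(orphans)) {
    stop("invalid tree: orphan node(s) ", paste(orphans, collapse = ", "),
         " are unreachable from the start node", call. = FALSE)
  }
  depth <- env_depths(ch)
  md <- max(depth)
  rm_ <- spec$reward_model
  if (is.null(rm_) || length(rm_) < md) {
    stop("reward_model must cover every depth 1..", md, call. = FALSE)
  }
  for (d in seq_len(md)) {
    m <- rm_[[d]]
    ok <- is.list(m) && ((identical(m$kind, "discrete") && length(m$values) >= 1) ||
                         (identical(m$kind, "normal") && is.numeric(m$sd) && m$sd > 0))
    if (!ok) stop("malformed reward model at depth ", d, call. = FALSE)
  }
  if (spec$click_cost < 0) stop("click_cost must be >= 0", call. = FALSE)
  invisible(spec)
}

env_depths <- function(children) {
  n <- length(children)
  depth <- rep(NA_integer_, n)
  depth[1L] <- 0L
  queue <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (k in children[[v + 1L]]) {
      depth[k + 1L] <- depth[v + 1L] + 1L
      queue <- c(queue, k)
    }
  }
  if (anyNA(depth)) stop("invalid tree: disconnected node(s)", call. = FALSE)
  depth
}

finalize_env <- function(spec, aspiration = NULL) {
  children <- lapply(spec$children, as.integer)
  n <- length(children)
  depth <- env_depths(children)
  md <- max(depth)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) for (k in children[[i]]) parent[k + 1L] <- i - 1L

  leaves <- which(lengths(children) == 0L) - 1L
  ancestors <- vector("list", n)   # non-start ancestors, nearest first
  for (i in seq_len(n)) {
    a <- integer(); p <- parent[i]
    while (!is.na(p) && p != 0L) { a <- c(a, p); p <- parent[p + 1L] }
    ancestors[[i]] <- a
  }
  descendants <- vector("list", n)
  for (i in rev(seq_len(n))) {
    ks <- children[[i]]
    descendants[[i]] <- c(ks, unlist(descendants[ks + 1L], use.names = FALSE))
  }
  siblings <- lapply(seq_len(n), function(i) {
    p <- parent[i]
    if (is.na(p)) integer() else setdiff(children[[p + 1L]], i - 1L)
  })

  paths <- list()
  walk <- function(v, acc) {
    acc <- c(acc, v)
    ks <- children[[v + 1L]]
    if (!length(ks)) { paths[[length(paths) + 1L]] <<- acc; return(invisible()) }
    for (k in sort(ks)) walk(k, acc)
  }
  walk(0L, integer())
  # deterministic lexicographic order by node-id sequence
  ord <- order(vapply(paths, function(p) paste(sprintf("%06d", p), collapse = ""),
                      character(1)))
  paths <- paths[ord]
  np <- length(paths)
  path_inc <- matrix(0, np, n)
  for (j in seq_len(np)) path_inc[j, paths[[j]][-1L] + 1L] <- 1
  paths_through <- lapply(seq_len(n), function(i) which(path_inc[, i] > 0))

  # per-depth discretised reward support used for expectations (VOI etc.)
  support <- vector("list", md)
  sds <- numeric(md); maxr <- numeric(md)
  for (d in seq_len(md)) {
    m <- spec$reward_model[[d]]
    if (identical(m$kind, "discrete")) {
      v <- as.numeric(m$values)
      support[[d]] <- list(values = v, probs = rep(1 / length(v), length(v)))
      sds[d] <- sqrt(mean(v^2) - mean(v)^2)
      maxr[d] <- max(v)
    } else {
      gh <- gauss_hermite(GH_POINTS)
      support[[d]] <- list(values = sqrt(2) * m$sd * gh$nodes,
                           probs = gh$weights / sqrt(pi))
      sds[d] <- m$sd
      maxr[d] <- 3 * m$sd  # nominal "large value" scale for normal rewards
    }
  }
  depth_means <- vapply(seq_len(md), function(d)
    sum(support[[d]]$values * support[[d]]$probs), numeric(1))

  # best achievable expected path return: rewards depend only on depth
  max_path_value <- max(vapply(leaves, function(l)
    sum(maxr[seq_len(depth[l + 1L])]), numeric(1)))
  leaf_depth_max <- max(depth[leaves + 1L])
  leaf_vals <- spec$reward_model[[leaf_depth_max]]
  if (identical(leaf_vals$kind, "discrete")) {
    lv <- sort(unique(as.numeric(leaf_vals$values)), decreasing = TRUE)
    leaf_goal <- lv[1L]
    leaf_goal2 <- if (length(lv) > 1) lv[2L] else lv[1L]
  } else {
    leaf_goal <- maxr[leaf_depth_max]
    leaf_goal2 <- leaf_vals$sd
  }
  if (is.null(aspiration)) aspiration <- min(48, max_path_value)

  env <- list(
    name = spec$name %||% "custom",
    n_nodes = n, children = children, parent = parent, depth = depth,
    max_depth = md, leaves = leaves, ancestors = ancestors,
    descendants = descendants, siblings = siblings,
    paths = paths, path_inc = path_inc, path_len = rowSums(path_inc),
    paths_through = paths_through,
    reward_model = spec$reward_model[seq_len(md)], support = support,
    depth_means = depth_means, depth_sds = sds, depth_max_reward = maxr,
    max_path_value = max_path_value, aspiration = aspiration,
    leaf_goal = leaf_goal, leaf_goal2 = leaf_goal2,
    click_cost = spec$click_cost
  )
  class(env) <- "mdp_env"
  env
}

gauss_hermite <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix for Hermite
  # polynomials; exact enough for the expectations taken here.
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' @export
print.mdp_env <- function(x, ...) {
  cat("Mouselab-MDP environment '", x$name, "'\n", sep = "")
  cat("  nodes:", x$n_nodes, " depth:", x$max_depth,
      " paths:", length(x$paths), "\n")
  cat("  click cost:", x$click_cost, " aspiration:", x$aspiration, "\n")
  invisible(x)
}

#' Enumerate all start-to-leaf paths
#'
#' @param env an `mdp_env`.
#' @return list of integer node-id vectors (each starting at node 0),
#'   in deterministic lexicographic order.
#' @export
enumerate_paths <- function(env) {
  stopifnot(inherits(env, "mdp_env"))
  env$paths
}

#' Sample a ground-truth reward assignment
#'
#' Draws one realized reward per non-start node, independently from that
#' node's depth distribution.
#'
#' @param env an `mdp_env`.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of length `env$n_nodes` (class `ground_truth`);
#'   entry `i + 1` is node `i`'s reward, `NA` for the start node.
#' @export
sample_ground_truth <- function(env, seed = NULL) {
  draw <- function() {
    g <- rep(NA_real_, env$n_nodes)
    for (i in 2:env$n_nodes) {
      m <- env$reward_model[[env$depth[i]]]
      g[i] <- if (identical(m$kind, "discrete")) {
        sample(as.numeric(m$values), 1L)
      } else {
        stats::rnorm(1L, 0, m$sd)
      }
    }
    class(g) <- "ground_truth"
    g
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Create an empty belief state
#'
#' A belief state is the set of node rewards revealed so far in a trial.
#'
#' @param env an `mdp_env`.
#' @return numeric vector of length `env$n_nodes` with all entries `NA`
#'   (class `belief_state`); clicking fills entries in.
#' @export
new_belief <- function(env) {
  b <- rep(NA_real_, env$n_nodes)
  attr(b, "env_name") <- env$name
  class(b) <- "belief_state"
  b
}

#' Reveal one node's reward
#'
#' @param belief a `belief_state`.
#' @param node 0-based id of an unclicked non-start node.
#' @param truth a `ground_truth` vector for the same environment.
#' @return the updated belief state.
#' @export
apply_click <- function(belief, node, truth) {
  i <- as.integer(node) + 1L
  if (i == 1L) stop("cannot click the start node", call. = FALSE)
  if (i < 1L || i > length(belief)) stop("unknown node ", node, call. = FALSE)
  if (!is.na(belief[i])) stop("node ", node, " was already clicked", call. = FALSE)
  belief[i] <- truth[i]
  belief
}

observed_nodes <- function(belief) which(!is.na(unclass(belief))) - 1L

#' Expected value of a path under a belief state
#'
#' Observed rewards contribute their revealed value; unobserved rewards
#' contribute their depth distribution's mean (zero in all presets).
#'
#' @param belief a `belief_state`.
#' @param path integer node-id vector starting at node 0 (as returned by
#'   [enumerate_paths()]).
#' @param env the `mdp_env` the belief belongs to.
#' @return expected path return in the task currency.
#' @export
expected_path_value <- function(belief, path, env) {
  nodes <- path[path != 0L]
  v <- unclass(belief)[nodes + 1L]
  miss <- is.na(v)
  v[miss] <- env$depth_means[env$depth[nodes + 1L][miss]]
  sum(v)
}

# Expected value of every path at once (row order = enumerate_paths order).
all_path_values <- function(belief, env) {
  b <- unclass(belief)
  ob <- ifelse(is.na(b), 0, b)
  base <- as.vector(env$path_inc %*% ob)
  if (any(env$depth_means != 0)) {
    miss <- ifelse(is.na(b), 1, 0)
    mu <- numeric(env$n_nodes)
    mu[-1L] <- env$depth_means[env$depth[-1L]]
    base <- base + as.vector(env$path_inc %*% (miss * mu))
  }
  base
}

#' Score of one completed trial
#'
#' @param path chosen path (integer node ids, starting at 0).
#' @param truth a `ground_truth` vector.
#' @param n_clicks number of clicks made before moving.
#' @param env the `mdp_env`.
#' @return sum of the rewards along the path minus the click fees.
#' @export
trial_score <- function(path, truth, n_clicks, env) {
  sum(truth[path[path != 0L] + 1L]) - env$click_cost * n_clicks
}
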