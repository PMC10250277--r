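# Structure of the strategy space: pairwise strategy distances, Ward
# clustering into strategy types, the relative influence of the five
# decision systems on each strategy, time-course summaries, and strategy
# performance scores.

#' Monte-Carlo strategy distance matrix
#'
#' Symmetrised Kullback-Leibler divergence between the click-sequence
#' distributions of every pair of strategies, estimated by Monte-Carlo
#' integration: trials are sampled from each strategy's fitted softmax
#' observation model and scored under both models. Negative finite-sample
#' estimates are clamped at zero (their count is recorded).
#'
#' @param obs_model an `obs_model`.
#' @param env the `mdp_env`.
#' @param n_mc Monte-Carlo sample size per strategy.
#' @param seed integer seed.
#' @param tau temperature of the sampling/scoring model.
#' @return a `strategy_distances` object: symmetric matrix `D` (zero
#'   diagonal), standard-error matrix `se`, `n_mc`, `seed`, and
#'   `n_clamped`.
#' @export
strategy_distance_matrix <- function(obs_model, env, n_mc = 1000, seed = 1,
                                     tau = 1) {
  stopifnot(n_mc >= 100)
  S <- ncol(obs_model$weights)
  KL <- matrix(0, S, S)      # KL[i, j] = KL[p_i || p_j]
  KLvar <- matrix(0, S, S)
  for (i in seq_len(S)) {
    trials <- lapply(seq_len(n_mc), function(k)
      sample_trial_from_model(obs_model, i, env, tau = tau,
                              seed = derive_seed(seed, i * 100000L + k)))
    L <- loglik_matrix(participant_cache(trials, obs_model, env), tau)
    diffs <- L[, i] - L       # n_mc x S, column j: log p_i - log p_j
    KL[i, ] <- colMeans(diffs)
    KLvar[i, ] <- apply(diffs, 2, stats::var) / n_mc
  }
  D <- KL + t(KL)
  se <- sqrt(KLvar + t(KLvar))
  n_clamped <- sum(D[upper.tri(D)] < 0)
  D[D < 0] <- 0
  diag(D) <- 0
  dimnames(D) <- dimnames(se) <-
    list(colnames(obs_model$weights), colnames(obs_model$weights))
  structure(list(D = D, se = se, n_mc = n_mc, seed = seed,
                 n_clamped = n_clamped),
            class = "strategy_distances")
}

#' Distance between two strategies
#'
#' @param obs_model an `obs_model`.
#' @param s1,s2 strategy ids or names.
#' @param env the `mdp_env`.
#' @param n_mc Monte-Carlo sample size per strategy.
#' @param seed integer seed.
#' @param tau temperature.
#' @return the symmetrised-KL estimate (exactly 0 when `s1 == s2`, exactly
#'   symmetric in its arguments).
#' @export
strategy_distance <- function(obs_model, s1, s2, env, n_mc = 1000, seed = 1,
                              tau = 1) {
  ids <- match(c(s1, s2), colnames(obs_model$weights))
  if (anyNA(ids)) ids <- c(s1, s2)
  i <- min(ids); j <- max(ids)     # symmetric by construction
  if (i == j) return(0)
  kl_dir <- function(from, to) {
    trials <- lapply(seq_len(n_mc), function(k)
      sample_trial_from_model(obs_model, from, env, tau = tau,
                              seed = derive_seed(seed, from * 100000L + k)))
    L <- loglik_matrix(participant_cache(trials, obs_model, env), tau)
    mean(L[, from] - L[, to])
  }
  max(0, kl_dir(i, j) + kl_dir(j, i))
}

#' Ward clustering of strategies into types
#'
#' @param distances a `strategy_distances` object or a symmetric matrix.
#' @param n_clusters number of clusters to cut the dendrogram into.
#' @return list with `assignment` (named integer vector strategy -> cluster),
#'   `linkage` (the `hclust` object), `n_clusters`.
#' @export
cluster_strategies <- function(distances, n_clusters) {
  D <- if (inherits(distances, "strategy_distances")) distances$D else distances
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  stopifnot(n_clusters >= 1, n_clusters <= nrow(D))
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  list(assignment = stats::cutree(hc, k = n_clusters), linkage = hc,
       n_clusters = n_clusters)
}

#' Relative influence of the five decision systems on a strategy
#'
#' For each decision system, the signed feature weights belonging to it are
#' summed (a feature's manifest sign says whether it reflects an increase
#' or a decrease of that system); the relative influence is the absolute
#' total weight, normalised across the five systems.
#'
#' @param w a feature weight vector (manifest order), or an `obs_model`
#'   column.
#' @param manifest feature manifest with `category` and `sign`.
#' @return named numeric vector over the five categories, summing to 1.
#'   All-zero weights yield a uniform profile with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
relative_influence <- function(w, manifest = default_feature_manifest()) {
  w_ds <- vapply(FEATURE_CATEGORIES, function(cat) {
    k <- manifest$category == cat
    sum(manifest$sign[k] * w[k])
  }, numeric(1))
  tot <- sum(abs(w_ds))
  if (tot == 0) {
    warning("all-zero weights: relative influence undefined, returning uniform")
    out <- rep(1 / length(w_ds), length(w_ds))
    names(out) <- FEATURE_CATEGORIES
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  abs(w_ds) / tot
}

#' Influence profiles of every strategy in an observation model
#'
#' @param obs_model an `obs_model`.
#' @return matrix (strategies x 5 categories) of relative influences; rows
#'   sum to 1.
#' @export
influence_profiles <- function(obs_model) {
  t(apply(obs_model$weights, 2, relative_influence,
          manifest = obs_model$feature_manifest))
}

#' Trial-by-trial summary across participants
#'
#' @param results list of `inference_result`s with a common trial count.
#' @param level `"strategy"` or `"type"` for relative frequencies per
#'   trial, or `"influence"` for the mean relative influence of each
#'   decision system per trial.
#' @param obs_model an `obs_model` (required for `level = "influence"`).
#' @return data.frame with a `trial` column; frequency columns sum to 1
#'   within each trial.
#' @export
time_course <- function(results, level = c("strategy", "type", "influence"),
                        obs_model = NULL) {
  level <- match.arg(level)
  if (!length(results)) stop("no inference results supplied", call. = FALSE)
  T_ <- unique(vapply(results, function(r) length(r$sequence), integer(1)))
  if (length(T_) != 1L) stop("participants differ in trial count", call. = FALSE)
  if (level == "influence") {
    if (is.null(obs_model)) stop("influence level needs the obs_model", call. = FALSE)
    RI <- influence_profiles(obs_model)
    M <- matrix(0, T_, ncol(RI), dimnames = list(NULL, colnames(RI)))
    for (r in results) M <- M + RI[r$sequence, , drop = FALSE]
    M <- M / length(results)
    return(data.frame(trial = seq_len(T_), M, check.names = FALSE))
  }
  lab <- lapply(results, function(r)
    if (level == "strategy") r$strategy_names else r$type_labels)
  levs <- sort(unique(unlist(lab)))
  M <- matrix(0, T_, length(levs), dimnames = list(NULL, levs))
  for (l in lab) for (t in seq_len(T_)) M[t, l[t]] <- M[t, l[t]] + 1
  M <- M / length(results)
  data.frame(trial = seq_len(T_), M, check.names = FALSE)
}

#' Mean simulated performance of a strategy
#'
#' @param strategy a `planning_strategy`.
#' @param env the `mdp_env`.
#' @param n_sims number of simulated trials.
#' @param seed integer seed.
#' @return mean trial score (path return minus click fees).
#' @export
strategy_performance <- function(strategy, env, n_sims = 1000, seed = 1) {
  stopifnot(n_sims >= 1)
  mean(vapply(seq_len(n_sims), function(i)
    simulate_trial(strategy, env, seed = derive_seed(seed, i))$score,
    numeric(1)))
}

#' Min-max normalised relative scores
#'
#' @param scores named numeric vector of mean strategy scores.
#' @return scores rescaled so the best strategy is 1 and the worst 0; if
#'   all scores are equal, every score is defined as 1 with a warning.
#' @export
relative_scores <- function(scores) {
  stopifnot(length(scores) >= 2)
  rng <- range(scores)
  if (diff(rng) == 0) {
    warning("all strategies scored identically; defining all relative scores as 1")
    return(stats::setNames(rep(1, length(scores)), names(scores)))
  }
  (scores - rng[1L]) / diff(rng)
}

#' Plot a time course
#'
#' Line plot of the per-trial frequencies or mean influences produced by
#' [time_course()]. Requires ggplot2.
#'
#' @param tc a data.frame from [time_course()].
#' @param top_n plot only the `top_n` most frequent columns.
#' @return a ggplot object.
#' @export
plot_time_course <- function(tc, top_n = Inf) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_time_course requires the ggplot2 package", call. = FALSE)
  }
  cols <- setdiff(names(tc), "trial")
  if (is.finite(top_n) && length(cols) > top_n) {
    cols <- cols[order(colMeans(tc[cols]), decreasing = TRUE)[seq_len(top_n)]]
  }
  long <- do.call(rbind, lapply(cols, function(cn)
    data.frame(trial = tc$trial, series = cn, value = tc[[cn]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "relative frequency / influence") +
    ggplot2::theme_minimal()
}
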