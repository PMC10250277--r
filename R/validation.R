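# Simulation-based validation with known ground truth: synthetic
# participants whose strategy sequences come from stated generative models
# and whose clicks come from the strategies' fitted observation models.
#
# Two experiments mirror the package's validation protocol: strategy /
# strategy-type recovery (generate -> infer -> score against the true
# sequences) and decision-system trend recovery (construct sequences with
# an increasing, decreasing, or constant influence of one decision system
# and test whether the inferred influence curve reproduces the trend).

#' Sample ground-truth strategy sequences
#'
#' @param kind `"random_per_trial"` (independent uniform draws),
#'   `"abrupt_markov"` (repeat with probability `p_stay`, else jump
#'   uniformly), or `"gradual_drift"` (transition probability decays as a
#'   Gaussian kernel of the strategy distance).
#' @param n number of sequences (participants).
#' @param n_trials sequence length.
#' @param n_strategies number of strategies.
#' @param p_stay self-transition probability for `"abrupt_markov"`.
#' @param distances strategy distance matrix, required for
#'   `"gradual_drift"`.
#' @param bandwidth kernel bandwidth for `"gradual_drift"`; defaults to
#'   half the median off-diagonal distance.
#' @param seed integer seed.
#' @return integer matrix (`n` x `n_trials`) of strategy ids.
#' @export
generate_sequences <- function(kind = c("random_per_trial", "abrupt_markov",
                                        "gradual_drift"),
                               n, n_trials, n_strategies, p_stay = 0.8,
                               distances = NULL, bandwidth = NULL, seed = 1) {
  kind <- match.arg(kind)
  S <- n_strategies
  if (kind == "gradual_drift") {
    if (is.null(distances)) stop("gradual_drift needs a distance matrix", call. = FALSE)
    D <- if (inherits(distances, "strategy_distances")) distances$D else distances
    if (is.null(bandwidth)) bandwidth <- stats::median(D[upper.tri(D)]) / 2
    K <- exp(-(D / bandwidth)^2 / 2)
    K <- K / rowSums(K)
  }
  with_seed(seed, {
    out <- matrix(0L, n, n_trials)
    for (i in seq_len(n)) {
      s <- sample.int(S, 1L)
      out[i, 1L] <- s
      if (n_trials > 1L) for (t in 2:n_trials) {
        s <- switch(kind,
          random_per_trial = sample.int(S, 1L),
          abrupt_markov = if (stats::runif(1) < p_stay) s else
            sample(setdiff(seq_len(S), s), 1L),
          gradual_drift = sample.int(S, 1L, prob = K[s, ]))
        out[i, t] <- s
      }
    }
    out
  })
}

#' Generate simulated participants with known strategy sequences
#'
#' For each participant a strategy sequence is drawn from the generative
#' sequence model; each trial's clicks are then sampled from the fitted
#' softmax observation model of that trial's strategy at temperature
#' `tau_gen`.
#'
#' @param kind sequence model, see [generate_sequences()].
#' @param obs_model an `obs_model`.
#' @param env the `mdp_env`.
#' @param n number of participants.
#' @param n_trials trials per participant.
#' @param tau_gen generation temperature.
#' @param p_stay,distances,bandwidth passed to [generate_sequences()].
#' @param seed integer seed.
#' @param label participant-id prefix.
#' @return list with `dataset` (a `ps_dataset`) and `sequences` (the true
#'   strategy-id matrix, participants x trials).
#' @export
generate_participants <- function(kind, obs_model, env, n, n_trials = 31,
                                  tau_gen = 1, p_stay = 0.8, distances = NULL,
                                  bandwidth = NULL, seed = 1, label = kind) {
  seqs <- generate_sequences(kind, n, n_trials, ncol(obs_model$weights),
                             p_stay = p_stay, distances = distances,
                             bandwidth = bandwidth, seed = derive_seed(seed, 1L))
  participants <- lapply(seq_len(n), function(i) {
    trials <- lapply(seq_len(n_trials), function(t)
      sample_trial_from_model(obs_model, seqs[i, t], env, tau = tau_gen,
                              seed = derive_seed(seed, i * 10000L + t), t = t))
    list(id = sprintf("%s_%03d", label, i), condition = kind, block = "all",
         trials = trials)
  })
  list(dataset = ps_dataset(participants, env$name,
                            name = paste0("synthetic_", kind),
                            provenance = list(source = "synthetic",
                                              generator = kind, seed = seed,
                                              tau_gen = tau_gen)),
       sequences = seqs)
}

#' Strategy-recovery experiment
#'
#' Generates simulated participants from one or more sequence models,
#' runs the full inference pipeline (hyperparameter fitting + Viterbi
#' decoding), and scores the MAP sequences against the true ones.
#'
#' @param obs_model an `obs_model`.
#' @param env the `mdp_env`.
#' @param generators character vector of sequence-model kinds.
#' @param n_per_generator simulated participants per generator.
#' @param n_trials trials per participant.
#' @param tau_gen generation temperature.
#' @param p_stay self-transition probability for the abrupt generator.
#' @param distances distance matrix for the drift generator (computed on
#'   the fly when needed).
#' @param seed integer seed.
#' @param tau_budget temperature-search budget per participant.
#' @return a `recovery_report`: pooled `strategy_accuracy` and
#'   `type_accuracy` (fractions in [0, 1]), `by_generator` breakdown,
#'   `confusion` (true x inferred strategy counts), `n_trials_scored`.
#' @export
recovery_experiment <- function(obs_model, env,
                                generators = c("random_per_trial",
                                               "abrupt_markov",
                                               "gradual_drift"),
                                n_per_generator = 50, n_trials = 31,
                                tau_gen = 1, p_stay = 0.8, distances = NULL,
                                seed = 1, tau_budget = 50) {
  S <- ncol(obs_model$weights)
  if ("gradual_drift" %in% generators && is.null(distances)) {
    distances <- strategy_distance_matrix(obs_model, env, n_mc = 300,
                                          seed = derive_seed(seed, 77L))
  }
  types <- obs_model$strategies$type_label
  confusion <- matrix(0L, S, S,
                      dimnames = list(true = colnames(obs_model$weights),
                                      inferred = colnames(obs_model$weights)))
  per_gen <- list()
  for (g in generators) {
    gen <- generate_participants(g, obs_model, env, n = n_per_generator,
                                 n_trials = n_trials, tau_gen = tau_gen,
                                 p_stay = p_stay, distances = distances,
                                 seed = derive_seed(seed, match(g, generators)))
    hits <- type_hits <- 0L; total <- 0L
    for (i in seq_along(gen$dataset$participants)) {
      res <- infer_strategies(gen$dataset$participants[[i]]$trials, obs_model,
                              env, tau_budget = tau_budget)
      truth <- gen$sequences[i, ]
      hits <- hits + sum(res$sequence == truth)
      type_hits <- type_hits + sum(types[res$sequence] == types[truth])
      total <- total + length(truth)
      for (t in seq_along(truth)) {
        confusion[truth[t], res$sequence[t]] <-
          confusion[truth[t], res$sequence[t]] + 1L
      }
    }
    per_gen[[g]] <- c(strategy_accuracy = hits / total,
                      type_accuracy = type_hits / total, n = total)
  }
  bg <- do.call(rbind, per_gen)
  n_tot <- sum(bg[, "n"])
  rep_ <- list(
    strategy_accuracy = sum(bg[, "strategy_accuracy"] * bg[, "n"]) / n_tot,
    type_accuracy = sum(bg[, "type_accuracy"] * bg[, "n"]) / n_tot,
    by_generator = bg, confusion = confusion, n_trials_scored = n_tot,
    chance_rate = 1 / S, seed = seed,
    settings = list(n_per_generator = n_per_generator, n_trials = n_trials,
                    tau_gen = tau_gen, p_stay = p_stay))
  class(rep_) <- "recovery_report"
  rep_
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Strategy recovery over %d simulated trials\n", x$n_trials_scored))
  cat(sprintf("  strategy accuracy: %.1f%%  (chance %.1f%%)\n",
              100 * x$strategy_accuracy, 100 * x$chance_rate))
  cat(sprintf("  type accuracy:     %.1f%%\n", 100 * x$type_accuracy))
  print(round(x$by_generator, 3))
  invisible(x)
}

#' Decision-system trend-recovery experiment
#'
#' Constructs ground-truth strategy sequences whose relative influence of
#' one decision system is increasing, decreasing, or constant over trials;
#' generates clicks; infers the sequences; and compares the inferred
#' influence curve against the construction. For the monotone trends each
#' strategy appears exactly once, ordered by the system's relative
#' influence; for the constant trend strategies are drawn within one of
#' three percentile groups (33rd/67th/100th) of that influence.
#'
#' @param obs_model an `obs_model`.
#' @param env the `mdp_env`.
#' @param factor one of the five decision-system categories.
#' @param trend `"increasing"`, `"decreasing"`, or `"constant"`.
#' @param n_sequences number of simulated sequences.
#' @param tau_gen generation temperature.
#' @param seed integer seed.
#' @param tau_budget temperature-search budget for inference.
#' @return a `trend_report`: per-trial mean `true_curve` and
#'   `inferred_curve`, per-sequence Spearman correlations `rho`,
#'   `mean_rho`, and the design (`factor`, `trend`).
#' @export
trend_experiment <- function(obs_model, env,
                             factor = FEATURE_CATEGORIES,
                             trend = c("increasing", "decreasing", "constant"),
                             n_sequences = 50, tau_gen = 1, seed = 1,
                             tau_budget = 50) {
  factor <- match.arg(factor)
  trend <- match.arg(trend)
  RI <- influence_profiles(obs_model)
  vals <- RI[, factor]
  S <- length(vals)
  T_ <- S
  seqs <- with_seed(derive_seed(seed, 5L), {
    if (trend %in% c("increasing", "decreasing")) {
      base <- order(vals)
      if (trend == "decreasing") base <- rev(base)
      matrix(rep(base, each = n_sequences), n_sequences, T_)
    } else {
      qs <- stats::quantile(vals, c(1 / 3, 2 / 3))
      grp <- findInterval(vals, qs + 1e-12) + 1L
      t(vapply(seq_len(n_sequences), function(i) {
        g <- sample.int(3L, 1L)
        pool <- which(grp == g)
        if (!length(pool)) pool <- seq_len(S)
        sample(pool, T_, replace = TRUE)
      }, integer(T_)))
    }
  })
  rho <- numeric(n_sequences)
  inferred_curve <- true_curve <- matrix(0, n_sequences, T_)
  for (i in seq_len(n_sequences)) {
    trials <- lapply(seq_len(T_), function(t)
      sample_trial_from_model(obs_model, seqs[i, t], env, tau = tau_gen,
                              seed = derive_seed(seed, i * 10000L + t), t = t))
    res <- infer_strategies(trials, obs_model, env, tau_budget = tau_budget)
    true_curve[i, ] <- vals[seqs[i, ]]
    inferred_curve[i, ] <- vals[res$sequence]
    r <- suppressWarnings(stats::cor(seq_len(T_), inferred_curve[i, ],
                                     method = "spearman"))
    rho[i] <- if (is.na(r)) 0 else r
  }
  rep_ <- list(factor = factor, trend = trend,
               true_curve = colMeans(true_curve),
               inferred_curve = colMeans(inferred_curve),
               rho = rho, mean_rho = mean(rho), n_sequences = n_sequences)
  class(rep_) <- "trend_report"
  rep_
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("Trend recovery for '%s' (%s): mean Spearman rho = %.2f over %d sequences\n",
              x$factor, x$trend, x$mean_rho, x$n_sequences))
  invisible(x)
}
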