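# Readers and writers for process-tracing datasets and inference results.
#
# Canonical dataset schema (JSON):
#   {dataset, env, provenance,
#    participants: [{id, condition, block,
#                    trials: [{t, ground_truth: {node: reward},
#                              clicks: [{node, value}], path: [nodes]}]}]}
# A CSV long-format twin (one row per click) is provided for
# interoperability with spreadsheet-based workflows.

#' Assemble a process-tracing dataset object
#'
#' @param participants list of participant records: each a list with `id`,
#'   `condition`, `block`, and `trials` (trial records as produced by
#'   [simulate_trial()]).
#' @param env_name environment preset name shared by all trials.
#' @param name dataset label.
#' @param provenance free-form metadata (seeds, generator, or "human").
#' @return a `ps_dataset`.
#' @export
ps_dataset <- function(participants, env_name, name = "dataset",
                       provenance = list(source = "unspecified")) {
  if (!length(participants)) stop("dataset must contain participants", call. = FALSE)
  d <- list(dataset = name, env = env_name, provenance = provenance,
            participants = participants)
  class(d) <- "ps_dataset"
  d
}

#' @export
print.ps_dataset <- function(x, ...) {
  nt <- vapply(x$participants, function(p) length(p$trials), integer(1))
  cat("Process-tracing dataset '", x$dataset, "' (environment: ", x$env, ")\n",
      sep = "")
  cat(" ", length(x$participants), "participants,",
      paste(range(nt), collapse = "-"), "trials each\n")
  invisible(x)
}

#' Write a dataset to disk
#'
#' @param dataset a `ps_dataset`.
#' @param path output file path.
#' @param dialect `"json"` (canonical schema) or `"csv"` (one row per
#'   click; zero-click trials get one row with an empty node).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, dialect = c("json", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    doc <- list(
      dataset = dataset$dataset, env = dataset$env,
      provenance = dataset$provenance,
      participants = lapply(dataset$participants, function(p) list(
        id = p$id, condition = p$condition %||% "none",
        block = p$block %||% "all",
        trials = lapply(p$trials, function(tr) {
          gt <- unclass(tr$ground_truth)
          nodes <- which(!is.na(gt)) - 1L
          list(t = tr$t,
               ground_truth = stats::setNames(as.list(gt[nodes + 1L]),
                                              as.character(nodes)),
               clicks = if (length(tr$clicks)) {
                 lapply(seq_along(tr$clicks), function(i)
                   list(node = tr$clicks[i], value = tr$values[i]))
               } else list(),
               path = tr$path)
        })
      ))
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  } else {
    rows <- list()
    for (p in dataset$participants) {
      for (tr in p$trials) {
        gt <- unclass(tr$ground_truth)
        nodes <- which(!is.na(gt)) - 1L
        gt_str <- paste(sprintf("%d=%.10g", nodes, gt[nodes + 1L]), collapse = ";")
        path_str <- paste(tr$path, collapse = ";")
        k <- max(length(tr$clicks), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = dataset$dataset, env = dataset$env,
          participant = p$id, condition = p$condition %||% "none",
          block = p$block %||% "all", trial = tr$t,
          click_index = if (length(tr$clicks)) seq_along(tr$clicks) else 0L,
          node = if (length(tr$clicks)) tr$clicks else NA_integer_,
          value = if (length(tr$clicks)) tr$values else NA_real_,
          path = path_str, ground_truth = gt_str,
          stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset from disk
#'
#' Validates the parsed dataset: unique clicks per trial, revealed values
#' consistent with the stored ground truth, valid chosen path.
#'
#' @param path file path.
#' @param dialect `"json"` or `"csv"`; guessed from the extension when
#'   missing.
#' @return a `ps_dataset`.
#' @export
read_dataset <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (dialect == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    env <- build_environment(doc$env)
    participants <- lapply(doc$participants, function(p) {
      trials <- lapply(p$trials, function(tr) {
        gt <- rep(NA_real_, env$n_nodes)
        for (nm in names(tr$ground_truth)) {
          gt[as.integer(nm) + 1L] <- as.numeric(tr$ground_truth[[nm]])
        }
        class(gt) <- "ground_truth"
        clicks <- vapply(tr$clicks, function(cl) as.integer(cl$node), integer(1))
        values <- vapply(tr$clicks, function(cl) as.numeric(cl$value), numeric(1))
        list(t = as.integer(tr$t), clicks = clicks, values = values,
             path = as.integer(unlist(tr$path)), ground_truth = gt,
             env_name = doc$env)
      })
      list(id = as.character(p$id), condition = p$condition %||% "none",
           block = p$block %||% "all", trials = trials)
    })
    out <- ps_dataset(participants, doc$env, name = doc$dataset,
                      provenance = doc$provenance %||% list())
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    env <- build_environment(df$env[1L])
    participants <- lapply(split(df, df$participant), function(pd) {
      pd <- pd[order(pd$trial, pd$click_index), ]
      trials <- lapply(split(pd, pd$trial), function(td) {
        gt <- rep(NA_real_, env$n_nodes)
        for (tok in strsplit(td$ground_truth[1L], ";", fixed = TRUE)[[1L]]) {
          kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
          gt[as.integer(kv[1L]) + 1L] <- as.numeric(kv[2L])
        }
        class(gt) <- "ground_truth"
        has_clicks <- !all(is.na(td$node))
        list(t = td$trial[1L],
             clicks = if (has_clicks) as.integer(td$node) else integer(0),
             values = if (has_clicks) as.numeric(td$value) else numeric(0),
             path = as.integer(strsplit(td$path[1L], ";", fixed = TRUE)[[1L]]),
             ground_truth = gt, env_name = df$env[1L])
      })
      trials <- trials[order(vapply(trials, `[[`, integer(1), "t"))]
      names(trials) <- NULL
      list(id = as.character(pd$participant[1L]), condition = pd$condition[1L],
           block = pd$block[1L], trials = trials)
    })
    names(participants) <- NULL
    out <- ps_dataset(participants, df$env[1L], name = df$dataset[1L],
                      provenance = list(source = "csv"))
  }
  validate_dataset(out, env)
  out
}

validate_dataset <- function(dataset, env = NULL) {
  if (is.null(env)) env <- build_environment(dataset$env)
  for (p in dataset$participants) {
    for (tr in p$trials) {
      where <- paste0("participant ", p$id, ", trial ", tr$t)
      if (anyDuplicated(tr$clicks)) {
        stop("integrity error (", where, "): duplicate click on node ",
             tr$clicks[duplicated(tr$clicks)][1L], call. = FALSE)
      }
      if (length(tr$clicks) &&
          any(abs(tr$values - unclass(tr$ground_truth)[tr$clicks + 1L]) > 1e-8)) {
        stop("integrity error (", where,
             "): revealed value differs from ground truth", call. = FALSE)
      }
      if (tr$path[1L] != 0L ||
          !any(vapply(env$paths, identical, logical(1), as.integer(tr$path)))) {
        stop("schema violation (", where, "): invalid chosen path", call. = FALSE)
      }
    }
  }
  invisible(dataset)
}

#' Write inference results as tables
#'
#' Writes the per-trial strategy-sequence table and the per-participant
#' hyperparameter table, each stamped with the feature- and
#' strategy-manifest hashes.
#'
#' @param results named list of `inference_result`s (see [infer_dataset()]).
#' @param obs_model the `obs_model` used for inference.
#' @param prefix output path prefix; writes `<prefix>_strategies.csv`,
#'   `<prefix>_hyperparameters.csv`, and `<prefix>.json`.
#' @return invisibly, the list of written paths.
#' @export
write_results <- function(results, obs_model, prefix) {
  seq_tab <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(participant = id, trial = seq_along(r$sequence),
               strategy_id = r$sequence, strategy = r$strategy_names,
               type_label = r$type_labels,
               feature_hash = obs_model$feature_hash,
               strategy_hash = obs_model$strategy_hash,
               stringsAsFactors = FALSE)
  }))
  hyp_tab <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(participant = id, p_stay = r$p_stay, tau = r$tau,
               log_prob = r$log_prob,
               feature_hash = obs_model$feature_hash,
               strategy_hash = obs_model$strategy_hash,
               stringsAsFactors = FALSE)
  }))
  paths <- c(paste0(prefix, "_strategies.csv"),
             paste0(prefix, "_hyperparameters.csv"),
             paste0(prefix, ".json"))
  utils::write.csv(seq_tab, paths[1L], row.names = FALSE)
  utils::write.csv(hyp_tab, paths[2L], row.names = FALSE)
  jsonlite::write_json(
    list(feature_hash = obs_model$feature_hash,
         strategy_hash = obs_model$strategy_hash,
         participants = lapply(results, function(r)
           list(sequence = r$sequence, strategy_names = r$strategy_names,
                type_labels = r$type_labels, p_stay = r$p_stay, tau = r$tau,
                log_prob = r$log_prob))),
    paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
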