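# Internal numeric and RNG helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise log-sum-exp of a small matrix (actions x strategies).
col_logsumexp <- function(M) {
  cm <- M[cbind(max.col(t(M), ties.method = "first"), seq_len(ncol(M)))]
  cm + log(colSums(exp(M - rep(cm, each = nrow(M)))))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministically derive a stream of sub-seeds from one master seed.
# Kept inside 32-bit signed integer range (Lehmer-style multiplicative step).
derive_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((as.numeric(seed %% m) * 48271 + as.numeric(i) * 7919 + 12345) %% m)
}

# Tiny FNV-1a style content hash used to stamp manifests on output tables,
# so weight tables and feature orderings cannot silently drift apart.
manifest_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("h%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
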