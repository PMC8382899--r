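# Internal numeric and RNG helpers.

# Row-wise log-sum-exp of (M + rep(logw, each = nrow)) where logw is a
# per-column offset. M: numeric matrix.
row_logsumexp <- function(M, logw = NULL) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx[!is.finite(mx)] <- 0
  if (is.null(logw)) {
    mx + log(rowSums(exp(M - mx)))
  } else {
    mx + log(as.vector(exp(M - mx) %*% exp(logw)))
  }
}

# Run `code` with a temporary, seed-derived L'Ecuyer-CMRG RNG state, restoring
# the caller's RNG afterwards. Returns the value of `code`, which may call
# next_stream() on the returned stream handle.
with_rng <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  old_kind <- RNGkind()
  on.exit(RNGkind(old_kind[1], old_kind[2], old_kind[3]), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "L'Ecuyer-CMRG")
  force(code)
}

# Loci are simulated in fixed-size blocks, each on its own L'Ecuyer-CMRG
# substream, so that enlarging a dataset (more loci) never reshuffles the loci
# already generated: the generator always produces whole blocks and truncates.
block_size <- function() 8192L

# Iterate f(block_len, block_index) over ceiling(total / B) blocks, each under
# its own substream of `seed`; f must consume RNG only through R's generator.
# Results are rbind-ed (matrices) or c-ed (vectors), truncated to `total`.
stream_blocks <- function(seed, total, f) {
  B <- block_size()
  nb <- as.integer(ceiling(total / B))
  pieces <- with_rng(seed, {
    s <- get(".Random.seed", globalenv())
    out <- vector("list", nb)
    for (k in seq_len(nb)) {
      assign(".Random.seed", s, globalenv())
      out[[k]] <- f(B, k)
      s <- parallel::nextRNGStream(s)
    }
    out
  })
  res <- if (is.matrix(pieces[[1]])) do.call(rbind, pieces)
         else if (is.data.frame(pieces[[1]])) do.call(rbind, pieces)
         else do.call(c, pieces)
  if (is.null(dim(res))) res[seq_len(total)] else res[seq_len(total), , drop = FALSE]
}

# Vectorized multinomial sampling: one draw of size n per row of the
# probability matrix P (rows sum to 1), via a cascade of binomials. The RNG
# consumption pattern (4 rbinom calls) is fixed regardless of the values in P.
rmultinom_rows <- function(n, P) {
  B <- nrow(P)
  X <- matrix(0L, B, 5L)
  rem <- rep.int(as.integer(n), B)
  tail_p <- 1
  for (j in 1:4) {
    q <- P[, j] / tail_p
    q[!is.finite(q)] <- 0
    q <- pmin(pmax(q, 0), 1)
    xj <- rbinom(B, rem, q)
    X[, j] <- xj
    rem <- rem - xj
    tail_p <- tail_p - P[, j]
  }
  X[, 5L] <- rem
  colnames(X) <- pattern_names()
  X
}
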