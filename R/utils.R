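# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed from a master seed and an index.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(k) * 7919) %% 2147483562L + 1)
}

# Numerical rank of a real matrix by QR with a relative tolerance.
matrix_rank <- function(x, tol = 1e-8) {
  if (length(x) == 0L || nrow(x) == 0L || ncol(x) == 0L) return(0L)
  q <- qr(x, tol = tol)
  q$rank
}

# Floor p-values away from zero so log/quantile transforms stay finite.
floor_pvalues <- function(p, context = "p-value") {
  bad <- !is.na(p) & p <= 0
  if (any(bad)) {
    warning(sprintf("%d %s(s) at or below zero floored to machine minimum",
                    sum(bad), context), call. = FALSE)
    p[bad] <- .Machine$double.xmin
  }
  p
}

# Deterministic TSV writer used for all pipeline artifacts: fixed quoting,
# fixed NA encoding, no row names, so reruns are byte-identical.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
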