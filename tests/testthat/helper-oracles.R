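# Independent oracles used by the tests. Deliberately naive
# implementations, kept separate from the package's code paths.

# Generic (structural) rank of a zero-pattern by exhaustive recursion:
# equals the maximum number of support entries no two of which share a
# row or column (maximum bipartite matching).
brute_force_generic_rank <- function(pattern) {
  recurse <- function(rows_free, cols) {
    if (length(cols) == 0L) return(0L)
    c1 <- cols[1L]
    best <- recurse(rows_free, cols[-1L])  # skip this column
    for (r in rows_free) {
      if (pattern[r, c1]) {
        best <- max(best, 1L + recurse(setdiff(rows_free, r), cols[-1L]))
      }
    }
    best
  }
  recurse(seq_len(nrow(pattern)), seq_len(ncol(pattern)))
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# draws of size n from a universe of size N containing K successes.
enumerate_hyper_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}

# Moderated t by direct arithmetic of its definition.
hand_moderated_t <- function(treated, control, d0, s02) {
  nt <- length(treated); nc <- length(control)
  lfc <- mean(treated) - mean(control)
  s2 <- (sum((treated - mean(treated))^2) + sum((control - mean(control))^2)) /
    (nt + nc - 2)
  s2_post <- (d0 * s02 + (nt + nc - 2) * s2) / (d0 + nt + nc - 2)
  t <- lfc / sqrt(s2_post * (1 / nt + 1 / nc))
  p <- 2 * pt(-abs(t), nt + nc - 2 + d0)
  list(lfc = lfc, t = t, p = p)
}

# Random support pattern with every row and column non-empty.
random_pattern <- function(n_genes, n_tfs, density = 0.4) {
  repeat {
    z <- matrix(runif(n_genes * n_tfs) < density, n_genes, n_tfs)
    if (all(rowSums(z) > 0) && all(colSums(z) > 0)) return(z)
  }
}

pattern_to_prior <- function(z) {
  rownames(z) <- sprintf("g%02d", seq_len(nrow(z)))
  colnames(z) <- sprintf("tf%02d", seq_len(ncol(z)))
  idx <- which(z, arr.ind = TRUE)
  connectivity_prior(data.frame(gene = rownames(z)[idx[, 1]],
                                tf = colnames(z)[idx[, 2]]))
}
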