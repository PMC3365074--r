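#' Connectivity prior: the zero-pattern of the strength matrix
#'
#' The set of allowed (gene, TF) regulatory pairs. Entries of the strength
#' matrix outside this support are constrained to exactly zero during the
#' network-component decomposition.
#'
#' @param support Data frame with columns `gene`, `tf` and optionally
#'   `sign` (`"+"`, `"-"` or `"unknown"`) and `provenance` (`"prior"` or
#'   `"clustering"`). Duplicated (gene, tf) pairs are collapsed, keeping
#'   the first occurrence.
#' @return An object of class `ConnectivityPrior` with elements `tfs`,
#'   `genes` (ordered id vectors) and `support` (the deduplicated data
#'   frame).
#' @export
connectivity_prior <- function(support) {
  stopifnot(is.data.frame(support), all(c("gene", "tf") %in% names(support)))
  if (nrow(support) == 0L) stop("empty support")
  if (is.null(support$sign)) support$sign <- "unknown"
  if (is.null(support$provenance)) support$provenance <- "prior"
  dup <- duplicated(support[, c("gene", "tf")])
  support <- support[!dup, , drop = FALSE]
  rownames(support) <- NULL
  structure(list(tfs = sort(unique(support$tf)),
                 genes = sort(unique(support$gene)),
                 support = support),
            class = "ConnectivityPrior")
}

#' @export
print.ConnectivityPrior <- function(x, ...) {
  cat(sprintf("ConnectivityPrior: %d TF-target pairs over %d TFs and %d genes\n",
              nrow(x$support), length(x$tfs), length(x$genes)))
  invisible(x)
}

#' Logical support pattern of a prior
#'
#' @param prior A [connectivity_prior()].
#' @param genes,tfs Optional orderings/subsets of gene and TF ids.
#' @return Logical genes x TFs matrix, `TRUE` on the support.
#' @export
support_matrix <- function(prior, genes = prior$genes, tfs = prior$tfs) {
  z <- matrix(FALSE, length(genes), length(tfs),
              dimnames = list(genes, tfs))
  keep <- prior$support$gene %in% genes & prior$support$tf %in% tfs
  s <- prior$support[keep, , drop = FALSE]
  z[cbind(match(s$gene, genes), match(s$tf, tfs))] <- TRUE
  z
}

#' Load a TF-target prior from an edge-list TSV
#'
#' Expects at least two columns (TF, target), optionally a third (sign)
#' and fourth (provenance). A header line whose first two fields are
#' `tf`/`TF` and `target` is skipped. Self-regulation (TF = target) and
#' TF-TF edges are retained; duplicate pairs are collapsed.
#'
#' @param path Path to the edge-list file.
#' @return A [connectivity_prior()].
#' @export
load_prior <- function(path) {
  if (!file.exists(path)) stop("prior file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty prior file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- tolower(trimws(fields[[1]]))
  if (length(f1) >= 2L && f1[1] %in% c("tf", "regulator") && f1[2] %in% c("target", "gene")) {
    start <- 2L
  }
  if (start > length(lines)) stop("prior file has a header but no rows: ", path)
  rows <- lapply(seq(start, length(lines)), function(i) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1]) || !nzchar(f[2])) {
      stop(sprintf("malformed prior row at line %d of %s", i, path))
    }
    data.frame(tf = f[1], gene = f[2],
               sign = if (length(f) >= 3L && nzchar(f[3])) f[3] else "unknown",
               provenance = if (length(f) >= 4L && nzchar(f[4])) f[4] else "prior")
  })
  support <- do.call(rbind, rows)
  connectivity_prior(support[, c("gene", "tf", "sign", "provenance")])
}

#' Write a connectivity prior as an edge-list TSV
#' @param prior A [connectivity_prior()].
#' @param path Output path.
#' @export
write_prior_tsv <- function(prior, path) {
  s <- prior$support
  df <- data.frame(tf = s$tf, target = s$gene, sign = s$sign,
                   provenance = s$provenance)
  df <- df[order(df$tf, df$target), , drop = FALSE]
  write_tsv(df, path)
}

#' Augment a prior by co-expression clustering
#'
#' Hierarchically clusters TFs together with candidate target genes on the
#' correlation distance 1 - |r| and proposes additional TF-target pairs:
#' for each TF, the candidate targets are the genes that share its cluster
#' when the tree is cut at height 1 - `r_threshold` (i.e. the smallest
#' subtree around the TF whose merges all happen at |r| above the
#' threshold), and a pair is added only if its pairwise |Pearson r|
#' exceeds `r_threshold`. The correlation sign is recorded.
#'
#' @param dataset An [expression_dataset()].
#' @param tfs Character vector of TF ids (must be rows of the dataset).
#' @param degs Character vector of candidate target gene ids.
#' @param r_threshold Correlation magnitude threshold (default 0.8).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return Data frame of proposed pairs with columns `gene`, `tf`, `sign`,
#'   `provenance = "clustering"` and `r`.
#' @export
augment_by_clustering <- function(dataset, tfs, degs, r_threshold = 0.8,
                                  linkage = "average") {
  stopifnot(r_threshold > 0, r_threshold < 1)
  ids <- unique(c(tfs, degs))
  missing <- setdiff(ids, rownames(dataset$values))
  if (length(missing) > 0L) {
    stop("ids absent from expression matrix: ", paste(head(missing, 5), collapse = ", "))
  }
  if (ncol(dataset$values) < 3L) stop("need >= 3 samples for correlation clustering")
  x <- dataset$values[ids, , drop = FALSE]
  const <- apply(x, 1L, sd) == 0
  if (any(const)) {
    warning(sum(const), " constant-expression gene(s) excluded from clustering",
            call. = FALSE)
    x <- x[!const, , drop = FALSE]
  }
  tfs <- intersect(tfs, rownames(x))
  degs <- intersect(degs, rownames(x))
  empty <- data.frame(gene = character(), tf = character(), sign = character(),
                      provenance = character(), r = numeric())
  if (length(tfs) == 0L || length(degs) == 0L || nrow(x) < 2L) return(empty)
  r <- cor(t(x))
  tree <- hclust(as.dist(1 - abs(r)), method = linkage)
  cl <- cutree(tree, h = 1 - r_threshold)
  out <- lapply(tfs, function(tf) {
    cand <- setdiff(intersect(degs, names(cl)[cl == cl[tf]]), tf)
    cand <- cand[abs(r[tf, cand]) > r_threshold]
    if (length(cand) == 0L) return(NULL)
    data.frame(gene = cand, tf = tf,
               sign = ifelse(r[tf, cand] >= 0, "+", "-"),
               provenance = "clustering", r = r[tf, cand])
  })
  out <- do.call(rbind, c(list(empty), out))
  rownames(out) <- NULL
  out
}

#' Merge clustering-derived pairs into a prior
#'
#' Pairs already in the prior keep their original annotation.
#'
#' @param prior A [connectivity_prior()].
#' @param additions Data frame from [augment_by_clustering()].
#' @return A [connectivity_prior()].
#' @export
augment_prior <- function(prior, additions) {
  if (is.null(additions) || nrow(additions) == 0L) return(prior)
  cols <- c("gene", "tf", "sign", "provenance")
  connectivity_prior(rbind(prior$support[, cols], additions[, cols]))
}

# Generic (structural) rank of a zero-pattern: the rank of a matrix with
# independent random entries on the support, which equals the pattern's
# maximal rank with probability one. Repeated over a few seeds to guard
# against unlucky draws.
generic_rank <- function(pattern, n_seeds = 3L, tol = 1e-8) {
  if (nrow(pattern) == 0L || ncol(pattern) == 0L) return(0L)
  if (!any(pattern)) return(0L)
  best <- 0L
  for (s in seq_len(n_seeds)) {
    a <- with_seed(1000L + s, {
      m <- matrix(0, nrow(pattern), ncol(pattern))
      m[pattern] <- runif(sum(pattern), 0.5, 1.5) * sample(c(-1, 1), sum(pattern), TRUE)
      m
    })
    best <- max(best, matrix_rank(a, tol = tol))
    if (best == min(dim(pattern))) break
  }
  best
}

#' Check NCA identifiability of a connectivity prior
#'
#' The constrained decomposition E = A P is unique (up to diagonal
#' rescaling) only if: (i) the support pattern of A has full column rank;
#' (ii) removing any TF together with all of its target genes leaves a
#' pattern that still has full column rank; and (iii) the activity matrix
#' P has full row rank, for which `n_samples >= n_TFs` is the necessary
#' condition testable without data. Criteria (i) and (ii) are evaluated as
#' generic rank of the zero-pattern via random instantiation.
#'
#' @param prior A [connectivity_prior()].
#' @param n_samples Number of conditions/columns the expression matrix
#'   will have.
#' @param tol Rank tolerance.
#' @return A list of class `identifiability_report`: `criterion_i`
#'   (logical), `criterion_ii` (named logical per TF), `criterion_iii`
#'   (logical), `overall`, and `generic_rank`.
#' @export
check_identifiability <- function(prior, n_samples, tol = 1e-8) {
  z <- support_matrix(prior)
  z <- z[rowSums(z) > 0, , drop = FALSE]
  l <- ncol(z)
  r <- generic_rank(z, tol = tol)
  crit_i <- r == l
  crit_ii <- vapply(seq_len(l), function(j) {
    keep_rows <- !z[, j]
    z2 <- z[keep_rows, -j, drop = FALSE]
    if (ncol(z2) == 0L) return(TRUE)
    generic_rank(z2, tol = tol) == ncol(z2)
  }, logical(1))
  names(crit_ii) <- colnames(z)
  crit_iii <- n_samples >= l
  structure(list(criterion_i = crit_i,
                 criterion_ii = crit_ii,
                 criterion_iii = crit_iii,
                 overall = crit_i && all(crit_ii) && crit_iii,
                 generic_rank = r,
                 n_tfs = l,
                 n_samples = n_samples),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf("identifiability: %s\n", if (x$overall) "PASS" else "FAIL"))
  cat(sprintf("  (i)   full column rank: %s (generic rank %d of %d TFs)\n",
              x$criterion_i, x$generic_rank, x$n_tfs))
  cat(sprintf("  (ii)  reduced networks: %d of %d TFs pass\n",
              sum(x$criterion_ii), length(x$criterion_ii)))
  cat(sprintf("  (iii) samples >= TFs:   %s (%d samples, %d TFs)\n",
              x$criterion_iii, x$n_samples, x$n_tfs))
  invisible(x)
}

# TFs whose instantiated columns are linearly dependent on the others,
# found by pivoted QR on one random instantiation of the pattern.
dependent_tfs <- function(z, tol = 1e-8) {
  a <- with_seed(4242L, {
    m <- matrix(0, nrow(z), ncol(z))
    m[z] <- runif(sum(z), 0.5, 1.5) * sample(c(-1, 1), sum(z), TRUE)
    m
  })
  q <- qr(a, tol = tol)
  if (q$rank == ncol(z)) return(character())
  colnames(z)[q$pivot[seq(q$rank + 1L, ncol(z))]]
}

#' Prune a prior until it satisfies the identifiability criteria
#'
#' Greedy removal of problem TFs: TFs with target sets identical to
#' another TF's are collapsed first; then, while the pattern is rank
#' deficient (directly or after removing some TF with its targets), the
#' dependent TF with the fewest targets is dropped; finally, if there are
#' more TFs than samples, the TFs with the fewest targets are dropped
#' until criterion (iii) holds. Genes left without any regulator are
#' removed. The result is a subset of the input support and a fixed point
#' of the procedure.
#'
#' @inheritParams check_identifiability
#' @param enforce_iii Also prune until `n_TFs <= n_samples` (criterion
#'   iii). With `FALSE`, only the structural criteria (i) and (ii) are
#'   enforced; useful when per-TF private targets keep the decomposition
#'   identifiable despite fewer conditions than TFs.
#' @return A pruned [connectivity_prior()] that passes
#'   [check_identifiability()] (criteria i and ii, plus iii when
#'   enforced).
#' @export
reduce_to_identifiable <- function(prior, n_samples, tol = 1e-8,
                                   enforce_iii = TRUE) {
  support <- prior$support
  drop_tf <- function(support, tf) support[support$tf != tf, , drop = FALSE]
  repeat {
    if (nrow(support) == 0L) stop("identifiability pruning removed every TF")
    pr <- connectivity_prior(support)
    rep_ <- check_identifiability(pr, n_samples, tol = tol)
    done <- rep_$criterion_i && all(rep_$criterion_ii) &&
      (rep_$criterion_iii || !enforce_iii)
    if (done) return(pr)
    z <- support_matrix(pr)
    z <- z[rowSums(z) > 0, , drop = FALSE]
    sizes <- colSums(z)

    # 1. collapse TFs with duplicated target sets (keep the first)
    sig <- apply(z, 2L, function(col) paste(which(col), collapse = ","))
    dup <- duplicated(sig)
    if (any(dup)) {
      for (tf in colnames(z)[dup]) support <- drop_tf(support, tf)
      next
    }
    # 2. direct rank deficiency: drop the dependent TF with fewest targets
    if (!rep_$criterion_i) {
      dep <- dependent_tfs(z, tol = tol)
      victim <- dep[which.min(sizes[dep])]
      support <- drop_tf(support, victim)
      next
    }
    # 3. a TF whose removal (with its targets) collapses the rest
    if (!all(rep_$criterion_ii)) {
      t_fail <- names(rep_$criterion_ii)[!rep_$criterion_ii][1L]
      z2 <- z[!z[, t_fail], colnames(z) != t_fail, drop = FALSE]
      dep <- dependent_tfs(z2, tol = tol)
      cand <- unique(c(dep, t_fail))
      victim <- cand[which.min(sizes[cand])]
      support <- drop_tf(support, victim)
      next
    }
    # 4. more TFs than samples: shed smallest TFs
    if (enforce_iii && !rep_$criterion_iii) {
      victim <- colnames(z)[which.min(sizes)]
      support <- drop_tf(support, victim)
      next
    }
  }
}
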