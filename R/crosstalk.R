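# Pathway crosstalk on a weighted PPI network: per-edge scores combine
# the differential-expression significance of the two endpoint genes
# with the significance of their co-expression; a pathway pair's C score
# sums the scores of the edges linking the two pathways and is assessed
# against a permutation null of random same-size gene sets.

#' Combine three p-values into an edge score
#'
#' Fisher's combination S = -2 (ln p1 + ln p2 + ln p3) (k = 3) of the
#' differential-expression p-values of the two endpoint genes and the
#' co-expression p-value of the pair. Strictly decreasing in each
#' argument, zero when all three p-values are 1. `"stouffer"` offers
#' Stouffer's Z as an alternative combination.
#'
#' @param p1,p2 Differential-expression p-values of the two endpoints,
#'   in (0, 1]. Vectorized.
#' @param p3 Co-expression p-value of the pair, in (0, 1].
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return Numeric vector of scores (>= 0 for Fisher).
#' @examples
#' edge_score(0.05, 0.05, 0.05)  # -6 log 0.05
#' @export
edge_score <- function(p1, p2, p3, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  if (any(c(p1, p2, p3) > 1, na.rm = TRUE)) stop("p-values must be <= 1")
  p1 <- floor_pvalues(p1)
  p2 <- floor_pvalues(p2)
  p3 <- floor_pvalues(p3)
  if (method == "fisher") {
    -2 * (log(p1) + log(p2) + log(p3))
  } else {
    (qnorm(1 - p1) + qnorm(1 - p2) + qnorm(1 - p3)) / sqrt(3)
  }
}

#' Weight a PPI network with expression evidence at one stage
#'
#' Maps two kinds of statistical evidence onto the network: each node
#' gets the moderated-t differential-expression p-value of its gene at
#' the stage, and each edge gets the two-sided p-value of the Pearson
#' correlation between its endpoint genes across all samples of the
#' stage (both arms pooled). The per-edge score combines the three
#' p-values via [edge_score()].
#'
#' @param ppi Data frame of edges (`from`, `to`). Self-loops and
#'   duplicate edges are dropped; edges with an endpoint absent from the
#'   dataset are dropped with a message.
#' @param dataset An [expression_dataset()].
#' @param stage Timepoint (hours); needs >= 3 pooled samples.
#' @param method Combination method for [edge_score()].
#' @return An object of class `WeightedPPINetwork`: `nodes` (character),
#'   `p_diff` (named numeric), `edges` (data frame `from`, `to`,
#'   `p_coexpr`, `score`), `n_dropped`, `stage`, `method`.
#' @export
weight_network <- function(ppi, dataset, stage, method = "fisher") {
  stopifnot(is.data.frame(ppi), all(c("from", "to") %in% names(ppi)))
  ppi <- ppi[ppi$from != ppi$to, , drop = FALSE]
  key <- paste(pmin(ppi$from, ppi$to), pmax(ppi$from, ppi$to), sep = "\r")
  ppi <- ppi[!duplicated(key), , drop = FALSE]
  present <- ppi$from %in% rownames(dataset$values) &
    ppi$to %in% rownames(dataset$values)
  n_dropped <- sum(!present)
  if (n_dropped > 0L) {
    message(n_dropped, " PPI edge(s) dropped: endpoint without expression")
  }
  ppi <- ppi[present, , drop = FALSE]
  if (nrow(ppi) == 0L) stop("no PPI edges left after matching to the dataset")

  s <- dataset$samples
  ids <- s$sample_id[s$time == stage]
  n <- length(ids)
  if (n < 3L) stop(sprintf("stage %s has %d samples; >= 3 required", format(stage), n))
  de <- moderated_t(dataset, stage)
  p_diff <- stats::setNames(de$p, de$gene)
  p_diff <- floor_pvalues(p_diff, "differential-expression p-value")

  x <- dataset$values[, ids, drop = FALSE]
  mu <- rowMeans(x)
  sdev <- sqrt(rowSums((x - mu)^2))
  const <- sdev == 0
  xs <- (x - mu) / ifelse(sdev == 0, 1, sdev)
  r <- rowSums(xs[ppi$from, , drop = FALSE] * xs[ppi$to, , drop = FALSE])
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_coexpr <- 2 * pt(-abs(tstat), n - 2)
  undef <- const[ppi$from] | const[ppi$to]
  if (any(undef)) {
    warning(sum(undef), " edge(s) with a constant gene: co-expression p set to 1",
            call. = FALSE)
    p_coexpr[undef] <- 1
  }
  p_coexpr <- floor_pvalues(p_coexpr, "co-expression p-value")
  edges <- data.frame(from = ppi$from, to = ppi$to, p_coexpr = p_coexpr,
                      score = edge_score(p_diff[ppi$from], p_diff[ppi$to],
                                         p_coexpr, method = method))
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, p_diff = p_diff[nodes], edges = edges,
                 n_dropped = n_dropped, stage = stage, method = method),
            class = "WeightedPPINetwork")
}

#' @export
print.WeightedPPINetwork <- function(x, ...) {
  cat(sprintf("WeightedPPINetwork at stage %s h: %d nodes, %d edges (%s scores)\n",
              format(x$stage), length(x$nodes), nrow(x$edges), x$method))
  invisible(x)
}

#' Overlap edges and C score of a pathway pair
#'
#' The overlap O_ij is the set of network edges with one endpoint in
#' pathway P_i and the other in P_j (in either orientation; edges wholly
#' inside the intersection qualify and are counted once). The C score is
#' the sum of edge scores over O_ij.
#'
#' @param p_i,p_j Character vectors of pathway member genes.
#' @param net A [weight_network()] result.
#' @return List with `edges` (the overlap, a data frame) and `c_score`.
#' @export
overlap_score <- function(p_i, p_j, net) {
  mi <- net$edges$from %in% p_i
  mj <- net$edges$to %in% p_j
  mi2 <- net$edges$from %in% p_j
  mj2 <- net$edges$to %in% p_i
  qual <- (mi & mj) | (mi2 & mj2)
  list(edges = net$edges[qual, , drop = FALSE],
       c_score = sum(net$edges$score[qual]))
}

# Fast C score for index-coded gene sets: `from_idx`/`to_idx` are edge
# endpoints coded into 1..n_nodes, `in_i`/`in_j` logical membership.
c_score_fast <- function(from_idx, to_idx, score, in_i, in_j) {
  qual <- (in_i[from_idx] & in_j[to_idx]) | (in_j[from_idx] & in_i[to_idx])
  sum(score[qual])
}

#' Permutation p-value for pathway crosstalk
#'
#' Compares the observed C score of a pathway pair against `B` draws of
#' two random gene sets of the same sizes from a sampling universe
#' (default: all network nodes; pass the pathway-covered subnetwork for
#' the stricter null). The empirical p-value uses the add-one estimator
#' p = (1 + #\{random C >= observed C\}) / (B + 1), so it is never
#' exactly zero. A pair with an empty observed overlap is reported
#' directly with p = 1.
#'
#' @param p_i,p_j Pathway member gene vectors.
#' @param net A [weight_network()] result.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param universe Sampling universe (character); defaults to
#'   `net$nodes`.
#' @return An object of class `CrosstalkResult`: `c_score`, `n_edges`,
#'   `B`, `p_value`, `empty_overlap`, `sizes`.
#' @export
permutation_pvalue <- function(p_i, p_j, net, B = 10000L, seed = 1L,
                               universe = NULL) {
  if (B < 1L) stop("B must be >= 1")
  universe <- unique(universe %||% net$nodes)
  obs <- overlap_score(p_i, p_j, net)
  si <- length(intersect(p_i, universe))
  sj <- length(intersect(p_j, universe))
  if (obs$c_score == 0) {
    return(structure(list(c_score = 0, n_edges = 0L, B = B, p_value = 1,
                          empty_overlap = TRUE, sizes = c(si, sj)),
                     class = "CrosstalkResult"))
  }
  if (length(universe) < max(si, sj) + 1L) {
    stop("sampling universe too small for the pathway sizes")
  }
  node_idx <- stats::setNames(seq_along(universe), universe)
  keep <- net$edges$from %in% universe & net$edges$to %in% universe
  from_idx <- node_idx[net$edges$from[keep]]
  to_idx <- node_idx[net$edges$to[keep]]
  score <- net$edges$score[keep]
  n_univ <- length(universe)
  exceed <- with_seed(seed, {
    cnt <- 0L
    in_i <- logical(n_univ)
    in_j <- logical(n_univ)
    for (b in seq_len(B)) {
      ii <- sample.int(n_univ, si)
      jj <- sample.int(n_univ, sj)
      in_i[ii] <- TRUE
      in_j[jj] <- TRUE
      cb <- c_score_fast(from_idx, to_idx, score, in_i, in_j)
      if (cb >= obs$c_score) cnt <- cnt + 1L
      in_i[ii] <- FALSE
      in_j[jj] <- FALSE
    }
    cnt
  })
  structure(list(c_score = obs$c_score, n_edges = nrow(obs$edges), B = B,
                 p_value = (1 + exceed) / (B + 1),
                 empty_overlap = FALSE, sizes = c(si, sj)),
            class = "CrosstalkResult")
}

#' @export
print.CrosstalkResult <- function(x, ...) {
  cat(sprintf("CrosstalkResult: C = %.4g over %d overlap edge(s), p = %.4g (B = %d)%s\n",
              x$c_score, x$n_edges, x$p_value, x$B,
              if (x$empty_overlap) " [empty overlap]" else ""))
  invisible(x)
}

#' Stage-wise crosstalk dynamics for a set of pathway pairs
#'
#' Re-weights the PPI network at each stage and recomputes each pair's C
#' score and permutation p-value, flagging significance at the 0.1 and
#' 0.3 thresholds. Each pair keeps the same derived seed across stages,
#' so identical data at two stages gives identical p-values.
#'
#' @param pairs Data frame with columns `pathway_a`, `pathway_b`.
#' @param pathways A [pathway_set()].
#' @param ppi PPI edge data frame (`from`, `to`).
#' @param dataset An [expression_dataset()].
#' @param stages Timepoints (default: all non-zero timepoints).
#' @param B Permutations per pair per stage.
#' @param seed Integer master seed.
#' @param universe Sampling universe; default: pathway-covered network
#'   nodes (genes in at least one pathway that are in the network).
#' @param method Edge-score combination method.
#' @return Data frame: `pathway_a`, `pathway_b`, `stage`, `c_score`,
#'   `n_edges`, `B`, `p_value`, `empty_overlap`, `significant_0.1`,
#'   `significant_0.3`.
#' @export
crosstalk_dynamics <- function(pairs, pathways, ppi, dataset,
                               stages = dataset_stages(dataset),
                               B = 2000L, seed = 1L, universe = NULL,
                               method = "fisher") {
  stopifnot(inherits(pathways, "PathwaySet"),
            all(c("pathway_a", "pathway_b") %in% names(pairs)))
  missing_stage <- setdiff(stages, dataset$samples$time)
  if (length(missing_stage) > 0L) {
    stop("stage(s) missing from the dataset: ",
         paste(missing_stage, collapse = ", "))
  }
  bad <- setdiff(unique(c(pairs$pathway_a, pairs$pathway_b)),
                 names(pathways$pathways))
  if (length(bad) > 0L) stop("unknown pathway(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (st in stages) {
    net <- weight_network(ppi, dataset, st, method = method)
    univ <- universe %||% intersect(unique(unlist(pathways$pathways)), net$nodes)
    for (i in seq_len(nrow(pairs))) {
      pa <- pairs$pathway_a[i]
      pb <- pairs$pathway_b[i]
      res <- permutation_pvalue(pathways$pathways[[pa]], pathways$pathways[[pb]],
                                net, B = B, seed = derive_seed(seed, i),
                                universe = univ)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_a = pa, pathway_b = pb, stage = st,
        c_score = res$c_score, n_edges = res$n_edges, B = res$B,
        p_value = res$p_value, empty_overlap = res$empty_overlap,
        significant_0.1 = res$p_value < 0.1,
        significant_0.3 = res$p_value < 0.3)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a weighted PPI network as GraphML
#'
#' Node attribute: differential-expression p-value; edge attributes:
#' co-expression p-value and combined score.
#'
#' @param net A [weight_network()] result.
#' @param path Output path.
#' @export
write_weighted_network_graphml <- function(net, path) {
  nodes <- data.frame(name = net$nodes, p_diff = unname(net$p_diff[net$nodes]))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
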