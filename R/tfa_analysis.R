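# Post-fit analytics on inferred TF activities and control strengths.

#' Correlation between each TF's activity and its own expression
#'
#' Pearson correlation of the inferred activity time course of each TF
#' with the TF gene's mean log-ratio expression over the same conditions
#' (both series normalized to the zero timepoint). TFs absent from the
#' dataset, or series with fewer than 3 conditions or zero variance, are
#' reported as `NA`.
#'
#' @param result An [fit_nca()] result.
#' @param dataset The [expression_dataset()] the fit came from.
#' @param reference Passed to [make_log_ratios()].
#' @return Data frame with columns `tf` and `r`.
#' @export
tfa_expression_correlation <- function(result, dataset,
                                       reference = c("control", "t0")) {
  e_all <- make_log_ratios(dataset, match.arg(reference))
  p <- result$activities
  conds <- intersect(colnames(p), colnames(e_all))
  r <- vapply(rownames(p), function(tf) {
    if (!tf %in% rownames(e_all) || length(conds) < 3L) return(NA_real_)
    x <- p[tf, conds]
    y <- e_all[tf, conds]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  data.frame(tf = rownames(p), r = unname(r))
}

#' Correlation matrix between TF activities
#'
#' @param result An [fit_nca()] result with at least 3 conditions.
#' @return Symmetric TF x TF Pearson correlation matrix with unit
#'   diagonal; rows/columns of constant-activity TFs are `NA` (with a
#'   warning).
#' @export
tfa_correlation_matrix <- function(result) {
  p <- result$activities
  if (ncol(p) < 3L) stop("need >= 3 conditions for an activity correlation matrix")
  const <- apply(p, 1L, sd) == 0
  cc <- suppressWarnings(cor(t(p)))
  if (any(const)) {
    warning("constant activity row(s) reported as NA: ",
            paste(rownames(p)[const], collapse = ", "), call. = FALSE)
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  diag(cc)[!const] <- 1
  cc
}

#' Infer combinatorial TF pairs from activity correlation and PPI
#'
#' A TF pair is reported when its activities are highly correlated
#' (|r| > `r_threshold`) or the pair has a protein-protein interaction,
#' and classified as supported by `both`, `correlation_only` or
#' `ppi_only`.
#'
#' @param corr TF x TF correlation matrix from
#'   [tfa_correlation_matrix()].
#' @param ppi Data frame of PPI edges (`from`, `to`) over the same TF
#'   universe (edges touching other genes are ignored).
#' @param r_threshold Activity-correlation threshold (default 0.6).
#' @return Data frame with columns `tf_a`, `tf_b` (lexicographically
#'   ordered), `activity_correlation`, `ppi_supported`,
#'   `evidence_class`.
#' @export
infer_combinatorial_pairs <- function(corr, ppi, r_threshold = 0.6) {
  tfs <- sort(rownames(corr))
  ppi_keys <- character(0)
  if (!is.null(ppi) && nrow(ppi) > 0L) {
    keep <- ppi$from %in% tfs & ppi$to %in% tfs & ppi$from != ppi$to
    ppi_keys <- unique(paste(pmin(ppi$from[keep], ppi$to[keep]),
                             pmax(ppi$from[keep], ppi$to[keep]), sep = "\r"))
  }
  if (length(tfs) < 2L) {
    return(data.frame(tf_a = character(), tf_b = character(),
                      activity_correlation = numeric(),
                      ppi_supported = logical(), evidence_class = character()))
  }
  pairs <- t(combn(tfs, 2L))
  r <- corr[cbind(pairs[, 1L], pairs[, 2L])]
  high <- !is.na(r) & abs(r) > r_threshold
  in_ppi <- paste(pairs[, 1L], pairs[, 2L], sep = "\r") %in% ppi_keys
  keep <- high | in_ppi
  out <- data.frame(tf_a = pairs[keep, 1L], tf_b = pairs[keep, 2L],
                    activity_correlation = r[keep],
                    ppi_supported = in_ppi[keep],
                    evidence_class = ifelse(high[keep] & in_ppi[keep], "both",
                                     ifelse(high[keep], "correlation_only",
                                            "ppi_only")))
  rownames(out) <- NULL
  out
}

#' Hierarchically cluster genes on their control-strength profiles
#'
#' Clusters the rows of the (normalized) strength matrix on Euclidean
#' distance, cuts the tree into flat clusters, and flags "major"
#' clusters with more than `major_min` members.
#'
#' @param result An [fit_nca()] result, normally after
#'   [normalize_result()] so strengths are on a comparable scale.
#' @param linkage Agglomeration method (default `"average"`).
#' @param h Cut height for flat clusters; default is the midpoint of the
#'   merge-height range.
#' @param major_min A cluster is "major" when it has more than this many
#'   members (default 3).
#' @return List with `tree` (an [stats::hclust] object, or `NULL` for a
#'   single gene), `clusters` (named integer vector), `major` (ids of
#'   major clusters), and `ordered` (strength matrix in dendrogram
#'   order).
#' @export
cluster_strengths <- function(result, linkage = "average", h = NULL,
                              major_min = 3L) {
  a <- result$strengths
  if (nrow(a) < 1L) stop("no genes to cluster")
  if (nrow(a) == 1L) {
    cl <- stats::setNames(1L, rownames(a))
    return(list(tree = NULL, clusters = cl, major = integer(0), ordered = a))
  }
  tree <- hclust(dist(a), method = linkage)
  if (is.null(h)) h <- mean(range(tree$height))
  clusters <- cutree(tree, h = h)
  sizes <- table(clusters)
  major <- as.integer(names(sizes)[sizes > major_min])
  list(tree = tree, clusters = clusters, major = major,
       ordered = a[tree$order, , drop = FALSE])
}

#' Export a gene dendrogram in Newick format
#' @param tree An [stats::hclust] object (e.g. from
#'   [cluster_strengths()]).
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Export the inferred regulatory network
#'
#' Builds a graph whose nodes are TFs (`node_type = "TF"`, drawn as
#' triangles by convention) and target genes (`node_type = "gene"`,
#' circles), with one edge per supported (TF, gene) pair carrying the
#' inferred strength and its sign. Optional subcellular locations are
#' passed through as a node attribute.
#'
#' @param result An [fit_nca()] result (normalized recommended).
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @param locations Optional data frame (`gene`, `location`) merged as a
#'   node attribute.
#' @return The path, invisibly.
#' @export
write_network_export <- function(result, path, format = c("graphml", "sif"),
                                 locations = NULL) {
  format <- match.arg(format)
  a <- result$strengths
  idx <- which(a != 0, arr.ind = TRUE)
  edges <- data.frame(tf = colnames(a)[idx[, 2L]],
                      gene = rownames(a)[idx[, 1L]],
                      strength = a[idx],
                      sign = ifelse(a[idx] >= 0, "+", "-"))
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", edges$tf,
                       ifelse(edges$sign == "+", "activates", "represses"),
                       edges$gene), path)
    return(invisible(path))
  }
  nodes <- data.frame(name = c(colnames(a), rownames(a)),
                      node_type = rep(c("TF", "gene"),
                                      c(ncol(a), nrow(a))))
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  if (!is.null(locations)) {
    nodes$location <- locations$location[match(nodes$name, locations$gene)]
    nodes$location[is.na(nodes$location)] <- "unknown"
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("tf", "gene", "strength", "sign")],
    directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
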