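# Pathway over-representation by the hypergeometric test.

#' Named pathway gene sets with a background universe
#'
#' @param pathways Named list of character vectors (gene ids).
#' @param universe Background gene set; pathway members outside it are
#'   dropped, and pathways left empty are removed with a warning.
#' @return An object of class `PathwaySet`: list with `pathways` and
#'   `universe`.
#' @export
pathway_set <- function(pathways, universe) {
  stopifnot(is.list(pathways), !is.null(names(pathways)),
            all(nzchar(names(pathways))))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  restricted <- lapply(pathways, function(g) intersect(unique(g), universe))
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    warning(sum(empty), " pathway(s) empty after restriction to the universe, dropped",
            call. = FALSE)
    restricted <- restricted[!empty]
  }
  if (length(restricted) == 0L) stop("no pathways left after restriction")
  structure(list(pathways = restricted, universe = universe),
            class = "PathwaySet")
}

#' @export
print.PathwaySet <- function(x, ...) {
  cat(sprintf("PathwaySet: %d pathways (sizes %d-%d) over a universe of %d genes\n",
              length(x$pathways), min(lengths(x$pathways)),
              max(lengths(x$pathways)), length(x$universe)))
  invisible(x)
}

#' Read / write GMT pathway files
#'
#' GMT: one tab-separated line per gene set -- name, description, then
#' member genes.
#'
#' @param path File path.
#' @param universe Background universe for the returned [pathway_set()];
#'   defaults to the union of all set members.
#' @return `read_gmt` returns a [pathway_set()] (descriptions in the
#'   `descriptions` attribute); `write_gmt` returns `path` invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s) (need name, description, >= 1 gene): ",
         paste(which(bad), collapse = ", "))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  desc <- vapply(fields, `[`, "", 2L)
  names(desc) <- names(sets)
  if (is.null(universe)) universe <- unique(unlist(sets))
  ps <- pathway_set(sets, universe)
  attr(ps, "descriptions") <- desc
  ps
}

#' @rdname read_gmt
#' @param pathways A [pathway_set()] or a named list of gene vectors.
#' @export
write_gmt <- function(pathways, path) {
  sets <- if (inherits(pathways, "PathwaySet")) pathways$pathways else pathways
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway, tests the overlap k between a gene list of size n
#' and the pathway (size K) against a universe of size N with the
#' hypergeometric upper tail p = P(X >= k). Genes outside the universe
#' are dropped from the list with a warning.
#'
#' @param gene_list Character vector of selected genes (e.g.
#'   differentially expressed genes).
#' @param pathways A [pathway_set()].
#' @return Data frame with columns `pathway`, `k`, `K`, `n`, `N`, `p`.
#' @examples
#' ps <- pathway_set(list(a = c("g1", "g2", "g3")), universe = paste0("g", 1:20))
#' hypergeometric_enrichment(c("g1", "g2"), ps)
#' @export
hypergeometric_enrichment <- function(gene_list, pathways) {
  stopifnot(inherits(pathways, "PathwaySet"))
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, pathways$universe)
  if (length(outside) > 0L) {
    warning(length(outside), " gene(s) outside the universe dropped from the list",
            call. = FALSE)
    gene_list <- setdiff(gene_list, outside)
  }
  n <- length(gene_list)
  n_univ <- length(pathways$universe)
  out <- lapply(names(pathways$pathways), function(nm) {
    members <- pathways$pathways[[nm]]
    k <- length(intersect(gene_list, members))
    kk <- length(members)
    p <- phyper(k - 1L, kk, n_univ - kk, n, lower.tail = FALSE)
    data.frame(pathway = nm, k = k, K = kk, n = n, N = n_univ, p = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter and sort enrichment results
#'
#' Keeps pathways with at least `min_members` genes from the list and a
#' raw p-value below `p_threshold`, sorted by p.
#'
#' @param results Data frame from [hypergeometric_enrichment()].
#' @param p_threshold Raw p-value threshold (default 0.1).
#' @param min_members Minimum overlap k (default 2).
#' @return The filtered, p-sorted data frame.
#' @export
select_significant <- function(results, p_threshold = 0.1, min_members = 2L) {
  keep <- results$k >= min_members & results$p < p_threshold
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
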