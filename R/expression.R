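#' Replicated time-course expression dataset
#'
#' Container for a genes x samples matrix of log2 expression values with
#' per-sample annotations (time in hours, treated/control arm, replicate).
#' This is the common input of the differential-expression, connectivity
#' and network-weighting stages.
#'
#' @param values Numeric matrix, genes in rows (rownames required) and
#'   samples in columns (colnames required), log2 scale, finite.
#' @param samples Data frame with columns `sample_id`, `time` (hours,
#'   numeric), `condition` (`"treated"` or `"control"`) and `replicate`
#'   (integer), one row per column of `values`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` and `samples`.
#' @examples
#' v <- matrix(rnorm(12), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' ann <- data.frame(sample_id = paste0("s", 1:6),
#'                   time = rep(c(0, 4), each = 3),
#'                   condition = "treated", replicate = 1:3)
#' expression_dataset(v, ann)
#' @export
expression_dataset <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (!all(is.finite(values))) stop("`values` must be finite")
  req <- c("sample_id", "time", "condition", "replicate")
  if (!all(req %in% names(samples))) {
    stop("`samples` must have columns: ", paste(req, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("every column of `values` needs a sample annotation")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample ids")
  if (!all(samples$condition %in% c("treated", "control"))) {
    stop("condition must be 'treated' or 'control'")
  }
  structure(list(values = values, samples = samples),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$time, x$samples$condition)
  cat("samples per (time, condition):\n")
  print(tab)
  invisible(x)
}

#' Stages (non-zero timepoints) of a dataset
#' @param dataset An [expression_dataset()].
#' @return Sorted numeric vector of non-zero timepoints.
#' @export
dataset_stages <- function(dataset) {
  t <- sort(unique(dataset$samples$time))
  t[t != 0]
}

# Sample ids of one arm at one timepoint.
arm_samples <- function(dataset, time, condition) {
  s <- dataset$samples
  s$sample_id[s$time == time & s$condition == condition]
}

#' Write / read an expression dataset as TSV
#'
#' One header row of sample ids, one row per gene. Sample annotations are
#' encoded in the ids as `<condition>_<time>h_r<replicate>` and recovered
#' on read.
#'
#' @param dataset An [expression_dataset()].
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expression_dataset()].
#' @export
write_expression_tsv <- function(dataset, path) {
  df <- data.frame(gene = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene
  ids <- colnames(values)
  m <- regmatches(ids, regexec("^(treated|control)_([0-9.]+)h_r([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("sample ids not parseable as <condition>_<time>h_r<rep>: ",
         paste(ids[bad], collapse = ", "))
  }
  samples <- data.frame(
    sample_id = ids,
    time = as.numeric(vapply(m, `[`, "", 3L)),
    condition = vapply(m, `[`, "", 2L),
    replicate = as.integer(vapply(m, `[`, "", 4L))
  )
  expression_dataset(values, samples)
}
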