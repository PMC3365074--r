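# Empirical-Bayes moderated two-sample t, treated vs control at one stage.
#
# The gene-wise residual variances s_g^2 (pooled over the two arms) are
# shrunk toward a prior variance s0^2 with prior degrees of freedom d0,
# estimated by moment matching of log s_g^2 against its theoretical
# scaled-F sampling distribution:
#   E[log s^2]  = log s0^2 + psi(d/2) - log(d/2) - psi(d0/2) + log(d0/2)
#   Var[log s^2] = psi'(d/2) + psi'(d0/2)
# giving d0 from the excess variance of log s^2 and s0^2 from its mean.

# Solve trigamma(x) = y by Newton iteration.
trigamma_inverse <- function(y) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Moment-matching fit of the variance prior. s2: gene-wise variances;
# df: their (common) residual degrees of freedom.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2L) return(list(d0 = Inf, s02 = mean(s2[ok])))
  evar <- var(z) - trigamma(df / 2)
  if (evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t-test for one time stage
#'
#' Compares the treated and control arms at a single timepoint with an
#' empirical-Bayes moderated t-statistic: the pooled two-sample variance
#' of each gene is shrunk toward a prior variance `s02` with prior
#' degrees of freedom `d0` (estimated across genes by moment matching
#' unless supplied), and the statistic is referred to a t distribution
#' with `residual df + d0` degrees of freedom.
#'
#' @param dataset An [expression_dataset()] (log2 values).
#' @param stage Timepoint (hours) to test; both arms must have >= 2
#'   replicates there.
#' @param d0,s02 Optional prior degrees of freedom and prior variance,
#'   overriding the moment-matching estimates. `d0 = 0` gives the
#'   ordinary two-sample pooled t-test.
#' @return Data frame with one row per gene: `gene`, `lfc` (log2 fold
#'   change, treated minus control mean), `t`, `p` (two-sided),
#'   `df_total`. The estimated `d0` and `s02` are attached as attributes.
#' @examples
#' study <- simulate_study(seed = 1)
#' de4 <- moderated_t(study$dataset, stage = 4)
#' head(de4)
#' @export
moderated_t <- function(dataset, stage, d0 = NULL, s02 = NULL) {
  tr <- arm_samples(dataset, stage, "treated")
  ct <- arm_samples(dataset, stage, "control")
  if (length(tr) < 2L || length(ct) < 2L) {
    stop(sprintf("stage %s needs >= 2 samples per arm (found %d treated, %d control)",
                 format(stage), length(tr), length(ct)))
  }
  x <- dataset$values[, tr, drop = FALSE]
  y <- dataset$values[, ct, drop = FALSE]
  nt <- ncol(x); nc <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  ssx <- rowSums((x - mx)^2); ssy <- rowSums((y - my)^2)
  df <- nt + nc - 2L
  s2 <- (ssx + ssy) / df
  if (is.null(d0) || is.null(s02)) {
    prior <- fit_variance_prior(s2, df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  lfc <- mx - my
  se <- sqrt(s2_post * (1 / nt + 1 / nc))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(tstat)) else 2 * pt(-abs(tstat), df_total)
  p[se == 0 & lfc == 0] <- 1
  out <- data.frame(gene = rownames(dataset$values), lfc = lfc, t = tstat,
                    p = p, df_total = df_total, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "stage") <- stage
  out
}

#' Run the moderated t at every stage
#'
#' @param dataset An [expression_dataset()].
#' @param stages Timepoints to test (default: all non-zero timepoints).
#' @param ... Passed to [moderated_t()].
#' @return Named list of per-stage data frames.
#' @export
moderated_t_all_stages <- function(dataset, stages = dataset_stages(dataset), ...) {
  out <- lapply(stages, function(st) moderated_t(dataset, st, ...))
  names(out) <- as.character(stages)
  out
}

#' Select differentially expressed genes across stages
#'
#' A gene is selected when the per-stage predicate -- linear-scale fold
#' change above `fc_threshold` in either direction (|lfc| > log2 of the
#' threshold) and raw p below `p_threshold` -- holds in at least
#' `min_stages` stages. The defaults mirror a common microarray rule:
#' fold change > 1.5, p < 0.05, differential in more than one stage.
#'
#' @param de_by_stage Named list of per-stage results from
#'   [moderated_t()] (or [moderated_t_all_stages()]).
#' @param fc_threshold Linear-scale fold-change threshold (> 1).
#' @param p_threshold Raw p-value threshold.
#' @param min_stages Minimum number of stages in which the predicate must
#'   hold.
#' @return Character vector of selected gene ids, with a `stage_counts`
#'   attribute (named integer vector over all genes).
#' @export
select_degs <- function(de_by_stage, fc_threshold = 1.5, p_threshold = 0.05,
                        min_stages = 2L) {
  stopifnot(fc_threshold > 1, p_threshold > 0, p_threshold <= 1)
  if (min_stages > length(de_by_stage)) {
    stop(sprintf("min_stages (%d) exceeds the number of stages (%d)",
                 min_stages, length(de_by_stage)))
  }
  lfc_cut <- log2(fc_threshold)
  hits <- vapply(de_by_stage, function(de) {
    !is.na(de$p) & abs(de$lfc) > lfc_cut & de$p < p_threshold
  }, logical(nrow(de_by_stage[[1]])))
  counts <- rowSums(hits)
  names(counts) <- de_by_stage[[1]]$gene
  selected <- names(counts)[counts >= min_stages]
  attr(selected, "stage_counts") <- counts
  selected
}
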