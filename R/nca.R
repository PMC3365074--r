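# Network component analysis: constrained bilinear decomposition of a
# log-ratio expression matrix E (genes x conditions) into a strength
# matrix A (zero off a known support) and a TF activity matrix P,
# minimizing ||E - A P||_F^2 by alternating least squares.

#' Build the log-ratio matrix for NCA
#'
#' Collapses replicates to per-(gene, timepoint) means and forms
#' log-ratios relative to a reference: with `reference = "control"`, the
#' treated mean minus the matched control mean at the same timepoint;
#' with `reference = "t0"`, the treated mean minus the treated mean at
#' time 0. In both cases the resulting matrix is additionally normalized
#' to the zero timepoint (its t = 0 column, when present, is subtracted),
#' so the t = 0 column is exactly zero.
#'
#' @param dataset An [expression_dataset()] (log2 values, so ratios are
#'   differences).
#' @param reference `"control"` (default) or `"t0"`.
#' @return Numeric genes x timepoints matrix with a `reference`
#'   attribute; columns are named by timepoint and ordered by time.
#' @export
make_log_ratios <- function(dataset, reference = c("control", "t0")) {
  reference <- match.arg(reference)
  s <- dataset$samples
  times <- sort(unique(s$time))
  arm_mean <- function(cond, t) {
    ids <- arm_samples(dataset, t, cond)
    if (length(ids) == 0L) {
      stop(sprintf("no %s samples at time %s", cond, format(t)))
    }
    rowMeans(dataset$values[, ids, drop = FALSE])
  }
  e <- vapply(times, function(t) {
    if (reference == "control") {
      arm_mean("treated", t) - arm_mean("control", t)
    } else {
      arm_mean("treated", t)
    }
  }, numeric(nrow(dataset$values)))
  dimnames(e) <- list(rownames(dataset$values), as.character(times))
  if (reference == "t0" && !"0" %in% colnames(e)) {
    stop("reference = 't0' requires samples at time 0")
  }
  if ("0" %in% colnames(e)) e <- e - e[, "0"]
  attr(e, "reference") <- reference
  e
}

# Solve the per-gene strength subproblem for one support signature:
# rows R of A restricted to TF set S minimize ||E_R - A_{R,S} P_S||.
solve_strength_block <- function(e_rows, p_sub, ridge_flag) {
  g <- tcrossprod(p_sub)            # S x S
  b <- tcrossprod(e_rows, p_sub)    # R x S
  sol <- tryCatch(t(solve(g, t(b))), error = function(err) NULL)
  if (is.null(sol)) {
    ridge_flag$hit <- TRUE
    sol <- t(solve(g + diag(1e-10, nrow(g)), t(b)))
  }
  sol
}

#' Fit a network component decomposition
#'
#' Alternating least squares under the support constraint: given P, each
#' gene's supported strength entries are solved by ordinary least squares
#' against the rows of P indexed by that gene's support (genes sharing a
#' support signature are solved as one block); given A, P is the
#' unconstrained least-squares solution. Iteration stops when the
#' relative objective decrease falls below `tol` or after `max_iter`
#' iterations; the best of `n_restarts` seeded random initializations is
#' returned. Each restart initializes P from the pseudo-inverse of a
#' random on-support A.
#'
#' Fitting refuses to run when the structural identifiability criteria
#' (full column rank of the support; full column rank after removing any
#' TF with its targets) fail. A failure of the sample-count condition
#' (more TFs than conditions) only triggers a warning, because structures
#' with per-TF private targets remain identifiable per TF.
#'
#' @param e Log-ratio matrix from [make_log_ratios()] (genes x
#'   conditions).
#' @param prior A [connectivity_prior()] covering every row of `e`.
#' @param n_restarts Number of random restarts.
#' @param tol Relative objective-decrease convergence tolerance.
#' @param max_iter Maximum ALS iterations per restart.
#' @param seed Integer seed (restart seeds are derived from it).
#' @return An object of class `NCAResult`: `strengths` (genes x TFs,
#'   exactly zero off support), `activities` (TFs x conditions),
#'   `objective` (final ||E - AP||^2), `n_iter`, `restarts` (final
#'   objective per restart), `converged`, `trace` (objective per
#'   iteration of the best restart), plus the inputs `e` and `prior`.
#' @examples
#' study <- simulate_study(noise_sd = 0, seed = 1)
#' e <- make_log_ratios(study$dataset)
#' e <- e[study$prior$genes, ]
#' fit <- fit_nca(e, study$prior, n_restarts = 2, seed = 1)
#' fit$objective
#' @export
fit_nca <- function(e, prior, n_restarts = 10L, tol = 1e-8,
                    max_iter = 2000L, seed = 1L) {
  stopifnot(is.matrix(e), n_restarts >= 1L)
  genes <- rownames(e)
  uncovered <- setdiff(genes, prior$genes)
  if (length(uncovered) > 0L) {
    stop("genes in E without any regulator in the prior: ",
         paste(head(uncovered, 5), collapse = ", "),
         if (length(uncovered) > 5L) ", ..." else "")
  }
  z <- support_matrix(prior, genes = genes)
  z <- z[, colSums(z) > 0, drop = FALSE]
  tfs <- colnames(z)
  l <- length(tfs)
  m <- ncol(e)

  report <- check_identifiability(connectivity_prior(
    prior$support[prior$support$gene %in% genes & prior$support$tf %in% tfs, ]
  ), n_samples = m)
  if (!report$criterion_i || !all(report$criterion_ii)) {
    stop("connectivity prior fails structural identifiability; ",
         "see check_identifiability() / reduce_to_identifiable()")
  }
  if (!report$criterion_iii) {
    warning(sprintf(
      "fewer conditions (%d) than TFs (%d): criterion (iii) unmet, activity rows may be linearly dependent",
      m, l), call. = FALSE)
  }

  sig <- apply(z, 1L, function(row) paste(which(row), collapse = ","))
  blocks <- split(seq_len(nrow(z)), sig)
  block_tfs <- lapply(blocks, function(rows) which(z[rows[1L], ]))
  e_norm2 <- sum(e^2)

  best <- NULL
  restart_obj <- numeric(n_restarts)
  ridge_flag <- new.env()
  ridge_flag$hit <- FALSE
  for (r in seq_len(n_restarts)) {
    a0 <- with_seed(derive_seed(seed, r), {
      a <- matrix(0, nrow(z), l)
      a[z] <- rnorm(sum(z))
      a
    })
    p <- MASS::ginv(a0) %*% e
    a <- matrix(0, nrow(z), l, dimnames = list(genes, tfs))
    obj_prev <- Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      for (b in seq_along(blocks)) {
        rows <- blocks[[b]]
        s_idx <- block_tfs[[b]]
        a[rows, s_idx] <- solve_strength_block(e[rows, , drop = FALSE],
                                               p[s_idx, , drop = FALSE],
                                               ridge_flag)
      }
      p <- tryCatch(qr.coef(qr(a), e), error = function(err) NULL)
      if (is.null(p) || anyNA(p)) {
        ridge_flag$hit <- TRUE
        p <- solve(crossprod(a) + diag(1e-10, l), crossprod(a, e))
      }
      obj <- sum((e - a %*% p)^2)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          (obj_prev - obj) < tol * max(obj_prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    restart_obj[r] <- obj
    if (is.null(best) || obj < best$objective) {
      dimnames(p) <- list(tfs, colnames(e))
      best <- list(strengths = a, activities = p, objective = obj,
                   n_iter = it, converged = converged, trace = trace)
    }
  }
  if (ridge_flag$hit) {
    warning("singular least-squares subproblem; ridge fallback (lambda = 1e-10) used",
            call. = FALSE)
  }
  structure(c(best,
              list(restarts = restart_obj, e = e, prior = prior,
                   e_norm2 = e_norm2, identifiability = report)),
            class = "NCAResult")
}

#' @export
print.NCAResult <- function(x, ...) {
  cat(sprintf("NCAResult: %d genes x %d TFs x %d conditions\n",
              nrow(x$strengths), ncol(x$strengths), ncol(x$activities)))
  cat(sprintf("  objective ||E - AP||^2 = %.6g (relative %.3g), %d iterations, converged: %s\n",
              x$objective, x$objective / max(x$e_norm2, .Machine$double.eps),
              x$n_iter, x$converged))
  cat(sprintf("  restarts: %d, best/worst objective %.4g / %.4g\n",
              length(x$restarts), min(x$restarts), max(x$restarts)))
  invisible(x)
}

#' Resolve the diagonal scaling ambiguity of an NCA fit
#'
#' The decomposition E = A P is invariant under A -> A X, P -> X^-1 P for
#' any nonsingular diagonal X. This fixes the convention:
#' `"unit_max_activity"` rescales each TF so its peak |activity| is 1;
#' `"unit_norm_strength"` rescales each TF so its strength column has
#' unit Euclidean norm. The sign is fixed so that the TF's activity
#' correlates non-negatively with its own expression log-ratio when the
#' TF is a row of E, and otherwise so that the first non-zero activity
#' entry is positive. The objective is untouched and the operation is
#' idempotent.
#'
#' @param result An [fit_nca()] result.
#' @param convention `"unit_max_activity"` (default) or
#'   `"unit_norm_strength"`.
#' @param expression Optional log-ratio matrix (e.g. the unrestricted
#'   [make_log_ratios()] output) consulted, in addition to the rows of
#'   the fitted matrix, for each TF's own expression when fixing signs.
#'   Useful because TF transcripts are usually not rows of the fitted
#'   matrix.
#' @return The rescaled `NCAResult`.
#' @export
normalize_result <- function(result,
                             convention = c("unit_max_activity", "unit_norm_strength"),
                             expression = NULL) {
  convention <- match.arg(convention)
  a <- result$strengths
  p <- result$activities
  tfs <- rownames(p)
  tf_expr <- function(tf) {
    if (tf %in% rownames(result$e)) return(result$e[tf, colnames(p)])
    if (!is.null(expression) && tf %in% rownames(expression)) {
      return(expression[tf, colnames(p)])
    }
    NULL
  }
  scale <- vapply(seq_along(tfs), function(j) {
    mag <- if (convention == "unit_max_activity") {
      max(abs(p[j, ]))
    } else {
      1 / sqrt(sum(a[, j]^2))
    }
    if (convention == "unit_max_activity" && mag == 0) {
      stop("all-zero activity row for TF ", tfs[j])
    }
    if (convention == "unit_norm_strength" && !is.finite(mag)) {
      stop("all-zero strength column for TF ", tfs[j])
    }
    sgn <- 0
    expr <- tf_expr(tfs[j])
    if (!is.null(expr) && sd(expr) > 0 && sd(p[j, ]) > 0) {
      sgn <- sign(cor(p[j, ], expr))
    }
    if (sgn == 0) {
      nz <- p[j, ][p[j, ] != 0]
      sgn <- if (length(nz) > 0L) sign(nz[1L]) else 1
    }
    sgn * mag
  }, numeric(1))
  result$strengths <- sweep(a, 2L, scale, `*`)
  result$activities <- sweep(p, 1L, scale, `/`)
  result
}

#' Bootstrap confidence summaries for an NCA fit
#'
#' Resamples genes (rows of E) with replacement, refits the
#' decomposition on each resample whose support pattern still passes the
#' structural identifiability criteria (failing resamples are redrawn
#' and counted), aligns every refit by [normalize_result()], and returns
#' per-entry percentile summaries.
#'
#' @param e,prior,seed As in [fit_nca()].
#' @param B Number of bootstrap refits (>= 1).
#' @param n_restarts Restarts per refit (fewer than a final fit; each
#'   resample is a perturbation of a well-determined problem).
#' @param convention Normalization convention for alignment.
#' @param probs Percentiles to report.
#' @param ... Further arguments to [fit_nca()].
#' @return List with `activity_quantiles` (TF x condition x percentile
#'   array), `strength_quantiles` (gene x TF x percentile array, `NA`
#'   where a gene was absent from every resample), `n_redraws`, `B`.
#' @export
bootstrap_nca <- function(e, prior, B = 100L, seed = 1L, n_restarts = 3L,
                          convention = "unit_max_activity",
                          probs = c(0.025, 0.5, 0.975), ...) {
  if (B < 1L) stop("B must be >= 1")
  genes <- rownames(e)
  z <- support_matrix(prior, genes = genes)
  z <- z[, colSums(z) > 0, drop = FALSE]
  tfs <- colnames(z)
  act_draws <- array(NA_real_, c(length(tfs), ncol(e), B),
                     dimnames = list(tfs, colnames(e), NULL))
  str_draws <- array(NA_real_, c(length(genes), length(tfs), B),
                     dimnames = list(genes, tfs, NULL))
  n_redraws <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      idx <- with_seed(derive_seed(seed, b * 1000L + attempt), {
        sample(length(genes), replace = TRUE)
      })
      zu <- z[unique(idx), , drop = FALSE]
      ok <- generic_rank(zu) == ncol(zu) &&
        all(vapply(seq_len(ncol(zu)), function(j) {
          z2 <- zu[!zu[, j], -j, drop = FALSE]
          ncol(z2) == 0L || generic_rank(z2) == ncol(z2)
        }, logical(1)))
      if (ok) break
      n_redraws <- n_redraws + 1L
      if (attempt > 2L * B + 10L || n_redraws > B) {
        stop("more than half of bootstrap resamples failed identifiability; ",
             "the support is too fragile to bootstrap by gene resampling")
      }
    }
    eb <- e[idx, , drop = FALSE]
    rownames(eb) <- sprintf("%s.%d", genes[idx], seq_along(idx))
    sb <- prior$support[prior$support$gene %in% genes[idx], , drop = FALSE]
    sb <- do.call(rbind, lapply(seq_along(idx), function(i) {
      si <- sb[sb$gene == genes[idx[i]], , drop = FALSE]
      if (nrow(si) > 0L) si$gene <- rownames(eb)[i]
      si
    }))
    fit <- suppressWarnings(
      fit_nca(eb, connectivity_prior(sb), n_restarts = n_restarts,
              seed = derive_seed(seed, b), ...)
    )
    fit <- normalize_result(fit, convention)
    act_draws[rownames(fit$activities), , b] <- fit$activities
    first_copy <- !duplicated(genes[idx])
    str_draws[genes[idx][first_copy], colnames(fit$strengths), b] <-
      fit$strengths[first_copy, ]
  }
  qfun <- function(v) if (all(is.na(v))) rep(NA_real_, length(probs)) else
    quantile(v, probs, na.rm = TRUE, names = FALSE)
  act_q <- apply(act_draws, c(1, 2), qfun)
  str_q <- apply(str_draws, c(1, 2), qfun)
  # move the percentile dimension last
  act_q <- aperm(act_q, c(2, 3, 1))
  str_q <- aperm(str_q, c(2, 3, 1))
  dimnames(act_q)[[3]] <- paste0("q", probs)
  dimnames(str_q)[[3]] <- paste0("q", probs)
  list(activity_quantiles = act_q, strength_quantiles = str_q,
       n_redraws = n_redraws, B = B)
}
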