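# End-to-end orchestration: DEG selection -> connectivity (prior +
# clustering augmentation + identifiability pruning) -> NCA -> activity
# analytics -> pathway enrichment -> stage-wise pathway crosstalk.

#' Build and validate a pipeline configuration
#'
#' @param expression,prior,ppi,pathways Paths to the input files: an
#'   expression TSV ([write_expression_tsv()] layout), a TF-target
#'   edge-list TSV, a PPI edge-list TSV, and a GMT pathway file. All must
#'   exist.
#' @param out_dir Output directory for stage artifacts (created).
#' @param fc_threshold,p_threshold,min_stages DEG selection thresholds.
#' @param r_augment Correlation threshold for prior augmentation.
#' @param r_pair Activity-correlation threshold for combinatorial TF
#'   pairs.
#' @param enrich_p,enrich_min_members Pathway-enrichment thresholds.
#' @param crosstalk_B Permutations per pathway pair per stage.
#' @param crosstalk_max_pairs At most this many pathway pairs are scored
#'   (pairs of the most significant enriched pathways first).
#' @param nca_restarts,nca_tol,nca_max_iter NCA fitting controls.
#' @param bootstrap_B Bootstrap refits (0 disables the bootstrap stage).
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(expression, prior, ppi, pathways, out_dir,
                            fc_threshold = 1.5, p_threshold = 0.05,
                            min_stages = 2L, r_augment = 0.8, r_pair = 0.6,
                            enrich_p = 0.1, enrich_min_members = 2L,
                            crosstalk_B = 2000L, crosstalk_max_pairs = 15L,
                            nca_restarts = 10L, nca_tol = 1e-8,
                            nca_max_iter = 2000L, bootstrap_B = 0L,
                            seed = 1L) {
  paths <- c(expression = expression, prior = prior, ppi = ppi,
             pathways = pathways)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  stopifnot(fc_threshold > 1, p_threshold > 0, p_threshold <= 1,
            min_stages >= 1L, r_augment > 0, r_augment < 1,
            r_pair > 0, r_pair < 1, enrich_p > 0, enrich_p <= 1,
            enrich_min_members >= 1L, crosstalk_B >= 1L,
            nca_restarts >= 1L, nca_tol > 0, bootstrap_B >= 0L)
  structure(list(expression = expression, prior = prior, ppi = ppi,
                 pathways = pathways, out_dir = out_dir,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 min_stages = min_stages, r_augment = r_augment,
                 r_pair = r_pair, enrich_p = enrich_p,
                 enrich_min_members = enrich_min_members,
                 crosstalk_B = crosstalk_B,
                 crosstalk_max_pairs = crosstalk_max_pairs,
                 nca_restarts = nca_restarts, nca_tol = nca_tol,
                 nca_max_iter = nca_max_iter, bootstrap_B = bootstrap_B,
                 seed = seed),
            class = "PipelineConfig")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(err) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(err)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing every artifact as deterministic
#' TSV/JSON into `config$out_dir` (reruns with the same configuration
#' and seed are byte-identical). A stage failure aborts with the stage
#' name while leaving completed artifacts intact.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a summary list (also written to `summary.json`):
#'   per-stage counts, thresholds, seed.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' paths <- write_study_files(simulate_study(seed = 1), dir)
#' cfg <- pipeline_config(paths$expression, paths$prior, paths$ppi,
#'                        paths$pathways, file.path(dir, "run"),
#'                        crosstalk_B = 200, seed = 1)
#' summary <- run_pipeline(cfg, quiet = TRUE)
#' }
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- function(f) file.path(config$out_dir, f)

  dataset <- run_stage("load", read_expression_tsv(config$expression))
  stages <- dataset_stages(dataset)
  say("loaded %d genes x %d samples, stages: %s",
      nrow(dataset$values), ncol(dataset$values),
      paste(stages, collapse = ", "))

  # -- differential expression ------------------------------------------
  de <- run_stage("deg", {
    de <- moderated_t_all_stages(dataset, stages)
    for (st in names(de)) {
      write_tsv(data.frame(de[[st]], row.names = NULL), out(sprintf("de_stage_%s.tsv", st)))
    }
    de
  })
  degs <- run_stage("deg", {
    degs <- select_degs(de, config$fc_threshold, config$p_threshold,
                        config$min_stages)
    writeLines(sort(degs), out("degs.txt"))
    degs
  })
  say("deg: %d genes selected", length(degs))

  # -- connectivity ------------------------------------------------------
  prior <- run_stage("connectivity", load_prior(config$prior))
  prior <- run_stage("connectivity", {
    tfs_in_data <- intersect(prior$tfs, rownames(dataset$values))
    extra <- if (length(tfs_in_data) > 0L && length(degs) > 0L) {
      augment_by_clustering(dataset, tfs_in_data, degs,
                            r_threshold = config$r_augment)
    } else NULL
    augmented <- augment_prior(prior, extra)
    # restrict targets to selected DEGs, then enforce identifiability
    keep <- augmented$support$gene %in% degs
    if (!any(keep)) stop("no prior edges onto the selected DEGs")
    restricted <- connectivity_prior(augmented$support[keep, , drop = FALSE])
    pruned <- reduce_to_identifiable(restricted, n_samples = length(stages) + 1L,
                                     enforce_iii = FALSE)
    write_prior_tsv(pruned, out("prior_pruned.tsv"))
    pruned
  })
  report <- check_identifiability(prior, n_samples = length(stages) + 1L)
  structurally_ok <- report$criterion_i && all(report$criterion_ii)
  say("connectivity: %d edges over %d TFs and %d genes (structurally identifiable: %s)",
      nrow(prior$support), length(prior$tfs), length(prior$genes),
      structurally_ok)

  # -- NCA ---------------------------------------------------------------
  fit <- run_stage("nca", {
    e_full <- make_log_ratios(dataset)
    e <- e_full[intersect(rownames(e_full), prior$genes), , drop = FALSE]
    fit <- suppressWarnings(
      fit_nca(e, prior, n_restarts = config$nca_restarts,
              tol = config$nca_tol, max_iter = config$nca_max_iter,
              seed = derive_seed(config$seed, 31L))
    )
    fit <- normalize_result(fit, expression = e_full)
    write_tsv(data.frame(gene = rownames(fit$strengths), fit$strengths,
                         check.names = FALSE), out("strengths.tsv"))
    write_tsv(data.frame(tf = rownames(fit$activities), fit$activities,
                         check.names = FALSE), out("activities.tsv"))
    jsonlite::write_json(
      list(objective = fit$objective,
           relative_objective = fit$objective / max(fit$e_norm2, .Machine$double.eps),
           n_iter = fit$n_iter, converged = fit$converged,
           restart_objectives = fit$restarts),
      out("nca_fit.json"), auto_unbox = TRUE, digits = NA)
    fit
  })
  say("nca: objective %.4g after %d iterations", fit$objective, fit$n_iter)

  if (config$bootstrap_B > 0L) {
    run_stage("nca_bootstrap", {
      bs <- bootstrap_nca(fit$e, prior, B = config$bootstrap_B,
                          seed = derive_seed(config$seed, 37L),
                          tol = config$nca_tol)
      jsonlite::write_json(
        list(B = bs$B, n_redraws = bs$n_redraws,
             activity_quantiles = bs$activity_quantiles,
             strength_quantiles = bs$strength_quantiles),
        out("nca_bootstrap.json"), auto_unbox = TRUE, digits = NA)
    })
  }

  # -- activity analytics ------------------------------------------------
  ppi <- run_stage("tfa_analysis", read_ppi_tsv(config$ppi))
  analytics <- run_stage("tfa_analysis", {
    expr_corr <- tfa_expression_correlation(fit, dataset)
    write_tsv(expr_corr, out("tfa_expression_correlation.tsv"))
    corr <- tfa_correlation_matrix(fit)
    write_tsv(data.frame(tf = rownames(corr), corr, check.names = FALSE),
              out("tfa_correlation_matrix.tsv"))
    pairs <- infer_combinatorial_pairs(corr, ppi, r_threshold = config$r_pair)
    write_tsv(pairs, out("combinatorial_pairs.tsv"))
    cl <- cluster_strengths(fit)
    write_tsv(data.frame(gene = names(cl$clusters), cluster = unname(cl$clusters),
                         major = unname(cl$clusters) %in% cl$major),
              out("strength_clusters.tsv"))
    if (!is.null(cl$tree)) write_dendrogram_newick(cl$tree, out("strength_dendrogram.nwk"))
    write_network_export(fit, out("network.graphml"), format = "graphml")
    write_network_export(fit, out("network.sif"), format = "sif")
    list(expr_corr = expr_corr, pairs = pairs, clusters = cl)
  })
  say("tfa: %d combinatorial pair(s), %d major cluster(s)",
      nrow(analytics$pairs), length(analytics$clusters$major))

  # -- enrichment --------------------------------------------------------
  pathways <- run_stage("enrichment", read_gmt(config$pathways))
  enriched <- run_stage("enrichment", {
    res <- suppressWarnings(hypergeometric_enrichment(degs, pathways))
    write_tsv(res[order(res$p, res$pathway), ], out("enrichment.tsv"))
    sig <- select_significant(res, config$enrich_p, config$enrich_min_members)
    write_tsv(sig, out("enrichment_significant.tsv"))
    sig
  })
  say("enrichment: %d significant pathway(s)", nrow(enriched))

  # -- crosstalk ---------------------------------------------------------
  xtalk <- run_stage("crosstalk", {
    cand <- if (nrow(enriched) >= 2L) enriched$pathway else names(pathways$pathways)
    pair_mat <- t(combn(sort(cand), 2L))
    pairs <- data.frame(pathway_a = pair_mat[, 1L], pathway_b = pair_mat[, 2L])
    if (nrow(pairs) > config$crosstalk_max_pairs) {
      pairs <- pairs[seq_len(config$crosstalk_max_pairs), , drop = FALSE]
    }
    tab <- crosstalk_dynamics(pairs, pathways, ppi, dataset, stages = stages,
                              B = config$crosstalk_B,
                              seed = derive_seed(config$seed, 41L))
    write_tsv(tab, out("crosstalk.tsv"))
    tab
  })
  say("crosstalk: %d pair-stage tests, %d significant at 0.1",
      nrow(xtalk), sum(xtalk$significant_0.1))

  summary <- list(
    seed = config$seed,
    thresholds = config[c("fc_threshold", "p_threshold", "min_stages",
                          "r_augment", "r_pair", "enrich_p",
                          "enrich_min_members", "crosstalk_B")],
    stages = stages,
    n_genes = nrow(dataset$values),
    n_samples = ncol(dataset$values),
    n_degs = length(degs),
    n_prior_edges = nrow(prior$support),
    n_prior_tfs = length(prior$tfs),
    n_prior_genes = length(prior$genes),
    identifiable = structurally_ok,
    nca_objective = fit$objective,
    nca_relative_objective = fit$objective / max(fit$e_norm2, .Machine$double.eps),
    n_combinatorial_pairs = nrow(analytics$pairs),
    n_major_clusters = length(analytics$clusters$major),
    n_significant_pathways = nrow(enriched),
    n_crosstalk_tests = nrow(xtalk),
    n_crosstalk_significant = sum(xtalk$significant_0.1)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(summary)
}

#' Write every file a simulated study produces
#'
#' Convenience for tests and examples: serializes a [simulate_study()]
#' result into the file layout [run_pipeline()] consumes.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created).
#' @return Named list of file paths (`expression`, `prior`, `ppi`,
#'   `pathways`, `truth`).
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                prior = file.path(dir, "prior.tsv"),
                ppi = file.path(dir, "ppi.tsv"),
                pathways = file.path(dir, "pathways.gmt"),
                truth = file.path(dir, "truth.json"))
  write_expression_tsv(study$dataset, paths$expression)
  write_prior_tsv(study$prior, paths$prior)
  write_ppi_tsv(study$ppi, paths$ppi)
  write_gmt(study$pathways, paths$pathways)
  jsonlite::write_json(
    list(seed = study$seed,
         phase_labels = as.list(study$truth$phase_labels),
         planted_degs = study$planted_degs,
         planted_pairs = study$planted_pairs,
         strengths = study$truth$strengths,
         activities = study$truth$activities),
    paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}
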