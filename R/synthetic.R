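# Synthetic-data generators. These emulate the inputs of the real
# analysis -- a TF-target prior with identifiable structure, phase-
# patterned TF activity time courses, log-linear replicated expression,
# a PPI graph with planted cross-pathway edge enrichment, and pathway
# gene sets -- so every pipeline stage can be exercised and validated
# against known ground truth.

#' Generate a sparse, identifiable TF-target connectivity prior
#'
#' Each TF receives one private "anchor" target gene that no other TF
#' regulates, plus further targets drawn from a shared pool (dealt
#' round-robin so the pool is covered before genes are reused). The
#' disjoint anchors guarantee by construction that the support pattern
#' passes all identifiability criteria testable without data: the anchor
#' rows embed an identity submatrix, which survives the removal of any
#' other TF together with its targets.
#'
#' @param n_genes Number of target genes (must be >= 2 * `n_tfs` so the
#'   anchors stay disjoint from a non-trivial shared pool).
#' @param n_tfs Number of transcription factors.
#' @param targets_per_tf Targets per TF (>= 2; one anchor + the rest from
#'   the pool).
#' @param seed Integer seed; the same seed reproduces the same edge set.
#' @return A [connectivity_prior()] with random `+`/`-` signs. The TF ids
#'   are `TF01, TF02, ...` and gene ids `G001, G002, ...`.
#' @examples
#' prior <- generate_connectivity(50, 10, 5, seed = 1)
#' check_identifiability(prior, n_samples = 12)
#' @export
generate_connectivity <- function(n_genes, n_tfs, targets_per_tf, seed) {
  if (n_genes < 2L * n_tfs) {
    stop(sprintf("infeasible parameters: n_genes (%d) must be >= 2 * n_tfs (%d) for disjoint anchors",
                 n_genes, n_tfs))
  }
  if (targets_per_tf < 2L) stop("targets_per_tf must be >= 2")
  with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    anchors <- sample(genes, n_tfs)
    pool <- setdiff(genes, anchors)
    if (targets_per_tf - 1L > length(pool)) {
      stop(sprintf("infeasible parameters: targets_per_tf - 1 (%d) exceeds the shared pool (%d genes)",
                   targets_per_tf - 1L, length(pool)))
    }
    extra_per_tf <- targets_per_tf - 1L
    # deal shuffled pool genes round-robin so coverage comes first
    dealt <- split(sample(pool), rep_len(seq_len(n_tfs), length(pool)))
    targets <- lapply(seq_len(n_tfs), function(j) {
      got <- head(dealt[[j]] %||% character(), extra_per_tf)
      need <- extra_per_tf - length(got)
      if (need > 0L) got <- c(got, sample(setdiff(pool, got), need))
      c(anchors[j], got)
    })
    support <- data.frame(
      gene = unlist(targets),
      tf = rep(tfs, lengths(targets))
    )
    support$sign <- sample(c("+", "-"), nrow(support), replace = TRUE)
    support$provenance <- "prior"
    prior <- connectivity_prior(support)
    # full gene universe, including genes no TF targets (null genes in
    # the generated expression data)
    attr(prior, "all_genes") <- genes
    prior
  })
}

#' Generate phase-patterned TF activity time courses
#'
#' Each TF is assigned an early, mid or late phase and given a
#' piecewise-linear peaked activity profile on the log scale: zero at
#' time 0 (profiles are normalized to the zero timepoint) and a
#' triangular peak of height ~ `amplitude` at the first, middle or last
#' non-zero timepoint respectively, with a random overall sign
#' (activation or deactivation) and a small multiplicative jitter.
#'
#' @param n_tfs Number of TFs.
#' @param timepoints Ordered vector of hours, must include 0.
#' @param phase_fractions Proportions of early/mid/late TFs (sums to 1).
#' @param amplitude Peak |activity| on the log2 scale.
#' @param seed Integer seed.
#' @return List with `activities` (TF x timepoint matrix, column "0" all
#'   zeros) and `phase_labels` (named character vector in
#'   `c("early", "mid", "late")`).
#' @export
generate_tfa_profiles <- function(n_tfs, timepoints = c(0, 4, 12, 24),
                                  phase_fractions = c(1, 1, 1) / 3,
                                  amplitude = 1, seed = 1L) {
  if (!0 %in% timepoints) stop("timepoints must include 0")
  stopifnot(length(phase_fractions) == 3L, all(phase_fractions >= 0))
  if (abs(sum(phase_fractions) - 1) > 1e-8) stop("phase_fractions must sum to 1")
  nz <- sort(timepoints[timepoints != 0])
  k <- length(nz)
  if (k < 3L && all(phase_fractions > 0)) {
    stop("need >= 3 non-zero timepoints to place early, mid and late phases")
  }
  with_seed(seed, {
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    counts <- floor(phase_fractions * n_tfs)
    while (sum(counts) < n_tfs) {
      i <- which.max(phase_fractions * n_tfs - counts)
      counts[i] <- counts[i] + 1L
    }
    phases <- sample(rep(c("early", "mid", "late"), counts))
    names(phases) <- tfs
    peak_idx <- c(early = 1L, mid = as.integer((k + 1L) %/% 2L), late = k)
    act <- matrix(0, n_tfs, length(timepoints),
                  dimnames = list(tfs, as.character(sort(timepoints))))
    for (j in seq_len(n_tfs)) {
      p <- peak_idx[[phases[j]]]
      shape <- 1 - abs(seq_len(k) - p) / k
      scale <- amplitude * runif(1, 0.9, 1.1) * sample(c(-1, 1), 1)
      act[j, as.character(nz)] <- scale * shape
    }
    list(activities = act, phase_labels = phases)
  })
}

#' Assemble a ground-truth object for expression generation
#'
#' Draws control strengths on the support of `prior` -- magnitudes
#' uniform on `strength_range`, signs taken from the prior's sign column
#' -- and bundles them with activity profiles.
#'
#' @param prior A [connectivity_prior()] (e.g. from
#'   [generate_connectivity()]).
#' @param profiles Output of [generate_tfa_profiles()] for the same TFs.
#' @param strength_range Magnitude range of the true control strengths.
#' @param tf_expression_coupling How strongly a TF's own mRNA follows its
#'   activity in the generated data (log2 units per activity unit).
#' @param seed Integer seed.
#' @return An object of class `SyntheticTruth`: `strengths` (gene x TF,
#'   zero off support), `activities` (TF x timepoint), `prior`,
#'   `phase_labels`, `tf_expression_coupling`, `seed`.
#' @export
synthetic_truth <- function(prior, profiles, strength_range = c(1, 2),
                            tf_expression_coupling = 0.9, seed = 1L) {
  stopifnot(setequal(prior$tfs, rownames(profiles$activities)))
  all_genes <- attr(prior, "all_genes") %||% prior$genes
  with_seed(seed, {
    z <- support_matrix(prior, genes = all_genes)
    a <- matrix(0, nrow(z), ncol(z), dimnames = dimnames(z))
    s <- prior$support
    sgn <- ifelse(s$sign == "-", -1, 1)
    mag <- runif(nrow(s), strength_range[1], strength_range[2])
    a[cbind(match(s$gene, rownames(a)), match(s$tf, colnames(a)))] <- sgn * mag
    structure(list(strengths = a,
                   activities = profiles$activities[colnames(a), , drop = FALSE],
                   prior = prior,
                   phase_labels = profiles$phase_labels,
                   tf_expression_coupling = tf_expression_coupling,
                   seed = seed),
              class = "SyntheticTruth")
  })
}

# True log2 effect (treated minus control) per expression row and
# timepoint: A.P for target genes, coupling * P for the TF genes' own
# transcripts, zero otherwise.
truth_effect_matrix <- function(truth) {
  ap <- truth$strengths %*% truth$activities
  tf_rows <- truth$tf_expression_coupling * truth$activities
  rbind(tf_rows, ap)
}

#' Generate a replicated two-arm expression dataset from a truth
#'
#' Log-linear generation: the treated-arm log2 expression of gene g at
#' time t is `baseline_g + effect[g, t] + N(0, noise_sd)` where the
#' effect matrix is the product of true strengths and activities (and,
#' for the TF genes themselves, coupling times their own activity); the
#' control arm is `baseline_g + N(0, noise_sd)`. Baselines are drawn once
#' per gene so fold changes are well defined. At `noise_sd = 0` the
#' per-gene log-ratio matrix equals the strength-activity product
#' exactly.
#'
#' Genes whose true |effect| clears both the fold-change threshold
#' `log2(1.5)` and `4 * noise_sd` in at least two non-zero stages are
#' recorded as planted differentially expressed genes.
#'
#' @param truth A [synthetic_truth()].
#' @param noise_sd Replicate noise standard deviation (log2 scale).
#' @param n_replicates Replicates per arm per timepoint.
#' @param seed Integer seed.
#' @return An [expression_dataset()] whose rows are the TF genes followed
#'   by the target genes, with attribute `planted_degs`.
#' @export
generate_expression <- function(truth, noise_sd = 0.1, n_replicates = 3L,
                                seed = 1L) {
  stopifnot(noise_sd >= 0, n_replicates >= 1L)
  effect <- truth_effect_matrix(truth)
  timepoints <- as.numeric(colnames(truth$activities))
  with_seed(seed, {
    genes <- rownames(effect)
    baseline <- rnorm(length(genes), mean = 8, sd = 1)
    names(baseline) <- genes
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        condition = c("treated", "control"),
                        time = timepoints,
                        stringsAsFactors = FALSE)
    grid$sample_id <- sprintf("%s_%gh_r%d", grid$condition, grid$time, grid$replicate)
    values <- vapply(seq_len(nrow(grid)), function(i) {
      eff <- if (grid$condition[i] == "treated") effect[, as.character(grid$time[i])] else 0
      baseline + eff + rnorm(length(genes), 0, noise_sd)
    }, numeric(length(genes)))
    dimnames(values) <- list(genes, grid$sample_id)
    ds <- expression_dataset(values, grid[, c("sample_id", "time", "condition", "replicate")])
    thr <- max(log2(1.5), 4 * noise_sd)
    nz <- as.character(timepoints[timepoints != 0])
    planted <- genes[rowSums(abs(effect[, nz, drop = FALSE]) >= thr) >= 2L]
    attr(ds, "planted_degs") <- planted
    ds
  })
}

#' Generate a PPI network and pathway gene sets with planted crosstalk
#'
#' Background protein-protein interaction edges are placed independently
#' with probability `edge_prob` over all gene pairs. Pathways are random
#' gene subsets of the requested size (overlapping by chance). For each
#' planted pathway pair, the probability of an edge between a gene
#' private to one pathway and a gene private to the other is multiplied
#' by `cross_edge_boost` (clamped at 1 with a warning), planting genuine
#' cross-pathway interaction enrichment. The graph is simple by
#' construction.
#'
#' @param genes Either a count (ids `P0001, ...` are invented) or a
#'   character vector of gene ids (e.g. the rows of an expression
#'   dataset, so the network can be weighted from data).
#' @param n_pathways,pathway_size Number and size of pathway gene sets.
#' @param n_planted_pairs Number of disjoint pathway pairs to plant
#'   crosstalk between.
#' @param cross_edge_boost Multiplier (>= 1) on cross-pathway edge
#'   probability for planted pairs; 1 means no planted signal.
#' @param edge_prob Background edge probability.
#' @param disjoint With `FALSE` (default) each pathway is an independent
#'   random subset, so pathways overlap by chance; with `TRUE` the
#'   pathways partition a sample of `n_pathways * pathway_size` genes and
#'   share no members (requires that many genes), which keeps planted
#'   cross-pathway signal from leaking into background pairs.
#' @param seed Integer seed.
#' @return List with `ppi` (data frame `from`/`to`), `pathways` (a
#'   [pathway_set()]), and `planted_pairs` (data frame `pathway_a`,
#'   `pathway_b`; zero rows when `n_planted_pairs = 0`).
#' @export
generate_ppi_pathways <- function(genes, n_pathways = 10L, pathway_size = 15L,
                                  n_planted_pairs = 2L, cross_edge_boost = 1,
                                  edge_prob = 0.005, disjoint = FALSE,
                                  seed = 1L) {
  if (length(genes) == 1L && is.numeric(genes)) {
    genes <- sprintf("P%04d", seq_len(genes))
  }
  n <- length(genes)
  stopifnot(cross_edge_boost >= 1, edge_prob > 0, edge_prob <= 1)
  if (pathway_size > n) stop("pathway_size exceeds the number of genes")
  if (2L * n_planted_pairs > n_pathways) {
    stop("not enough pathways for the requested number of disjoint planted pairs")
  }
  if (disjoint && n_pathways * pathway_size > n) {
    stop("disjoint pathways need n_pathways * pathway_size <= number of genes")
  }
  with_seed(seed, {
    pw_names <- sprintf("PW%02d", seq_len(n_pathways))
    if (disjoint) {
      picked <- sample(genes, n_pathways * pathway_size)
      pathways <- split(picked, rep(seq_len(n_pathways), each = pathway_size))
    } else {
      pathways <- lapply(pw_names, function(p) sample(genes, pathway_size))
    }
    names(pathways) <- pw_names
    planted <- data.frame(pathway_a = character(), pathway_b = character())
    if (n_planted_pairs > 0L) {
      idx <- sample(n_pathways, 2L * n_planted_pairs)
      planted <- data.frame(
        pathway_a = pw_names[idx[seq_len(n_planted_pairs)]],
        pathway_b = pw_names[idx[seq_len(n_planted_pairs) + n_planted_pairs]]
      )
      swap <- planted$pathway_a > planted$pathway_b
      tmp <- planted$pathway_a[swap]
      planted$pathway_a[swap] <- planted$pathway_b[swap]
      planted$pathway_b[swap] <- tmp
    }
    pairs <- combn(n, 2L)
    prob <- rep(edge_prob, ncol(pairs))
    if (nrow(planted) > 0L && cross_edge_boost > 1) {
      for (i in seq_len(nrow(planted))) {
        pa <- pathways[[planted$pathway_a[i]]]
        pb <- pathways[[planted$pathway_b[i]]]
        ia <- genes %in% setdiff(pa, pb)
        ib <- genes %in% setdiff(pb, pa)
        cross <- (ia[pairs[1L, ]] & ib[pairs[2L, ]]) |
                 (ib[pairs[1L, ]] & ia[pairs[2L, ]])
        prob[cross] <- prob[cross] * cross_edge_boost
      }
      if (any(prob > 1)) {
        warning(sum(prob > 1), " edge probabilities exceeded 1 and were clamped",
                call. = FALSE)
        prob[prob > 1] <- 1
      }
    }
    keep <- runif(ncol(pairs)) < prob
    ppi <- data.frame(from = genes[pairs[1L, keep]],
                      to = genes[pairs[2L, keep]])
    list(ppi = ppi,
         pathways = pathway_set(pathways, universe = genes),
         planted_pairs = planted)
  })
}

#' Simulate a complete study
#'
#' One call that generates every pipeline input with consistent ids: an
#' identifiable TF-target prior, phased activity profiles, a replicated
#' two-arm expression dataset over the TF and target genes, and a PPI
#' network plus pathway sets over the same gene universe.
#'
#' The defaults emulate the scale of a small time-course microarray
#' study: 3 replicates per arm at 0/4/12/24 h, an order of magnitude more
#' target genes than TFs, and log2 effects around 1.
#'
#' @param n_genes,n_tfs,targets_per_tf Connectivity parameters (see
#'   [generate_connectivity()]).
#' @param timepoints Hours, including 0.
#' @param amplitude Peak activity amplitude (log2 scale).
#' @param noise_sd,n_replicates Expression noise and replication.
#' @param n_pathways,pathway_size,n_planted_pairs,cross_edge_boost,edge_prob,disjoint_pathways
#'   PPI/pathway parameters (see [generate_ppi_pathways()];
#'   `disjoint_pathways` maps to its `disjoint` argument).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return List with `dataset`, `prior`, `truth`, `ppi`, `pathways`,
#'   `planted_pairs`, `planted_degs`, `seed`.
#' @examples
#' study <- simulate_study(seed = 1)
#' study$prior
#' length(study$planted_degs)
#' @export
simulate_study <- function(n_genes = 50L, n_tfs = 10L, targets_per_tf = 5L,
                           timepoints = c(0, 4, 12, 24), amplitude = 1,
                           noise_sd = 0.1, n_replicates = 3L,
                           n_pathways = 10L, pathway_size = 15L,
                           n_planted_pairs = 2L, cross_edge_boost = 1,
                           edge_prob = 0.005, disjoint_pathways = FALSE,
                           seed = 1L) {
  prior <- generate_connectivity(n_genes, n_tfs, targets_per_tf,
                                 seed = derive_seed(seed, 1L))
  profiles <- generate_tfa_profiles(n_tfs, timepoints = timepoints,
                                    amplitude = amplitude,
                                    seed = derive_seed(seed, 2L))
  truth <- synthetic_truth(prior, profiles, seed = derive_seed(seed, 3L))
  dataset <- generate_expression(truth, noise_sd = noise_sd,
                                 n_replicates = n_replicates,
                                 seed = derive_seed(seed, 4L))
  net <- generate_ppi_pathways(rownames(dataset$values),
                               n_pathways = n_pathways,
                               pathway_size = pathway_size,
                               n_planted_pairs = n_planted_pairs,
                               cross_edge_boost = cross_edge_boost,
                               edge_prob = edge_prob,
                               disjoint = disjoint_pathways,
                               seed = derive_seed(seed, 5L))
  list(dataset = dataset, prior = prior, truth = truth,
       ppi = net$ppi, pathways = net$pathways,
       planted_pairs = net$planted_pairs,
       planted_degs = attr(dataset, "planted_degs"),
       seed = seed)
}

#' Write a PPI edge list as TSV
#' @param ppi Data frame with columns `from`, `to`.
#' @param path Output path.
#' @export
write_ppi_tsv <- function(ppi, path) {
  write_tsv(ppi[order(ppi$from, ppi$to), c("from", "to")], path)
}

#' Read a PPI edge list from TSV
#' @param path Input path (two columns, header optional).
#' @return Data frame with columns `from`, `to`.
#' @export
read_ppi_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) %in% c("from", "gene_a")) df <- df[-1, , drop = FALSE]
  names(df)[1:2] <- c("from", "to")
  df[, c("from", "to")]
}
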