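crosstalk_fixture <- function(seed = 171, boost = 1, edge_prob = 0.01,
                              n_planted = 0) {
  simulate_study(n_genes = 120, n_tfs = 8, targets_per_tf = 4,
                 n_pathways = 10, pathway_size = 12,
                 n_planted_pairs = n_planted, cross_edge_boost = boost,
                 edge_prob = edge_prob, seed = seed)
}

test_that("edge score evaluates Fisher's combination and is strictly monotone", {
  expect_equal(edge_score(1, 1, 1), 0, tolerance = 1e-15)
  expect_equal(edge_score(0.05, 0.05, 0.05), -6 * log(0.05), tolerance = 1e-12)
  withr::with_seed(181, {
    p <- matrix(runif(3000, 1e-6, 1), ncol = 3)
    s <- edge_score(p[, 1], p[, 2], p[, 3])
    expect_true(all(s >= 0))
    shrunk <- edge_score(p[, 1], p[, 2], p[, 3] * 0.9)
    expect_true(all(shrunk > s))
  })
  expect_warning(s0 <- edge_score(0, 0.5, 0.5), "floored")
  expect_true(is.finite(s0))
  expect_error(edge_score(1.2, 0.5, 0.5), "<= 1")
  # Stouffer alternative is monotone too
  expect_gt(edge_score(0.01, 0.5, 0.5, method = "stouffer"),
            edge_score(0.5, 0.5, 0.5, method = "stouffer"))
})

test_that("network weighting reproduces the closed-form correlation test", {
  study <- crosstalk_fixture()
  net <- weight_network(study$ppi, study$dataset, stage = 4)
  s4 <- study$dataset$samples$sample_id[study$dataset$samples$time == 4]
  for (i in sample(nrow(net$edges), 5)) {
    ct <- cor.test(study$dataset$values[net$edges$from[i], s4],
                   study$dataset$values[net$edges$to[i], s4])
    expect_equal(net$edges$p_coexpr[i], ct$p.value, tolerance = 1e-10)
  }
  de <- moderated_t(study$dataset, 4)
  g <- net$nodes[1]
  expect_equal(unname(net$p_diff[g]), de$p[de$gene == g], tolerance = 1e-12)
  # score recomputable from the three p-values
  expect_equal(net$edges$score,
               edge_score(net$p_diff[net$edges$from], net$p_diff[net$edges$to],
                          net$edges$p_coexpr),
               tolerance = 1e-12, ignore_attr = TRUE)

  # perfectly correlated pair over 6 samples -> tiny p
  v <- study$dataset$values
  v["G001", s4] <- 2 * v["G002", s4] + 1
  ds2 <- expression_dataset(v, study$dataset$samples)
  net2 <- weight_network(data.frame(from = "G001", to = "G002"), ds2, 4)
  expect_lt(net2$edges$p_coexpr, 1e-6)
})

test_that("overlap C score matches a brute-force edge scan and ignores pair order", {
  study <- crosstalk_fixture(seed = 191, edge_prob = 0.03)
  net <- weight_network(study$ppi, study$dataset, stage = 12)
  pw <- study$pathways$pathways
  for (pair in list(c(1, 2), c(3, 7), c(5, 6))) {
    pi_ <- pw[[pair[1]]]; pj <- pw[[pair[2]]]
    got <- overlap_score(pi_, pj, net)
    manual <- 0
    for (i in seq_len(nrow(net$edges))) {
      x <- net$edges$from[i]; y <- net$edges$to[i]
      if ((x %in% pi_ && y %in% pj) || (x %in% pj && y %in% pi_)) {
        manual <- manual + net$edges$score[i]
      }
    }
    expect_equal(got$c_score, manual, tolerance = 1e-12)
    expect_equal(overlap_score(pj, pi_, net)$c_score, got$c_score,
                 tolerance = 1e-12)
  }
  # disjoint pathways with no cross edges
  empty <- overlap_score("nosuchgene1", "nosuchgene2", net)
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(empty$c_score, 0)
})

test_that("edges inside the pathway intersection qualify and count once", {
  net <- structure(list(
    nodes = c("a", "b", "c"),
    p_diff = c(a = 0.5, b = 0.5, c = 0.5),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                       p_coexpr = 0.5, score = c(10, 3))),
    class = "WeightedPPINetwork")
  # a and b are in both pathways; edge a-b lies inside the intersection
  res <- overlap_score(c("a", "b"), c("a", "b", "c"), net)
  expect_equal(res$c_score, 13)
  expect_identical(nrow(res$edges), 2L)
})

test_that("permutation p-values are seeded, bounded below, and direct for empty overlaps", {
  study <- crosstalk_fixture(seed = 201, boost = 20, edge_prob = 0.004,
                             n_planted = 2)
  net <- weight_network(study$ppi, study$dataset, stage = 4)
  univ <- intersect(unique(unlist(study$pathways$pathways)), net$nodes)
  pw <- study$pathways$pathways
  planted <- study$planted_pairs

  r1 <- permutation_pvalue(pw[[planted$pathway_a[1]]], pw[[planted$pathway_b[1]]],
                           net, B = 500, seed = 7, universe = univ)
  r2 <- permutation_pvalue(pw[[planted$pathway_a[1]]], pw[[planted$pathway_b[1]]],
                           net, B = 500, seed = 7, universe = univ)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 501)
  # the planted pair is enriched even in this tiny universe, where every
  # random 12-gene draw overlaps the pathways themselves; full planted-
  # pair power is exercised at scale in the acceptance suite
  expect_lte(r1$p_value, 0.15)

  empty <- permutation_pvalue("nosuchgene1", "nosuchgene2", net, B = 10, seed = 1)
  expect_true(empty$empty_overlap)
  expect_identical(empty$p_value, 1)
  expect_error(permutation_pvalue(pw[[1]], pw[[2]], net, B = 0, seed = 1),
               "B must be")
})

test_that("stage-wise dynamics keep per-pair seeds and flag absent pairs", {
  study <- crosstalk_fixture(seed = 211, edge_prob = 0.02)
  pairs <- data.frame(pathway_a = c("PW01", "PW03"),
                      pathway_b = c("PW02", "PW04"))
  tab <- crosstalk_dynamics(pairs, study$pathways, study$ppi, study$dataset,
                            B = 200, seed = 5)
  expect_identical(nrow(tab), 2L * length(dataset_stages(study$dataset)))
  expect_true(all(tab$p_value >= 1 / 201 & tab$p_value <= 1))
  expect_identical(tab$significant_0.1, tab$p_value < 0.1)
  tab2 <- crosstalk_dynamics(pairs, study$pathways, study$ppi, study$dataset,
                             B = 200, seed = 5)
  expect_identical(tab$p_value, tab2$p_value)

  expect_error(
    crosstalk_dynamics(pairs, study$pathways, study$ppi, study$dataset,
                       stages = c(4, 99), B = 10, seed = 1),
    "missing from the dataset")
  expect_error(
    crosstalk_dynamics(data.frame(pathway_a = "PW01", pathway_b = "NOPE"),
                       study$pathways, study$ppi, study$dataset, B = 10, seed = 1),
    "unknown pathway")
})
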