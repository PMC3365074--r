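# A hand-built NCAResult-shaped object is enough for the analytics.
fake_result <- function(activities, e = NULL) {
  structure(list(activities = activities,
                 strengths = NULL,
                 e = e %||% activities,
                 objective = 0),
            class = "NCAResult")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("activity-expression correlation reproduces direct Pearson values", {
  study <- simulate_study(noise_sd = 0, seed = 131)
  e <- make_log_ratios(study$dataset)
  fit <- suppressWarnings(fit_nca(e[study$prior$genes, ], study$prior,
                                  n_restarts = 2, seed = 1))
  fit <- normalize_result(fit)
  tab <- tfa_expression_correlation(fit, study$dataset)
  for (tf in tab$tf) {
    expect_equal(tab$r[tab$tf == tf],
                 cor(fit$activities[tf, colnames(e)], e[tf, ]),
                 tolerance = 1e-12)
  }
  # the generator couples TF transcripts to their activities, so the
  # recovered correlations should be strongly positive
  expect_gt(median(abs(tab$r)), 0.8)

  # hand cases via a synthetic activity/expression pairing
  act <- rbind(tfA = c(0, 1, 2, 3), tfB = c(0, -1, -2, -3))
  e2 <- rbind(tfA = c(0, 1, 2, 3), tfB = c(0, 1, 2, 3))
  colnames(act) <- colnames(e2) <- c("0", "4", "12", "24")
  # r of (0,1,2,3) against itself is 1; against its negation -1
  expect_equal(cor(act["tfA", ], e2["tfA", ]), 1)
  expect_equal(cor(act["tfB", ], e2["tfB", ]), -1)
  # worked example: activity (0,1,2,3) vs expression (0,1,1,2)
  expect_equal(cor(c(0, 1, 2, 3), c(0, 1, 1, 2)), 0.948683298, tolerance = 1e-8)
})

test_that("activity correlation matrix is symmetric, unit-diagonal and PSD", {
  act <- rbind(a = c(0, 1, 2, 1), b = c(0, 2, 4, 2), c = c(0, -1, 0.5, 2))
  colnames(act) <- c("0", "4", "12", "24")
  cc <- tfa_correlation_matrix(fake_result(act))
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc["a", "b"], 1)  # proportional activities
  expect_equal(cc["a", "c"], cor(act["a", ], act["c", ]), tolerance = 1e-12)
  expect_gte(min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  act2 <- rbind(a = c(0, 1, 2, 1), flat = c(1, 1, 1, 1))
  colnames(act2) <- colnames(act)
  expect_warning(cc2 <- tfa_correlation_matrix(fake_result(act2)), "constant")
  expect_true(all(is.na(cc2["flat", ])))
  expect_error(tfa_correlation_matrix(fake_result(act[, 1:2])), "3 conditions")
})

test_that("combinatorial pairs follow the three-way evidence rule and ignore TF order", {
  cc <- matrix(c(1, 0.7, 0.1,
                 0.7, 1, 0.65,
                 0.1, 0.65, 1), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ppi <- data.frame(from = c("b", "c"), to = c("a", "x"))
  pairs <- infer_combinatorial_pairs(cc, ppi, r_threshold = 0.6)
  key <- paste(pairs$tf_a, pairs$tf_b)
  expect_identical(pairs$evidence_class[key == "a b"], "both")
  expect_identical(pairs$evidence_class[key == "b c"], "correlation_only")
  expect_false("a c" %in% key)

  # PPI-only pair
  cc2 <- cc; cc2["a", "b"] <- cc2["b", "a"] <- 0.1
  p2 <- infer_combinatorial_pairs(cc2, ppi)
  expect_identical(p2$evidence_class[paste(p2$tf_a, p2$tf_b) == "a b"], "ppi_only")

  # invariance to row/column ordering of the correlation matrix
  ord <- c("c", "a", "b")
  p3 <- infer_combinatorial_pairs(cc[ord, ord], ppi)
  expect_equal(pairs[order(pairs$tf_a, pairs$tf_b), ],
               p3[order(p3$tf_a, p3$tf_b), ], ignore_attr = TRUE)
})

test_that("strength clustering merges identical rows first and finds planted blocks", {
  a <- rbind(g1 = c(1, 0, 2), g2 = c(1, 0, 2),           # identical pair
             g3 = c(-5, 4, 0), g4 = c(-5.1, 4.2, 0.1))
  res <- structure(list(strengths = a), class = "NCAResult")
  cl <- cluster_strengths(res, major_min = 1)
  m <- cl$tree$merge
  first <- m[1, ]
  expect_true(all(first < 0) && setequal(-first, match(c("g1", "g2"), rownames(a))))
  expect_equal(cl$tree$height[1], 0)

  # two well-separated planted blocks -> exactly 2 clusters at mid height
  withr::with_seed(141, {
    block1 <- matrix(rnorm(40, 5, 0.1), 10, 4)
    block2 <- matrix(rnorm(40, -5, 0.1), 10, 4)
    ab <- rbind(block1, block2)
    rownames(ab) <- sprintf("g%02d", 1:20)
    res2 <- structure(list(strengths = ab), class = "NCAResult")
    cl2 <- cluster_strengths(res2, major_min = 3)
    expect_identical(length(unique(cl2$clusters)), 2L)
    expect_identical(length(cl2$major), 2L)
    expect_identical(unname(cl2$clusters["g01"]), unname(cl2$clusters["g10"]))
    expect_false(cl2$clusters["g01"] == cl2$clusters["g11"])
  })

  single <- structure(list(strengths = a[1, , drop = FALSE]), class = "NCAResult")
  cs <- cluster_strengths(single)
  expect_null(cs$tree)
  expect_identical(unname(cs$clusters), 1L)
})

test_that("network exports round-trip through GraphML, SIF and Newick", {
  study <- simulate_study(noise_sd = 0, seed = 151)
  e <- make_log_ratios(study$dataset)
  fit <- suppressWarnings(fit_nca(e[study$prior$genes, ], study$prior,
                                  n_restarts = 2, seed = 1))
  fit <- normalize_result(fit)
  dir <- withr::local_tempdir()

  gml <- file.path(dir, "net.graphml")
  write_network_export(fit, gml, format = "graphml",
                       locations = data.frame(gene = study$prior$genes[1],
                                              location = "Nucleus"))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), sum(fit$strengths != 0))
  expect_setequal(unique(igraph::V(g)$node_type), c("TF", "gene"))
  expect_true("Nucleus" %in% igraph::V(g)$location)

  sif <- file.path(dir, "net.sif")
  write_network_export(fit, sif, format = "sif")
  lines <- readLines(sif)
  expect_length(lines, sum(fit$strengths != 0))
  expect_true(all(grepl("\t(activates|represses)\t", lines)))

  cl <- cluster_strengths(fit)
  nwk <- file.path(dir, "dend.nwk")
  write_dendrogram_newick(cl$tree, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, rownames(fit$strengths))
})
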