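# Small noiseless study reused across NCA tests.
nca_fixture <- function(seed = 101, noise_sd = 0) {
  study <- simulate_study(n_genes = 24, n_tfs = 4, targets_per_tf = 4,
                          noise_sd = noise_sd, seed = seed)
  e <- make_log_ratios(study$dataset)
  list(study = study, e = e[study$prior$genes, , drop = FALSE])
}

test_that("log ratios are reference-normalized means over replicates", {
  study <- simulate_study(seed = 111)
  e <- make_log_ratios(study$dataset)
  expect_true(all(e[, "0"] == 0))
  g <- rownames(e)[1]
  tr <- rowMeans(study$dataset$values[, arm_samples(study$dataset, 12, "treated"), drop = FALSE])
  ct <- rowMeans(study$dataset$values[, arm_samples(study$dataset, 12, "control"), drop = FALSE])
  tr0 <- rowMeans(study$dataset$values[, arm_samples(study$dataset, 0, "treated"), drop = FALSE])
  ct0 <- rowMeans(study$dataset$values[, arm_samples(study$dataset, 0, "control"), drop = FALSE])
  expect_equal(e[g, "12"], unname((tr - ct)[g] - (tr0 - ct0)[g]),
               tolerance = 1e-12)
  e_t0 <- make_log_ratios(study$dataset, reference = "t0")
  expect_equal(e_t0[g, "12"], unname((tr - tr0)[g]), tolerance = 1e-12)
})

test_that("a single-TF single-target problem factors exactly under the unit-max convention", {
  e <- matrix(c(0, 2, 4), 1, 3, dimnames = list("g1", c("0", "4", "12")))
  prior <- connectivity_prior(data.frame(gene = "g1", tf = "tf1"))
  fit <- suppressWarnings(fit_nca(e, prior, n_restarts = 2, seed = 1))
  fit <- normalize_result(fit)
  expect_equal(unname(fit$activities["tf1", ]), c(0, 0.5, 1), tolerance = 1e-10)
  expect_equal(unname(fit$strengths["g1", "tf1"]), 4, tolerance = 1e-10)
  expect_lt(fit$objective, 1e-16)
})

test_that("noiseless data is recovered to machine precision with truth-level activities", {
  fx <- nca_fixture()
  fit <- suppressWarnings(fit_nca(fx$e, fx$study$prior, n_restarts = 3, seed = 2))
  expect_lt(fit$objective, 1e-8 * sum(fx$e^2))
  for (tf in rownames(fit$activities)) {
    expect_gte(abs(cor(fit$activities[tf, ], fx$study$truth$activities[tf, ])),
               0.999)
  }
  # off-support entries are exactly zero
  z <- support_matrix(fx$study$prior, genes = rownames(fit$strengths))
  expect_true(all(fit$strengths[!z] == 0))
})

test_that("the ALS objective never increases within a restart", {
  fx <- nca_fixture(noise_sd = 0.15)
  fit <- suppressWarnings(fit_nca(fx$e, fx$study$prior, n_restarts = 3, seed = 3))
  expect_true(all(diff(fit$trace) <= 1e-10 * pmax(fit$trace[-length(fit$trace)], 1)))
})

test_that("permuting gene rows permutes strengths but not activities", {
  fx <- nca_fixture()
  fit1 <- suppressWarnings(fit_nca(fx$e, fx$study$prior, n_restarts = 2, seed = 4))
  perm <- rev(seq_len(nrow(fx$e)))
  fit2 <- suppressWarnings(fit_nca(fx$e[perm, ], fx$study$prior,
                                   n_restarts = 2, seed = 4))
  n1 <- normalize_result(fit1)
  n2 <- normalize_result(fit2)
  expect_equal(n1$activities, n2$activities, tolerance = 1e-6)
  expect_equal(n1$strengths[rownames(n2$strengths), ], n2$strengths,
               tolerance = 1e-6)
})

test_that("fitting refuses structurally unidentifiable priors and uncovered genes", {
  e <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("g1", "g2"), c("0", "4", "12", "24")))
  dup <- connectivity_prior(data.frame(gene = c("g1", "g2", "g1", "g2"),
                                       tf = c("a", "a", "b", "b")))
  expect_error(fit_nca(e, dup, seed = 1), "identifiability")
  ok <- connectivity_prior(data.frame(gene = "g1", tf = "a"))
  expect_error(fit_nca(e, ok, seed = 1), "without any regulator")
})

test_that("normalization preserves the objective, is idempotent, and fails on zero rows", {
  fx <- nca_fixture(noise_sd = 0.1)
  fit <- suppressWarnings(fit_nca(fx$e, fx$study$prior, n_restarts = 2, seed = 5))
  n1 <- normalize_result(fit)
  obj_recomputed <- sum((n1$e - n1$strengths %*% n1$activities)^2)
  expect_lt(abs(obj_recomputed - fit$objective), 1e-12 * max(fit$objective, 1))
  expect_equal(unname(apply(abs(n1$activities), 1, max)),
               rep(1, nrow(n1$activities)), tolerance = 1e-12)
  n2 <- normalize_result(n1)
  expect_equal(n2$strengths, n1$strengths, tolerance = 1e-14)
  expect_equal(n2$activities, n1$activities, tolerance = 1e-14)
  nn <- normalize_result(fit, "unit_norm_strength")
  expect_equal(unname(sqrt(colSums(nn$strengths^2))),
               rep(1, ncol(nn$strengths)), tolerance = 1e-12)

  broken <- fit
  broken$activities[1, ] <- 0
  expect_error(normalize_result(broken), rownames(fit$activities)[1])
})

test_that("ALS matches a gradient-based minimizer started from the truth on tiny problems", {
  withr::with_seed(121, {
    for (case in 1:3) {
      n_g <- 6; n_tf <- 3
      z <- random_pattern(n_g, n_tf, 0.5)
      # private target per TF for identifiability
      for (j in seq_len(n_tf)) {
        z[j, ] <- FALSE
        z[j, j] <- TRUE
      }
      prior <- pattern_to_prior(z)
      a_true <- matrix(0, n_g, n_tf)
      a_true[z] <- runif(sum(z), 1, 2) * sample(c(-1, 1), sum(z), TRUE)
      p_true <- matrix(rnorm(n_tf * 5), n_tf, 5)
      e <- a_true %*% p_true + matrix(rnorm(n_g * 5, 0, 0.1), n_g, 5)
      dimnames(e) <- list(sprintf("g%02d", 1:n_g), paste(1:5))

      fit <- suppressWarnings(fit_nca(e, prior, n_restarts = 5, seed = case))

      # oracle: BFGS on the free parameters, started at the truth
      nz <- which(z)
      objfun <- function(theta) {
        a <- matrix(0, n_g, n_tf); a[nz] <- theta[seq_along(nz)]
        p <- matrix(theta[-seq_along(nz)], n_tf, 5)
        sum((e - a %*% p)^2)
      }
      gradfun <- function(theta) {
        a <- matrix(0, n_g, n_tf); a[nz] <- theta[seq_along(nz)]
        p <- matrix(theta[-seq_along(nz)], n_tf, 5)
        r <- e - a %*% p
        ga <- -2 * (r %*% t(p))
        gp <- -2 * (t(a) %*% r)
        c(ga[nz], as.vector(gp))
      }
      opt <- optim(c(a_true[nz], as.vector(p_true)), objfun, gradfun,
                   method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
      expect_lt(fit$objective, opt$value * (1 + 1e-6) + 1e-12)
    }
  })
})

test_that("gene-resampled bootstrap is degenerate on noiseless data and seeded", {
  fx <- nca_fixture()
  bs <- bootstrap_nca(fx$e, fx$study$prior, B = 15, seed = 6)
  widths <- bs$activity_quantiles[, , "q0.975"] - bs$activity_quantiles[, , "q0.025"]
  expect_lt(max(widths, na.rm = TRUE), 1e-6)
  bs2 <- bootstrap_nca(fx$e, fx$study$prior, B = 15, seed = 6)
  expect_identical(bs$activity_quantiles, bs2$activity_quantiles)
  expect_error(bootstrap_nca(fx$e, fx$study$prior, B = 0, seed = 1), "B must be")
})
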