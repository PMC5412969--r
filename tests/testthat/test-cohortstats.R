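test_that("z-transform standardizes to mean 0, sample SD 1", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  x <- rlnorm(38)
  z <- z_transform(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(z_transform(rep(2, 10)), "zero variance")
  expect_error(z_transform(1), "length >= 2")
})

test_that("correlation-matrix PCA matches equicorrelation closed forms", {
  # sample correlation matrix constructed to be exactly equicorrelated at
  # r = 0.65: lambda1 = 1 + 2r = 2.30, explaining 76.67% -> "77%"
  sigma <- matrix(0.65, 3, 3); diag(sigma) <- 1
  x <- make_exact_cor_data(38, sigma, seed = 2)
  p <- pca_composite(x)
  expect_equal(p$eigenvalues[1], 2.30, tolerance = 1e-10)
  expect_equal(sum(p$eigenvalues), 3, tolerance = 1e-10)
  expect_equal(p$pct_variance_pc1, 230 / 3, tolerance = 1e-10)
  expect_equal(round_half_up(p$pct_variance_pc1), 77)
  # equicorrelation: loadings are equal and positive
  expect_equal(p$loadings, rep(sqrt(2.30 / 3), 3), tolerance = 1e-8)
  expect_equal(mean(p$scores), 0, tolerance = 1e-10)

  # independent columns: eigenvalues near 1, PC1 ~ 1/3 of variance
  x0 <- make_exact_cor_data(38, diag(3), seed = 3)
  p0 <- pca_composite(x0)
  expect_equal(p0$eigenvalues, rep(1, 3), tolerance = 1e-10)
  expect_equal(p0$pct_variance_pc1, 100 / 3, tolerance = 1e-8)
})

test_that("PCA composite is invariant to column order up to sign fix", {
  set.seed(8)
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 31)
  x <- co[c("nart_raw", "towre_swe_raw", "towre_pde_raw")]
  p1 <- pca_composite(x)
  p2 <- pca_composite(x[c(3, 1, 2)])
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)
  expect_equal(sort(p1$loadings), sort(p2$loadings), tolerance = 1e-10)
  expect_true(all(p1$loadings > 0))
})

test_that("PCA rejects degenerate inputs", {
  x <- cbind(a = 1:10, b = rnorm(10), c = rnorm(10))
  x[, "a"] <- 5
  expect_error(pca_composite(x), "constant")
  y <- cbind(a = 1:10, b = 2 * (1:10), c = rnorm(10))
  expect_warning(pca_composite(y), "perfectly correlated")
  expect_error(pca_composite(cbind(1:10, 1:10)), "3 score columns")
  expect_error(pca_composite(matrix(rnorm(9), 3, 3)), "more than 3")
})

test_that("variance_explained is the eigenvalue share", {
  expect_equal(variance_explained(2.30, 3), 76.66667, tolerance = 1e-6)
  expect_equal(round_half_up(variance_explained(2.30, 3)), 77)
  expect_equal(variance_explained(3, 3), 100)
  expect_equal(variance_explained(0.49, 3), 16.33333, tolerance = 1e-5)
  expect_error(variance_explained(3.5, 3), "eigenvalue")
})

test_that("normality gate has the right size and power", {
  # size: standard normal samples pass the gate in >= 90% of seeds
  par_rate <- mean(vapply(1:100, function(s) {
    set.seed(s)
    normality_gate(rnorm(38))$method == "parametric"
  }, logical(1)))
  expect_gte(par_rate, 0.9)
  # power: strongly right-skewed samples are gated to rank
  rank_rate <- mean(vapply(1:100, function(s) {
    set.seed(s)
    normality_gate(rlnorm(38, sdlog = 1))$method == "rank"
  }, logical(1)))
  expect_gte(rank_rate, 0.9)
  # degenerate gates
  set.seed(1)
  expect_equal(normality_gate(rnorm(38), alpha = 0)$method, "parametric")
  expect_warning(g <- normality_gate(rep(1, 10)), "constant")
  expect_equal(g$method, "rank")
})

test_that("semipartial matches a brute-force two-step oracle", {
  # 6-row worked table
  x <- c(1.2, -0.5, 0.3, 2.0, -1.1, 0.8)
  y <- c(0.9, -0.2, 0.1, 1.5, -0.9, 0.4)
  z <- cbind(c(1, 0, 1, 0, 1, 0), c(0.2, -1.3, 0.5, 1.8, -0.7, 0.1))
  sp <- semipartial(x, y, z, method = "pearson")
  expect_equal(sp$estimate, semipartial_oracle(x, y, z), tolerance = 1e-12)
  expect_equal(sp$df, 6 - 2 - 2)
  # spearman = ranks first, then the same construction
  sps <- semipartial(x, y, z, method = "spearman")
  expect_equal(sps$estimate,
               semipartial_oracle(rank(x), rank(y), apply(z, 2, rank)),
               tolerance = 1e-12)
})

test_that("semipartial reduces to plain correlation without covariates", {
  set.seed(21)
  x <- rnorm(38); y <- 0.5 * x + rnorm(38)
  expect_equal(semipartial(x, y)$estimate, cor(x, y), tolerance = 1e-12)
  expect_equal(semipartial(x, y, method = "spearman")$estimate,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  # orthogonal covariates leave the coefficient unchanged
  z <- make_exact_cor_data(38, diag(2), seed = 5)
  zo <- z - cbind(1, x) %*% solve(crossprod(cbind(1, x)),
                                  crossprod(cbind(1, x), z))
  expect_equal(semipartial(x, y, zo)$estimate, cor(x, y),
               tolerance = 1e-10)
})

test_that("semipartial flags degenerate and rank-deficient inputs", {
  set.seed(2)
  z <- cbind(rnorm(20), rnorm(20))
  x <- 2 + z %*% c(0.5, -1)          # exact linear function of covariates
  y <- rnorm(20)
  sp <- semipartial(as.numeric(x), y, z)
  expect_true(sp$degenerate)
  expect_equal(sp$estimate, 0)
  expect_error(semipartial(rnorm(20), y, cbind(z, z[, 1])), "rank-deficient")
})

test_that("spearman semipartial is invariant under monotone transforms", {
  set.seed(33)
  x <- rnorm(38); y <- -0.4 * x + rnorm(38)
  z <- cbind(rnorm(38), rbinom(38, 1, 0.2))
  base <- semipartial(x, y, z, method = "spearman")$estimate
  expect_equal(semipartial(exp(x), y, z, "spearman")$estimate, base,
               tolerance = 1e-12)
  expect_equal(semipartial(x, y^3 + 2 * y, z, "spearman")$estimate, base,
               tolerance = 1e-12)
  expect_equal(semipartial(x, y, cbind(qnorm(pnorm(z[, 1])), z[, 2]),
                           "spearman")$estimate, base, tolerance = 1e-10)
})

test_that("cohort analysis emits the full 10-row gated report", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 91)
  res <- analyze_cohort(co)
  rep_ <- res$report
  expect_equal(nrow(rep_), 10)
  expect_equal(sum(rep_$predictor == "reading_composite"), 8)
  expect_equal(sum(rep_$predictor == "nonverbal_iq"), 2)
  expect_true(all(abs(rep_$estimate) <= 1))
  expect_true(all(rep_$method %in% c("pearson", "spearman")))
  # the gate decides the method
  for (i in seq_len(nrow(rep_))) {
    expect_equal(rep_$method[i],
                 if (rep_$normality_p[i] < 0.05) "spearman" else "pearson")
  }
  expect_error(analyze_cohort(co[1:3, ]), "at least 4")
  expect_error(analyze_cohort(co[-match("form_slope", names(co))]),
               "missing columns")
})
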