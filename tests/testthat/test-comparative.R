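test_that("Brownian covariance has MRCA depths off-diagonal, tip depths on it", {
  V2 <- brownian_vcv(ape::read.tree(text = "(A:1,B:1);"))
  expect_equal(unname(V2), diag(2))
  V3 <- brownian_vcv(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(V3["A", "B"], 1)
  expect_equal(V3["A", "C"], 0)
  expect_equal(unname(diag(V3)), rep(2, 3))
})

test_that("lambda transform scales off-diagonals only; lambda 0 is a star", {
  V <- brownian_vcv(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  V0 <- lambda_transform(V, 0)
  expect_equal(unname(V0), diag(diag(V)))
  Vh <- lambda_transform(V, 0.5)
  expect_equal(Vh["A", "B"], 0.5)
  expect_equal(diag(Vh), diag(V))
})

test_that("PGLS at lambda 0 on an ultrametric tree equals OLS", {
  tr <- simulate_tree(40, 0.5, 0, seed = 21)
  set.seed(22)
  d <- data.frame(species = tr$tip.label, x = rnorm(40))
  d$y <- 1.5 + 2 * d$x + rnorm(40, sd = 0.5)
  fit <- pgls(y ~ x, d, tr, lambda = 0)
  ols <- lm(y ~ x, d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-8)
})

test_that("an exact linear relationship gives the exact slope and R2 = 1", {
  tr <- simulate_tree(20, 0.5, 0, seed = 31)
  set.seed(32)
  d <- data.frame(species = tr$tip.label, x = rnorm(20))
  d$y <- 3 - 0.7 * d$x
  for (lam in c(0, 0.5, 1)) {
    fit <- pgls(y ~ x, d, tr, lambda = lam)
    expect_equal(fit$coefficients["x", "estimate"], -0.7,
                 tolerance = 1e-8)
    expect_equal(fit$r_squared_raw, 1, tolerance = 1e-8)
  }
})

test_that("profile log-likelihood at the ML lambda dominates a grid", {
  tr <- simulate_tree(60, 0.4, 0.1, seed = 41)
  x <- simulate_bm_trait(tr, 1, seed = 42)
  y <- simulate_bm_trait(tr, 0.6, lambda_true = 0.7, beta = 1.2,
                         predictor = x, seed = 43)
  d <- data.frame(species = tr$tip.label, x = x, y = y)
  fit <- pgls(y ~ x, d, tr, lambda = "ML")
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_gte(fit$loglik + 1e-6, pgls(y ~ x, d, tr, lambda = lam)$loglik)
  }
})

test_that("PGLS estimates are invariant to row and tip ordering", {
  tr <- simulate_tree(25, 0.5, 0, seed = 51)
  x <- simulate_bm_trait(tr, 1, seed = 52)
  y <- simulate_bm_trait(tr, 1, beta = 0.8, predictor = x, seed = 53)
  d <- data.frame(species = tr$tip.label, x = x, y = y)
  f1 <- pgls(y ~ x, d, tr)
  shuf <- d[sample(nrow(d)), ]
  f2 <- pgls(y ~ x, shuf, tr)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  f3 <- pgls(y ~ x, d, tr2)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate)
  expect_equal(f1$coefficients$estimate, f3$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f1$lambda, f2$lambda)
})

test_that("PGLS agrees with an independent GLS implementation (corPagel)", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(80, 0.4, 0.1, seed = 61)
  x <- simulate_bm_trait(tr, 1, seed = 62)
  y <- simulate_bm_trait(tr, 0.5, lambda_true = 0.6, beta = 1.5,
                         predictor = x, seed = 63)
  d <- data.frame(species = tr$tip.label, x = x, y = y)
  fit <- pgls(y ~ x, d, tr, lambda = "ML")
  ref <- nlme::gls(y ~ x, data = d, method = "ML",
                   correlation = ape::corPagel(0.5, tr, form = ~species))
  lam_ref <- unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-4)
  expect_equal(fit$lambda, lam_ref, tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("PGLS errors on collinear designs and tiny samples", {
  tr <- simulate_tree(10, 0.5, 0, seed = 71)
  d <- data.frame(species = tr$tip.label, x = rnorm(10))
  d$x2 <- 2 * d$x
  d$y <- rnorm(10)
  expect_error(pgls(y ~ x + x2, d, tr, lambda = 0.5), "collinear")
  d3 <- d[1:2, ]
  expect_error(pgls(y ~ x, d3, tr), "fewer than 3")
})

test_that("species absent from the tree are dropped with a manifest", {
  tr <- simulate_tree(15, 0.5, 0, seed = 81)
  d <- data.frame(species = c(tr$tip.label, "ghost_species"),
                  x = rnorm(16))
  d$y <- d$x + rnorm(16, sd = 0.1)
  fit <- pgls(y ~ x, d, tr)
  expect_equal(fit$dropped, "ghost_species")
  expect_equal(fit$n, 15)
})

test_that("phylogenetic ANOVA is calibrated, deterministic and guarded", {
  tr <- simulate_tree(30, 0.5, 0, seed = 91)
  y <- simulate_bm_trait(tr, 1, seed = 92)
  set.seed(93)
  g <- sample(rep(c("a", "b", "c"), each = 10))
  r1 <- phylo_anova(y, g, tr, n_sim = 200, seed = 7)
  r2 <- phylo_anova(y, g, tr, n_sim = 200, seed = 7)
  expect_identical(r1, r2)
  expect_gt(r1$p_phylogenetic, 0)
  expect_lte(r1$p_phylogenetic, 1)
  expect_equal(length(r1$group_means), 3)
  expect_error(phylo_anova(y, rep("a", 30), tr), "2 groups")
  expect_error(phylo_anova(y, c("b", rep("a", 29)), tr), ">= 2 species")
})

test_that("phylogenetic ANOVA detects a 10-SD group separation", {
  tr <- simulate_tree(40, 0.5, 0, seed = 101)
  y <- simulate_bm_trait(tr, 1, seed = 102)
  g <- rep(c("lo", "hi"), each = 20)[rank(match(tr$tip.label,
                                                tr$tip.label))]
  g <- sample(rep(c("lo", "hi"), each = 20))
  y <- y + ifelse(g == "hi", 10 * sd(y), 0)
  r <- phylo_anova(y, g, tr, n_sim = 1000, seed = 11)
  expect_lte(r$p_phylogenetic, 0.001)
})

test_that("phylogenetic ANOVA F matches an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(24, 0.5, 0, seed = 111)
  y <- simulate_bm_trait(tr, 1, seed = 112)
  set.seed(113)
  g <- sample(rep(c("a", "b"), each = 12))
  names(g) <- names(y)
  mine <- phylo_anova(y, g, tr, n_sim = 500, seed = 5)
  ref <- phytools::phylANOVA(tr, factor(g), y, nsim = 500, posthoc = FALSE)
  expect_equal(mine$f_observed, ref$F, tolerance = 1e-8)
  expect_lt(abs(mine$p_phylogenetic - ref$Pf), 0.1)
})

test_that("posthoc pairwise matrix is symmetric with Holm-adjusted entries", {
  tr <- simulate_tree(30, 0.5, 0, seed = 121)
  y <- simulate_bm_trait(tr, 1, seed = 122)
  set.seed(123)
  g <- sample(rep(c("a", "b", "c"), each = 10))
  r <- phylo_anova(y, g, tr, n_sim = 200, seed = 3, posthoc = TRUE)
  expect_equal(dim(r$pairwise_p), c(3, 3))
  expect_equal(r$pairwise_p, t(r$pairwise_p))
  expect_true(all(r$pairwise_p[upper.tri(r$pairwise_p)] > 0))
})

test_that("variance partition fractions always sum to one exactly", {
  set.seed(131)
  for (i in 1:20) {
    n <- sample(6:60, 1)
    x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n); y <- x1 - x2 + rnorm(n)
    vp <- variance_partition(y, x1, x2)
    expect_lt(abs(vp$unique_x1 + vp$unique_x2 + vp$shared +
                    vp$unexplained - 1), 1e-10)
  }
})

test_that("duplicated predictors put all explained variance in shared", {
  set.seed(141)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30, sd = 0.3)
  vp <- variance_partition(y, x, x)
  expect_equal(vp$unique_x1, 0, tolerance = 1e-12)
  expect_equal(vp$unique_x2, 0, tolerance = 1e-12)
  expect_gt(vp$shared, 0.8)
})

test_that("orthogonal predictors leave (almost) nothing shared", {
  set.seed(151)
  x1 <- rnorm(200)
  x2 <- residuals(lm(rnorm(200) ~ x1))  # exactly orthogonal to x1
  y <- x1 + rnorm(200, sd = 0.5)
  vp <- variance_partition(y, x1, x2)
  expect_lt(abs(vp$shared), 0.02)
  expect_lt(abs(vp$unique_x2), 0.03)
  expect_gt(vp$unique_x1, 0.5)
})

test_that("variance partition matches vegan's adjusted-R2 varpart", {
  skip_if_not_installed("vegan")
  set.seed(161)
  x1 <- rnorm(80); x2 <- 0.6 * x1 + rnorm(80); y <- x1 + 0.5 * x2 + rnorm(80)
  vp <- variance_partition(y, x1, x2)
  ref <- vegan::varpart(y, ~x1, ~x2)$part$indfract$Adj.R.square
  # vegan's indfract rows: [a] = X1|X2, [b] = X2|X1, [c] shared, [d] resid
  expect_equal(vp$unique_x1, ref[1], tolerance = 1e-8)
  expect_equal(vp$unique_x2, ref[2], tolerance = 1e-8)
  expect_equal(vp$shared, ref[3], tolerance = 1e-8)
  expect_equal(vp$unexplained, ref[4], tolerance = 1e-8)
})

test_that("constant predictors are rejected", {
  expect_error(variance_partition(rnorm(10), rep(1, 10), rnorm(10)),
               "constant")
})
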