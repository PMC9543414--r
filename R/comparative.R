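#' Brownian-motion covariance of a phylogeny
#'
#' Entry (i, j) is the depth (from the root) of the most recent common
#' ancestor of tips i and j; the diagonal holds root-to-tip depths.
#'
#' @param tree rooted `ape::phylo` tree with branch lengths >= 0.
#' @return Symmetric n x n matrix, dimnames = tip labels.
#' @export
brownian_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. lambda = 1 is pure Brownian covariance; lambda = 0 the
#' star-tree (independent tips, variances = tip depths).
#'
#' @param vcv covariance matrix from [brownian_vcv()].
#' @param lambda value in [0, 1].
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(vcv, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  out <- vcv * lambda
  diag(out) <- diag(vcv)
  out
}

# Gaussian GLS fit at fixed V: coefficients, RSS, log-likelihood (full ML
# sigma2 = RSS/n, or REML). Uses a Cholesky whitening solve.
.gls_fit <- function(y, X, V, reml = FALSE) {
  n <- length(y)
  p <- ncol(X)
  L <- chol(V)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qr_ <- qr(Xw)
  if (qr_$rank < p) {
    bad <- colnames(X)[qr_$pivot[seq(qr_$rank + 1, p)]]
    stop("singular design under the phylogenetic covariance; ",
         "collinear columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_, yw)
  resw <- yw - Xw %*% beta
  rss <- sum(resw^2)
  ldetV <- 2 * sum(log(diag(L)))
  if (reml) {
    sigma2 <- rss / (n - p)
    XtX <- crossprod(Xw)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + ldetV +
                    determinant(XtX, logarithm = TRUE)$modulus[1] +
                    rss / sigma2)
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + ldetV + n)
  }
  list(beta = beta, rss = rss, sigma2 = sigma2, loglik = as.numeric(ll),
       qr = qr_, L = L, yw = yw, Xw = Xw)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits y = X beta + e, e ~ N(0, sigma2 V(lambda)) where V is the Brownian
#' covariance of the tree and V(lambda) its Pagel transform. With
#' `lambda = "ML"` the Gaussian profile log-likelihood is maximized over
#' lambda in [0, 1] by bounded scalar optimization (tolerance 1e-8).
#' Residual variance uses the full-ML estimator by default (`reml = TRUE`
#' switches to restricted ML). Coefficient t-tests use n - p degrees of
#' freedom; the reported R-squared is the adjusted R-squared of the
#' GLS-whitened model against the whitened intercept-only model.
#'
#' @param formula model formula, e.g. `dr ~ bsi`.
#' @param data data frame with a `species` column naming tree tips (matched
#'   via [match_species()]); species absent from the tree are dropped with
#'   a logged manifest (attribute `dropped`).
#' @param tree rooted `ape::phylo` tree.
#' @param lambda `"ML"` (default) or a fixed value in [0, 1].
#' @param reml logical; use restricted ML for the residual variance and
#'   lambda profile.
#' @return A `pgls_fit` list: `coefficients` table (estimate, SE, t, p),
#'   `lambda`, `loglik`, `r_squared` (adjusted), `sigma2`, `n`, `dropped`.
#' @export
pgls <- function(formula, data, tree, lambda = "ML", reml = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!"species" %in% names(data))
    stop("data needs a 'species' column naming tree tips")
  mm <- match_species(data$species, tree$tip.label)
  keep <- !is.na(mm$idx)
  dropped <- data$species[!keep]
  d <- data[keep, , drop = FALSE]
  tr <- ape::keep.tip(tree, mm$idx[keep])
  # align rows to the pruned tree's tip order
  idx2 <- match_species(d$species, tr$tip.label)$idx
  d <- d[order(idx2), , drop = FALSE]

  mf <- stats::model.frame(formula, d)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  if (n < 3) stop("fewer than 3 species after matching to the tree")
  V <- brownian_vcv(tr)

  obj <- function(lam) .gls_fit(y, X, lambda_transform(V, lam), reml)$loglik
  if (identical(lambda, "ML")) {
    opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-8)
    # optimize() never probes the exact endpoints; take them if better
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, obj(0), obj(1))
    lam_hat <- cand[which.max(ll)]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lam_hat <- lambda
  }
  Vl <- lambda_transform(V, lam_hat)
  fit <- .gls_fit(y, X, Vl, reml)
  p <- ncol(X)
  sig2_unb <- fit$rss / (n - p)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtXinv) * sig2_unb)
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)

  null_fit <- .gls_fit(y, matrix(1, n, 1), Vl, reml = FALSE)
  r2 <- 1 - fit$rss / null_fit$rss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p)

  coefs <- data.frame(estimate = as.numeric(fit$beta), se = as.numeric(se),
                      t = as.numeric(tval), p = as.numeric(pval),
                      row.names = colnames(X))
  structure(list(coefficients = coefs, lambda = lam_hat,
                 lambda_mode = if (identical(lambda, "ML")) "ML" else "fixed",
                 loglik = fit$loglik, sigma2 = fit$sigma2,
                 r_squared = r2_adj, r_squared_raw = r2, n = n,
                 reml = reml, formula = formula, dropped = dropped),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), " (n =", x$n, ")\n")
  cat(sprintf("  Pagel's lambda = %.4f (%s), logLik = %.3f, adj R^2 = %.3f\n",
              x$lambda, x$lambda_mode, x$loglik, x$r_squared))
  print(round(x$coefficients, 5))
  if (length(x$dropped) > 0)
    cat("  dropped (not on tree):", length(x$dropped), "species\n")
  invisible(x)
}

#' Simulation-based phylogenetic ANOVA
#'
#' Computes the ordinary one-way ANOVA F statistic of `y` across `groups`,
#' then builds its null distribution by simulating `n_sim` Brownian-motion
#' datasets on the tree (rate = maximum-likelihood estimate from the
#' observed response) and recomputing F for each. The p-value is the
#' add-one upper-tail proportion (1 + #\{F_sim >= F_obs\}) / (n_sim + 1).
#' Optional pairwise post-hoc tests compare group-pair t statistics with
#' their simulated distributions, with Holm adjustment.
#'
#' @param y named numeric response (names = tree tips) or numeric vector
#'   with `species` given separately via names.
#' @param groups factor/character of group labels, aligned with `y`.
#' @param tree rooted `ape::phylo` tree containing all species in `y`.
#' @param n_sim number of Brownian simulations (default 1000).
#' @param seed integer seed.
#' @param posthoc logical; compute the pairwise matrix.
#' @return A `phylo_anova_result` list: `f_observed`, `p_phylogenetic`,
#'   `n_sim`, `group_means`, `sigma2`, optional `pairwise_p`.
#' @export
phylo_anova <- function(y, groups, tree, n_sim = 1000, seed = 1L,
                        posthoc = FALSE) {
  stopifnot(inherits(tree, "phylo"), n_sim >= 1)
  if (is.null(names(y))) stop("y must be named by species")
  mm <- match_species(names(y), tree$tip.label)
  if (any(is.na(mm$idx)))
    stop("species absent from the tree: ",
         paste(names(y)[is.na(mm$idx)], collapse = ", "))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 species")
  tr <- ape::keep.tip(tree, mm$idx)
  ord <- match_species(tr$tip.label, names(y))$idx
  yv <- as.numeric(y)[ord]
  gv <- groups[ord]

  fstat <- function(vals) {
    gm <- tapply(vals, gv, mean)
    ssb <- sum(tabulate(gv) * (gm - mean(vals))^2)
    ssw <- sum((vals - gm[as.integer(gv)])^2)
    k <- nlevels(gv)
    (ssb / (k - 1)) / (ssw / (length(vals) - k))
  }
  f_obs <- fstat(yv)

  V <- brownian_vcv(tr)
  n <- length(yv)
  one <- rep(1, n)
  Vi_y <- solve(V, yv)
  Vi_1 <- solve(V, one)
  mu <- sum(Vi_y) / sum(Vi_1)
  sig2 <- as.numeric(crossprod(yv - mu, solve(V, yv - mu))) / n  # ML rate

  set.seed(as.integer(seed))
  Lt <- t(chol(V))
  Z <- matrix(stats::rnorm(n * n_sim), n, n_sim)
  Ysim <- sqrt(sig2) * (Lt %*% Z)          # location drops out of F
  f_sim <- apply(Ysim, 2, fstat)
  p <- (1 + sum(f_sim >= f_obs)) / (n_sim + 1)

  res <- list(f_observed = f_obs, p_phylogenetic = p, n_sim = n_sim,
              seed = as.integer(seed),
              group_means = tapply(yv, gv, mean), sigma2 = sig2)
  if (posthoc) {
    lev <- levels(gv)
    np <- length(lev)
    tstat <- function(vals, a, b) {
      ia <- gv == a; ib <- gv == b
      sp <- sqrt(((sum(ia) - 1) * stats::var(vals[ia]) +
                    (sum(ib) - 1) * stats::var(vals[ib])) /
                   (sum(ia) + sum(ib) - 2))
      (mean(vals[ia]) - mean(vals[ib])) /
        (sp * sqrt(1 / sum(ia) + 1 / sum(ib)))
    }
    pm <- matrix(NA_real_, np, np, dimnames = list(lev, lev))
    raw <- c()
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    for (pr in pairs) {
      t_obs <- abs(tstat(yv, pr[1], pr[2]))
      t_sim <- abs(apply(Ysim, 2, tstat, a = pr[1], b = pr[2]))
      raw <- c(raw, (1 + sum(t_sim >= t_obs)) / (n_sim + 1))
    }
    adj <- stats::p.adjust(raw, method = "holm")
    for (i in seq_along(pairs)) {
      pm[pairs[[i]][1], pairs[[i]][2]] <- adj[i]
      pm[pairs[[i]][2], pairs[[i]][1]] <- adj[i]
    }
    res$pairwise_p <- pm
  }
  class(res) <- "phylo_anova_result"
  res
}

#' @export
print.phylo_anova_result <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic ANOVA: F = %.3f, p = %.4g (%d Brownian simulations)\n",
    x$f_observed, x$p_phylogenetic, x$n_sim))
  cat("group means:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

#' Variance partitioning between two predictors (adjusted R-squared)
#'
#' Splits the variance of `y` explained by `x1` and `x2` from the adjusted
#' R-squared of the three ordinary regressions y~x1, y~x2, y~x1+x2:
#' unique_x1 = R2adj(both) - R2adj(x2); unique_x2 = R2adj(both) -
#' R2adj(x1); shared = R2adj(both) - unique_x1 - unique_x2; unexplained =
#' 1 - R2adj(both). The four fractions sum to 1 by construction; the shared
#' fraction can be negative (adjusted-R-squared arithmetic) and is reported
#' as-is.
#'
#' @param y,x1,x2 aligned numeric vectors, n >= 4.
#' @return A `variance_partition` list with `unique_x1`, `unique_x2`,
#'   `shared`, `unexplained`, and the three adjusted R-squared values.
#' @export
variance_partition <- function(y, x1, x2) {
  n <- length(y)
  stopifnot(length(x1) == n, length(x2) == n)
  if (n < 4) stop("need at least 4 observations")
  if (stats::var(x1) == 0 || stats::var(x2) == 0)
    stop("constant predictor")
  r2a <- function(fit) summary(fit)$adj.r.squared
  r1 <- r2a(stats::lm(y ~ x1))
  r2 <- r2a(stats::lm(y ~ x2))
  r12 <- r2a(stats::lm(y ~ x1 + x2))
  u1 <- r12 - r2
  u2 <- r12 - r1
  structure(list(unique_x1 = u1, unique_x2 = u2,
                 shared = r12 - u1 - u2, unexplained = 1 - r12,
                 r2_x1 = r1, r2_x2 = r2, r2_both = r12),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partition (adjusted R^2 fractions of the response):\n")
  cat(sprintf("  unique x1: %.4f  unique x2: %.4f  shared: %.4f  unexplained: %.4f\n",
              x$unique_x1, x$unique_x2, x$shared, x$unexplained))
  invisible(x)
}
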