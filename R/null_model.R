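#' One richness-constrained randomization of an occupancy matrix
#'
#' For each biome with observed richness R_b, exactly R_b distinct species
#' are marked present, drawn uniformly without replacement from the full
#' species pool, independently across biomes. Column sums therefore equal
#' the observed per-biome richness exactly, while row sums (species BSI)
#' are free to vary — species can end up in zero biomes.
#'
#' @param matrix an `occupancy_matrix`.
#' @return An `occupancy_matrix` with `allow_zero_rows = TRUE`.
#' @export
randomize_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "occupancy_matrix"))
  m <- unclass(matrix)
  n <- nrow(m)
  rich <- colSums(m)
  if (any(rich > n))
    stop("biome richness exceeds the number of species")
  out <- matrix(0L, n, ncol(m), dimnames = dimnames(m))
  for (b in seq_along(rich)) {
    if (rich[b] > 0)
      out[sample.int(n, rich[b]), b] <- 1L
  }
  occupancy_matrix(out, allow_zero_rows = TRUE)
}

# Per-rep statistics of one (randomized) binary matrix: counts of species
# per BSI class 0..K and per-biome specialist counts.
.matrix_stats <- function(m, nb) {
  bsi <- rowSums(m)
  list(bsi_counts = tabulate(bsi + 1L, nbins = nb + 1L),
       spec_counts = colSums(m[bsi == 1, , drop = FALSE]))
}

#' Monte Carlo null model for biomic specialization
#'
#' Randomizes the observed occupancy matrix `n_reps` times with
#' [randomize_matrix()] (per-biome richness fixed, memberships free),
#' records per-rep BSI class counts and per-biome specialist counts, and
#' compares the observed statistics with the simulated distributions using
#' add-one empirical p-values.
#'
#' BSI class 0 (species that received no presence in a randomization) is
#' tracked explicitly; observed-vs-simulated comparisons for classes
#' 1..10 are counts over all species, so per-rep class counts (including
#' class 0) always sum to the number of species.
#'
#' @param matrix observed `occupancy_matrix`.
#' @param n_reps number of randomizations (default 10000).
#' @param seed integer seed; the whole run is reproducible given it.
#' @return A `null_model_result` list:
#'   \describe{
#'     \item{observed}{observed BSI class counts (0..10) and per-biome
#'       specialist counts/proportions}
#'     \item{sim_bsi_counts}{n_reps x 11 matrix of per-rep class counts}
#'     \item{sim_specialists_per_biome}{n_reps x 10 matrix of per-rep
#'       specialist counts}
#'     \item{expected}{simulation means (and medians) per statistic}
#'     \item{pvalues}{two-sided empirical p per statistic}
#'     \item{direction}{sign of observed minus expected}
#'     \item{stars}{significance coding per statistic}
#'   }
#' @export
run_null_model <- function(matrix, n_reps = 10000, seed = 1L) {
  stopifnot(inherits(matrix, "occupancy_matrix"), n_reps >= 1)
  set.seed(as.integer(seed))
  m <- unclass(matrix)
  nb <- ncol(m)
  obs <- .matrix_stats(m, nb)
  rich <- colSums(m)

  sim_bsi <- matrix(0L, n_reps, nb + 1L,
                    dimnames = list(NULL, as.character(0:nb)))
  sim_spec <- matrix(0L, n_reps, nb, dimnames = list(NULL, colnames(m)))
  n <- nrow(m)
  r <- matrix(0L, n, nb)
  for (i in seq_len(n_reps)) {
    r[] <- 0L
    for (b in seq_len(nb)) {
      if (rich[b] > 0) r[sample.int(n, rich[b]), b] <- 1L
    }
    st <- .matrix_stats(r, nb)
    sim_bsi[i, ] <- st$bsi_counts
    sim_spec[i, ] <- st$spec_counts
  }

  exp_bsi <- colMeans(sim_bsi)
  exp_spec <- colMeans(sim_spec)
  p_bsi <- vapply(seq_len(nb + 1L), function(k)
    empirical_pvalue(obs$bsi_counts[k], sim_bsi[, k], "two-sided"),
    numeric(1))
  p_spec <- vapply(seq_len(nb), function(b)
    empirical_pvalue(obs$spec_counts[b], sim_spec[, b], "two-sided"),
    numeric(1))
  names(p_bsi) <- colnames(sim_bsi)
  names(p_spec) <- colnames(sim_spec)
  names(obs$bsi_counts) <- colnames(sim_bsi)
  names(obs$spec_counts) <- colnames(sim_spec)

  structure(list(
    n_reps = n_reps, seed = as.integer(seed),
    observed = list(
      bsi_counts = obs$bsi_counts,
      spec_counts = obs$spec_counts,
      spec_props = ifelse(rich > 0, obs$spec_counts / rich, 0)),
    richness = rich,
    sim_bsi_counts = sim_bsi,
    sim_specialists_per_biome = sim_spec,
    expected = list(
      bsi_counts = exp_bsi,
      bsi_counts_median = apply(sim_bsi, 2, stats::median),
      spec_counts = exp_spec,
      spec_props = ifelse(rich > 0, exp_spec / rich, 0)),
    pvalues = list(bsi_counts = p_bsi, spec_counts = p_spec),
    direction = list(bsi_counts = sign(obs$bsi_counts - exp_bsi),
                     spec_counts = sign(obs$spec_counts - exp_spec)),
    stars = list(bsi_counts = p_stars(p_bsi),
                 spec_counts = p_stars(p_spec))),
    class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat("Richness-constrained null model:", x$n_reps, "randomizations (seed",
      paste0(x$seed, ")\n"))
  tab <- data.frame(observed = x$observed$bsi_counts,
                    expected = round(x$expected$bsi_counts, 2),
                    p = signif(x$pvalues$bsi_counts, 3),
                    sig = x$stars$bsi_counts)
  cat("BSI class counts (class 0 = no biome in a randomization):\n")
  print(tab)
  invisible(x)
}

#' Add-one empirical p-value from a simulated null distribution
#'
#' Upper-tail p = (1 + #\{sim >= observed\}) / (n + 1); the lower tail is
#' analogous; the two-sided p is min(1, 2 min(upper, lower)). The add-one
#' correction means p can never be 0.
#'
#' @param observed observed statistic (scalar).
#' @param simulated numeric vector of per-rep simulated statistics.
#' @param tail "upper", "lower" or "two-sided" (default).
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, simulated,
                             tail = c("two-sided", "upper", "lower")) {
  tail <- match.arg(tail)
  if (length(simulated) < 1) stop("empty simulation vector")
  n <- length(simulated)
  up <- (1 + sum(simulated >= observed)) / (n + 1)
  lo <- (1 + sum(simulated <= observed)) / (n + 1)
  switch(tail,
         upper = up,
         lower = lo,
         `two-sided` = min(1, 2 * min(up, lo)))
}

#' Significance stars for p-values
#'
#' `***` for p < .001, `**` for .001 <= p < .01, `*` for .01 <= p < .05,
#' `n.s.` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "n.s.")))
}
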