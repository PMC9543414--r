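# Independent oracles and small fixtures shared across test files.

# Equal-splits by explicit root-path enumeration, carrying the split
# weight as an exact integer fraction (numerator/denominator) and only
# converting at the end. Independent of the package's traversal.
oracle_equal_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  nchild <- tabulate(tree$edge[, 1], nbins = ntip + tree$Nnode)
  es <- numeric(ntip)
  for (i in seq_len(ntip)) {
    # collect the full root path first, then weight each edge
    path <- integer(0)
    node <- i
    while (node != root) {
      path <- c(path, node)
      node <- parent[node]
    }
    num <- 1; den <- 1
    acc <- 0
    for (j in seq_along(path)) {
      if (j > 1) den <- den * nchild[path[j]]
      acc <- acc + elen[path[j]] * (num / den)
    }
    es[i] <- acc
  }
  names(es) <- tree$tip.label
  es
}

# Exact expected null-model statistics by exhaustive enumeration of all
# equally likely column assignments (feasible for <= 3 species x 3
# active biomes). Returns expected per-biome specialist counts and
# expected BSI class counts (classes 0..nb).
oracle_null_expected <- function(n_species, richness) {
  nb <- length(richness)
  col_choices <- lapply(richness, function(r) {
    if (r == 0) list(integer(0)) else
      utils::combn(n_species, r, simplify = FALSE)
  })
  grid <- expand.grid(lapply(col_choices, seq_along))
  spec_sum <- numeric(nb)
  bsi_sum <- numeric(n_species + 1)
  for (g in seq_len(nrow(grid))) {
    m <- matrix(0L, n_species, nb)
    for (b in seq_len(nb)) m[col_choices[[b]][[grid[g, b]]], b] <- 1L
    bsi <- rowSums(m)
    spec_sum <- spec_sum + colSums(m[bsi == 1, , drop = FALSE])
    bsi_sum <- bsi_sum + tabulate(bsi + 1L, nbins = n_species + 1)
  }
  list(spec_counts = spec_sum / nrow(grid),
       bsi_counts = bsi_sum / nrow(grid),
       n_assignments = nrow(grid))
}

# Build a 10-biome occupancy matrix from a compact species x k block
# (remaining biomes empty).
occ_from_block <- function(block, allow_zero_rows = FALSE) {
  n <- nrow(block)
  m <- matrix(0L, n, 10,
              dimnames = list(if (is.null(rownames(block)))
                sprintf("s%02d", seq_len(n)) else rownames(block),
                biome_codes()))
  m[, seq_len(ncol(block))] <- as.integer(block)
  occupancy_matrix(m, allow_zero_rows = allow_zero_rows)
}

# Wide overlap data frame from a named-fraction list per species.
overlap_from_list <- function(lst) {
  m <- matrix(0, length(lst), 10,
              dimnames = list(names(lst), biome_codes()))
  for (s in names(lst)) m[s, names(lst[[s]])] <- lst[[s]]
  overlap_table(data.frame(species = rownames(m), m, check.names = FALSE))
}

# Random tree of <= max_tips tips, sometimes with polytomies.
random_small_tree <- function(max_tips = 12, polytomy_prob = 0.3) {
  n <- sample(3:max_tips, 1)
  tr <- ape::rtree(n)
  if (stats::runif(1) < polytomy_prob) {
    tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.25))
  }
  tr$edge.length <- tr$edge.length + 1e-3  # keep paths strictly positive
  tr
}
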