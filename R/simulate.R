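# Forward-time birth-death engine with an optional binary state.
# Lineages are recorded as (parent, birth time, end time, state, alive);
# speciation ends the parent lineage and starts two daughters (fission),
# so every internal lineage has exactly two children and the pruned tree
# is strictly bifurcating. The run is taxa-stopped: when the extant count
# first reaches n_tips, the stopping epoch is drawn uniformly between that
# moment and the next event, which avoids conditioning the tree on an
# event happening exactly at the present.
.simulate_bd_engine <- function(n_tips, lambda, mu, q, root_state,
                                max_events = 2e5) {
  par <- integer(0); tb <- numeric(0); te <- numeric(0)
  st <- integer(0); alive <- logical(0)
  new_lin <- function(parent, t, state) {
    par[length(par) + 1L] <<- parent
    tb[length(tb) + 1L] <<- t
    te[length(te) + 1L] <<- NA_real_
    st[length(st) + 1L] <<- state
    alive[length(alive) + 1L] <<- TRUE
    length(par)
  }
  new_lin(0L, 0, root_state)  # crown lineages
  new_lin(0L, 0, root_state)
  t <- 0
  stop_time <- NA_real_
  for (ev in seq_len(max_events)) {
    ia <- which(alive)
    if (length(ia) == 0) return(NULL)          # clade died out
    rt <- lambda[st[ia] + 1L] + mu[st[ia] + 1L] + q[st[ia] + 1L]
    total <- sum(rt)
    dt <- stats::rexp(1, total)
    if (length(ia) >= n_tips) {                # first time at target size
      stop_time <- t + stats::runif(1) * dt
      break
    }
    t <- t + dt
    i <- ia[sample.int(length(ia), 1, prob = rt)]
    s <- st[i] + 1L
    u <- stats::runif(1) * (lambda[s] + mu[s] + q[s])
    if (u < lambda[s]) {                       # speciation
      te[i] <- t; alive[i] <- FALSE
      new_lin(i, t, st[i]); new_lin(i, t, st[i])
    } else if (u < lambda[s] + mu[s]) {        # extinction
      te[i] <- t; alive[i] <- FALSE
    } else {                                   # state flip
      st[i] <- 1L - st[i]
    }
  }
  if (is.na(stop_time)) stop("event budget exhausted in tree simulation")
  te[alive] <- stop_time
  list(par = par, tb = tb, te = te, st = st, alive = alive)
}

# Build a Newick string from the lineage table, pruning extinct subtrees
# and splicing unbranched paths.
.engine_to_newick <- function(eng) {
  kids <- split(seq_along(eng$par), eng$par)
  keep <- logical(length(eng$par))
  ord <- order(eng$tb, decreasing = TRUE)      # children before parents
  for (i in ord) {
    ch <- kids[[as.character(i)]]
    keep[i] <- eng$alive[i] || (!is.null(ch) && any(keep[ch]))
  }
  tip_id <- 0L
  tip_states <- integer(0)
  build <- function(i, extra) {
    len <- (eng$te[i] - eng$tb[i]) + extra
    ch <- kids[[as.character(i)]]
    ch <- ch[keep[ch]]
    if (length(ch) == 0) {
      tip_id <<- tip_id + 1L
      tip_states[tip_id] <<- eng$st[i]
      sprintf("t%d:%.10g", tip_id, len)
    } else if (length(ch) == 1) {
      build(ch, len)
    } else {
      sprintf("(%s,%s):%.10g", build(ch[1], 0), build(ch[2], 0), len)
    }
  }
  roots <- which(eng$par == 0L & keep)
  if (length(roots) == 1) {
    # one crown lineage died out entirely; remaining subtree is the tree
    txt <- paste0(sub(":[0-9.eE+-]+$", "", build(roots, 0)), ";")
  } else {
    txt <- sprintf("(%s,%s);", build(roots[1], 0), build(roots[2], 0))
  }
  list(newick = txt, states = tip_states)
}

#' Simulate an ultrametric birth-death tree with a fixed tip count
#'
#' Forward-time constant-rate birth-death simulation conditioned on
#' `n_tips` extant tips by rejection: runs in which the whole clade goes
#' extinct are discarded and redrawn (bounded retry budget). The result is
#' ultrametric by construction, with branch lengths in the same time unit
#' as the rates (Myr when rates are events/lineage/Myr).
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth speciation rate (> death).
#' @param death extinction rate (>= 0, default 0 = pure birth).
#' @param seed integer seed.
#' @param max_tries retry budget for whole-clade extinction.
#' @return An `ape::phylo` tree with exactly `n_tips` tips.
#' @export
simulate_tree <- function(n_tips, birth, death = 0, seed = 1L,
                          max_tries = 1000) {
  stopifnot(n_tips >= 2, birth > death, death >= 0)
  set.seed(as.integer(seed))
  for (k in seq_len(max_tries)) {
    eng <- .simulate_bd_engine(n_tips, c(birth, birth), c(death, death),
                               c(0, 0), 0L)
    if (!is.null(eng)) {
      out <- .engine_to_newick(eng)
      return(ape::read.tree(text = out$newick))
    }
  }
  stop("whole-clade extinction in every attempt; raise max_tries or birth")
}

#' Simulate a tree under two-state state-dependent diversification
#'
#' Forward-time binary-state birth-death process with state-specific
#' speciation (`lambda0`, `lambda1`) and extinction (`mu0`, `mu1`) rates
#' and anagenetic state flips at rates `q01` (0 to 1) and `q10`. Extinct
#' lineages are pruned; the run stops when `max_taxa` extant lineages are
#' reached (stopping epoch drawn uniformly within the final inter-event
#' interval). The state labels match the specialist/generalist coding used
#' downstream: state 1 = specialist, state 0 = generalist.
#'
#' @param max_taxa extant tip count at which to stop (>= 2).
#' @param lambda0,lambda1 speciation rates for states 0 and 1.
#' @param mu0,mu1 extinction rates.
#' @param q01,q10 transition rates.
#' @param root_state 0 or 1.
#' @param seed integer seed.
#' @param max_tries retry budget for whole-clade extinction.
#' @return List with `tree` (`ape::phylo`) and `states` (named 0/1 integer
#'   vector per tip).
#' @export
simulate_state_tree <- function(max_taxa, lambda0, lambda1, mu0 = 0,
                                mu1 = 0, q01 = 0, q10 = 0, root_state = 0,
                                seed = 1L, max_tries = 1000) {
  stopifnot(max_taxa >= 2, lambda0 >= 0, lambda1 >= 0, mu0 >= 0, mu1 >= 0,
            q01 >= 0, q10 >= 0, root_state %in% c(0, 1))
  set.seed(as.integer(seed))
  for (k in seq_len(max_tries)) {
    eng <- .simulate_bd_engine(max_taxa, c(lambda0, lambda1), c(mu0, mu1),
                               c(q01, q10), as.integer(root_state))
    if (!is.null(eng)) {
      out <- .engine_to_newick(eng)
      tr <- ape::read.tree(text = out$newick)
      states <- out$states
      names(states) <- paste0("t", seq_along(states))
      states <- states[tr$tip.label]
      return(list(tree = tr, states = states))
    }
  }
  stop("whole-clade extinction in every attempt; raise max_tries")
}

#' Simulate a Brownian trait with tunable phylogenetic signal
#'
#' Draws tip values from a multivariate normal with covariance
#' `sigma2 * V(lambda_true)` where V is the tree's Brownian covariance and
#' the lambda transform scales its off-diagonal. Optional fixed effects
#' `X %*% beta` are added on top, so the draw can serve as a regression
#' oracle with known slope and residual signal.
#'
#' @param tree `ape::phylo` tree.
#' @param sigma2 Brownian rate (>= 0; 0 gives every tip the root value).
#' @param lambda_true Pagel's lambda of the residual covariance, in [0, 1].
#' @param beta optional coefficient vector for `predictor`.
#' @param predictor optional numeric matrix/vector (rows = tips, tree tip
#'   order) of fixed-effect covariates.
#' @param root root (ancestral) value, default 0.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2, lambda_true = 1, beta = NULL,
                              predictor = NULL, root = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(tree$tip.label)
  y <- rep(root, n)
  if (sigma2 > 0) {
    V <- lambda_transform(brownian_vcv(tree), lambda_true)
    y <- y + as.numeric(t(chol(sigma2 * V)) %*% stats::rnorm(n))
  }
  if (!is.null(beta)) {
    X <- as.matrix(predictor)
    y <- y + as.numeric(X %*% beta)
  }
  names(y) <- tree$tip.label
  y
}

#' Simulate a right-skewed biome-occupancy dataset
#'
#' Generates an [overlap_table()] whose occupancy, after the inclusive
#' 15%-of-range / 50%-of-patch rules, matches the requested per-biome
#' richness targets exactly, with a BSI distribution whose right skew is
#' controlled by `theta`.
#'
#' Construction: each species gets a home biome (sampled against remaining
#' per-biome capacity); the remaining per-biome quota is then filled by
#' weighted sampling with species propensities drawn from a
#' Gamma(`theta`, 1) — small `theta` concentrates the extra presences on
#' few species (many specialists, a handful of strong generalists), large
#' `theta` spreads them evenly. Range fractions for the occupied biomes are
#' a Dirichlet(`theta`) draw conditioned on every occupied biome holding at
#' least 15% of the range; because at most 6 biomes can each hold >= 15% of
#' one range, species with more than 6 biomes carry their extra occupancies
#' as isolated-patch records with coverage >= 50%.
#'
#' @param n_species number of species.
#' @param richness_targets named or ordered length-10 integer vector of
#'   per-biome species richness; `sum(richness_targets)` must be >=
#'   `n_species` (every species needs a home) and every entry <=
#'   `n_species`.
#' @param theta concentration parameter (> 0) controlling BSI skew.
#' @param seed integer seed.
#' @param subfamily_split optional proportion in (0,1); labels that share
#'   of species "Parnassiinae" and the rest "Papilioninae" in the metadata
#'   (crude two-clade structure for subfamily-stratified runs).
#' @return An `overlap_table` with patches (when needed) and metadata
#'   (`area_km2` drawn log-normally, correlated with BSI).
#' @export
simulate_occupancy <- function(n_species, richness_targets, theta = 0.5,
                               seed = 1L, subfamily_split = NULL) {
  stopifnot(n_species >= 1, theta > 0, length(richness_targets) == 10)
  targets <- as.integer(round(richness_targets))
  if (any(targets < 0) || any(targets > n_species))
    stop("infeasible richness targets: each must lie in [0, n_species]")
  if (sum(targets) < n_species)
    stop("infeasible richness targets: sum must be >= n_species ",
         "(every species inhabits at least one biome)")
  if (sum(targets) > 10L * n_species)
    stop("infeasible richness targets: exceed total matrix capacity")
  set.seed(as.integer(seed))
  codes <- biome_codes()
  nb <- 10L

  # home biome per species, respecting per-biome capacity
  cap <- targets
  home <- integer(n_species)
  for (s in sample.int(n_species)) {
    if (all(cap == 0)) stop("infeasible richness targets: no home capacity")
    home[s] <- sample.int(nb, 1, prob = cap)
    cap[home[s]] <- cap[home[s]] - 1L
  }
  pres <- matrix(0L, n_species, nb,
                 dimnames = list(sprintf("sp%03d", seq_len(n_species)),
                                 codes))
  pres[cbind(seq_len(n_species), home)] <- 1L

  # fill remaining quota with propensity-weighted extra presences
  prop <- stats::rgamma(n_species, shape = theta, rate = 1) + 1e-12
  for (b in seq_len(nb)) {
    extra <- targets[b] - sum(pres[, b])
    if (extra > 0) {
      pool <- which(pres[, b] == 0L & rowSums(pres) < nb)
      if (length(pool) < extra)
        stop("infeasible richness targets: biome ", codes[b],
             " cannot reach its target")
      take <- pool[.weighted_sample(length(pool), extra, prop[pool])]
      pres[take, b] <- 1L
    }
  }

  # range fractions: occupied biomes share >= 0.15 each (at most 6 by
  # fractions; overflow occupancies become isolated-patch records)
  frac <- matrix(0, n_species, nb, dimnames = dimnames(pres))
  patch <- list()
  for (s in seq_len(n_species)) {
    occ <- which(pres[s, ] == 1L)
    k <- length(occ)
    if (k > 6) {
      main <- occ[seq_len(6)]
      for (b in occ[-seq_len(6)])
        patch[[length(patch) + 1L]] <- data.frame(
          species = rownames(pres)[s], biome = codes[b],
          patch_id = sprintf("p%d", b),
          patch_fraction = stats::runif(1, 0.5, 1))
      occ <- main
      k <- 6L
    }
    w <- stats::rgamma(k, shape = theta, rate = 1) + 1e-12
    frac[s, occ] <- 0.15 + (1 - 0.15 * k) * w / sum(w)
  }

  meta <- data.frame(
    species = rownames(pres),
    area_km2 = exp(stats::rnorm(n_species,
                                mean = 11 + 0.8 * log(rowSums(pres)),
                                sd = 1.2)),
    stringsAsFactors = FALSE)
  if (!is.null(subfamily_split)) {
    stopifnot(subfamily_split > 0, subfamily_split < 1)
    n_par <- round(subfamily_split * n_species)
    meta$subfamily <- c(rep("Parnassiinae", n_par),
                        rep("Papilioninae", n_species - n_par))
  }
  overlap_table(data.frame(species = rownames(frac), frac,
                           check.names = FALSE),
                patches = if (length(patch) > 0) do.call(rbind, patch),
                metadata = meta)
}

# weighted sampling without replacement (successive draws)
.weighted_sample <- function(n, size, w) {
  sample.int(n, size, replace = FALSE, prob = w)
}

#' Papilionid-like occupancy preset
#'
#' Study-scale conditions for the occupancy generator: 593 species across
#' the 10 biomes with a rainforest- and tropical-woodland-dominated
#' richness pattern whose total presence mass (990) pins the mean BSI at
#' 1.67, and a concentration `theta` calibrated so that the specialist
#' share falls in the mid-50% range with a handful of extreme generalists.
#'
#' @return List with `n_species`, `richness_targets`, `theta`.
#' @export
papilionid_preset <- function() {
  targets <- c(rainforest = 331, tropical_deciduous_woodland = 337,
               savannah = 25, subtropical_desert = 7,
               sclerophyllous_woodland = 46,
               temperate_evergreen_forest = 60,
               broadleaf_deciduous_forest = 120, steppe = 29,
               taiga = 23, tundra = 12)
  list(n_species = 593L, richness_targets = targets, theta = 0.5)
}
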