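#' Read and validate a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] and attaches a validation summary: duplicate tip
#' labels are an error; polytomies, zero-length pendant branches and
#' non-ultrametric root-to-tip depths (relative tolerance 1e-3) are
#' reported via warnings and the `validation` attribute, not errors — a
#' published time-calibrated tree may carry rounding jitter.
#'
#' @param path Newick file; branch lengths required.
#' @return An `ape::phylo` tree with attribute `validation` (list with
#'   `n_polytomies`, `zero_pendant_tips`, `ultrametric`, `depth_range`).
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  validate_phylogeny(tr)
}

#' Validate a phylogeny for tip-rate computation
#'
#' @param tr an `ape::phylo` object.
#' @return `tr` with a `validation` attribute; warns on polytomies,
#'   zero-length pendant edges and ultrametricity violations.
#' @export
validate_phylogeny <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths")
  if (any(tr$edge.length < 0))
    stop("negative branch lengths")
  ntip <- length(tr$tip.label)
  # root edge (if read from the file) is ignored throughout
  tr$root.edge <- NULL
  kids <- tabulate(tr$edge[, 1], nbins = ntip + tr$Nnode)
  n_poly <- sum(kids > 2)
  pend <- tr$edge[, 2] <= ntip
  zero_pend <- tr$tip.label[tr$edge[pend & tr$edge.length == 0, 2]]
  depths <- ape::node.depth.edgelength(tr)[seq_len(ntip)]
  ultra <- diff(range(depths)) <= 1e-3 * max(depths)
  if (n_poly > 0)
    warning(n_poly, " polytomies present; equal splits divides credit 1/c",
            call. = FALSE)
  if (length(zero_pend) > 0)
    warning("zero-length pendant branches: ",
            paste(zero_pend, collapse = ", "), call. = FALSE)
  if (!ultra)
    warning(sprintf(
      "tree not ultrametric (root-to-tip depth range %.6g..%.6g)",
      min(depths), max(depths)), call. = FALSE)
  attr(tr, "validation") <- list(n_polytomies = n_poly,
                                 zero_pendant_tips = zero_pend,
                                 ultrametric = ultra,
                                 depth_range = range(depths))
  tr
}

#' Equal-splits evolutionary isolation per tip
#'
#' For tip i with root-path edges e_1 (pendant), e_2, ..., e_N (rootmost),
#' ES_i = sum_j len(e_j) * w_j where w_1 = 1 and the weight is divided by
#' the number of daughters of each internal node passed on the way to the
#' root; on a strictly bifurcating tree ES_i = sum_j len(e_j) / 2^(j-1).
#' A node with c daughters contributes factor 1/c, generalizing the
#' bifurcating 1/2 to polytomies.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return Named numeric vector of ES scores (Myr on a time tree), one per
#'   tip.
#' @export
equal_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  elen <- numeric(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  nkids <- tabulate(tree$edge[, 1], nbins = nnode)
  root <- ntip + 1L
  es <- numeric(ntip)
  for (i in seq_len(ntip)) {
    w <- 1
    node <- i
    acc <- 0
    while (node != root) {
      acc <- acc + elen[node] * w
      node <- parent[node]
      if (node != root) w <- w / nkids[node]
    }
    if (acc <= 0)
      stop("tip with zero-length root path: ", tree$tip.label[i])
    es[i] <- acc
  }
  names(es) <- tree$tip.label
  es
}

#' DR tip-rate statistic
#'
#' The DR statistic is the inverse of the equal-splits evolutionary
#' isolation score, DR = 1/ES. It is a nonparametric per-tip summary of
#' recent diversification (events/lineage/Myr on a time-calibrated tree)
#' that up-weights branches and splitting events close to the present; on
#' ultrametric trees it is commonly read as a net diversification proxy.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return A `tip_rate_table` data frame with columns `species`, `es`, `dr`.
#' @export
dr_statistic <- function(tree) {
  es <- equal_splits(tree)
  if (any(es == 0)) stop("equal-splits score of 0; DR undefined")
  out <- data.frame(species = names(es), es = unname(es), dr = 1 / unname(es),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("tip_rate_table", "data.frame")
  out
}

#' Write a tip-rate table to CSV
#' @param x a `tip_rate_table`.
#' @param path output file.
#' @export
write_tip_rates_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match species identifiers between a table and a tree
#'
#' Exact match after trimming whitespace and normalizing internal
#' whitespace/underscores; unmatched species on either side are listed,
#' never silently dropped.
#'
#' @param species character vector of table identifiers.
#' @param tip_labels character vector of tree tip labels.
#' @return List with `idx` (positions of `species` in `tip_labels`, NA when
#'   absent), `unmatched_species`, `unmatched_tips`.
#' @export
match_species <- function(species, tip_labels) {
  norm <- function(x) gsub("[ _]+", "_", trimws(x))
  a <- norm(species)
  b <- norm(tip_labels)
  idx <- match(a, b)
  list(idx = idx,
       unmatched_species = species[is.na(idx)],
       unmatched_tips = tip_labels[!(b %in% a)])
}
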