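#' Build a range-biome overlap table
#'
#' The overlap table is the raw input of the occupancy stage: for every
#' species, the fraction of its geographical range that falls inside each of
#' the ten biomes, plus (optionally) per-patch coverage records used by the
#' isolated-patch rule, a range area in km^2 and a subfamily label.
#'
#' @param fractions data frame or matrix: either wide (one row per species,
#'   one column per biome, plus a `species` column or rownames) or long
#'   (columns `species`, `biome`, `range_fraction`). Biome labels are mapped
#'   through [match_biomes()].
#' @param patches optional data frame with columns `species`, `biome`,
#'   `patch_id`, `patch_fraction` — the fraction of that biome patch covered
#'   by the species, in [0, 1].
#' @param metadata optional data frame with column `species` and any of
#'   `area_km2`, `subfamily`.
#' @param extra_aliases passed to [match_biomes()].
#' @return An object of class `overlap_table`: a list with elements
#'   `fractions` (species x 10 numeric matrix, rows sum to <= 1 + 1e-6),
#'   `patches` (data frame or NULL) and `metadata` (data frame or NULL).
#' @export
overlap_table <- function(fractions, patches = NULL, metadata = NULL,
                          extra_aliases = NULL) {
  codes <- biome_codes()
  if (is.data.frame(fractions) &&
      all(c("species", "biome") %in% names(fractions))) {
    frac_col <- intersect(c("range_fraction", "fraction"), names(fractions))
    if (length(frac_col) == 0)
      stop("long-format fractions need a 'range_fraction' column")
    sp <- as.character(fractions$species)
    bio <- match_biomes(fractions$biome, extra_aliases)
    val <- as.numeric(fractions[[frac_col[1]]])
    usp <- unique(sp)
    m <- matrix(0, length(usp), length(codes),
                dimnames = list(usp, codes))
    m[cbind(match(sp, usp), match(bio, codes))] <- val
  } else {
    m <- as.matrix(fractions)
    if ("species" %in% colnames(m)) {
      rn <- m[, "species"]
      m <- m[, setdiff(colnames(m), "species"), drop = FALSE]
      storage.mode(m) <- "numeric"
      rownames(m) <- rn
    } else if (is.data.frame(fractions) && "species" %in% names(fractions)) {
      rn <- as.character(fractions$species)
      m <- as.matrix(fractions[setdiff(names(fractions), "species")])
      rownames(m) <- rn
    }
    storage.mode(m) <- "numeric"
    colnames(m) <- match_biomes(colnames(m), extra_aliases)
    if (anyDuplicated(colnames(m)))
      stop("duplicate biome columns after alias mapping")
    full <- matrix(0, nrow(m), length(codes),
                   dimnames = list(rownames(m), codes))
    full[, colnames(m)] <- m
    m <- full
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("species identifiers must be present and unique")
  if (anyNA(m)) m[is.na(m)] <- 0
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("range fraction outside [0,1] for ",
         paste(rownames(m)[bad[, 1]], colnames(m)[bad[, 2]],
               sep = "/", collapse = ", "))
  rs <- rowSums(m)
  if (any(rs > 1 + 1e-6))
    stop("per-species fractions sum to > 1 for: ",
         paste(rownames(m)[rs > 1 + 1e-6], collapse = ", "))
  if (!is.null(patches)) {
    need <- c("species", "biome", "patch_id", "patch_fraction")
    if (!all(need %in% names(patches)))
      stop("patches must have columns ", paste(need, collapse = ", "))
    patches$biome <- match_biomes(patches$biome, extra_aliases)
    pf <- patches$patch_fraction
    if (any(pf < 0 | pf > 1))
      stop("patch_fraction outside [0,1] for ",
           paste(patches$species[pf < 0 | pf > 1], collapse = ", "))
  }
  structure(list(fractions = m, patches = patches, metadata = metadata),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("Range-biome overlap table:", nrow(x$fractions), "species x",
      ncol(x$fractions), "biomes\n")
  if (!is.null(x$patches))
    cat("  patch-coverage records:", nrow(x$patches), "\n")
  if (!is.null(x$metadata))
    cat("  metadata columns:",
        paste(setdiff(names(x$metadata), "species"), collapse = ", "), "\n")
  invisible(x)
}

#' Read an overlap table from CSV files
#'
#' Accepts the wide layout (species + 10 biome columns) or the long layout
#' (species,biome,range_fraction), detected from the header.
#'
#' @param path CSV of range fractions.
#' @param patches_path optional CSV (species,biome,patch_id,patch_fraction).
#' @param metadata_path optional CSV (species, area_km2, subfamily, ...).
#' @inheritParams overlap_table
#' @return An `overlap_table`.
#' @export
read_overlap_csv <- function(path, patches_path = NULL, metadata_path = NULL,
                             extra_aliases = NULL) {
  fr <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  pa <- if (!is.null(patches_path))
    utils::read.csv(patches_path, comment.char = "#")
  me <- if (!is.null(metadata_path))
    utils::read.csv(metadata_path, comment.char = "#")
  overlap_table(fr, patches = pa, metadata = me, extra_aliases = extra_aliases)
}

#' Convert overlap fractions into binary biome occupancy
#'
#' A species occupies a biome if that biome holds at least `range_threshold`
#' (default 15%) of the species' range, or if the species covers at least
#' `patch_threshold` (default 50%) of an isolated patch of that biome. Both
#' boundaries are inclusive.
#'
#' Species that fail both rules in every biome are reported via the
#' `unplaced` attribute and excluded, unless `rescue_max_biome = TRUE`, in
#' which case each is assigned to its single largest-fraction biome.
#'
#' @param overlaps an [overlap_table()].
#' @param range_threshold minimum fraction of the species range, in (0, 1].
#' @param patch_threshold minimum fraction of an isolated biome patch
#'   covered, in (0, 1].
#' @param rescue_max_biome logical; fall back to the largest-fraction biome
#'   for species that fail both rules everywhere (default `FALSE`).
#' @return An `occupancy_matrix`: binary species x biome matrix with
#'   attributes `thresholds`, `unplaced` (character vector of species
#'   excluded or rescued) and `rescued`.
#' @export
apply_occupancy_rules <- function(overlaps, range_threshold = 0.15,
                                  patch_threshold = 0.50,
                                  rescue_max_biome = FALSE) {
  stopifnot(inherits(overlaps, "overlap_table"))
  if (!(range_threshold > 0 && range_threshold <= 1) ||
      !(patch_threshold > 0 && patch_threshold <= 1))
    stop("thresholds must lie in (0, 1]")
  m <- overlaps$fractions
  pres <- (m >= range_threshold) * 1L
  pa <- overlaps$patches
  if (!is.null(pa) && nrow(pa) > 0) {
    hit <- pa[pa$patch_fraction >= patch_threshold, , drop = FALSE]
    if (nrow(hit) > 0) {
      idx <- cbind(match(as.character(hit$species), rownames(m)),
                   match(hit$biome, colnames(m)))
      if (anyNA(idx[, 1]))
        stop("patch records for species absent from the fraction table: ",
             paste(unique(hit$species[is.na(idx[, 1])]), collapse = ", "))
      pres[idx] <- 1L
    }
  }
  empty <- rowSums(pres) == 0
  rescued <- character(0)
  if (any(empty)) {
    if (rescue_max_biome) {
      ix <- which(empty)
      best <- max.col(m[ix, , drop = FALSE], ties.method = "first")
      pres[cbind(ix, best)] <- 1L
      rescued <- rownames(m)[ix]
      empty[] <- FALSE
    } else {
      pres <- pres[!empty, , drop = FALSE]
    }
  }
  occupancy_matrix(pres,
                   thresholds = c(range = range_threshold,
                                  patch = patch_threshold),
                   unplaced = unname(rownames(m)[empty]),
                   rescued = unname(rescued))
}

#' Construct a binary occupancy matrix
#'
#' @param presence binary species x biome matrix; columns must match
#'   [biome_codes()] (any order / alias, remapped), rownames are species.
#' @param thresholds,unplaced,rescued optional provenance attributes.
#' @param allow_zero_rows logical; observed data must have every species in
#'   at least one biome, but randomized matrices may not (see
#'   [randomize_matrix()]).
#' @return An object of class `occupancy_matrix` (an integer 0/1 matrix).
#' @export
occupancy_matrix <- function(presence, thresholds = NULL,
                             unplaced = character(0),
                             rescued = character(0),
                             allow_zero_rows = FALSE) {
  m <- as.matrix(presence)
  storage.mode(m) <- "integer"
  if (is.null(colnames(m)))
    stop("presence matrix needs biome column names")
  colnames(m) <- match_biomes(colnames(m))
  m <- m[, match(biome_codes(), colnames(m)), drop = FALSE]
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("species rownames must be present and unique")
  if (!all(m %in% c(0L, 1L)))
    stop("presence entries must be 0 or 1")
  if (!allow_zero_rows && any(rowSums(m) == 0))
    stop("species with no biome occupancy: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  structure(m, class = c("occupancy_matrix", "matrix"),
            thresholds = thresholds, unplaced = unplaced, rescued = rescued)
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("Biome occupancy matrix:", nrow(x), "species x", ncol(x), "biomes\n")
  cat("  per-biome richness:",
      paste(colSums(unclass(x)), collapse = " "), "\n")
  th <- attr(x, "thresholds")
  if (!is.null(th))
    cat(sprintf("  thresholds: range >= %g, patch >= %g\n",
                th[["range"]], th[["patch"]]))
  un <- attr(x, "unplaced")
  if (length(un) > 0)
    cat("  unplaced species (failed both rules):",
        paste(un, collapse = ", "), "\n")
  invisible(x)
}

#' Read a binary occupancy matrix from a wide CSV
#'
#' @param path CSV with a `species` column and one 0/1 column per biome.
#' @param allow_zero_rows passed to [occupancy_matrix()].
#' @return An `occupancy_matrix`.
#' @export
read_occupancy_csv <- function(path, allow_zero_rows = FALSE) {
  d <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (!"species" %in% names(d)) stop("occupancy CSV needs a species column")
  m <- as.matrix(d[setdiff(names(d), "species")])
  rownames(m) <- as.character(d$species)
  occupancy_matrix(m, allow_zero_rows = allow_zero_rows)
}

#' Write an occupancy matrix to CSV
#'
#' The header carries the thresholds used as a comment line.
#' @param x an `occupancy_matrix`.
#' @param path output file.
#' @export
write_occupancy_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  th <- attr(x, "thresholds")
  if (!is.null(th))
    writeLines(sprintf("# occupancy thresholds: range >= %g, patch >= %g",
                       th[["range"]], th[["patch"]]), con)
  d <- data.frame(species = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Biomic specialization index (BSI) per species
#'
#' The BSI of a species is the number of biomes it inhabits — the row sum of
#' the binary occupancy matrix. Species are categorized as biome specialists
#' (BSI = 1), semi-generalists (1 < BSI < 5) or extreme generalists
#' (BSI >= 5).
#'
#' @param matrix an `occupancy_matrix` whose rows all have at least one
#'   presence.
#' @return A `bsi_profile`: data frame with columns `species`, `bsi`,
#'   `category`, and a `summary` attribute (mean BSI, class counts,
#'   category shares).
#' @export
compute_bsi <- function(matrix) {
  stopifnot(inherits(matrix, "occupancy_matrix"))
  bsi <- rowSums(unclass(matrix))
  if (any(bsi == 0))
    stop("species with all-zero occupancy rows: ",
         paste(rownames(matrix)[bsi == 0], collapse = ", "))
  prof <- data.frame(species = rownames(matrix), bsi = as.integer(bsi),
                     category = bsi_category(bsi),
                     row.names = NULL, stringsAsFactors = FALSE)
  counts <- tabulate(prof$bsi, nbins = ncol(matrix))
  names(counts) <- as.character(seq_len(ncol(matrix)))
  attr(prof, "summary") <- list(
    n_species = nrow(prof),
    mean_bsi = mean(prof$bsi),
    class_counts = counts,
    category_counts = table(factor(prof$category,
      levels = c("specialist", "semi-generalist", "extreme-generalist"))),
    category_shares = as.numeric(table(factor(prof$category,
      levels = c("specialist", "semi-generalist", "extreme-generalist")))) /
      nrow(prof))
  class(prof) <- c("bsi_profile", "data.frame")
  prof
}

#' Categorize BSI values
#' @param bsi integer vector of biome counts (>= 1).
#' @return character vector: "specialist", "semi-generalist" or
#'   "extreme-generalist".
#' @export
bsi_category <- function(bsi) {
  stopifnot(all(bsi >= 1))
  ifelse(bsi == 1, "specialist",
         ifelse(bsi < 5, "semi-generalist", "extreme-generalist"))
}

#' @export
print.bsi_profile <- function(x, ...) {
  s <- attr(x, "summary")
  cat("BSI profile:", s$n_species, "species, mean BSI",
      sprintf("%.3f", s$mean_bsi), "\n")
  cat("  specialists:", s$category_counts[["specialist"]],
      sprintf("(%.1f%%)", 100 * s$category_shares[1]),
      "| semi-generalists:", s$category_counts[["semi-generalist"]],
      "| extreme generalists:", s$category_counts[["extreme-generalist"]],
      "\n")
  invisible(x)
}

#' Per-biome specialist counts and proportions
#'
#' For each biome: the number of inhabitant species, the number of those
#' that are biome specialists (BSI = 1), and the specialist proportion.
#' Empty biome columns get proportion 0 and are flagged.
#'
#' @param matrix an `occupancy_matrix`.
#' @param profile the [compute_bsi()] profile derived from `matrix`.
#' @return Data frame with columns `biome`, `n_inhabitants`,
#'   `n_specialists`, `proportion_specialists`, `empty`.
#' @export
specialist_table <- function(matrix, profile) {
  stopifnot(inherits(matrix, "occupancy_matrix"),
            inherits(profile, "bsi_profile"))
  if (nrow(matrix) != nrow(profile) ||
      !all(rownames(matrix) == profile$species))
    stop("profile does not match the occupancy matrix rows")
  m <- unclass(matrix)
  n_inh <- colSums(m)
  spec <- profile$bsi == 1
  n_spec <- colSums(m[spec, , drop = FALSE])
  data.frame(
    biome = colnames(m),
    n_inhabitants = as.integer(n_inh),
    n_specialists = as.integer(n_spec),
    proportion_specialists = ifelse(n_inh > 0, n_spec / n_inh, 0),
    empty = n_inh == 0,
    row.names = NULL, stringsAsFactors = FALSE)
}
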