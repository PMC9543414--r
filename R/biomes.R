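#' The fixed ten-biome vocabulary
#'
#' Occupancy is scored against the ten global climatic-vegetation zones of
#' Walter's classification. The order returned here is fixed and used for
#' every matrix produced in one run, so column positions are comparable
#' across objects.
#'
#' @return Character vector of the 10 canonical biome codes, in fixed order.
#' @export
#' @examples
#' biome_codes()
biome_codes <- function() {
  c(
    "rainforest",                  # equatorial rainforest (warm-humid)
    "tropical_deciduous_woodland",
    "savannah",
    "subtropical_desert",          # warm-arid
    "sclerophyllous_woodland",
    "temperate_evergreen_forest",
    "broadleaf_deciduous_forest",
    "steppe",                      # cold-arid
    "taiga",                       # boreal coniferous forest
    "tundra"                       # cold-humid
  )
}

# Accepted input spellings, matched case-insensitively after squashing
# whitespace/hyphens to underscores. Keys are normalized aliases.
.biome_aliases <- function() {
  al <- c(
    "rainforest"                   = "rainforest",
    "equatorial_rainforest"        = "rainforest",
    "evergreen_equatorial_rainforest" = "rainforest",
    "i"                            = "rainforest",
    "tropical_deciduous_woodland"  = "tropical_deciduous_woodland",
    "tropical_deciduous_forest"    = "tropical_deciduous_woodland",
    "ii"                           = "tropical_deciduous_woodland",
    "savannah"                     = "savannah",
    "savanna"                      = "savannah",
    "ii_iii"                       = "savannah",
    "subtropical_desert"           = "subtropical_desert",
    "desert"                       = "subtropical_desert",
    "tropical_desert"              = "subtropical_desert",
    "iii"                          = "subtropical_desert",
    "sclerophyllous_woodland"      = "sclerophyllous_woodland",
    "sclerophyllous_woodland_and_shrubland" = "sclerophyllous_woodland",
    "mediterranean"                = "sclerophyllous_woodland",
    "iv"                           = "sclerophyllous_woodland",
    "temperate_evergreen_forest"   = "temperate_evergreen_forest",
    "laurel_forest"                = "temperate_evergreen_forest",
    "v"                            = "temperate_evergreen_forest",
    "broadleaf_deciduous_forest"   = "broadleaf_deciduous_forest",
    "broad_leaf_deciduous_forest"  = "broadleaf_deciduous_forest",
    "nemoral"                      = "broadleaf_deciduous_forest",
    "vi"                           = "broadleaf_deciduous_forest",
    "steppe"                       = "steppe",
    "vii"                          = "steppe",
    "taiga"                        = "taiga",
    "boreal_coniferous_forest"     = "taiga",
    "viii"                         = "taiga",
    "tundra"                       = "tundra",
    "ix"                           = "tundra"
  )
  al
}

.normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[\\s\\-]+", "_", x, perl = TRUE)
  x <- gsub("[^a-z0-9_]+", "_", x)
  gsub("^_+|_+$", "", gsub("_+", "_", x))
}

#' Map biome labels onto the canonical vocabulary
#'
#' Labels are matched case-insensitively after whitespace and hyphens are
#' collapsed to underscores; common synonyms (e.g. "desert",
#' "boreal coniferous forest", Walter's Roman numerals) are accepted.
#'
#' @param x character vector of biome labels as found in input files.
#' @param extra_aliases optional named character vector mapping additional
#'   input spellings (names) to canonical codes (values).
#' @return Character vector of canonical codes, same length as `x`.
#' @export
match_biomes <- function(x, extra_aliases = NULL) {
  al <- .biome_aliases()
  if (!is.null(extra_aliases)) {
    stopifnot(is.character(extra_aliases), !is.null(names(extra_aliases)))
    add <- stats::setNames(as.character(extra_aliases),
                           .normalize_label(names(extra_aliases)))
    if (!all(add %in% biome_codes()))
      stop("extra_aliases values must be canonical biome codes")
    al[names(add)] <- add
  }
  key <- .normalize_label(x)
  out <- unname(al[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown biome code(s): ", paste(bad, collapse = ", "))
  }
  out
}
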