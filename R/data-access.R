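#' Fetch the published swallowtail biome-occupancy dataset
#'
#' Downloads the deposited Papilionidae biome-occupancy database from the
#' Dryad Digital Repository (dataset doi:10.5061/dryad.sbcc2fr5b) and
#' returns the path of the downloaded archive. Requires network access;
#' the rest of the package is fully usable offline on synthetic or local
#' data.
#'
#' @param dest_dir directory to download into (default `tempdir()`).
#' @param quiet passed to [utils::download.file()].
#' @return Path to the downloaded archive.
#' @export
fetch_swallowtail_occupancy <- function(dest_dir = tempdir(),
                                        quiet = TRUE) {
  url <- paste0("https://datadryad.org/api/v2/datasets/",
                "doi%3A10.5061%2Fdryad.sbcc2fr5b/download")
  dest <- file.path(dest_dir, "swallowtail_occupancy.zip")
  status <- tryCatch(
    utils::download.file(url, dest, mode = "wb", quiet = quiet),
    error = function(e) stop("could not download the occupancy dataset ",
                             "(doi:10.5061/dryad.sbcc2fr5b): ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("could not download the occupancy dataset ",
                               "(doi:10.5061/dryad.sbcc2fr5b): ",
                               conditionMessage(w), call. = FALSE))
  if (!identical(status, 0L) || !file.exists(dest))
    stop("download of doi:10.5061/dryad.sbcc2fr5b failed")
  dest
}

#' Load a deposited occupancy archive into an occupancy matrix
#'
#' Unzips the archive from [fetch_swallowtail_occupancy()], locates the
#' first tabular member whose columns can be mapped onto the ten-biome
#' vocabulary (via [match_biomes()]), and builds an [occupancy_matrix()].
#' Columns other than species and biomes (e.g. subfamily, area) are
#' returned as metadata.
#'
#' @param archive path to a .zip archive or directly to a CSV file.
#' @return List with `occupancy` (an `occupancy_matrix`) and `metadata`
#'   (data frame of the non-biome columns).
#' @export
load_occupancy_archive <- function(archive) {
  files <- archive
  if (grepl("\\.zip$", archive, ignore.case = TRUE)) {
    exdir <- file.path(tempdir(), "biomediv_archive")
    utils::unzip(archive, exdir = exdir)
    files <- list.files(exdir, pattern = "\\.(csv|txt|tsv)$",
                        recursive = TRUE, full.names = TRUE,
                        ignore.case = TRUE)
  }
  for (f in files) {
    d <- tryCatch(utils::read.csv(f, check.names = FALSE),
                  error = function(e) NULL)
    if (is.null(d) || nrow(d) == 0) next
    cand <- vapply(names(d), function(nm)
      !inherits(tryCatch(match_biomes(nm), error = function(e) e),
                "error"), logical(1))
    if (sum(cand) == 10) {
      sp_col <- names(d)[!cand][1]
      m <- as.matrix(d[names(d)[cand]])
      m[is.na(m)] <- 0
      m <- (m != 0) * 1L
      rownames(m) <- as.character(d[[sp_col]])
      occ <- occupancy_matrix(m)
      meta <- d[!cand]
      names(meta)[1] <- "species"
      return(list(occupancy = occ, metadata = meta))
    }
  }
  stop("no table with the ten biome columns found in ", archive)
}
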