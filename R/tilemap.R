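#' Texture labels
#'
#' The six texture classes a tile can carry. \code{"empty"} is slide
#' background; the remaining five classes constitute tissue and form the
#' tissue-texture list used throughout composition and harmonisation
#' computations.
#'
#' @return \code{texture_labels()} returns all six labels;
#'   \code{tissue_textures()} returns the five tissue labels
#'   (blood, cancer, normal, stroma, other).
#' @export
texture_labels <- function() {
  c("cancer", "normal", "stroma", "blood", "empty", "other")
}

#' @rdname texture_labels
#' @export
tissue_textures <- function() {
  c("blood", "cancer", "normal", "stroma", "other")
}

#' Tile geometry
#'
#' Physical geometry of the square tiles a slide was cut into.
#'
#' @param tile_size_px Edge length of one tile in pixels.
#' @param microns_per_px Scan resolution in micrometres per pixel.
#' @return A \code{tile_geometry} object (list with \code{tile_size_px},
#'   \code{microns_per_px}).
#' @examples
#' g <- tile_geometry(256, 0.25)  # 64 um tile edge
#' @export
tile_geometry <- function(tile_size_px = 256, microns_per_px = 0.25) {
  stopifnot(length(tile_size_px) == 1, tile_size_px > 0,
            length(microns_per_px) == 1, microns_per_px > 0)
  structure(list(tile_size_px = as.numeric(tile_size_px),
                 microns_per_px = as.numeric(microns_per_px)),
            class = "tile_geometry")
}

#' Construct a tile map
#'
#' A tile map is a rectangular grid of texture labels, optionally paired with
#' a co-registered grid of continuous lymphocyte scores in [0, 1]. Rows are
#' indexed top to bottom and columns left to right; the long-table I/O
#' convention uses 0-based (row, col) coordinates with the origin at the
#' top-left tile.
#'
#' @param textures Character matrix of texture labels; every entry must be one
#'   of \code{texture_labels()}.
#' @param scores Optional numeric matrix of lymphocyte scores with the same
#'   dimensions; values in [0, 1], \code{NA} allowed (typically on empty
#'   tiles).
#' @param sample_id Sample identifier.
#' @param centre_id Clinical centre (batch) identifier, or \code{NA}.
#' @param geometry A \code{\link{tile_geometry}}.
#' @return A \code{tile_map} object.
#' @examples
#' m <- tile_map(matrix(c("cancer", "cancer", "stroma", "empty"), 2, 2))
#' dim(m$textures)
#' @export
tile_map <- function(textures, scores = NULL, sample_id = "sample",
                     centre_id = NA_character_, geometry = tile_geometry()) {
  if (!is.matrix(textures) || !is.character(textures))
    stop("`textures` must be a character matrix")
  if (nrow(textures) < 1 || ncol(textures) < 1)
    stop("tile map must have at least one row and one column")
  bad <- setdiff(unique(as.vector(textures)), texture_labels())
  if (length(bad))
    stop("unknown texture label: ", paste(bad, collapse = ", "))
  if (!is.null(scores)) {
    if (!is.matrix(scores) || !identical(dim(scores), dim(textures)))
      stop("`scores` must be a numeric matrix with the same dimensions as `textures`")
    storage.mode(scores) <- "double"
    v <- scores[!is.na(scores)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("lymphocyte scores must lie in [0, 1]")
  }
  if (!inherits(geometry, "tile_geometry"))
    stop("`geometry` must be a tile_geometry object")
  structure(list(sample_id = as.character(sample_id),
                 centre_id = as.character(centre_id),
                 geometry = geometry,
                 textures = textures,
                 scores = scores),
            class = "tile_map")
}

#' @export
print.tile_map <- function(x, ...) {
  d <- dim(x$textures)
  cat(sprintf("tile_map '%s' (%d x %d tiles, %g px @ %g um/px)\n",
              x$sample_id, d[1], d[2],
              x$geometry$tile_size_px, x$geometry$microns_per_px))
  tab <- table(factor(x$textures, levels = texture_labels()))
  cat("  textures:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (!is.null(x$scores))
    cat(sprintf("  lymphocyte scores: %d/%d tiles scored\n",
                sum(!is.na(x$scores)), length(x$scores)))
  invisible(x)
}

#' @export
dim.tile_map <- function(x) dim(x$textures)

#' Tile counts per texture
#'
#' @param map A \code{\link{tile_map}}.
#' @return Named integer vector of tile counts over all six labels.
#' @export
texture_counts <- function(map) {
  stopifnot(inherits(map, "tile_map"))
  tab <- table(factor(map$textures, levels = texture_labels()))
  stats::setNames(as.integer(tab), names(tab))
}
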