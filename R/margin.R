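#' Partition a sample into tumour core, margin, non-margin and background
#'
#' The tumour margin is the band of non-cancer *tissue* tiles whose Chebyshev
#' (chessboard) distance to the nearest cancer tile is at most
#' \code{depth_tiles}: a square-neighbourhood dilation of the cancer mask by
#' \code{depth_tiles}, minus the cancer mask, intersected with tissue. With
#' the default depth of 2 the band is the first two rings of non-cancer tiles
#' around the tumour. Remaining tissue is non-margin; empty tiles are
#' background. Margins are normally extracted from the pooled (smoothed) map.
#'
#' @param map A \code{\link{tile_map}}.
#' @param depth_tiles Margin depth in tiles (>= 1). Default 2.
#' @return A \code{region_partition}: list with \code{sample_id},
#'   \code{regions} (character matrix over core/margin/non_margin/background)
#'   and \code{depth_tiles}. A map with no cancer tiles yields an empty core
#'   and margin.
#' @examples
#' tx <- matrix("normal", 7, 7); tx[4, 4] <- "cancer"
#' p <- extract_margin(tile_map(tx), depth_tiles = 2)
#' sum(p$regions == "margin")  # 24: the 5x5 Chebyshev ball minus the centre
#' @export
extract_margin <- function(map, depth_tiles = 2L) {
  stopifnot(inherits(map, "tile_map"))
  depth_tiles <- as.integer(depth_tiles)
  if (depth_tiles < 1L) stop("`depth_tiles` must be >= 1")
  tx <- map$textures
  nr <- nrow(tx); nc <- ncol(tx)
  cancer <- tx == "cancer"
  empty <- tx == "empty"

  # Chebyshev dilation by shifting the cancer mask over the (2d+1)^2 square
  dil <- matrix(FALSE, nr, nc)
  if (any(cancer)) {
    for (dr in -depth_tiles:depth_tiles) {
      rs <- max(1L, 1L + dr):min(nr, nr + dr)
      ro <- rs - dr
      for (dc in -depth_tiles:depth_tiles) {
        cs <- max(1L, 1L + dc):min(nc, nc + dc)
        co <- cs - dc
        dil[rs, cs] <- dil[rs, cs] | cancer[ro, co]
      }
    }
  }

  regions <- matrix("non_margin", nr, nc)
  regions[dil & !cancer & !empty] <- "margin"
  regions[cancer] <- "core"
  regions[empty] <- "background"
  structure(list(sample_id = map$sample_id, regions = regions,
                 depth_tiles = depth_tiles),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  tab <- table(factor(x$regions, levels = c("core", "margin", "non_margin", "background")))
  cat(sprintf("region_partition '%s' (depth %d tiles): %s\n", x$sample_id,
              x$depth_tiles,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Physical width of the tumour margin band
#'
#' @param geometry A \code{\link{tile_geometry}}.
#' @param depth_tiles Margin depth in tiles.
#' @return Named numeric vector \code{c(pixels, microns)}.
#' @examples
#' margin_width_px(tile_geometry(256, 0.25), 2)  # 512 px, 128 um
#' @export
margin_width_px <- function(geometry, depth_tiles = 2L) {
  stopifnot(inherits(geometry, "tile_geometry"), depth_tiles >= 1)
  px <- depth_tiles * geometry$tile_size_px
  c(pixels = px, microns = px * geometry$microns_per_px)
}

#' Margin-analysis eligibility
#'
#' Margin analyses are restricted to samples whose tissue contains at least
#' \code{min_normal} normal renal texture (inclusive bound), guarding against
#' tumour-core-only sampling bias.
#'
#' @param profile A profile row or list carrying tissue proportions named
#'   \code{prop_normal}, or a plain named numeric vector of proportions with
#'   a \code{"normal"} entry.
#' @param min_normal Minimum normal-tissue fraction. Default 0.01.
#' @return Logical.
#' @export
margin_eligibility <- function(profile, min_normal = 0.01) {
  p <- if ("prop_normal" %in% names(profile)) profile[["prop_normal"]]
       else if ("normal" %in% names(profile)) profile[["normal"]]
  if (is.null(p) || is.na(p)) return(FALSE)
  p >= min_normal
}
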