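#' Majority vote within one pooling window
#'
#' Returns the most common texture among the tiles of a window. Ties are
#' resolved by a fixed hierarchy reflecting which textures dominate mixed
#' tiles: a tie involving cancer goes to cancer; a tie involving stroma (but
#' not cancer) goes to stroma; any other tie is broken uniformly at random
#' among the tied labels, using the current RNG state.
#'
#' @param counts Named integer vector of tile counts per texture label
#'   (labels from \code{\link{texture_labels}}), total > 0.
#' @return A single texture label.
#' @examples
#' pool_window(c(cancer = 4, stroma = 4, blood = 1))  # "cancer"
#' @export
pool_window <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty window: no tile counts")
  bad <- setdiff(names(counts), texture_labels())
  if (length(bad)) stop("unknown texture label: ", paste(bad, collapse = ", "))
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1L) return(tied)
  if ("cancer" %in% tied) return("cancer")
  if ("stroma" %in% tied) return("stroma")
  tied <- sort(tied)  # canonical order so the draw is representation-independent
  tied[sample.int(length(tied), 1L)]
}

# Window offsets along one axis: stride steps, with the final offset clamped
# so the last window touches the map edge.
window_offsets <- function(n, window, stride) {
  offs <- seq.int(1L, n - window + 1L, by = stride)
  last <- n - window + 1L
  if (offs[length(offs)] != last) offs <- c(offs, last)
  offs
}

# Deterministic per-sample seed below 2^31, derived from the global seed and
# the sample id so cohort runs are reproducible sample-by-sample.
derive_seed <- function(seed, sample_id) {
  h <- 0
  for (k in utf8ToInt(as.character(sample_id))) h <- (h * 131 + k) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

#' Smooth a texture map by sliding-window majority vote
#'
#' Slides a \code{window} x \code{window} tile window at the given stride over
#' the texture grid (raster order; final row/column offsets clamped to the map
#' edge so every tile is covered) and unifies each visited window to its
#' majority texture under the tie hierarchy of \code{\link{pool_window}}.
#' Window counts are always taken from the pre-pooling map: a single pass over
#' one input. With the default \code{mode = "inplace"} all tiles of a visited
#' window are reassigned in the output grid and, where windows overlap, the
#' later window in raster order wins, so the map keeps its shape and
#' downstream area accounting is unchanged. \code{mode = "downsample"}
#' instead emits one tile per window.
#'
#' Lymphocyte scores are not smoothed: they pass through unchanged in
#' \code{"inplace"} mode and are window-averaged (ignoring missing values) in
#' \code{"downsample"} mode.
#'
#' @param map A \code{\link{tile_map}}.
#' @param window Window edge in tiles; odd, >= 1. Default 3.
#' @param stride Step between window origins in tiles; 1..window. Default 2.
#' @param seed Integer seed for random tie-breaking. The RNG is seeded per
#'   sample from (seed, sample_id), so a fixed seed gives identical output for
#'   identical input.
#' @param mode \code{"inplace"} (default) or \code{"downsample"}.
#' @return A \code{tile_map} with pooled texture labels.
#' @examples
#' m <- tile_map(matrix("cancer", 5, 5))
#' identical(pool_map(m)$textures, m$textures)  # uniform maps are fixed points
#' @export
pool_map <- function(map, window = 3L, stride = 2L, seed = 0L,
                     mode = c("inplace", "downsample")) {
  stopifnot(inherits(map, "tile_map"))
  mode <- match.arg(mode)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd and >= 1")
  if (stride < 1L || stride > window) stop("`stride` must lie in 1..window")
  src <- map$textures
  nr <- nrow(src); nc <- ncol(src)
  if (nr < window || nc < window) {
    warning("map ", map$sample_id, " smaller than the pooling window; returned unchanged")
    return(map)
  }
  roffs <- window_offsets(nr, window, stride)
  coffs <- window_offsets(nc, window, stride)

  withr::with_seed(derive_seed(seed, map$sample_id), {
    if (mode == "inplace") {
      out <- src
      for (r in roffs) for (c in coffs) {
        win <- src[r:(r + window - 1L), c:(c + window - 1L)]
        out[r:(r + window - 1L), c:(c + window - 1L)] <-
          pool_window(table(win))
      }
      tile_map(out, map$scores, sample_id = map$sample_id,
               centre_id = map$centre_id, geometry = map$geometry)
    } else {
      out <- matrix(NA_character_, length(roffs), length(coffs))
      sc <- if (is.null(map$scores)) NULL else
        matrix(NA_real_, length(roffs), length(coffs))
      for (i in seq_along(roffs)) for (j in seq_along(coffs)) {
        r <- roffs[i]; c <- coffs[j]
        win <- src[r:(r + window - 1L), c:(c + window - 1L)]
        out[i, j] <- pool_window(table(win))
        if (!is.null(sc)) {
          v <- map$scores[r:(r + window - 1L), c:(c + window - 1L)]
          sc[i, j] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
        }
      }
      geo <- tile_geometry(map$geometry$tile_size_px * stride,
                           map$geometry$microns_per_px)
      tile_map(out, sc, sample_id = map$sample_id,
               centre_id = map$centre_id, geometry = geo)
    }
  })
}
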