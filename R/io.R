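#' Read a tile map from a long-format table
#'
#' Reconstructs the rectangular texture and lymphocyte-score grids from a
#' delimited long table with header columns \code{sample_id}, \code{row},
#' \code{col}, \code{texture} and (optionally) \code{lymphocyte_score}.
#' Coordinates are 0-based with the origin at the top-left tile. Positions
#' inside the bounding box that are absent from the file are filled with
#' \code{"empty"}: sparse exports that omit background tiles are the natural
#' interchange format.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param sample_id If the file holds several samples, the one to extract;
#'   with the default \code{NULL} the file must contain exactly one sample.
#' @param sep Field separator; \code{"\t"} or \code{","}.
#' @param n_rows,n_cols Declared bounding box. Defaults to the maximal
#'   row/col index in the file plus one.
#' @param centre_id,geometry Metadata attached to the returned map (the long
#'   table itself carries neither).
#' @return A \code{\link{tile_map}} whose \code{scores} element is the
#'   co-registered lymphocyte map (\code{NULL} when the file has no score
#'   column).
#' @seealso \code{\link{write_tilemap}}
#' @export
read_tilemap <- function(path, sample_id = NULL, sep = "\t",
                         n_rows = NULL, n_cols = NULL,
                         centre_id = NA_character_, geometry = tile_geometry()) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "row", "col", "texture")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tile-map table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.null(sample_id)) {
    df <- df[df$sample_id == sample_id, , drop = FALSE]
    if (!nrow(df)) stop("sample_id '", sample_id, "' not present in ", path)
  } else {
    ids <- unique(df$sample_id)
    if (length(ids) != 1)
      stop("file holds ", length(ids), " samples; pass `sample_id` to select one")
    sample_id <- ids
  }
  row <- suppressWarnings(as.integer(df$row))
  col <- suppressWarnings(as.integer(df$col))
  if (anyNA(row) || anyNA(col))
    stop("non-integer row/col coordinate in ", path)
  if (any(row < 0) || any(col < 0))
    stop("negative tile coordinate in ", path)

  bad <- !(df$texture %in% texture_labels())
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown texture label '", df$texture[i], "' (data line ", i, ")")
  }
  dup <- duplicated(cbind(row, col))
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate tile position (", row[i], ", ", col[i], ") (data line ", i, ")")
  }

  nr <- if (is.null(n_rows)) max(row) + 1L else as.integer(n_rows)
  nc <- if (is.null(n_cols)) max(col) + 1L else as.integer(n_cols)
  if (nr <= max(row) || nc <= max(col))
    stop("declared bounding box ", nr, "x", nc, " smaller than listed coordinates")

  textures <- matrix("empty", nr, nc)
  idx <- cbind(row + 1L, col + 1L)
  textures[idx] <- df$texture

  scores <- NULL
  if ("lymphocyte_score" %in% names(df)) {
    raw <- df$lymphocyte_score
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    if (any(!is.na(raw) & is.na(val)))
      stop("non-numeric lymphocyte_score in ", path)
    out <- !is.na(val) & (val < 0 | val > 1)
    if (any(out)) {
      i <- which(out)[1]
      stop("lymphocyte_score ", val[i], " outside [0, 1] (data line ", i, ")")
    }
    scores <- matrix(NA_real_, nr, nc)
    scores[idx] <- val
  }
  tile_map(textures, scores, sample_id = sample_id, centre_id = centre_id,
           geometry = geometry)
}

#' Write a tile map as a long-format table
#'
#' Serialises a tile map (and its co-registered lymphocyte scores, when
#' present) to the long-table dialect read by \code{\link{read_tilemap}}.
#' Every tile is written, including empty ones, so the bounding box survives
#' a round trip; missing scores become empty fields.
#'
#' @param map A \code{\link{tile_map}}.
#' @param path Output file path.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
write_tilemap <- function(map, path, sep = "\t") {
  stopifnot(inherits(map, "tile_map"))
  nr <- nrow(map$textures); nc <- ncol(map$textures)
  grid <- expand.grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L,
                      KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(sample_id = map$sample_id,
                   row = grid$row, col = grid$col,
                   texture = as.vector(map$textures),
                   stringsAsFactors = FALSE)
  if (!is.null(map$scores))
    df$lymphocyte_score <- as.vector(map$scores)
  df <- df[order(df$row, df$col), , drop = FALSE]
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort metadata table
#'
#' @param path TSV/CSV with required columns \code{sample_id},
#'   \code{centre_id}, \code{microns_per_px}; any further columns are kept as
#'   covariates. Survival columns, when present, are named \code{os_months}
#'   and \code{os_event} (0/1).
#' @param sep Field separator.
#' @return A data.frame, one row per sample.
#' @export
read_cohort <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "centre_id", "microns_per_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in cohort table")
  if (any(!nzchar(df$centre_id) | is.na(df$centre_id)))
    stop("empty centre_id in cohort table")
  df
}

#' Cross-check a cohort table against available tile maps
#'
#' Report-only consistency check: lists samples present in the cohort table
#' without a tile map, maps whose sample is absent from the table, and the
#' per-sample resolution.
#'
#' @param cohort Cohort data.frame (see \code{\link{read_cohort}}).
#' @param maps List of \code{\link{tile_map}} objects.
#' @return A list with data.frames \code{missing_map}, \code{orphan_map}
#'   and \code{resolution}.
#' @export
validate_cohort <- function(cohort, maps) {
  map_ids <- vapply(maps, function(m) m$sample_id, character(1))
  missing_map <- setdiff(cohort$sample_id, map_ids)
  orphan_map <- setdiff(map_ids, cohort$sample_id)
  list(
    missing_map = data.frame(sample_id = missing_map,
                             issue = rep("missing map", length(missing_map)),
                             stringsAsFactors = FALSE),
    orphan_map = data.frame(sample_id = orphan_map,
                            issue = rep("orphan map", length(orphan_map)),
                            stringsAsFactors = FALSE),
    resolution = data.frame(sample_id = cohort$sample_id,
                            microns_per_px = cohort$microns_per_px,
                            stringsAsFactors = FALSE)
  )
}
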