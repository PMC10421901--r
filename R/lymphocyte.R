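#' Texture-specific lymphocyte density
#'
#' Mean lymphocyte score over the tiles of each tissue texture, optionally
#' restricted to the regions of a margin partition. Missing scores (typically
#' on empty tiles) are ignored; a texture with fewer than
#' \code{min_texture_tiles} scored tiles gets an undefined (\code{NA})
#' density.
#'
#' @param map A \code{\link{tile_map}} carrying lymphocyte scores.
#' @param partition Optional \code{\link{extract_margin}} result; when given,
#'   densities are returned per region.
#' @param min_texture_tiles Minimum scored tiles for a density to be defined.
#' @return Without a partition: named numeric vector over
#'   \code{\link{tissue_textures}}. With one: a regions x textures matrix
#'   (rows core, margin, non_margin).
#' @examples
#' tx <- matrix("cancer", 1, 3)
#' m <- tile_map(tx, matrix(c(0.2, 0.4, 0.6), 1, 3))
#' density_per_texture(m)["cancer"]  # 0.4
#' @export
density_per_texture <- function(map, partition = NULL, min_texture_tiles = 1L) {
  stopifnot(inherits(map, "tile_map"))
  if (is.null(map$scores)) stop("map carries no lymphocyte scores")
  tt <- tissue_textures()
  dens1 <- function(keep) {
    vapply(tt, function(t) {
      v <- map$scores[keep & map$textures == t]
      v <- v[!is.na(v)]
      if (length(v) < min_texture_tiles) NA_real_ else mean(v)
    }, numeric(1))
  }
  if (is.null(partition)) return(dens1(rep(TRUE, length(map$textures))))
  if (!inherits(partition, "region_partition") ||
      !identical(dim(partition$regions), dim(map$textures)))
    stop("partition does not match the map")
  regs <- c("core", "margin", "non_margin")
  out <- t(vapply(regs, function(r) dens1(partition$regions == r),
                  numeric(length(tt))))
  dimnames(out) <- list(regs, tt)
  out
}

#' Total lymphocyte density over tissue
#'
#' Mean lymphocyte score over all scored tissue tiles; the raw,
#' composition-sensitive infiltration measure that \code{\link{ctm_alpha}}
#' harmonises.
#'
#' @inheritParams density_per_texture
#' @return A single number, or \code{NA} if no tissue tile is scored.
#' @export
total_density <- function(map) {
  stopifnot(inherits(map, "tile_map"))
  if (is.null(map$scores)) stop("map carries no lymphocyte scores")
  v <- map$scores[map$textures %in% tissue_textures()]
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else mean(v)
}

#' Relative lymphocyte proportions
#'
#' Rescales per-texture lymphocyte densities so the defined tissue textures
#' sum to 100 percent. The relative proportion rho_t expresses the lymphocyte
#' enrichment of texture t compared to the other textures, independent of how
#' much of each texture the section happens to contain and of any
#' multiplicative stain intensity bias. Undefined textures get rho = 0 and
#' are flagged in the \code{"undefined"} attribute; if every defined density
#' is zero the proportions are uniform and flagged via attribute
#' \code{"degenerate"}.
#'
#' @param density Named numeric vector of densities over (a subset of)
#'   \code{\link{tissue_textures}}; \code{NA} = undefined.
#' @return Named numeric vector rho (percent) over the tissue textures,
#'   summing to 100 over the defined ones.
#' @examples
#' relative_proportions(c(blood = .1, cancer = .3, normal = .4,
#'                        stroma = .15, other = .05))
#' @export
relative_proportions <- function(density) {
  tt <- tissue_textures()
  d <- stats::setNames(rep(NA_real_, length(tt)), tt)
  d[names(density)] <- density
  def <- !is.na(d)
  if (!any(def)) stop("no defined texture density")
  rho <- stats::setNames(rep(0, length(tt)), tt)
  tot <- sum(d[def])
  degenerate <- tot == 0
  rho[def] <- if (degenerate) 100 / sum(def) else 100 * d[def] / tot
  attr(rho, "undefined") <- tt[!def]
  attr(rho, "degenerate") <- degenerate
  rho
}

#' Texture-harmonised lymphocyte infiltration (alpha)
#'
#' The CTM-normalised infiltration index: the area-weighted mean of the
#' relative lymphocyte proportions over the tissue textures,
#' alpha = sum_t rho_t A_t / sum_t A_t. Area units cancel, so tile counts
#' and px^2 areas give the same alpha, and alpha always lies between the
#' smallest and largest rho entering it. Textures absent from a sample
#' contribute zero area and vanish from both sums.
#'
#' @param rho Named vector of relative proportions (percent), e.g. from
#'   \code{\link{relative_proportions}}.
#' @param area Named vector of texture areas (tiles or px^2) over the same
#'   textures; total must be positive.
#' @return alpha, in percent.
#' @examples
#' rho <- c(blood = 10, cancer = 40, normal = 30, stroma = 15, other = 5)
#' A <- c(blood = 10, cancer = 50, normal = 20, stroma = 15, other = 5)
#' ctm_alpha(rho, A)  # 29.5
#' @export
ctm_alpha <- function(rho, area) {
  tt <- intersect(tissue_textures(), intersect(names(rho), names(area)))
  if (!length(tt)) stop("`rho` and `area` share no tissue texture")
  a <- area[tt]; r <- rho[tt]
  keep <- !is.na(r) & !is.na(a)
  a <- a[keep]; r <- r[keep]
  if (sum(a) <= 0) stop("total texture area must be positive")
  sum(r * a) / sum(a)
}

#' Harmonisation configuration
#'
#' @param rho_source \code{"per_sample"} (default): each sample's rho comes
#'   from its own densities; \code{"cohort_median"}: densities are
#'   median-averaged over the cohort per texture first, and the resulting
#'   shared rho is applied to every sample's areas.
#' @param min_texture_tiles Per-texture tile floor for densities.
#' @param min_centre_n Minimum centre size for High/Low binarisation;
#'   default 21, i.e. centres with more than 20 samples.
#' @param excluded_centres Centres dropped from lymphocyte analyses (e.g.
#'   after manual review of stain quality).
#' @return A \code{harmonisation_config} list.
#' @export
harmonisation_config <- function(rho_source = c("per_sample", "cohort_median"),
                                 min_texture_tiles = 1L, min_centre_n = 21L,
                                 excluded_centres = character()) {
  rho_source <- match.arg(rho_source)
  stopifnot(min_centre_n >= 1, min_texture_tiles >= 1)
  structure(list(rho_source = rho_source,
                 min_texture_tiles = as.integer(min_texture_tiles),
                 min_centre_n = as.integer(min_centre_n),
                 excluded_centres = excluded_centres),
            class = "harmonisation_config")
}

#' Lymphocyte profiles for a cohort
#'
#' Computes, for every map: per-texture densities, total raw density,
#' relative proportions rho and the harmonised index alpha (using tile
#' counts as areas).
#'
#' @param maps List of \code{\link{tile_map}} objects with scores.
#' @param cfg A \code{\link{harmonisation_config}}.
#' @return Data.frame with \code{sample_id}, \code{centre_id},
#'   \code{density_<t>}, \code{total_density}, \code{rho_<t>} and
#'   \code{alpha}.
#' @export
lympho_profiles <- function(maps, cfg = harmonisation_config()) {
  stopifnot(inherits(cfg, "harmonisation_config"))
  tt <- tissue_textures()
  dens <- t(vapply(maps, density_per_texture, numeric(length(tt)),
                   min_texture_tiles = cfg$min_texture_tiles))
  areas <- t(vapply(maps, function(m) texture_counts(m)[tt],
                    numeric(length(tt))))
  shared_rho <- NULL
  if (cfg$rho_source == "cohort_median") {
    med <- apply(dens, 2, stats::median, na.rm = TRUE)
    shared_rho <- relative_proportions(med)
  }
  out <- data.frame(
    sample_id = vapply(maps, function(m) m$sample_id, character(1)),
    centre_id = vapply(maps, function(m) m$centre_id, character(1)),
    stringsAsFactors = FALSE)
  for (j in seq_along(tt)) out[[paste0("density_", tt[j])]] <- dens[, j]
  out$total_density <- vapply(maps, total_density, numeric(1))
  rho_rows <- t(vapply(seq_along(maps), function(i) {
    if (!is.null(shared_rho)) shared_rho else relative_proportions(dens[i, ])
  }, numeric(length(tt))))
  for (j in seq_along(tt)) out[[paste0("rho_", tt[j])]] <- rho_rows[, j]
  out$alpha <- vapply(seq_along(maps), function(i)
    ctm_alpha(stats::setNames(rho_rows[i, ], tt),
              stats::setNames(areas[i, ], tt)), numeric(1))
  out
}

#' High/Low infiltration by clinical-centre median
#'
#' Binarises a per-sample infiltration value (alpha or raw density) against
#' the median of the sample's own clinical centre, neutralising residual
#' centre-level staining differences. Only centres with at least
#' \code{min_centre_n} samples (default: more than 20) are classified;
#' samples in smaller or excluded centres get \code{NA}. Classification is
#' strict: a sample exactly at its centre median is Low.
#'
#' @param values Named numeric vector (names = sample ids) or unnamed vector
#'   parallel to \code{cohort}.
#' @param cohort Cohort data.frame with \code{sample_id} and
#'   \code{centre_id}.
#' @param cfg A \code{\link{harmonisation_config}}.
#' @return Character vector ("High"/"Low"/NA) parallel to \code{values}.
#' @export
centre_binarise <- function(values, cohort, cfg = harmonisation_config()) {
  stopifnot(inherits(cfg, "harmonisation_config"))
  if (!is.null(names(values))) {
    centre <- cohort$centre_id[match(names(values), cohort$sample_id)]
  } else {
    stopifnot(length(values) == nrow(cohort))
    centre <- cohort$centre_id
  }
  out <- rep(NA_character_, length(values))
  for (ct in unique(centre)) {
    idx <- which(centre == ct & !is.na(values))
    if (ct %in% cfg$excluded_centres) next
    if (length(idx) < cfg$min_centre_n) next
    med <- stats::median(values[idx])
    out[idx] <- ifelse(values[idx] > med, "High", "Low")
  }
  out
}

#' Centre-dispersion report: raw density vs alpha
#'
#' Quantifies how much texture harmonisation reduces between-centre
#' differences in total lymphocyte infiltration: the variance of per-centre
#' mean values (raw total density vs alpha, each scaled by its grand mean so
#' the two are comparable) and the Kruskal-Wallis statistic of value ~
#' centre for both measures.
#'
#' @param lympho Data.frame from \code{\link{lympho_profiles}} (needs
#'   \code{total_density}, \code{alpha}, \code{centre_id}).
#' @return List with \code{between_centre_var} (named: raw, alpha),
#'   \code{variance_ratio} (alpha / raw), \code{kruskal} (statistics and p
#'   values) and \code{degenerate} (TRUE when fewer than 2 centres).
#' @export
harmonisation_report <- function(lympho) {
  centres <- unique(lympho$centre_id)
  if (length(centres) < 2) {
    return(list(between_centre_var = c(raw = NA_real_, alpha = NA_real_),
                variance_ratio = NA_real_, kruskal = NULL, degenerate = TRUE))
  }
  bvar <- function(v) {
    v <- v / mean(v, na.rm = TRUE)  # scale-free: compare dispersion, not units
    stats::var(tapply(v, lympho$centre_id, mean, na.rm = TRUE))
  }
  vr <- c(raw = bvar(lympho$total_density), alpha = bvar(lympho$alpha))
  kw_raw <- stats::kruskal.test(lympho$total_density, factor(lympho$centre_id))
  kw_alpha <- stats::kruskal.test(lympho$alpha, factor(lympho$centre_id))
  list(between_centre_var = vr,
       variance_ratio = unname(vr["alpha"] / vr["raw"]),
       kruskal = data.frame(measure = c("raw", "alpha"),
                            statistic = c(kw_raw$statistic, kw_alpha$statistic),
                            p_value = c(kw_raw$p.value, kw_alpha$p.value),
                            row.names = NULL),
       degenerate = FALSE)
}
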