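#' Margin vs non-margin enrichment profile
#'
#' Compares the tumour margin with the remaining (non-margin) tissue of one
#' sample: texture composition within each region (tissue denominator),
#' per-texture lymphocyte densities within each region, and the
#' margin:non-margin enrichment ratios. A ratio with a zero denominator is
#' \code{NA} — no pseudocounts are added, so sparse regions cannot
#' manufacture enrichment; \code{pseudo = TRUE} instead adds one tile to
#' both region areas of each texture for users who need finite ratios.
#'
#' @param map A \code{\link{tile_map}} (scores optional; lymphocyte ratios
#'   are \code{NA} without them).
#' @param partition Matching \code{\link{extract_margin}} result.
#' @param pseudo Add-one-tile smoothing of the composition ratios.
#'   Default \code{FALSE}.
#' @return A \code{margin_profile} list: \code{composition} (2 x 5 matrix,
#'   rows margin/non_margin), \code{density} (idem), \code{ratio_texture},
#'   \code{ratio_lympho} (named per-texture vectors),
#'   \code{ratio_lympho_total}, and a \code{flag} marking samples whose
#'   margin or non-margin region is empty (all ratios \code{NA}).
#' @export
margin_profile <- function(map, partition, pseudo = FALSE) {
  stopifnot(inherits(map, "tile_map"), inherits(partition, "region_partition"))
  if (!identical(dim(partition$regions), dim(map$textures)))
    stop("partition does not match the map")
  tt <- tissue_textures()
  regs <- c("margin", "non_margin")
  comp <- matrix(NA_real_, 2, length(tt), dimnames = list(regs, tt))
  dens <- matrix(NA_real_, 2, length(tt), dimnames = list(regs, tt))
  counts <- matrix(0, 2, length(tt), dimnames = list(regs, tt))
  tot_dens <- c(margin = NA_real_, non_margin = NA_real_)
  for (r in regs) {
    in_r <- partition$regions == r & map$textures %in% tt
    n_r <- sum(in_r)
    counts[r, ] <- vapply(tt, function(t) sum(in_r & map$textures == t),
                          numeric(1))
    if (n_r > 0) comp[r, ] <- counts[r, ] / n_r
    if (!is.null(map$scores)) {
      dens[r, ] <- vapply(tt, function(t) {
        v <- map$scores[in_r & map$textures == t]
        v <- v[!is.na(v)]
        if (!length(v)) NA_real_ else mean(v)
      }, numeric(1))
      v <- map$scores[in_r]; v <- v[!is.na(v)]
      tot_dens[[r]] <- if (!length(v)) NA_real_ else mean(v)
    }
  }
  flag <- any(rowSums(counts) == 0)
  safe_ratio <- function(num, den)
    ifelse(is.na(num) | is.na(den) | den == 0, NA_real_, num / den)
  if (pseudo) {
    pm <- (counts["margin", ] + 1) / (sum(counts["margin", ]) + length(tt))
    pn <- (counts["non_margin", ] + 1) / (sum(counts["non_margin", ]) + length(tt))
    ratio_texture <- pm / pn
  } else {
    ratio_texture <- safe_ratio(comp["margin", ], comp["non_margin", ])
  }
  ratio_lympho <- safe_ratio(dens["margin", ], dens["non_margin", ])
  if (flag) {
    ratio_texture[] <- NA_real_
    ratio_lympho[] <- NA_real_
    tot_ratio <- NA_real_
  } else {
    tot_ratio <- safe_ratio(tot_dens[["margin"]], tot_dens[["non_margin"]])
  }
  structure(list(sample_id = map$sample_id,
                 composition = comp, density = dens, counts = counts,
                 ratio_texture = stats::setNames(as.numeric(ratio_texture), tt),
                 ratio_lympho = stats::setNames(as.numeric(ratio_lympho), tt),
                 ratio_lympho_total = tot_ratio,
                 flag = flag),
            class = "margin_profile")
}

#' Tabulate margin profiles for a cohort
#'
#' @param profiles List of \code{\link{margin_profile}} objects.
#' @return Data.frame with one row per sample: \code{ratio_texture_<t>},
#'   \code{ratio_lympho_<t>}, \code{ratio_lympho_total}, \code{flag}.
#' @export
margin_profile_table <- function(profiles) {
  tt <- tissue_textures()
  do.call(rbind, lapply(profiles, function(p) {
    out <- data.frame(sample_id = p$sample_id, stringsAsFactors = FALSE)
    for (t in tt) out[[paste0("ratio_texture_", t)]] <- p$ratio_texture[[t]]
    for (t in tt) out[[paste0("ratio_lympho_", t)]] <- p$ratio_lympho[[t]]
    out$ratio_lympho_total <- p$ratio_lympho_total
    out$flag <- p$flag
    out
  }))
}

#' Binary High/Low classes from enrichment ratios
#'
#' Splits a vector of per-sample enrichment ratios at a cohort quantile
#' (default the median, the usual Kaplan-Meier split). The quantile uses the
#' standard linear-interpolation convention (type 7); values strictly above
#' it are High. \code{NA} ratios propagate.
#'
#' @param ratios Numeric vector.
#' @param quantile Split point in (0, 1). Default 0.5.
#' @return Character vector ("High"/"Low"/NA).
#' @export
enrichment_classes <- function(ratios, quantile = 0.5) {
  stopifnot(quantile > 0, quantile < 1)
  ok <- !is.na(ratios)
  if (sum(ok) < 2) return(rep(NA_character_, length(ratios)))
  q <- stats::quantile(ratios[ok], probs = quantile, type = 7, names = FALSE)
  out <- rep(NA_character_, length(ratios))
  out[ok] <- ifelse(ratios[ok] > q, "High", "Low")
  out
}
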