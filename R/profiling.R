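#' Per-sample texture composition
#'
#' Counts tiles per texture and converts them to proportions. By default the
#' denominator is the tissue area (the five tissue textures; empty excluded),
#' matching the convention used for sample percentages throughout the
#' package; \code{denominator = "all_tiles"} divides by the full grid
#' instead.
#'
#' @param map A \code{\link{tile_map}}.
#' @param denominator \code{"tissue"} (default) or \code{"all_tiles"}.
#' @return One-row data.frame with \code{sample_id}, \code{centre_id},
#'   per-texture tile counts \code{area_<t>}, tissue tile count
#'   \code{tissue_tiles}, proportions \code{prop_<t>} and a logical
#'   \code{undefined} flag set when the map holds no tissue (proportions are
#'   then \code{NA}).
#' @examples
#' tx <- matrix(rep(c("cancer", "stroma"), c(6, 3)), 3, 3)
#' texture_composition(tile_map(tx))$prop_cancer  # 2/3
#' @export
texture_composition <- function(map, denominator = c("tissue", "all_tiles")) {
  stopifnot(inherits(map, "tile_map"))
  denominator <- match.arg(denominator)
  cnt <- texture_counts(map)
  tt <- tissue_textures()
  tissue <- sum(cnt[tt])
  denom <- if (denominator == "tissue") tissue else sum(cnt)
  undefined <- denominator == "tissue" && tissue == 0
  props <- if (denom > 0 && !undefined) cnt[tt] / denom else
    stats::setNames(rep(NA_real_, length(tt)), tt)
  out <- data.frame(sample_id = map$sample_id, centre_id = map$centre_id,
                    n_tiles = sum(cnt), tissue_tiles = tissue,
                    stringsAsFactors = FALSE)
  for (t in tt) out[[paste0("area_", t)]] <- cnt[[t]]
  out[["area_empty"]] <- cnt[["empty"]]
  for (t in tt) out[[paste0("prop_", t)]] <- unname(props[t])
  out$undefined <- undefined
  out
}

#' Profile a collection of samples
#'
#' @param maps List of \code{\link{tile_map}} objects.
#' @inheritParams texture_composition
#' @return A data.frame, one \code{\link{texture_composition}} row per map.
#' @export
profile_samples <- function(maps, denominator = c("tissue", "all_tiles")) {
  denominator <- match.arg(denominator)
  do.call(rbind, lapply(maps, texture_composition, denominator = denominator))
}

#' Quality-control policy
#'
#' @param min_cancer Samples with a cancer tissue proportion strictly below
#'   this are excluded (default 0.05, i.e. the <5 percent cancer rule).
#' @param resolution_range Accepted scan-resolution band in um/px; samples
#'   outside it (e.g. ~0.50 um/px scans against the usual ~0.25) are
#'   excluded. Default \code{c(0.1, 0.4)}.
#' @param excluded_centres Centres excluded wholesale (manual review;
#'   typically applied to lymphocyte analyses only).
#' @return A \code{qc_policy} list.
#' @export
qc_policy <- function(min_cancer = 0.05, resolution_range = c(0.1, 0.4),
                      excluded_centres = character()) {
  stopifnot(min_cancer >= 0, min_cancer <= 1,
            length(resolution_range) == 2, resolution_range[1] <= resolution_range[2])
  structure(list(min_cancer = min_cancer, resolution_range = resolution_range,
                 excluded_centres = excluded_centres),
            class = "qc_policy")
}

#' Apply cohort quality control
#'
#' Excludes samples scanned outside the accepted resolution band, samples
#' with too little cancer texture, and samples from manually excluded
#' centres, in that order; each sample is reported once with its first
#' matching reason. Samples lacking a resolution are retained with a
#' warning.
#'
#' @param profiles Profile data.frame from \code{\link{profile_samples}}.
#' @param cohort Cohort data.frame (see \code{\link{read_cohort}}).
#' @param policy A \code{\link{qc_policy}}.
#' @return List with \code{kept} (profile rows), \code{excluded}
#'   (data.frame sample_id, reason) and \code{counts} (exclusions per
#'   reason).
#' @export
apply_qc <- function(profiles, cohort, policy = qc_policy()) {
  stopifnot(inherits(policy, "qc_policy"))
  res <- cohort$microns_per_px[match(profiles$sample_id, cohort$sample_id)]
  centre <- cohort$centre_id[match(profiles$sample_id, cohort$sample_id)]
  if (any(is.na(res)))
    warning("sample(s) without resolution retained: ",
            paste(profiles$sample_id[is.na(res)], collapse = ", "))
  reason <- rep(NA_character_, nrow(profiles))
  bad_res <- !is.na(res) &
    (res < policy$resolution_range[1] | res > policy$resolution_range[2])
  reason[bad_res] <- "resolution"
  low <- is.na(reason) & !is.na(profiles$prop_cancer) &
    profiles$prop_cancer < policy$min_cancer
  reason[low] <- "low_cancer"
  man <- is.na(reason) & centre %in% policy$excluded_centres
  reason[man] <- "manual"
  excluded <- data.frame(sample_id = profiles$sample_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(kept = profiles[is.na(reason), , drop = FALSE],
       excluded = excluded,
       counts = table(factor(excluded$reason,
                             levels = c("resolution", "low_cancer", "manual"))))
}

#' N+/N- stratification by normal-tissue content
#'
#' Samples with at least \code{threshold} normal renal texture are "N+"
#' (sampling spans the peritumoural tissue); the rest are "N-" (tumour-core
#' sampling).
#'
#' @param profiles Profile data.frame (needs \code{prop_normal}), or a
#'   numeric vector of normal proportions.
#' @param threshold Normal-proportion cut, inclusive for N+. Default 0.01.
#' @return Character vector over \code{c("N_plus", "N_minus")}.
#' @export
stratify_n <- function(profiles, threshold = 0.01) {
  p <- if (is.data.frame(profiles)) profiles$prop_normal else as.numeric(profiles)
  ifelse(is.na(p), NA_character_,
         ifelse(p >= threshold, "N_plus", "N_minus"))
}

#' Per-centre composition medians and fold-variation
#'
#' Summarises sampling heterogeneity across clinical centres: the median
#' tissue proportion of each texture per centre, and for each texture the
#' fold-variation max(centre median) / min(centre median).
#'
#' @param profiles Profile data.frame from \code{\link{profile_samples}}.
#' @param cohort Optional cohort data.frame supplying \code{centre_id} when
#'   the profiles lack one.
#' @return List with \code{medians} (centres x textures matrix, proportions)
#'   and \code{fold} (named vector per texture; \code{NA} when a centre
#'   median is 0).
#' @export
centre_composition_summary <- function(profiles, cohort = NULL) {
  centre <- profiles$centre_id
  if ((is.null(centre) || all(is.na(centre))) && !is.null(cohort))
    centre <- cohort$centre_id[match(profiles$sample_id, cohort$sample_id)]
  if (is.null(centre) || any(is.na(centre)))
    stop("centre_id unavailable for some samples")
  tt <- tissue_textures()
  med <- sapply(tt, function(t)
    tapply(profiles[[paste0("prop_", t)]], centre, stats::median, na.rm = TRUE))
  med <- matrix(med, ncol = length(tt),
                dimnames = list(sort(unique(centre)), tt))
  fold <- apply(med, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v) || min(v) == 0) NA_real_ else max(v) / min(v)
  })
  list(medians = med, fold = fold)
}
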