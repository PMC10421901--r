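#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs. Serialisable to/from a
#' single YAML file (\code{\link{read_pipeline_config}}).
#'
#' @param maps_dir Directory of tile-map TSVs (one sample per file).
#' @param cohort_path Cohort metadata TSV.
#' @param out_dir Output directory; one TSV per stage plus a run manifest.
#' @param tile_size_px Tile edge in pixels.
#' @param pool_window,pool_stride,pool_mode Texture-pooling parameters.
#' @param margin_depth Margin depth in tiles.
#' @param qc A \code{\link{qc_policy}}.
#' @param harmonisation A \code{\link{harmonisation_config}}.
#' @param binarise_on Value fed to the centre-median High/Low split:
#'   \code{"alpha"} (default) or \code{"total_density"}.
#' @param seed Global seed (pooling tie-breaks).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(maps_dir, cohort_path, out_dir,
                            tile_size_px = 256,
                            pool_window = 3L, pool_stride = 2L,
                            pool_mode = "inplace",
                            margin_depth = 2L,
                            qc = qc_policy(),
                            harmonisation = harmonisation_config(),
                            binarise_on = c("alpha", "total_density"),
                            seed = 0L) {
  binarise_on <- match.arg(binarise_on)
  structure(list(maps_dir = maps_dir, cohort_path = cohort_path,
                 out_dir = out_dir, tile_size_px = tile_size_px,
                 pool_window = as.integer(pool_window),
                 pool_stride = as.integer(pool_stride),
                 pool_mode = pool_mode,
                 margin_depth = as.integer(margin_depth),
                 qc = qc, harmonisation = harmonisation,
                 binarise_on = binarise_on, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching the arguments of
#'   \code{\link{pipeline_config}}; \code{qc} and \code{harmonisation} are
#'   nested mappings.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  qc <- do.call(qc_policy, y$qc %||% list())
  hc <- do.call(harmonisation_config, y$harmonisation %||% list())
  y$qc <- NULL; y$harmonisation <- NULL
  do.call(pipeline_config, c(y, list(qc = qc, harmonisation = hc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage <- function(df, out_dir, name) {
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

#' Run the full texture-mapping pipeline
#'
#' Executes pool -> profile/QC -> N+/N- stratification -> margin ->
#' lymphocyte harmonisation -> margin enrichment -> association statistics
#' over an on-disk cohort, writing one TSV per stage plus a JSON run
#' manifest (seed, config, per-stage sample counts). The run is a pure
#' function of (inputs, config, seed): rerunning yields identical files.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Invisibly, the result bundle: maps, profiles, qc, lympho,
#'   margins, stats and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$maps_dir))
    stop("maps_dir does not exist: ", cfg$maps_dir)
  if (!file.exists(cfg$cohort_path))
    stop("cohort table does not exist: ", cfg$cohort_path)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- read_cohort(cfg$cohort_path)
  files <- list.files(cfg$maps_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no tile-map TSVs under ", cfg$maps_dir)
  maps <- lapply(files, function(f) {
    m <- read_tilemap(f)
    res <- cohort$microns_per_px[match(m$sample_id, cohort$sample_id)]
    ctr <- cohort$centre_id[match(m$sample_id, cohort$sample_id)]
    m$geometry <- tile_geometry(cfg$tile_size_px,
                                if (is.na(res)) 0.25 else res)
    m$centre_id <- if (is.na(ctr)) NA_character_ else ctr
    m
  })
  names(maps) <- vapply(maps, function(m) m$sample_id, character(1))
  check <- validate_cohort(cohort, maps)

  pooled <- lapply(maps, pool_map, window = cfg$pool_window,
                   stride = cfg$pool_stride, seed = cfg$seed,
                   mode = cfg$pool_mode)

  profiles <- profile_samples(pooled)
  qc <- apply_qc(profiles, cohort, cfg$qc)
  kept <- qc$kept
  kept$n_class <- stratify_n(kept)
  write_stage(kept, cfg$out_dir, "profiles")
  qc_report <- rbind(
    data.frame(sample_id = kept$sample_id,
               status = rep("pass", nrow(kept)),
               reason = rep(NA_character_, nrow(kept)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = qc$excluded$sample_id,
               status = rep("excluded", nrow(qc$excluded)),
               reason = qc$excluded$reason, stringsAsFactors = FALSE))
  write_stage(qc_report, cfg$out_dir, "qc")

  kept_maps <- pooled[kept$sample_id]
  partitions <- lapply(kept_maps, extract_margin,
                       depth_tiles = cfg$margin_depth)
  eligible <- vapply(seq_len(nrow(kept)), function(i)
    margin_eligibility(kept[i, ]), logical(1))
  mprofiles <- lapply(which(eligible), function(i)
    margin_profile(kept_maps[[i]], partitions[[i]]))
  margins <- if (length(mprofiles)) margin_profile_table(mprofiles) else NULL
  if (!is.null(margins)) {
    margins$class_normal <- enrichment_classes(margins$ratio_texture_normal)
    write_stage(margins, cfg$out_dir, "margins")
  }

  lympho <- lympho_profiles(kept_maps, cfg$harmonisation)
  lympho$infiltration_class <- centre_binarise(
    stats::setNames(lympho[[cfg$binarise_on]], lympho$sample_id),
    cohort, cfg$harmonisation)
  write_stage(lympho, cfg$out_dir, "lympho")
  harmon <- harmonisation_report(lympho)

  stats_rows <- list()
  if (length(unique(kept$n_class)) == 2)
    stats_rows$alpha_by_nclass <- within(
      associate(lympho$alpha, kept$n_class[match(lympho$sample_id, kept$sample_id)],
                feature = "alpha"), group_var <- "n_class")
  if (length(unique(lympho$centre_id)) >= 3)
    stats_rows$density_by_centre <- within(
      associate(lympho$total_density, lympho$centre_id,
                feature = "total_density"), group_var <- "centre_id")
  stats_tab <- if (length(stats_rows)) {
    st <- do.call(rbind, stats_rows)
    st$p_adjusted <- adjust_bh(st$p_value)
    rownames(st) <- NULL
    st
  } else NULL
  if (!is.null(stats_tab)) write_stage(stats_tab, cfg$out_dir, "stats")

  surv <- NULL
  cls <- lympho$infiltration_class
  if (all(c("os_months", "os_event") %in% names(cohort)) &&
      length(unique(stats::na.omit(cls))) == 2) {
    idx <- match(lympho$sample_id, cohort$sample_id)
    surv <- survival_logrank(cohort$os_months[idx], cohort$os_event[idx], cls)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctmap")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("qc", "harmonisation"))],
    qc_policy = unclass(cfg$qc),
    harmonisation = unclass(cfg$harmonisation),
    counts = list(input_maps = length(maps),
                  cohort_rows = nrow(cohort),
                  kept = nrow(kept),
                  excluded = nrow(qc$excluded),
                  excluded_by_reason = as.list(qc$counts),
                  margin_eligible = sum(eligible)),
    warnings = list(missing_map = check$missing_map$sample_id,
                    orphan_map = check$orphan_map$sample_id))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(maps = maps, pooled = pooled, profiles = kept, qc = qc,
                 partitions = partitions, margins = margins, lympho = lympho,
                 harmonisation = harmon, stats = stats_tab, survival = surv,
                 manifest = manifest))
}
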