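#' Configuration for a synthetic tile-map cohort
#'
#' Describes a cohort of spatially coherent synthetic samples with known
#' ground truth, emulating the features of multi-centre whole-slide cohorts
#' that the package's pipeline must cope with: centre-specific sampling
#' conventions (some centres sample across the tumour border, others the
#' tumour core only), centre-biased texture composition, a texture-specific
#' lymphocyte enrichment shared by all centres, and a per-centre
#' multiplicative stain-intensity bias on the lymphocyte scores.
#'
#' Each sample is an elliptical cancer core inside an empty border. An
#' "N+ style" sample surrounds the core with a stroma-dominated ring and an
#' outer normal-tissue rim; an "N- style" sample fills the non-core interior
#' with a stroma/blood/other mixture drawn from per-centre Dirichlet
#' concentrations and contains no normal tissue. Blood/other speckles are
#' injected everywhere so majority-vote pooling has something to smooth.
#' Per-tile lymphocyte scores are clip(b_c * e_t + noise, 0, 1) where e_t is
#' the shared texture enrichment and b_c the centre stain bias.
#'
#' @param seed Integer seed; a fixed seed yields a byte-identical cohort.
#' @param n_centres,samples_per_centre Cohort layout.
#' @param grid c(rows, cols) tile-grid shape per sample.
#' @param geometry A \code{\link{tile_geometry}} (default 256 px, 0.25
#'   um/px).
#' @param p_nplus Per-centre probability that a sample is N+ style (recycled
#'   to \code{n_centres}).
#' @param core_frac Per-centre mean cancer-core radius as a fraction of the
#'   interior half-size (recycled).
#' @param ring_width Stroma-ring width relative to the core radius.
#' @param noncore_alpha Dirichlet concentrations (stroma, blood, other) for
#'   the N- style non-core fill; one row per centre or a single vector.
#' @param enrichment Named ground-truth lymphocyte enrichment e_t per tissue
#'   texture; the default ordering normal > cancer > stroma > blood > other
#'   follows the density ordering typically seen in renal sections.
#' @param stain_bias_sd SD of log b_c, the per-centre stain bias.
#' @param noise_sd SD of the Gaussian per-tile score noise.
#' @param speckle_rate Per-tile probability of replacing a tissue label with
#'   a blood/other speckle.
#' @param border Empty-border width in tiles.
#' @param surv_median_months Baseline median overall survival of the
#'   exponential survival model.
#' @param surv_beta Log hazard ratio linking survival to the N+ truth
#'   covariate (0 = no association).
#' @return A \code{synthetic_cohort_config} list.
#' @export
synthetic_cohort_config <- function(seed = 1L, n_centres = 4L,
                                    samples_per_centre = 25L,
                                    grid = c(48L, 48L),
                                    geometry = tile_geometry(256, 0.25),
                                    p_nplus = c(0.95, 0.70, 0.35, 0.05),
                                    core_frac = c(0.35, 0.40, 0.45, 0.55),
                                    ring_width = 0.5,
                                    noncore_alpha = c(stroma = 6, blood = 1.5, other = 2.5),
                                    enrichment = c(blood = 0.15, cancer = 0.35,
                                                   normal = 0.45, stroma = 0.25,
                                                   other = 0.08),
                                    stain_bias_sd = 0.15, noise_sd = 0.05,
                                    speckle_rate = 0.04, border = 2L,
                                    surv_median_months = 60,
                                    surv_beta = 0.7) {
  stopifnot(n_centres >= 1, samples_per_centre >= 1, length(grid) == 2,
            all(grid >= 8), all(p_nplus >= 0 & p_nplus <= 1),
            all(enrichment > 0), stain_bias_sd >= 0, noise_sd >= 0,
            speckle_rate >= 0, speckle_rate < 1, border >= 1)
  stopifnot(setequal(names(enrichment), tissue_textures()))
  p_nplus <- rep_len(p_nplus, n_centres)
  core_frac <- rep_len(core_frac, n_centres)
  if (is.null(dim(noncore_alpha)))
    noncore_alpha <- matrix(noncore_alpha, n_centres, 3, byrow = TRUE,
                            dimnames = list(NULL, c("stroma", "blood", "other")))
  structure(list(seed = as.integer(seed), n_centres = as.integer(n_centres),
                 samples_per_centre = as.integer(samples_per_centre),
                 grid = as.integer(grid), geometry = geometry,
                 p_nplus = p_nplus, core_frac = core_frac,
                 ring_width = ring_width, noncore_alpha = noncore_alpha,
                 enrichment = enrichment[tissue_textures()],
                 stain_bias_sd = stain_bias_sd, noise_sd = noise_sd,
                 speckle_rate = speckle_rate, border = as.integer(border),
                 surv_median_months = surv_median_months,
                 surv_beta = surv_beta),
            class = "synthetic_cohort_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate one synthetic sample
#'
#' Draws from the current RNG state (seed it, or use
#' \code{\link{generate_cohort}} which seeds from the config).
#'
#' @param cfg A \code{\link{synthetic_cohort_config}}.
#' @param centre Centre index in 1..n_centres.
#' @param sample_id Sample identifier.
#' @param stain_bias Centre stain bias b_c; drawn per centre by
#'   \code{\link{generate_cohort}}.
#' @param style Force "N_plus" or "N_minus" style; default draws from the
#'   centre's p_nplus.
#' @return List with \code{map} (a \code{\link{tile_map}} carrying scores)
#'   and \code{truth} (one-row data.frame: style, stain bias, core/ring
#'   geometry).
#' @export
generate_sample <- function(cfg, centre, sample_id = "synthetic",
                            stain_bias = 1, style = NULL) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"),
            centre >= 1, centre <= cfg$n_centres)
  nr <- cfg$grid[1]; nc <- cfg$grid[2]; b <- cfg$border
  if (is.null(style))
    style <- if (stats::runif(1) < cfg$p_nplus[centre]) "N_plus" else "N_minus"
  interior_r <- (nr - 2 * b) / 2
  interior_c <- (nc - 2 * b) / 2
  frac <- cfg$core_frac[centre] * stats::runif(1, 0.8, 1.2)
  ar <- frac * interior_r * stats::runif(1, 0.85, 1.15)
  ac <- frac * interior_c * stats::runif(1, 0.85, 1.15)
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  rad <- sqrt(outer(((seq_len(nr) - r0) / ar)^2,
                    ((seq_len(nc) - c0) / ac)^2, `+`))

  tx <- matrix("empty", nr, nc)
  inside <- matrix(FALSE, nr, nc)
  inside[(b + 1):(nr - b), (b + 1):(nc - b)] <- TRUE
  core <- inside & rad <= 1
  if (!any(core))
    stop("grid too small for the requested cancer core (no core tile)")
  tx[core] <- "cancer"
  ring_w <- cfg$ring_width * stats::runif(1, 0.8, 1.2)
  noncore <- inside & !core
  if (style == "N_plus") {
    ring <- noncore & rad <= 1 + ring_w
    rim <- noncore & rad > 1 + ring_w
    tx[ring] <- "stroma"
    tx[rim] <- "normal"
  } else {
    probs <- rdirichlet1(cfg$noncore_alpha[centre, ])
    n_fill <- sum(noncore)
    tx[noncore] <- sample(colnames(cfg$noncore_alpha), n_fill,
                          replace = TRUE, prob = probs)
  }
  # speckle noise for the pooling stage to clean up
  tissue <- tx %in% tissue_textures()
  spk <- tissue & stats::runif(length(tx)) < cfg$speckle_rate
  if (any(spk))
    tx[spk] <- sample(c("blood", "other"), sum(spk), replace = TRUE)

  e <- cfg$enrichment
  sc <- matrix(NA_real_, nr, nc)
  tis <- which(tx %in% tissue_textures())
  sc[tis] <- pmin(1, pmax(0, stain_bias * e[tx[tis]] +
                            stats::rnorm(length(tis), 0, cfg$noise_sd)))
  map <- tile_map(tx, sc, sample_id = sample_id,
                  centre_id = sprintf("centre_%02d", centre),
                  geometry = cfg$geometry)
  truth <- data.frame(sample_id = sample_id,
                      centre_id = sprintf("centre_%02d", centre),
                      style = style, stain_bias = stain_bias,
                      core_frac = frac, ring_width = ring_w,
                      stringsAsFactors = FALSE)
  list(map = map, truth = truth)
}

#' Generate a reproducible synthetic cohort
#'
#' Seeds the RNG from the config, draws one stain bias per centre
#' (lognormal around 1), generates every sample, and attaches exponential
#' synthetic survival optionally linked to the N+ truth covariate
#' (administrative censoring window 24-120 months).
#'
#' @param cfg A \code{\link{synthetic_cohort_config}}.
#' @return List with \code{maps} (named list of \code{\link{tile_map}}),
#'   \code{cohort} (data.frame: sample_id, centre_id, microns_per_px,
#'   os_months, os_event), \code{truth} (per-sample ground truth incl.
#'   stain bias and style) and \code{config}.
#' @examples
#' coh <- generate_cohort(synthetic_cohort_config(seed = 7, n_centres = 2,
#'                                                samples_per_centre = 3,
#'                                                grid = c(24, 24)))
#' length(coh$maps)
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  withr::with_seed(cfg$seed, {
    bias <- exp(stats::rnorm(cfg$n_centres, 0, cfg$stain_bias_sd))
    maps <- list(); truths <- list()
    for (ct in seq_len(cfg$n_centres)) {
      for (i in seq_len(cfg$samples_per_centre)) {
        sid <- sprintf("C%02d_S%03d", ct, i)
        g <- generate_sample(cfg, ct, sample_id = sid, stain_bias = bias[ct])
        maps[[sid]] <- g$map
        truths[[sid]] <- g$truth
      }
    }
    truth <- do.call(rbind, truths)
    rownames(truth) <- NULL
    n <- nrow(truth)
    rate0 <- log(2) / cfg$surv_median_months
    lp <- cfg$surv_beta * (truth$style == "N_plus")
    t_ev <- stats::rexp(n, rate = rate0 * exp(lp))
    t_cn <- stats::runif(n, 24, 120)
    cohort <- data.frame(sample_id = truth$sample_id,
                         centre_id = truth$centre_id,
                         microns_per_px = cfg$geometry$microns_per_px,
                         os_months = pmin(t_ev, t_cn),
                         os_event = as.integer(t_ev <= t_cn),
                         stringsAsFactors = FALSE)
    list(maps = maps, cohort = cohort, truth = truth, config = cfg)
  })
}

#' Write a synthetic cohort to disk
#'
#' One tile-map TSV per sample plus \code{cohort.tsv} and \code{truth.tsv},
#' the on-disk layout the pipeline consumes.
#'
#' @param cohort Result of \code{\link{generate_cohort}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps_dir <- file.path(dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)
  for (m in cohort$maps)
    write_tilemap(m, file.path(maps_dir, paste0(m$sample_id, ".tsv")))
  utils::write.table(cohort$cohort, file.path(dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
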