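test_that("texture densities are plain means over scored tiles", {
  tx <- matrix(c("cancer", "cancer", "cancer", "stroma"), 1, 4)
  m <- tile_map(tx, matrix(c(0.2, 0.4, 0.6, 1.0), 1, 4))
  d <- density_per_texture(m)
  expect_equal(d[["cancer"]], 0.4)
  expect_equal(d[["stroma"]], 1.0)
  expect_true(is.na(d[["normal"]]))  # absent texture is undefined

  all1 <- tile_map(matrix(c("blood", "other"), 1, 2), matrix(1, 1, 2))
  expect_equal(unname(density_per_texture(all1)[c("blood", "other")]), c(1, 1))
})

test_that("densities can be restricted to margin-partition regions", {
  tx <- matrix("normal", 5, 5); tx[3, 3] <- "cancer"
  sc <- matrix(0.2, 5, 5); sc[3, 3] <- 0.9; sc[1, 1] <- 0.6
  m <- tile_map(tx, sc)
  p <- extract_margin(m, 1)
  d <- density_per_texture(m, p)
  expect_equal(d["core", "cancer"], 0.9)
  expect_equal(d["margin", "normal"], 0.2)
  # (1,1) is outside the 3x3 margin ring
  expect_equal(d["non_margin", "normal"], mean(c(0.6, rep(0.2, 15))))
  expect_error(density_per_texture(m, extract_margin(random_map(3, 3))),
               "does not match")
})

test_that("relative proportions rescale defined densities to 100%", {
  rho <- relative_proportions(c(blood = .10, cancer = .30, normal = .40,
                                stroma = .15, other = .05))
  expect_equal(unname(rho[c("blood", "cancer", "normal", "stroma", "other")]),
               c(10, 30, 40, 15, 5))
  expect_equal(as.numeric(relative_proportions(
    c(blood = .2, cancer = .2, normal = .2, stroma = .2, other = .2))),
    rep(20, 5))
  part <- relative_proportions(c(cancer = 0.3, stroma = 0.1))
  expect_equal(part[["cancer"]], 75)
  expect_equal(part[["stroma"]], 25)
  expect_equal(part[["normal"]], 0)
  expect_setequal(attr(part, "undefined"), c("blood", "normal", "other"))
})

test_that("all-zero densities degrade to a flagged uniform rho", {
  rho <- relative_proportions(c(cancer = 0, stroma = 0))
  expect_true(attr(rho, "degenerate"))
  expect_equal(unname(rho[c("cancer", "stroma")]), c(50, 50))
  expect_error(relative_proportions(c(cancer = NA_real_)), "no defined")
})

test_that("alpha is the area-weighted mean of rho", {
  rho <- c(blood = 10, cancer = 40, normal = 30, stroma = 15, other = 5)
  A <- c(blood = 10, cancer = 50, normal = 20, stroma = 15, other = 5)
  expect_equal(ctm_alpha(rho, A), 29.5)  # (100+2000+600+225+25)/100
  expect_equal(ctm_alpha(setNames(rep(20, 5), names(rho)), A), 20)
  expect_equal(ctm_alpha(c(cancer = 37), c(cancer = 123)), 37)
  expect_error(ctm_alpha(rho, A * 0), "positive")
})

test_that("alpha is invariant to the units areas are measured in", {
  set.seed(33)
  for (i in 1:10) {
    rho <- relative_proportions(setNames(runif(5, .05, .5), tissue_textures()))
    A <- setNames(sample(1:60, 5), tissue_textures())
    expect_equal(ctm_alpha(rho, A), ctm_alpha(rho, A * 256^2))
  }
})

test_that("every profiled sample satisfies the rho and alpha invariants", {
  coh <- generate_cohort(biased_cohort_config(seed = 77, samples_per_centre = 5))
  ly <- lympho_profiles(coh$maps)
  rho <- as.matrix(ly[, paste0("rho_", tissue_textures())])
  expect_equal(unname(rowSums(rho)), rep(100, nrow(ly)), tolerance = 1e-6)
  expect_true(all(ly$alpha >= apply(rho, 1, min) - 1e-9))
  expect_true(all(ly$alpha <= apply(rho, 1, max) + 1e-9))
  expect_true(all(ly$total_density >= 0 & ly$total_density <= 1))
})

test_that("cohort-median rho applies one shared profile to every sample", {
  coh <- generate_cohort(biased_cohort_config(seed = 12, samples_per_centre = 4))
  ly <- lympho_profiles(coh$maps, harmonisation_config(rho_source = "cohort_median"))
  rho <- as.matrix(ly[, paste0("rho_", tissue_textures())])
  expect_true(all(apply(rho, 2, function(v) diff(range(v)) == 0)))
})

test_that("centre binarisation splits at the centre median, ties Low", {
  cohort <- data.frame(sample_id = paste0("s", 1:21),
                       centre_id = "c1", microns_per_px = 0.25)
  v <- setNames(as.numeric(1:21), cohort$sample_id)
  cls <- centre_binarise(v, cohort)
  expect_identical(cls[v == 21], "High")
  expect_identical(cls[v == 1], "Low")
  expect_identical(cls[v == 11], "Low")  # the median itself
  expect_identical(sum(cls == "High"), 10L)

  # strict-median rule caps High at ceiling(n/2)
  expect_lte(sum(cls == "High"), ceiling(21 / 2))

  allequal <- centre_binarise(setNames(rep(3, 21), cohort$sample_id), cohort)
  expect_identical(unique(allequal), "Low")
})

test_that("centres at or below 20 samples, or excluded, are unclassified", {
  cohort <- data.frame(sample_id = paste0("s", 1:20),
                       centre_id = "small", microns_per_px = 0.25)
  v <- setNames(runif(20), cohort$sample_id)
  expect_true(all(is.na(centre_binarise(v, cohort))))

  cohort2 <- data.frame(sample_id = paste0("t", 1:21),
                        centre_id = "fox", microns_per_px = 0.25)
  v2 <- setNames(runif(21), cohort2$sample_id)
  cls <- centre_binarise(v2, cohort2,
                         harmonisation_config(excluded_centres = "fox"))
  expect_true(all(is.na(cls)))
})

test_that("harmonisation shrinks between-centre dispersion on biased cohorts", {
  coh <- generate_cohort(biased_cohort_config(seed = 5, samples_per_centre = 10))
  rep <- harmonisation_report(lympho_profiles(coh$maps))
  expect_false(rep$degenerate)
  expect_lt(rep$variance_ratio, 1)
  expect_lt(rep$kruskal$statistic[rep$kruskal$measure == "alpha"],
            rep$kruskal$statistic[rep$kruskal$measure == "raw"])
})

test_that("a single-centre report is degenerate", {
  coh <- generate_cohort(synthetic_cohort_config(seed = 2, n_centres = 1,
                                                 samples_per_centre = 3,
                                                 grid = c(24, 24)))
  expect_true(harmonisation_report(lympho_profiles(coh$maps))$degenerate)
})
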