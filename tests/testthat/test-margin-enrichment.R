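# Build a partition object directly so region contents are fully controlled.
manual_partition <- function(regions, sample_id = "s", depth = 2L) {
  structure(list(sample_id = sample_id, regions = regions,
                 depth_tiles = depth),
            class = "region_partition")
}

test_that("margin:non-margin texture ratios compare region compositions", {
  # margin: 2 stroma + 3 normal; non-margin: 1 stroma + 4 normal
  tx <- matrix(c("stroma", "stroma", "normal", "normal", "normal",
                 "stroma", "normal", "normal", "normal", "normal"), 2, 5,
               byrow = TRUE)
  reg <- matrix(rep(c("margin", "non_margin"), each = 5), 2, 5, byrow = TRUE)
  p <- margin_profile(tile_map(tx), manual_partition(reg))
  expect_equal(p$ratio_texture[["stroma"]], (2 / 5) / (1 / 5))  # 2.0
  expect_equal(p$ratio_texture[["normal"]], (3 / 5) / (4 / 5))
  expect_true(is.na(p$ratio_texture[["cancer"]]))  # 0/0
  expect_false(p$flag)
})

test_that("a zero denominator yields NA unless pseudocounts are requested", {
  tx <- matrix(c("normal", "stroma", "stroma", "stroma"), 2, 2)
  reg <- matrix(c("margin", "non_margin", "margin", "non_margin"), 2, 2)
  p <- margin_profile(tile_map(tx), manual_partition(reg))
  expect_true(is.na(p$ratio_texture[["normal"]]))  # normal absent non-margin
  pp <- margin_profile(tile_map(tx), manual_partition(reg), pseudo = TRUE)
  expect_true(is.finite(pp$ratio_texture[["normal"]]))
})

test_that("identical region compositions give unit ratios", {
  tx <- matrix(rep(c("stroma", "normal"), 8), 4, 4)
  reg <- matrix(rep(c("margin", "margin", "non_margin", "non_margin"), 4), 4, 4,
                byrow = TRUE)
  p <- margin_profile(tile_map(tx), manual_partition(reg))
  def <- !is.na(p$ratio_texture)
  expect_equal(unname(p$ratio_texture[def]), rep(1, sum(def)))
})

test_that("swapping margin and non-margin inverts every defined ratio", {
  set.seed(61)
  for (i in 1:10) {
    m <- random_map(8, 8, scores = TRUE)
    reg <- matrix(sample(c("margin", "non_margin"), 64, replace = TRUE), 8, 8)
    reg[m$textures == "empty"] <- "background"
    swapped <- reg
    swapped[reg == "margin"] <- "non_margin"
    swapped[reg == "non_margin"] <- "margin"
    p1 <- margin_profile(m, manual_partition(reg))
    p2 <- margin_profile(m, manual_partition(swapped))
    for (slot in c("ratio_texture", "ratio_lympho")) {
      a <- p1[[slot]]; b <- p2[[slot]]
      def <- !is.na(a) & !is.na(b) & a > 0
      expect_equal(unname(b[def]), unname(1 / a[def]))
    }
    if (!is.na(p1$ratio_lympho_total) && p1$ratio_lympho_total > 0)
      expect_equal(p2$ratio_lympho_total, 1 / p1$ratio_lympho_total)
  }
})

test_that("an empty margin flags the sample and voids all ratios", {
  tx <- matrix("stroma", 3, 3)
  reg <- matrix("non_margin", 3, 3)
  p <- margin_profile(tile_map(tx), manual_partition(reg))
  expect_true(p$flag)
  expect_true(all(is.na(p$ratio_texture)))
  expect_true(is.na(p$ratio_lympho_total))
})

test_that("lymphocyte ratios compare region mean scores", {
  tx <- matrix("stroma", 2, 2)
  sc <- matrix(c(0.8, 0.8, 0.2, 0.2), 2, 2)
  reg <- matrix(c("margin", "margin", "non_margin", "non_margin"), 2, 2)
  p <- margin_profile(tile_map(tx, sc), manual_partition(reg))
  expect_equal(p$ratio_lympho[["stroma"]], 4)
  expect_equal(p$ratio_lympho_total, 4)
})

test_that("enrichment classes split at the cohort quantile and keep NA", {
  expect_identical(table(enrichment_classes(1:10))[["High"]], 5L)
  expect_identical(table(enrichment_classes(1:10))[["Low"]], 5L)
  expect_true(all(is.na(enrichment_classes(c(NA, NA, NA)))))
  cls <- enrichment_classes(1:8, quantile = 0.75)
  expect_identical(sum(cls == "High"), 2L)  # type-7 quantile at 6.25
  withNA <- enrichment_classes(c(1, NA, 10))
  expect_identical(withNA, c("Low", NA, "High"))
})

test_that("margin profile tables collect per-sample ratios", {
  coh <- generate_cohort(biased_cohort_config(seed = 31, samples_per_centre = 3))
  mp <- lapply(coh$maps, function(m) margin_profile(m, extract_margin(m)))
  tab <- margin_profile_table(mp)
  expect_identical(nrow(tab), length(coh$maps))
  expect_true(all(c("ratio_texture_stroma", "ratio_lympho_total") %in% names(tab)))
})
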