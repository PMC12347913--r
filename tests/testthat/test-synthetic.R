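empty_spec <- function(seed = 1, ...) {
  scene_spec(kind = "core", seed = seed, microns_per_pixel = 1,
             cortex_area_mm2 = 1, core_width_mm = 0.5,
             medulla_area_mm2 = 0.2,
             n_nsg = 0, n_gsg = 0, n_empty = 0, n_edge_glomeruli = 0,
             tubule_fill = 0, n_ta = 0, n_arteries = 0, n_arterioles = 0,
             n_ah = 0, n_interlobar = 0, ...)
}

test_that("an all-empty scene yields all-zero structural counts", {
  g <- generate_section(empty_spec())
  res <- quantify(g$section)
  expect_equal(res$nsg_count, 0)
  expect_equal(res$gsg_count, 0)
  expect_equal(res$empty_capsule_count, 0)
  expect_equal(res$ta_foci_count, 0)
  expect_equal(res$ah_lesion_count, 0)
  expect_true(is.na(res$glomerular_volume_mm3))
  expect_true(is.na(res$pct_gsg))
  expect_true(is.na(res$pct_luminal_stenosis))
  expect_true("pct_gsg" %in% names(res$missing))
  expect_gt(res$cortex_area_mm2, 0.9)
})

test_that("a fixed seed reproduces the scene bit-identically", {
  sp <- donor_scene_spec(cortex_area_mm2 = 0.3, seed = 77)
  a <- generate_section(sp)
  b <- generate_section(sp)
  expect_identical(a$section$masks, b$section$masks)
  expect_identical(a$section$capsule, b$section$capsule)
  expect_identical(a$truth$measures, b$truth$measures)
  # a different seed changes the scene
  c <- generate_section(donor_scene_spec(cortex_area_mm2 = 0.3, seed = 78))
  expect_false(identical(a$section$masks, c$section$masks))
})

test_that("18 NSG + 2 GSG gives 10% GSG in truth and in measurement", {
  sp <- scene_spec(kind = "core", seed = 9, microns_per_pixel = 1,
                   cortex_area_mm2 = 3, n_nsg = 18, n_gsg = 2, n_empty = 0,
                   n_edge_glomeruli = 0, tubule_fill = 0.15, n_ta = 1,
                   n_arteries = 1, n_arterioles = 2, n_ah = 1,
                   n_interlobar = 0, medulla_area_mm2 = 0)
  g <- generate_section(sp)
  expect_equal(g$truth$measures$pct_gsg, 10)
  res <- quantify(g$section)
  expect_equal(res$nsg_count, 18)
  expect_equal(res$gsg_count, 2)
  expect_equal(res$pct_gsg, 10)
})

test_that("infeasible packing raises an explicit error, never truncates", {
  sp <- scene_spec(kind = "core", seed = 2, cortex_area_mm2 = 0.05,
                   core_width_mm = 0.25, n_nsg = 40, n_gsg = 0, n_empty = 0,
                   n_edge_glomeruli = 0, n_ta = 0, n_arteries = 0,
                   n_arterioles = 0, n_ah = 0, n_interlobar = 0,
                   medulla_area_mm2 = 0, tubule_fill = 0)
  expect_error(generate_section(sp), class = "nephromorph_packing_error")
})

test_that("zero-magnitude perturbation returns an identical section", {
  g <- small_scene(seed = 31, cortex = 0.25)
  p <- perturb_annotation(g$section, dilate_px = 0, erode_px = 0)
  expect_identical(p$masks, g$section$masks)
})

test_that("pure dilation keeps sensitivity at 100% and lowers precision", {
  g <- small_scene(seed = 32, cortex = 0.25)
  p <- perturb_annotation(g$section, dilate_px = 1,
                          classes = "Nonglobally sclerosed glomeruli")
  row <- pairwise_agreement(p, g$section, "Nonglobally sclerosed glomeruli")
  expect_equal(row$sensitivity, 100)
  expect_lt(row$precision, 100)
})

test_that("flipping all GSG to NSG zeroes GSG sensitivity", {
  sp <- scene_spec(kind = "core", seed = 12, microns_per_pixel = 1,
                   cortex_area_mm2 = 1.5, n_nsg = 3, n_gsg = 2, n_empty = 0,
                   n_edge_glomeruli = 0, tubule_fill = 0, n_ta = 0,
                   n_arteries = 0, n_arterioles = 0, n_ah = 0,
                   n_interlobar = 0, medulla_area_mm2 = 0)
  g <- generate_section(sp)
  p <- perturb_annotation(g$section, flip = data.frame(
    from = "Globally sclerosed glomeruli",
    to = "Nonglobally sclerosed glomeruli", rate = 1))
  row <- pairwise_agreement(p, g$section, "Globally sclerosed glomeruli")
  expect_equal(row$sensitivity, 0)
})

test_that("generated glomerular areas match the declared distribution", {
  # across 100 seeds the empirical mean must land within 3 standard errors
  sp0 <- scene_spec(kind = "core", microns_per_pixel = 1,
                    cortex_area_mm2 = 0.25, core_width_mm = 0.5,
                    medulla_area_mm2 = 0, n_nsg = 4, n_gsg = 0, n_empty = 0,
                    n_edge_glomeruli = 0, tubule_fill = 0, n_ta = 0,
                    n_arteries = 0, n_arterioles = 0, n_ah = 0,
                    n_interlobar = 0,
                    glom_area_mean_um2 = 16150, glom_area_sd_um2 = 4000)
  areas <- unlist(lapply(1:100, function(k) {
    sp <- sp0; sp$seed <- k
    tr <- generate_section(sp)$truth
    tr$structures$area_um2[tr$structures$type == "nsg"]
  }))
  expect_equal(length(areas), 400)
  se <- 4000 / sqrt(length(areas))
  expect_lt(abs(mean(areas) - 16150), 3 * se)
})
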