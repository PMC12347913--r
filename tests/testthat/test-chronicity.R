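test_that("band scores reproduce the printed thresholds", {
  b <- chronicity_bands()
  # TA focus density: <=5 -> 0, 6-10 -> 1, 11-20 -> 2, > 20 -> 3
  expect_equal(band_score(15, b$ta_foci_density_per_mm2), 2L)
  expect_equal(band_score(5, b$ta_foci_density_per_mm2), 0L)
  expect_equal(band_score(20, b$ta_foci_density_per_mm2), 2L)
  expect_equal(band_score(21, b$ta_foci_density_per_mm2), 3L)
  # AH area: <=500 -> 0, 501-750 -> 1, 751-1000 -> 2, > 1000 -> 3
  expect_equal(band_score(800, b$mean_ah_area_um2), 2L)
  expect_equal(band_score(500, b$mean_ah_area_um2), 0L)
  expect_equal(band_score(1000.5, b$mean_ah_area_um2), 3L)
  # cortex per glomerulus: <=0.075, 0.076-0.125, 0.126-0.175, > 0.175
  expect_equal(band_score(0.15, b$cortex_per_glomerulus_mm3), 2L)
  expect_equal(band_score(0.075, b$cortex_per_glomerulus_mm3), 0L)
  expect_equal(band_score(0.2, b$cortex_per_glomerulus_mm3), 3L)
  # %GSG / %ITA: half-open reading of <10, 10-25, 26-50, >50
  expect_equal(band_score(9.9, b$pct_gsg), 0L)
  expect_equal(band_score(10, b$pct_gsg), 1L)
  expect_equal(band_score(25.5, b$pct_gsg), 1L)
  expect_equal(band_score(26, b$pct_gsg), 2L)
  expect_equal(band_score(50, b$pct_gsg), 2L)
  expect_equal(band_score(50.1, b$pct_gsg), 3L)
  expect_true(is.na(band_score(NA, b$pct_gsg)))
  expect_error(band_spec("x", c(1, 1, 2)), "ascending")
})

test_that("each banding is a 4-level step function with jumps at the cuts", {
  for (b in chronicity_bands()) {
    hi <- b$cuts[3] * 2
    grid <- sort(unique(c(seq(0, hi, length.out = 4001),
                          b$cuts - 1e-9, b$cuts, b$cuts + 1e-9)))
    scores <- vapply(grid, band_score, integer(1), spec = b)
    expect_setequal(unique(scores), 0:3)
    jumps <- grid[which(diff(scores) != 0)]
    expect_equal(length(jumps), 3)
    expect_true(all(abs(jumps - b$cuts) <= 1e-9 * pmax(1, b$cuts)))
    expect_true(all(diff(scores) >= 0))   # monotone steps
  }
})

test_that("the two 0-12 scores sum their four banded components", {
  low <- list(pct_gsg = 1, pct_ita_per_tubulointerstitial = 5,
              ta_foci_density_per_mm2 = 1, mean_ah_area_um2 = 100,
              cortex_per_glomerulus_mm3 = 0.05)
  high <- list(pct_gsg = 90, pct_ita_per_tubulointerstitial = 90,
               ta_foci_density_per_mm2 = 50, mean_ah_area_um2 = 5000,
               cortex_per_glomerulus_mm3 = 0.5)
  mid <- list(pct_gsg = 30, pct_ita_per_tubulointerstitial = 30,
              ta_foci_density_per_mm2 = 15, mean_ah_area_um2 = 800,
              cortex_per_glomerulus_mm3 = 0.15)
  expect_equal(nephrosclerosis_score(low)$total, 0L)
  expect_equal(hypertrophy_score(low)$total, 0L)
  expect_equal(nephrosclerosis_score(high)$total, 12L)
  expect_equal(hypertrophy_score(high)$total, 12L)
  expect_equal(nephrosclerosis_score(mid)$total, 8L)   # 2+2+2+2
  expect_equal(hypertrophy_score(mid)$total, 8L)
  # boundary case: everything at its first cut scores 0
  at_cuts <- list(pct_gsg = 9, ta_foci_density_per_mm2 = 5,
                  mean_ah_area_um2 = 500, cortex_per_glomerulus_mm3 = 0.075)
  expect_equal(hypertrophy_score(at_cuts)$total, 0L)
})

test_that("exchanging %ITA and cortex-per-glomerulus converts the scores", {
  m <- list(pct_gsg = 12, ta_foci_density_per_mm2 = 7,
            mean_ah_area_um2 = 600,
            pct_ita_per_tubulointerstitial = 40,
            cortex_per_glomerulus_mm3 = 0.05)
  swapped <- m
  # give cortex-per-glom the band that %ITA had (band 2) and vice versa (0)
  swapped$cortex_per_glomerulus_mm3 <- 0.15   # band 2, like %ITA 40
  swapped$pct_ita_per_tubulointerstitial <- 5 # band 0, like cpg 0.05
  expect_equal(nephrosclerosis_score(m)$total, hypertrophy_score(swapped)$total)
  expect_equal(hypertrophy_score(m)$total, nephrosclerosis_score(swapped)$total)
})

test_that("both totals are monotone in every underlying measure", {
  set.seed(11)
  base <- list(pct_gsg = 12, pct_ita_per_tubulointerstitial = 20,
               ta_foci_density_per_mm2 = 7, mean_ah_area_um2 = 600,
               cortex_per_glomerulus_mm3 = 0.1)
  for (i in 1:50) {
    m1 <- lapply(base, function(v) v * runif(1, 0.2, 3))
    m2 <- m1
    nm <- sample(names(base), 1)
    m2[[nm]] <- m1[[nm]] * runif(1, 1, 3)     # increase one measure
    expect_gte(nephrosclerosis_score(m2)$total,
               nephrosclerosis_score(m1)$total)
    expect_gte(hypertrophy_score(m2)$total, hypertrophy_score(m1)$total)
  }
})

test_that("missing components propagate by default but can impute zero", {
  m <- list(pct_gsg = 12, pct_ita_per_tubulointerstitial = 20,
            ta_foci_density_per_mm2 = 7, mean_ah_area_um2 = NA)
  expect_true(is.na(nephrosclerosis_score(m)$total))
  expect_equal(nephrosclerosis_score(m, missing_policy = "zero")$total, 3L)
})

test_that("reference reports flag values above the donor-derived limit", {
  set.seed(4)
  ref <- data.frame(pct_gsg = runif(100, 0, 8),
                    mean_ah_area_um2 = runif(100, 0, 300))
  patient_ok <- list(pct_gsg = 1, mean_ah_area_um2 = 50)
  rep_ok <- reference_report(patient_ok, ref)
  expect_false(any(rep_ok$flagged))
  # degenerate constant reference: any exceedance flags
  const_ref <- data.frame(pct_gsg = rep(3, 100))
  rep_hi <- reference_report(list(pct_gsg = 4), const_ref)
  expect_true(rep_hi$flagged[rep_hi$measure == "pct_gsg"])
  expect_equal(rep_hi$upper_limit[1], 3)
  # order-statistic check: 95th percentile of uniform(0,1), n = 10000
  set.seed(21)
  unif_ref <- data.frame(pct_gsg = runif(10000))
  lim <- reference_report(list(pct_gsg = 0.5), unif_ref)$upper_limit[1]
  expect_lt(abs(lim - 0.95), 0.02)
  # too few reference observations: limit omitted with a note
  tiny <- data.frame(pct_gsg = runif(10))
  rep_tiny <- reference_report(list(pct_gsg = 1), tiny)
  expect_true(is.na(rep_tiny$upper_limit[1]))
  expect_match(rep_tiny$note[1], "fewer than 20")
  # JSON rendering round-trips
  js <- jsonlite::fromJSON(report_json(rep_ok))
  expect_equal(js$reference_percentile, 0.95)
  expect_equal(nrow(js$measures), nrow(rep_ok))
})
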