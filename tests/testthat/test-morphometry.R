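test_that("Weibel-Gomez glomerular volume follows (beta/d) * A^1.5", {
  # direct arithmetic: (1.38/1.01) * 10000^1.5 um3 = 1.3663e6 um3
  expect_equal(glomerular_volume(10000), (1.38 / 1.01) * 1e6 / 1e9,
               tolerance = 1e-12)
  expect_equal(glomerular_volume(1, beta = 1, d = 1), 1e-9)
  expect_true(is.na(glomerular_volume(NA)))
  # inverting V = 0.0028 mm3 under defaults lands in a plausible donor range
  a_bar <- uniroot(function(a) glomerular_volume(a) - 0.0028,
                   c(1000, 1e5))$root
  expect_gt(a_bar, 15000)
  expect_lt(a_bar, 17500)
})

test_that("cortex per glomerulus applies the areal-to-volumetric conversion", {
  # arithmetic oracle: N_A = 2.46 / mm2, V = 0.0028 mm3, T = 2.5 um
  d_mm <- (6 * 0.0028 / pi)^(1 / 3)
  expect_equal(cortex_per_glomerulus(1, 2.46, 0.0028, 2.5),
               (d_mm + 0.0025) / 2.46, tolerance = 1e-12)
  expect_gt(cortex_per_glomerulus(1, 2.46, 0.0028, 2.5), 0.066)
  expect_lt(cortex_per_glomerulus(1, 2.46, 0.0028, 2.5), 0.078)
  # linearity: doubling cortex area at fixed count doubles the result
  expect_equal(cortex_per_glomerulus(2, 10, 0.0028),
               2 * cortex_per_glomerulus(1, 10, 0.0028))
  # degenerate N_V = 1 identity: count chosen so N_A = D + T per mm2
  v <- 0.004
  d <- (6 * v / pi)^(1 / 3)
  expect_equal(cortex_per_glomerulus(1, d + 0.0025, v, 2.5), 1)
  expect_true(is.na(cortex_per_glomerulus(1, 0, 0.0028)))
})

test_that("pct_gsg handles the printed worked cases and empty input", {
  expect_equal(pct_gsg(18, 2), 10)
  expect_equal(pct_gsg(7, 0), 0)
  expect_equal(pct_gsg(0, 5), 100)
  expect_true(is.na(pct_gsg(0, 0)))
})

test_that("mean tubular area averages exact areas, excluding clipped ones", {
  nx <- 300; ny <- 180
  # four 100x80 px rectangles at 0.5 um/px: 8000 px * 0.25 = 2000 um2 each
  mk <- function(x0, y0) rect_mask(nx, ny, x0, x0 + 99, y0, y0 + 79)
  prox <- mk(5, 5) | mk(110, 5) | mk(5, 95) | mk(110, 95)
  s <- build_section(list(`Proximal tubule` = prox), mpp = 0.5)
  expect_equal(mean_tubular_area(s, "proximal"), 2000)
  # a fifth tubule clipped at the cut edge is excluded from the mean
  clipped <- rect_mask(nx, ny, 250, 299, 0, 79)   # touches the x = nx-1 edge
  s2 <- build_section(list(`Proximal tubule` = prox | clipped), mpp = 0.5)
  expect_equal(suppressWarnings(mean_tubular_area(s2, "proximal")), 2000)
  cfg_keep <- morphometry_config(exclude_edge_bisected = FALSE)
  expect_false(isTRUE(all.equal(
    suppressWarnings(mean_tubular_area(s2, "proximal", cfg_keep)), 2000)))
  # tubules overlapping a TA cluster are excluded too
  ta <- rect_mask(nx, ny, 110, 130, 95, 120)
  s3 <- build_section(list(`Proximal tubule` = prox,
                           `Tubular atrophy cluster` = ta), mpp = 0.5)
  expect_equal(suppressWarnings(mean_tubular_area(s3, "proximal")), 2000)
  # no tubules at all: missing
  s4 <- build_section(list(Cortex = rect_mask(20, 20, 2, 17, 2, 17)))
  expect_true(is.na(mean_tubular_area(s4, "proximal")))
})

test_that("TA measures follow their printed definitions", {
  nx <- 400; ny <- 300
  # at 10 um/px: tubules 9500 px = 0.95 mm2, TA 500 px = 0.05 mm2
  tubules <- rect_mask(nx, ny, 0, 94, 0, 99)           # 9500 px
  ta <- rect_mask(nx, ny, 200, 224, 0, 19)             # 500 px
  ti <- rect_mask(nx, ny, 0, 299, 0, 199)              # 60000 px = 6 mm2
  s <- build_section(list(Tubulointerstitium = ti | ta, Tubules = tubules,
                          `Distal tubule` = tubules,
                          `Tubular atrophy cluster` = ta), mpp = 10)
  out <- ta_measures(s)
  expect_equal(out$pct_ta_per_tubular, 5)              # 0.05 / 1.00
  ti_mm2 <- sum(ti | ta) * 100 / 1e6
  expect_equal(out$pct_ita_per_tubulointerstitial,
               100 * (ti_mm2 - 0.95) / ti_mm2)
  expect_equal(out$ta_foci_density_per_mm2, 1)         # 1 focus / 1 mm2
  # 10 foci over 2.5 mm2 of tubular area -> 4 per mm2
  ta10 <- matrix(FALSE, nx, ny)
  for (k in 0:9) ta10[(100 + 20 * k):(104 + 20 * k) + 1, 251:255] <- TRUE
  stopifnot(sum(ta10) == 250)
  tub2 <- matrix(FALSE, nx, ny)
  tub2[1:99, 1:250] <- TRUE                            # 24750 px
  # denominator: tubules + TA = 25000 px = 2.5 mm2
  stopifnot(sum(tub2) + sum(ta10) == 25000)
  s2 <- build_section(list(Tubulointerstitium = ti | ta10 | tub2,
                           Tubules = tub2, `Proximal tubule` = tub2,
                           `Tubular atrophy cluster` = ta10), mpp = 10)
  expect_equal(ta_measures(s2)$ta_foci_density_per_mm2, 4)
  # absent denominators flag missing
  s3 <- build_section(list(Cortex = rect_mask(20, 20, 1, 18, 1, 18)))
  expect_true(is.na(ta_measures(s3)$pct_ta_per_tubular))
})

test_that("AH lesions merge below 500 um, strictly", {
  nx <- 2400; ny <- 200
  mk2 <- function(d_px) {
    # two 11x11 px lesions; nearest boundary-pixel centres are d_px+1 apart
    a <- rect_mask(nx, ny, 10, 20, 50, 60)
    b <- rect_mask(nx, ny, 21 + d_px, 31 + d_px, 50, 60)
    s <- build_section(list(`Arteriolar hyalinosis` = a | b), mpp = 0.5)
    comps <- extract_components(s, "Arteriolar hyalinosis")
    merge_ah_lesions(comps, 0.5)
  }
  # boundary distance 300.5 um -> one counted
  expect_equal(nrow(mk2(600)), 1)
  # boundary distance exactly 500 um -> strict inequality keeps both
  expect_equal(nrow(mk2(999)), 2)
  # boundary distance 499.5 um -> one
  expect_equal(nrow(mk2(998)), 1)
})

test_that("AH merging is transitive and keeps the largest representative", {
  nx <- 4000; ny <- 120
  # chain: A-B and B-C about 400 um apart, A-C about 810 um
  A <- rect_mask(nx, ny, 0, 10, 40, 50)        # 11x11
  B <- rect_mask(nx, ny, 811, 831, 35, 55)     # 21x21, the largest
  C <- rect_mask(nx, ny, 1632, 1642, 40, 50)
  s <- build_section(list(`Arteriolar hyalinosis` = A | B | C), mpp = 0.5)
  comps <- extract_components(s, "Arteriolar hyalinosis")
  merged <- merge_ah_lesions(comps, 0.5)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_lesions, 3L)
  expect_equal(merged$n_px, 441L)    # the 21x21 lesion represents the cluster
  # matches the exhaustive pairwise transitive-closure oracle
  gaps <- matrix(Inf, 3, 3)
  gaps[1, 2] <- gaps[2, 1] <- (811 - 10) * 0.5
  gaps[2, 3] <- gaps[3, 2] <- (1632 - 831) * 0.5
  gaps[1, 3] <- gaps[3, 1] <- (1632 - 10) * 0.5
  expect_equal(nrow(merged), merge_count_oracle(gaps, 3, 500))
  # merge idempotence: merging the merged set changes nothing
  again <- merge_ah_lesions(merged, 0.5)
  expect_equal(nrow(again), nrow(merged))
  expect_equal(again$area_um2, merged$area_um2)
})

test_that("AH summary measures are plain arithmetic on merged lesions", {
  nx <- 500; ny <- 200
  cortex <- rect_mask(nx, ny, 0, 499, 0, 199)   # 1e5 px * 100 um2 = 10 mm2
  # 16 arterioles of 2x2 px at 10 um/px (400 um2 each, below the artery gate)
  xs <- seq(10, 460, by = 30)[1:16]
  art <- matrix(FALSE, nx, ny)
  for (k in seq_along(xs)) {
    y0 <- if (k == 2) 100 else 10
    art[(xs[k]:(xs[k] + 1)) + 1, (y0:(y0 + 1)) + 1] <- TRUE
  }
  # 3 lesions far apart -> 3 merged, density 3/10 = 0.30 per mm2
  lesions <- rect_mask(nx, ny, 10, 11, 10, 11) |
    rect_mask(nx, ny, 200, 201, 150, 151) |
    rect_mask(nx, ny, 400, 401, 30, 31)
  s <- build_section(list(Cortex = cortex,
                          `Arteries and arterioles` = art,
                          `Arteriolar hyalinosis` = lesions), mpp = 10)
  merged <- merge_ah_lesions(extract_components(s, "Arteriolar hyalinosis"),
                             10)
  expect_equal(nrow(merged), 3)
  out <- ah_measures(s, merged)
  expect_equal(out$ah_density_per_cortex_mm2, 0.30)
  expect_equal(out$mean_ah_area_um2, 400)        # each lesion 4 px * 100 um2
  # 2 of 16 arterioles contain an AH pixel -> 12.5%
  with_ah <- rect_mask(nx, ny, xs[1], xs[1] + 1, 10, 11) |
    rect_mask(nx, ny, xs[2], xs[2] + 1, 100, 101)
  s2 <- build_section(list(Cortex = cortex,
                           `Arteries and arterioles` = art,
                           `Arteriolar hyalinosis` = with_ah), mpp = 10)
  out2 <- ah_measures(s2, merge_ah_lesions(
    extract_components(s2, "Arteriolar hyalinosis"), 10))
  expect_equal(out2$pct_arterioles_with_ah, 12.5)
  # no lesions: density 0, mean area missing
  s3 <- build_section(list(Cortex = cortex,
                           `Arteries and arterioles` = art), mpp = 10)
  out3 <- ah_measures(s3, merge_ah_lesions(
    extract_components(s3, "Arteriolar hyalinosis"), 10))
  expect_equal(out3$ah_density_per_cortex_mm2, 0)
  expect_true(is.na(out3$mean_ah_area_um2))
})

test_that("luminal stenosis gates arteries at 7850 um2 and averages", {
  nx <- 300; ny <- 300
  # a 70x70 = 4900 um2 artery at 1 um/px: below the gate -> missing
  small <- rect_mask(nx, ny, 10, 79, 10, 79)
  s_small <- build_section(list(`Arteries and arterioles` = small), mpp = 1)
  expect_true(is.na(luminal_stenosis(s_small)$pooled))
  # one 100x100 = 10000 um2 artery, intima 200 um2, lumen 800 um2 -> 20%
  art <- rect_mask(nx, ny, 10, 109, 10, 109)
  intima <- rect_mask(nx, ny, 12, 13, 10, 109)        # 2x100 = 200 px
  lumen <- rect_mask(nx, ny, 20, 27, 10, 109)         # 8x100 = 800 px
  expect_equal(sum(intima), 200)
  expect_equal(sum(lumen), 800)
  s_big <- build_section(list(`Arteries and arterioles` = art,
                              `Intimal thickening` = intima,
                              `Arterial lumen` = lumen), mpp = 1)
  expect_equal(luminal_stenosis(s_big)$pooled, 20)
  # qualifying artery with no detected intima contributes 0%
  s_plain <- build_section(list(`Arteries and arterioles` = art,
                                `Arterial lumen` = lumen), mpp = 1)
  expect_equal(luminal_stenosis(s_plain)$pooled, 0)
  # medullary interlobar arteries follow the same rule and pool
  med_art <- rect_mask(nx, ny, 150, 249, 150, 249)
  med_int <- rect_mask(nx, ny, 152, 153, 150, 249)    # 200 px
  med_lum <- rect_mask(nx, ny, 160, 167, 150, 249)    # 800 px
  s_two <- build_section(list(`Arteries and arterioles` = art,
                              `Intimal thickening` = intima,
                              `Arterial lumen` = lumen,
                              `Interlobar arteries` = med_art,
                              `Intimal thickening (medullary)` = med_int,
                              `Artery lumen` = med_lum), mpp = 1)
  st <- luminal_stenosis(s_two)
  expect_equal(st$cortical, 20)
  expect_equal(st$medullary, 20)
  expect_equal(st$pooled, 20)
  expect_equal(st$n_qualifying, 2)
})

test_that("quantify is deterministic and flags missing on empty input", {
  g <- small_scene(seed = 41, cortex = 0.3)
  r1 <- quantify(g$section)
  r2 <- quantify(g$section)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  s0 <- labeled_section(list(Tissue = matrix(TRUE, 50, 50)), calibration(0.5))
  r0 <- suppressWarnings(quantify(s0))
  expect_equal(r0$nsg_count + r0$gsg_count + r0$ta_foci_count, 0)
  expect_true(is.na(r0$pct_gsg))
  expect_true(is.na(r0$pct_ita_per_tubulointerstitial))
  expect_true(length(r0$missing) >= 5)
})

test_that("scaling the calibration scales areas by k^2 and nothing else", {
  g <- small_scene(seed = 51, cortex = 0.25)
  s1 <- g$section
  s2 <- s1
  s2$calibration <- calibration(2 * s1$calibration$microns_per_pixel,
                                s1$calibration$section_thickness)
  r1 <- quantify(s1)
  r2 <- quantify(s2)
  expect_equal(r2$cortex_area_mm2, 4 * r1$cortex_area_mm2)
  expect_equal(r2$mean_proximal_tubular_area_um2,
               4 * r1$mean_proximal_tubular_area_um2)
  expect_equal(r2$nsg_count, r1$nsg_count)
  expect_equal(r2$pct_gsg, r1$pct_gsg)
  expect_equal(r2$pct_ita_per_tubulointerstitial,
               r1$pct_ita_per_tubulointerstitial)
  expect_equal(r2$pct_ta_per_tubular, r1$pct_ta_per_tubular)
})

test_that("adding lesions never decreases the related measures", {
  expect_gte(pct_gsg(10, 3), pct_gsg(10, 2))
  # an isolated extra AH lesion raises the merged count and density
  nx <- 3000; ny <- 200
  two <- rect_mask(nx, ny, 10, 20, 50, 60) |
    rect_mask(nx, ny, 2500, 2510, 50, 60)   # ~1.2 mm apart at 0.5 um/px
  three <- two | rect_mask(nx, ny, 1300, 1310, 100, 110)
  density <- function(m) {
    s <- build_section(list(Cortex = matrix(TRUE, nx, ny),
                            `Arteries and arterioles` = m,
                            `Arteriolar hyalinosis` = m), mpp = 0.5)
    ah_measures(s, merge_ah_lesions(
      extract_components(s, "Arteriolar hyalinosis"), 0.5))
  }
  expect_gt(density(three)$ah_density_per_cortex_mm2,
            density(two)$ah_density_per_cortex_mm2)
})
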