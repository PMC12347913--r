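# nephron-size and nephrosclerosis measures from a labeled section

#' Configuration of the morphometry pipeline
#'
#' Collects every tunable decision of the measure battery, with the field's
#' printed constants as defaults.
#'
#' @param connectivity component connectivity (8 or 4).
#' @param edge_eps_px tolerance (pixels) for calling a structure adjacent to
#'   the tissue cut edge.
#' @param exclude_edge_bisected exclude edge-bisected profiles from mean-area
#'   and volume computations (they remain in counts and densities).
#' @param include_empty_capsules_in_gsg include empty capsules in the %GSG
#'   denominator (default FALSE).
#' @param ah_merge_distance_um arteriolar hyalinosis lesions closer than this
#'   (strict, boundary-to-boundary) count once; 500 um, about the width of two
#'   adjacent glomerular profiles.
#' @param artery_min_area_um2 profile area above which a vessel counts as an
#'   artery for the luminal-stenosis average (7850 um2, a 100 um diameter
#'   disc); smaller vessels are arterioles for the AH measures.
#' @param wg_beta,wg_d Weibel-Gomez shape and size-distribution coefficients
#'   for glomerular volume (1.38 for a sphere, 1.01).
#' @param stenosis_report which luminal-stenosis average to report in
#'   [quantify()]: cortical and medullary (interlobar) arteries pooled
#'   (default), or one compartment alone.
#' @param exclude_tubules_in_ta exclude tubule components overlapping tubular
#'   atrophy clusters from mean tubular areas.
#' @return A `morphometry_config` list.
#' @export
morphometry_config <- function(connectivity = 8, edge_eps_px = 1,
                               exclude_edge_bisected = TRUE,
                               include_empty_capsules_in_gsg = FALSE,
                               ah_merge_distance_um = 500,
                               artery_min_area_um2 = 7850,
                               wg_beta = 1.38, wg_d = 1.01,
                               stenosis_report = c("pooled", "cortical",
                                                   "medullary"),
                               exclude_tubules_in_ta = TRUE) {
  stenosis_report <- match.arg(stenosis_report)
  structure(as.list(environment()), class = "morphometry_config")
}

#' Glomerular volume from the mean non-sclerosed profile area
#'
#' Weibel-Gomez stereologic estimate from two-dimensional profiles:
#' `V = (beta / d) * A^(3/2)`, with shape coefficient `beta` (1.38 for
#' spheres) and size-distribution coefficient `d` (1.01).
#'
#' @param mean_profile_area_um2 mean non-sclerosed glomerular profile area in
#'   square micrometers (edge-bisected profiles excluded upstream).
#' @param beta,d stereologic coefficients.
#' @return Volume in cubic millimeters (`NA` for missing input).
#' @export
glomerular_volume <- function(mean_profile_area_um2, beta = 1.38, d = 1.01) {
  if (is.na(mean_profile_area_um2)) return(NA_real_)
  stopifnot(mean_profile_area_um2 > 0)
  (beta / d) * mean_profile_area_um2^1.5 / 1e9
}

#' Cortical volume per glomerulus
#'
#' Converts the areal glomerular profile density to a volumetric density with
#' the section-thickness correction `N_V = N_A / (D + T)`, where `D` is the
#' sphere-equivalent glomerular diameter `(6V/pi)^(1/3)` and `T` the section
#' thickness, and reports its inverse: the cortex volume supplying one
#' glomerulus.
#'
#' @param cortex_area_mm2 cortex area of the section (mm2).
#' @param n_profiles number of glomerular profiles (non-sclerosed plus
#'   globally sclerosed; empty capsules excluded).
#' @param volume_mm3 glomerular volume (mm3), see [glomerular_volume()].
#' @param section_thickness_um section thickness in micrometers.
#' @return Cortex per glomerulus in mm3 (`NA` when no profiles).
#' @export
cortex_per_glomerulus <- function(cortex_area_mm2, n_profiles, volume_mm3,
                                  section_thickness_um = 2.5) {
  if (is.na(n_profiles) || n_profiles <= 0 || is.na(volume_mm3))
    return(NA_real_)
  stopifnot(cortex_area_mm2 > 0, volume_mm3 > 0)
  n_a <- n_profiles / cortex_area_mm2
  d_mm <- (6 * volume_mm3 / pi)^(1 / 3)
  n_v <- n_a / (d_mm + section_thickness_um / 1000)
  1 / n_v
}

#' Percent globally sclerosed glomeruli
#'
#' @param nsg_count,gsg_count non-sclerosed and globally sclerosed profile
#'   counts.
#' @return `100 * gsg / (nsg + gsg)`, `NA` when there are no glomeruli.
#' @export
pct_gsg <- function(nsg_count, gsg_count) {
  if (nsg_count + gsg_count <= 0) return(NA_real_)
  100 * gsg_count / (nsg_count + gsg_count)
}

# edge zone used to flag structures near the (non-capsule) tissue boundary
.edge_zone <- function(section, eps_px) {
  tissue <- class_mask(section, .cls$tissue)
  edge <- .mask_edge(tissue)
  if (!is.null(section$capsule)) edge <- edge & !section$capsule
  .dilate(edge, eps_px)
}

.flag_with_zone <- function(components, zone) {
  if (!nrow(components)) return(components)
  components$edge_bisected <-
    vapply(components$pixels, function(idx) any(zone[idx]), logical(1))
  components
}

#' Mean tubular profile area
#'
#' Total class area over component count for the proximal or distal tubule
#' layer, excluding (by default) components that overlap tubular atrophy
#' clusters and components bisected by the cut edge.
#'
#' @param section a [labeled_section()].
#' @param tubule_class `"proximal"` or `"distal"`.
#' @param config a [morphometry_config()].
#' @param edge_zone optional precomputed cut-edge zone (as built internally
#'   from the tissue boundary and capsule); computed when `NULL`.
#' @return Mean area in square micrometers, `NA` when no tubule qualifies.
#' @export
mean_tubular_area <- function(section, tubule_class = c("proximal", "distal"),
                              config = morphometry_config(),
                              edge_zone = NULL) {
  tubule_class <- match.arg(tubule_class)
  nm <- if (tubule_class == "proximal") .cls$proximal else .cls$distal
  comps <- extract_components(section, nm, config$connectivity)
  if (!nrow(comps)) return(NA_real_)
  keep <- rep(TRUE, nrow(comps))
  if (config$exclude_tubules_in_ta) {
    ta <- class_mask(section, .cls$ta)
    if (any(ta))
      keep <- keep & !vapply(comps$pixels, function(idx) any(ta[idx]),
                             logical(1))
  }
  if (config$exclude_edge_bisected) {
    if (is.null(edge_zone))
      edge_zone <- .edge_zone(section, config$edge_eps_px)
    comps <- .flag_with_zone(comps, edge_zone)
    keep <- keep & !comps$edge_bisected
  }
  if (!any(keep)) return(NA_real_)
  sum(comps$area_um2[keep]) / sum(keep)
}

#' Tubular atrophy measures
#'
#' Three measures of tubular atrophy (TA): the TA area fraction of the
#' tubular compartment, the interstitium-plus-TA fraction of the
#' tubulointerstitium (%ITA, the surrogate for interstitial fibrosis and TA
#' when fibrosis cannot be told from normal interstitium), and the TA focus
#' count density over the tubular area.
#'
#' @param section a [labeled_section()].
#' @param config a [morphometry_config()].
#' @return List with `pct_ta_per_tubular` (`100 * TA / (tubules + TA)`),
#'   `pct_ita_per_tubulointerstitial`
#'   (`100 * (TI - tubules) / TI`), and `ta_foci_density_per_mm2`
#'   (TA component count per mm2 of `tubules + TA`); `NA` where the
#'   denominator is absent.
#' @export
ta_measures <- function(section, config = morphometry_config()) {
  ta_area <- class_area_um2(section, .cls$ta)
  tub_area <- class_area_um2(section, .cls$tubules)
  ti_area <- class_area_um2(section, .cls$ti)
  n_ta <- nrow(extract_components(section, .cls$ta, config$connectivity))
  denom <- tub_area + ta_area
  list(
    pct_ta_per_tubular = if (denom > 0) 100 * ta_area / denom else NA_real_,
    pct_ita_per_tubulointerstitial =
      if (ti_area > 0) 100 * (ti_area - tub_area) / ti_area else NA_real_,
    ta_foci_density_per_mm2 = if (denom > 0) n_ta / (denom / 1e6) else NA_real_)
}

#' Merge arteriolar hyalinosis lesions closer than a distance threshold
#'
#' Two AH lesions whose boundaries lie closer than the threshold (strict
#' inequality; default 500 um, about the width of two adjacent glomerular
#' profiles) are counted once. Lesions are linked into clusters by this
#' pairwise rule (transitively), and each cluster is represented by its
#' largest-area lesion; the representative's own area (not the cluster sum)
#' is the retained area.
#'
#' @param components AH lesion components from [extract_components()].
#' @param microns_per_pixel calibration of the source raster.
#' @param distance_um merge threshold in micrometers.
#' @return The representative rows of `components`, with added columns
#'   `cluster` and `n_lesions` (cluster size).
#' @export
merge_ah_lesions <- function(components, microns_per_pixel,
                             distance_um = 500) {
  n <- nrow(components)
  if (n == 0) {
    out <- components
    out$cluster <- integer(0); out$n_lesions <- integer(0)
    return(out)
  }
  # boundary coordinates per lesion, in pixel units
  bounds <- lapply(components$pixels, .component_boundary_xy,
                   dim = c(.guess_nrow(components), NA))
  dist_fun <- function(i, j) {
    a <- bounds[[i]]; b <- bounds[[j]]
    dx <- outer(a[, 1], b[, 1], "-"); dy <- outer(a[, 2], b[, 2], "-")
    sqrt(min(dx^2 + dy^2)) * microns_per_pixel
  }
  cl <- .merge_clusters_by_distance(n, dist_fun, distance_um)
  rep_rows <- vapply(split(seq_len(n), cl), function(ix)
    ix[which.max(components$area_um2[ix])], integer(1))
  out <- components[rep_rows, , drop = FALSE]
  out$cluster <- seq_along(rep_rows)
  out$n_lesions <- as.integer(table(cl))
  rownames(out) <- NULL
  attr(out, "mask_nrow") <- .guess_nrow(components)
  out
}

# components carry linear pixel indices; the raster's row count travels as an
# attribute set by extract_components via the section, or is supplied
.guess_nrow <- function(components) {
  nr <- attr(components, "mask_nrow")
  if (is.null(nr)) stop("components lack the mask_nrow attribute")
  nr
}

#' Arteriolar hyalinosis measures
#'
#' @param section a [labeled_section()].
#' @param merged merged AH lesions from [merge_ah_lesions()].
#' @param config a [morphometry_config()].
#' @return List with `ah_density_per_cortex_mm2` (merged lesion count per mm2
#'   of cortex), `pct_arterioles_with_ah` (percent of arterioles — vessel
#'   components at or below the artery area gate — containing at least one AH
#'   pixel; `NA` when there are no arterioles), and `mean_ah_area_um2` (mean
#'   over merged representatives; `NA` when there are no lesions).
#' @export
ah_measures <- function(section, merged, config = morphometry_config()) {
  cortex_mm2 <- class_area_um2(section, .cls$cortex) / 1e6
  vessels <- extract_components(section, .cls$vessels, config$connectivity)
  arterioles <- vessels[vessels$area_um2 <= config$artery_min_area_um2, ,
                        drop = FALSE]
  ah_mask <- class_mask(section, .cls$ah)
  n_with_ah <- if (nrow(arterioles))
    sum(vapply(arterioles$pixels, function(idx) any(ah_mask[idx]),
               logical(1))) else 0L
  list(
    ah_density_per_cortex_mm2 =
      if (cortex_mm2 > 0) nrow(merged) / cortex_mm2 else NA_real_,
    pct_arterioles_with_ah = if (nrow(arterioles))
      100 * n_with_ah / nrow(arterioles) else NA_real_,
    mean_ah_area_um2 =
      if (nrow(merged)) mean(merged$area_um2) else NA_real_)
}

#' Luminal stenosis of arteries
#'
#' Percent lumen stenosis from intimal thickening,
#' `100 * intima / (intima + lumen)` per artery, averaged (unweighted) over
#' all arteries with a profile area above the gate (default 7850 um2).
#' Arteries with no detected intima contribute 0%: intima is only segmented
#' when thickened, so its absence means no thickening. Cortical
#' (arteries-and-arterioles layer) and medullary (interlobar) arteries are
#' evaluated under the same rule and reported separately and pooled.
#'
#' @param section a [labeled_section()].
#' @param config a [morphometry_config()].
#' @return List with `pooled`, `cortical`, `medullary` mean stenosis (%),
#'   each `NA` when no artery in that scope passes the gate, and
#'   `n_qualifying` (pooled artery count).
#' @export
luminal_stenosis <- function(section, config = morphometry_config()) {
  per_artery <- function(vessel_class, intima_class, lumen_class) {
    comps <- extract_components(section, vessel_class, config$connectivity)
    comps <- comps[comps$area_um2 > config$artery_min_area_um2, ,
                   drop = FALSE]
    if (!nrow(comps)) return(numeric(0))
    intima <- class_mask(section, intima_class)
    lumen <- class_mask(section, lumen_class)
    vapply(comps$pixels, function(idx) {
      n_i <- sum(intima[idx]); n_l <- sum(lumen[idx])
      if (n_i == 0) 0 else 100 * n_i / (n_i + n_l)
    }, numeric(1))
  }
  s_cort <- per_artery(.cls$vessels, .cls$intima, .cls$lumen)
  s_med <- per_artery(.cls$interlobar, .cls$intima_med, .cls$lumen_med)
  pooled <- c(s_cort, s_med)
  list(
    pooled = if (length(pooled)) mean(pooled) else NA_real_,
    cortical = if (length(s_cort)) mean(s_cort) else NA_real_,
    medullary = if (length(s_med)) mean(s_med) else NA_real_,
    n_qualifying = length(pooled))
}

#' Quantify a section: all structural and derived measures
#'
#' Runs the full measure battery on a labeled section: compartment areas,
#' structure counts, the nephron-size measures (glomerular volume, cortex per
#' glomerulus, mean proximal/distal tubular areas) and the nephrosclerosis
#' measures (%GSG, %TA, %ITA, TA focus density, AH density/percent/mean area
#' after distance merging, luminal stenosis). Measures whose denominator class
#' is absent are returned as `NA` and flagged in `$missing` rather than
#' silently zeroed. The result is deterministic given the section and config.
#'
#' @param section a [labeled_section()].
#' @param config a [morphometry_config()].
#' @return A `morphometry_result`: a list with the measure fields, raw
#'   structural details in `$detail`, missing-measure reasons in `$missing`,
#'   and the config in `$config`. `as.data.frame()` yields the one-row
#'   measure table.
#' @export
quantify <- function(section, config = morphometry_config()) {
  mpp <- section$calibration$microns_per_pixel
  thick <- section$calibration$section_thickness
  missing <- list()
  miss <- function(name, reason) missing[[name]] <<- reason

  cortex_mm2 <- class_area_um2(section, .cls$cortex) / 1e6
  medulla_mm2 <- class_area_um2(section, .cls$medulla) / 1e6

  zone <- .edge_zone(section, config$edge_eps_px)
  comp <- function(cl) {
    x <- extract_components(section, cl, config$connectivity)
    attr(x, "mask_nrow") <- section$dim[1]
    x
  }

  nsg <- .flag_with_zone(comp(.cls$nsg), zone)
  gsg <- comp(.cls$gsg)
  emp <- comp(.cls$empty_capsule)
  ta_comps <- comp(.cls$ta)

  nsg_for_mean <- if (config$exclude_edge_bisected)
    nsg[!nsg$edge_bisected, , drop = FALSE] else nsg
  mean_nsg_area <- if (nrow(nsg_for_mean))
    mean(nsg_for_mean$area_um2) else NA_real_
  if (is.na(mean_nsg_area))
    miss("glomerular_volume_mm3", "no non-edge-bisected NSG profile")
  vol <- glomerular_volume(mean_nsg_area, config$wg_beta, config$wg_d)

  n_profiles <- nrow(nsg) + nrow(gsg) +
    if (config$include_empty_capsules_in_gsg) nrow(emp) else 0L
  cpg <- cortex_per_glomerulus(cortex_mm2, n_profiles, vol, thick)
  if (is.na(cpg) && is.null(missing$glomerular_volume_mm3))
    miss("cortex_per_glomerulus_mm3", "no glomerular profiles")

  gsg_denom_nsg <- nrow(nsg) +
    if (config$include_empty_capsules_in_gsg) nrow(emp) else 0L
  p_gsg <- pct_gsg(gsg_denom_nsg, nrow(gsg))
  if (is.na(p_gsg)) miss("pct_gsg", "no glomeruli")

  mean_prox <- mean_tubular_area(section, "proximal", config, edge_zone = zone)
  if (is.na(mean_prox))
    miss("mean_proximal_tubular_area_um2", "no qualifying proximal tubule")
  mean_dist <- mean_tubular_area(section, "distal", config, edge_zone = zone)
  if (is.na(mean_dist))
    miss("mean_distal_tubular_area_um2", "no qualifying distal tubule")

  ta <- ta_measures(section, config)
  if (is.na(ta$pct_ta_per_tubular))
    miss("pct_ta_per_tubular", "no tubular area")
  if (is.na(ta$pct_ita_per_tubulointerstitial))
    miss("pct_ita_per_tubulointerstitial", "no tubulointerstitium")
  if (is.na(ta$ta_foci_density_per_mm2))
    miss("ta_foci_density_per_mm2", "no tubular area")

  ah_comps <- comp(.cls$ah)
  merged <- merge_ah_lesions(ah_comps, mpp, config$ah_merge_distance_um)
  ah <- ah_measures(section, merged, config)
  if (is.na(ah$pct_arterioles_with_ah))
    miss("pct_arterioles_with_ah", "no arterioles")
  if (is.na(ah$mean_ah_area_um2))
    miss("mean_ah_area_um2", "no AH lesions")

  sten <- luminal_stenosis(section, config)
  sten_report <- sten[[config$stenosis_report]]
  if (is.na(sten_report))
    miss("pct_luminal_stenosis",
         sprintf("no artery above %g um2", config$artery_min_area_um2))

  structure(list(
    cortex_area_mm2 = cortex_mm2,
    medulla_area_mm2 = medulla_mm2,
    nsg_count = nrow(nsg),
    gsg_count = nrow(gsg),
    empty_capsule_count = nrow(emp),
    ta_foci_count = nrow(ta_comps),
    ah_lesion_count = nrow(merged),
    glomerular_volume_mm3 = vol,
    cortex_per_glomerulus_mm3 = cpg,
    mean_proximal_tubular_area_um2 = mean_prox,
    mean_distal_tubular_area_um2 = mean_dist,
    pct_gsg = p_gsg,
    pct_ta_per_tubular = ta$pct_ta_per_tubular,
    pct_ita_per_tubulointerstitial = ta$pct_ita_per_tubulointerstitial,
    ta_foci_density_per_mm2 = ta$ta_foci_density_per_mm2,
    ah_density_per_cortex_mm2 = ah$ah_density_per_cortex_mm2,
    pct_arterioles_with_ah = ah$pct_arterioles_with_ah,
    mean_ah_area_um2 = ah$mean_ah_area_um2,
    pct_luminal_stenosis = sten_report,
    missing = missing,
    detail = list(mean_nsg_area_um2 = mean_nsg_area,
                  n_glomerular_profiles = n_profiles,
                  n_ah_lesions_premerge = nrow(ah_comps),
                  stenosis = sten),
    config = config),
    class = "morphometry_result")
}

#' Measure names of a morphometry result
#' @keywords internal
.measure_names <- c(
  "cortex_area_mm2", "medulla_area_mm2", "nsg_count", "gsg_count",
  "empty_capsule_count", "ta_foci_count", "ah_lesion_count",
  "glomerular_volume_mm3", "cortex_per_glomerulus_mm3",
  "mean_proximal_tubular_area_um2", "mean_distal_tubular_area_um2",
  "pct_gsg", "pct_ta_per_tubular", "pct_ita_per_tubulointerstitial",
  "ta_foci_density_per_mm2", "ah_density_per_cortex_mm2",
  "pct_arterioles_with_ah", "mean_ah_area_um2", "pct_luminal_stenosis")

#' @export
as.data.frame.morphometry_result <- function(x, ...) {
  as.data.frame(lapply(setNames(nm = .measure_names), function(nm)
    if (is.null(x[[nm]])) NA_real_ else x[[nm]]))
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  df <- as.data.frame(x)
  for (nm in names(df))
    cat(sprintf("  %-34s %s\n", nm,
                if (is.na(df[[nm]])) "missing" else format(df[[nm]],
                                                           digits = 5)))
  if (length(x$missing)) {
    cat("  missing measures:\n")
    for (nm in names(x$missing))
      cat(sprintf("    %s: %s\n", nm, x$missing[[nm]]))
  }
  invisible(x)
}
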