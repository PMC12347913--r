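# seeded synthetic section generator with analytic ground truth

#' Specification of a synthetic kidney section scene
#'
#' Describes a needle-core or wedge section to be generated: compartment
#' geometry, structure counts, and the size distributions of every structure
#' family. All structures are laid out as vector shapes (discs, ellipses,
#' annuli) and rasterized afterwards, so true areas are known analytically
#' before rasterization. Defaults describe a living-donor needle core at the
#' native 0.5 um/px scan calibration: cortex 6.7 mm2, 16 non-sclerosed + 1
#' globally sclerosed glomeruli, 3 empty capsules, 6 tubular-atrophy foci,
#' proximal/distal tubule mean areas 2768/1523 um2, one arteriolar-hyalinosis
#' lesion of mean area 138 um2.
#'
#' @param kind `"core"` (needle biopsy; capsule at one end, long sides are
#'   needle-cut edges) or `"wedge"` (capsule along the top edge).
#' @param seed integer; fixes the scene exactly.
#' @param microns_per_pixel,section_thickness calibration (um/px, um).
#' @param cortex_area_mm2 target cortex area.
#' @param core_width_mm needle-core width (core only).
#' @param medulla_area_mm2 target medulla area (0 for cortex-only tissue).
#' @param capsule_um depth of the capsule band along the anatomical edge.
#' @param n_nsg,n_gsg,n_empty counts of non-sclerosed glomeruli, globally
#'   sclerosed glomeruli and empty Bowman capsules.
#' @param n_edge_glomeruli how many of the `n_nsg` glomeruli are placed
#'   straddling a needle-cut edge (edge-bisected ground truth).
#' @param glom_area_mean_um2,glom_area_sd_um2 lognormal profile-area
#'   distribution of glomeruli (natural-scale mean and SD).
#' @param empty_area_mean_um2 mean area of empty capsules.
#' @param tubule_fill target tubular fraction of the tubulointerstitium.
#' @param prox_frac fraction of tubules that are proximal.
#' @param prox_area_mean_um2,prox_area_sd_um2 proximal tubule area distribution.
#' @param dist_area_mean_um2,dist_area_sd_um2 distal tubule area distribution.
#' @param n_ta,ta_area_mean_um2,ta_area_sd_um2 tubular-atrophy focus count and
#'   area distribution (elliptical foci).
#' @param n_arteries,artery_area_mean_um2 cortical arteries (annular profiles,
#'   all above the 7850 um2 stenosis gate).
#' @param artery_lumen_frac lumen area as a fraction of the artery profile.
#' @param stenosis_mean mean luminal stenosis fraction across arteries
#'   (arteries without intimal thickening contribute 0).
#' @param p_intima probability an artery has detectable (thickened) intima.
#' @param n_arterioles,arteriole_area_mean_um2,arteriole_area_sd_um2 arteriole
#'   count and size (all below the artery gate).
#' @param n_ah number of arteriolar-hyalinosis lesions (each in its own
#'   arteriole; requires `n_ah <= n_arterioles`).
#' @param ah_area_mean_um2,ah_area_sd_um2 AH lesion area distribution.
#' @param n_ah_close_pairs how many AH lesion pairs are placed with boundary
#'   distance in (150, 350) um, i.e. below the 500 um merge rule; consumes two
#'   of `n_ah` per pair. Remaining lesions are kept > 600 um apart.
#' @param n_interlobar interlobar arteries in the medulla.
#' @return A `scene_spec`.
#' @seealso [generate_section()], [donor_scene_spec()], [tumor_scene_spec()]
#' @export
scene_spec <- function(kind = c("core", "wedge"), seed = 1,
                       microns_per_pixel = 0.5, section_thickness = 2.5,
                       cortex_area_mm2 = 6.7, core_width_mm = 1.0,
                       medulla_area_mm2 = 1.0, capsule_um = 30,
                       n_nsg = 16, n_gsg = 1, n_empty = 3,
                       n_edge_glomeruli = 1,
                       glom_area_mean_um2 = 16150, glom_area_sd_um2 = 4000,
                       empty_area_mean_um2 = 8000,
                       tubule_fill = 0.5, prox_frac = 0.6,
                       prox_area_mean_um2 = 2768, prox_area_sd_um2 = 550,
                       dist_area_mean_um2 = 1523, dist_area_sd_um2 = 300,
                       n_ta = 6, ta_area_mean_um2 = 30000,
                       ta_area_sd_um2 = 10000,
                       n_arteries = 2, artery_area_mean_um2 = 20000,
                       artery_lumen_frac = 0.2,
                       stenosis_mean = 0.16, p_intima = 0.7,
                       n_arterioles = 8, arteriole_area_mean_um2 = 2000,
                       arteriole_area_sd_um2 = 500,
                       n_ah = 1, ah_area_mean_um2 = 138, ah_area_sd_um2 = 60,
                       n_ah_close_pairs = 0,
                       n_interlobar = 1) {
  kind <- match.arg(kind)
  spec <- as.list(environment())
  counts <- c("n_nsg", "n_gsg", "n_empty", "n_edge_glomeruli", "n_ta",
              "n_arteries", "n_arterioles", "n_ah", "n_ah_close_pairs",
              "n_interlobar")
  for (f in counts)
    if (spec[[f]] < 0 || spec[[f]] != round(spec[[f]]))
      stop(f, " must be a non-negative integer")
  areas <- c("microns_per_pixel", "section_thickness", "cortex_area_mm2",
             "core_width_mm", "capsule_um", "glom_area_mean_um2",
             "empty_area_mean_um2", "prox_area_mean_um2", "dist_area_mean_um2",
             "ta_area_mean_um2", "artery_area_mean_um2",
             "arteriole_area_mean_um2", "ah_area_mean_um2")
  for (f in areas)
    if (spec[[f]] <= 0) stop(f, " must be positive")
  if (spec$medulla_area_mm2 < 0) stop("medulla_area_mm2 must be >= 0")
  if (spec$n_edge_glomeruli > spec$n_nsg)
    stop("n_edge_glomeruli cannot exceed n_nsg")
  if (spec$n_ah > spec$n_arterioles)
    stop("n_ah cannot exceed n_arterioles (one lesion per arteriole)")
  if (2 * spec$n_ah_close_pairs > spec$n_ah)
    stop("n_ah_close_pairs consumes two lesions per pair")
  if (spec$tubule_fill < 0 || spec$tubule_fill >= 1)
    stop("tubule_fill must be in [0, 1)")
  structure(spec, class = "scene_spec")
}

#' Donor-like scene at a chosen cortex area
#'
#' Structure counts follow the living-donor per-cortex densities (2.46
#' non-sclerosed glomeruli, 0.09 globally sclerosed, 0.43 empty capsules,
#' 0.84 TA foci, 0.10 AH lesions and about 4 arterioles per mm2 of cortex);
#' sizes follow the donor means.
#'
#' @param cortex_area_mm2 cortex area (default the donor mean 6.7 mm2).
#' @param seed scene seed.
#' @param ... overrides passed on to [scene_spec()].
#' @return A `scene_spec`.
#' @export
donor_scene_spec <- function(cortex_area_mm2 = 6.7, seed = 1, ...) {
  a <- cortex_area_mm2
  args <- list(
    kind = "core", seed = seed, cortex_area_mm2 = a,
    medulla_area_mm2 = max(0.4, 0.15 * a),
    n_nsg = max(2L, round(2.46 * a)),
    n_gsg = round(0.09 * a),
    n_empty = round(0.43 * a),
    n_edge_glomeruli = 1L,
    n_ta = round(0.84 * a),
    n_arteries = max(1L, round(0.3 * a)),
    n_arterioles = max(2L, round(4 * a)),
    n_ah = round(0.10 * a),
    stenosis_mean = 0.16,
    glom_area_mean_um2 = 16150,
    prox_area_mean_um2 = 2768, dist_area_mean_um2 = 1523,
    ah_area_mean_um2 = 138, ah_area_sd_um2 = 60)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}

#' Tumor-like wedge scene at a chosen cortex area
#'
#' Structure densities and sizes follow the renal-tumor cohort composition
#' (2.48 glomeruli, 0.29 globally sclerosed, 2.54 TA foci and 0.39 AH lesions
#' per mm2 of cortex; proximal/distal tubule means 4205/2598 um2; mean AH area
#' 405 um2; stenosis ~28%). Full-size tumor wedges (~135 mm2 of cortex) are
#' far larger than a workstation test needs, so the default cortex area is
#' scaled down with all densities preserved.
#'
#' @param cortex_area_mm2 cortex area (default 8 mm2, density-preserving
#'   scale-down of the 135 mm2 cohort mean).
#' @param seed scene seed.
#' @param ... overrides passed on to [scene_spec()].
#' @return A `scene_spec`.
#' @export
tumor_scene_spec <- function(cortex_area_mm2 = 8, seed = 1, ...) {
  a <- cortex_area_mm2
  args <- list(
    kind = "wedge", seed = seed, cortex_area_mm2 = a,
    medulla_area_mm2 = max(0.5, 0.25 * a),
    n_nsg = max(2L, round(2.48 * a)),
    n_gsg = max(1L, round(0.29 * a)),
    n_empty = round(0.16 * a),
    n_edge_glomeruli = 1L,
    n_ta = max(1L, round(2.54 * a)),
    ta_area_mean_um2 = 24000, ta_area_sd_um2 = 8000,
    n_arteries = max(1L, round(0.35 * a)),
    n_arterioles = max(2L, round(3.2 * a)),
    n_ah = max(1L, round(0.39 * a)),
    n_ah_close_pairs = if (round(0.39 * a) >= 2) 1L else 0L,
    stenosis_mean = 0.28, p_intima = 0.85,
    glom_area_mean_um2 = 15760,
    prox_area_mean_um2 = 4205, prox_area_sd_um2 = 700,
    dist_area_mean_um2 = 2598, dist_area_sd_um2 = 450,
    ah_area_mean_um2 = 405, ah_area_sd_um2 = 120)
  args[names(list(...))] <- list(...)
  do.call(scene_spec, args)
}

# lognormal sampler parameterized by natural-scale mean and sd
.rlnorm_ms <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

# circular-segment area beyond a chord at distance d from the centre
.seg_area <- function(r, d) {
  if (d >= r) return(0)
  r^2 * acos(d / r) - d * sqrt(r^2 - d^2)
}

.packing_error <- function(what) {
  stop(errorCondition(
    paste0("packing failure: could not place ", what,
           "; the requested structures do not fit in the section"),
    class = c("nephromorph_packing_error", "error", "condition")))
}

#' Generate a synthetic labeled section with ground truth
#'
#' Lays out the scene described by a [scene_spec()] as analytic vector shapes,
#' rasterizes them into a 20-class [labeled_section()], and returns alongside
#' it a `scene_truth` record of every placed structure and every derived
#' morphometric measure computed from the analytic (pre-rasterization) areas.
#' Placement is non-overlapping within compartments and honours the taxonomy
#' nesting; the capsule band is drawn along the anatomical outer edge only, so
#' needle-cut edges carry no capsule. A fixed seed reproduces the scene
#' bit-identically.
#'
#' @param spec a [scene_spec()].
#' @return List with elements `section` (a [labeled_section()]) and `truth`
#'   (a `scene_truth` list: `$counts`, `$areas`, `$measures` — named like
#'   [quantify()]'s result — and a `$structures` data.frame).
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  mpp <- spec$microns_per_pixel
  um2px <- function(um) um / mpp
  px_area <- function(um2) um2 / mpp^2

  # ---- frame geometry -------------------------------------------------------
  cap_px <- max(1L, round(um2px(spec$capsule_um)))
  cortex_px_target <- px_area(spec$cortex_area_mm2 * 1e6)
  medulla_px_target <- px_area(spec$medulla_area_mm2 * 1e6)
  if (spec$kind == "core") {
    W <- round(um2px(spec$core_width_mm * 1000))
    Lc <- max(1L, round(cortex_px_target / W))
    Lm <- round(medulla_px_target / W)
    nx <- cap_px + Lc + Lm; ny <- W
    # cortex occupies x in [cap_px, cap_px + Lc), 0-based
    cortex_x <- c(cap_px, cap_px + Lc - 1L)
    cortex_y <- c(0L, ny - 1L)
    medulla_x <- if (Lm > 0) c(cap_px + Lc, nx - 1L) else NULL
    medulla_y <- cortex_y
    # needle-cut edges: y = 0, y = ny-1, x = nx-1; capsule along x < cap_px
    cut_axis <- "y"
  } else {
    nxw <- max(1L, round(sqrt(2 * cortex_px_target)))
    Hc <- max(1L, round(cortex_px_target / nxw))
    Hm <- round(medulla_px_target / nxw)
    nx <- nxw; ny <- cap_px + Hc + Hm
    cortex_x <- c(0L, nx - 1L)
    cortex_y <- c(cap_px, cap_px + Hc - 1L)
    medulla_x <- cortex_x
    medulla_y <- if (Hm > 0) c(cap_px + Hc, ny - 1L) else NULL
    cut_axis <- "x"
  }
  cortex_area_mm2 <- diff(cortex_x + c(0, 1)) * diff(cortex_y + c(0, 1)) *
    mpp^2 / 1e6
  medulla_area_mm2 <- if (is.null(medulla_x)) 0 else
    diff(medulla_x + c(0, 1)) * diff(medulla_y + c(0, 1)) * mpp^2 / 1e6

  # ---- placement bookkeeping ------------------------------------------------
  bx <- numeric(0); by <- numeric(0); br <- numeric(0)  # blocker circles (px)
  add_blocker <- function(x, y, r) {
    bx[length(bx) + 1L] <<- x; by[length(by) + 1L] <<- y
    br[length(br) + 1L] <<- r
  }
  clear_of_blockers <- function(x, y, r, gap = 3) {
    !length(bx) || all((bx - x)^2 + (by - y)^2 >= (br + r + gap)^2)
  }
  # uniform position with radius-dependent inset from the compartment box
  rand_pos <- function(xr, yr, r, edge_buffer = 5) {
    lo_x <- xr[1] + r + edge_buffer; hi_x <- xr[2] - r - edge_buffer
    lo_y <- yr[1] + r + edge_buffer; hi_y <- yr[2] - r - edge_buffer
    if (lo_x > hi_x || lo_y > hi_y) return(NULL)
    c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
  }
  place <- function(r, xr, yr, what, gap = 3, max_tries = 400,
                    accept = NULL) {
    for (i in seq_len(max_tries)) {
      p <- rand_pos(xr, yr, r)
      if (is.null(p)) break
      if (!clear_of_blockers(p[1], p[2], r, gap)) next
      if (!is.null(accept) && !accept(p[1], p[2])) next
      add_blocker(p[1], p[2], r)
      return(p)
    }
    .packing_error(what)
  }

  structures <- list()
  note <- function(type, x, y, area_um2, edge = FALSE, extra = NULL) {
    structures[[length(structures) + 1L]] <<-
      c(list(type = type, x_um = x * mpp, y_um = y * mpp,
             area_um2 = area_um2, edge_bisected = edge), extra)
  }

  # ---- edge-bisected glomeruli (placed first: they are confined to a
  # narrow strip along the needle-cut edge) --------------------------------
  gloms <- list()   # each: x, y, r, class, edge, area_um2 (in-tissue)
  draw_glom_r <- function(n) sqrt(px_area(
    pmax(2000, .rlnorm_ms(n, spec$glom_area_mean_um2,
                          spec$glom_area_sd_um2))) / pi)
  if (spec$n_edge_glomeruli > 0) {
    r <- draw_glom_r(spec$n_edge_glomeruli)
    for (k in seq_len(spec$n_edge_glomeruli)) {
      # straddle a needle-cut edge: centre at distance d < r inside the edge
      placed <- FALSE
      for (i in 1:800) {
        d <- stats::runif(1, 0.2, 0.7) * r[k]
        flip <- stats::runif(1) < 0.5
        if (cut_axis == "y") {         # core: cut edges at y = 0 and ny-1
          x <- stats::runif(1, cortex_x[1] + r[k] + 5, cortex_x[2] - r[k] - 5)
          y <- if (flip) ny - 1 - d else d
        } else {                       # wedge: cut edges at x = 0 and nx-1
          x <- if (flip) nx - 1 - d else d
          y <- stats::runif(1, cortex_y[1] + r[k] + 5, cortex_y[2] - r[k] - 5)
        }
        if (!clear_of_blockers(x, y, r[k])) next
        add_blocker(x, y, r[k])
        # analytic in-tissue area: disc clipped by the cell-boundary half-plane
        a_in <- (pi * r[k]^2 - .seg_area(r[k], d + 0.5)) * mpp^2
        gloms[[length(gloms) + 1L]] <-
          list(x = x, y = y, r = r[k], class = "nsg", edge = TRUE,
               area_um2 = a_in)
        note("nsg", x, y, a_in, edge = TRUE)
        placed <- TRUE
        break
      }
      if (!placed) .packing_error("edge-bisected glomerulus")
    }
  }

  # ---- arteries (cortical annuli) ------------------------------------------
  artery_s <- numeric(0)
  arteries <- list()
  if (spec$n_arteries > 0) {
    A <- pmax(9000, .rlnorm_ms(spec$n_arteries, spec$artery_area_mean_um2,
                               0.3 * spec$artery_area_mean_um2))
    for (k in seq_len(spec$n_arteries)) {
      R <- sqrt(px_area(A[k]) / pi)
      p <- place(R, cortex_x, cortex_y, "cortical artery")
      r_l <- sqrt(spec$artery_lumen_frac) * R
      s <- 0
      if (stats::runif(1) < spec$p_intima)
        s <- min(0.7, spec$stenosis_mean / max(spec$p_intima, 0.05) *
                   stats::runif(1, 0.5, 1.5))
      r_i <- r_l / sqrt(1 - s)
      if (r_i > 0.92 * R) { r_i <- 0.92 * R; s <- 1 - (r_l / r_i)^2 }
      arteries[[k]] <- list(x = p[1], y = p[2], R = R, r_l = r_l, r_i = r_i,
                            s = s)
      artery_s <- c(artery_s, s)
      note("artery", p[1], p[2], pi * R^2 * mpp^2,
           extra = list(stenosis = s))
    }
  }

  # ---- interlobar arteries (medullary annuli) ------------------------------
  interlobar <- list()
  if (spec$n_interlobar > 0) {
    if (is.null(medulla_x)) .packing_error("interlobar artery (no medulla)")
    A <- pmax(9000, .rlnorm_ms(spec$n_interlobar,
                               1.5 * spec$artery_area_mean_um2,
                               0.3 * spec$artery_area_mean_um2))
    for (k in seq_len(spec$n_interlobar)) {
      R <- sqrt(px_area(A[k]) / pi)
      p <- place(R, medulla_x, medulla_y, "interlobar artery")
      r_l <- sqrt(spec$artery_lumen_frac) * R
      s <- 0
      if (stats::runif(1) < spec$p_intima)
        s <- min(0.7, spec$stenosis_mean / max(spec$p_intima, 0.05) *
                   stats::runif(1, 0.5, 1.5))
      r_i <- r_l / sqrt(1 - s)
      if (r_i > 0.92 * R) { r_i <- 0.92 * R; s <- 1 - (r_l / r_i)^2 }
      interlobar[[k]] <- list(x = p[1], y = p[2], R = R, r_l = r_l,
                              r_i = r_i, s = s)
      artery_s <- c(artery_s, s)
      note("interlobar", p[1], p[2], pi * R^2 * mpp^2,
           extra = list(stenosis = s))
    }
  }

  # ---- tubular atrophy foci (ellipses) -------------------------------------
  ta_foci <- list()
  ta_area_true <- 0
  if (spec$n_ta > 0) {
    A <- pmax(4000, .rlnorm_ms(spec$n_ta, spec$ta_area_mean_um2,
                               spec$ta_area_sd_um2))
    for (k in seq_len(spec$n_ta)) {
      q <- stats::runif(1, 0.5, 0.9)
      a <- sqrt(px_area(A[k]) / (pi * q)); b <- a * q
      th <- stats::runif(1, 0, pi)
      p <- place(a, cortex_x, cortex_y, "tubular atrophy focus", gap = 5)
      ta_foci[[k]] <- list(x = p[1], y = p[2], a = a, b = b, th = th)
      ta_area_true <- ta_area_true + pi * a * b * mpp^2
      note("ta_focus", p[1], p[2], pi * a * b * mpp^2)
    }
  }

  # ---- interior glomeruli ---------------------------------------------------
  n_interior_nsg <- spec$n_nsg - spec$n_edge_glomeruli
  if (n_interior_nsg > 0) {
    r <- draw_glom_r(n_interior_nsg)
    for (k in seq_len(n_interior_nsg)) {
      p <- place(r[k], cortex_x, cortex_y, "glomerulus")
      gloms[[length(gloms) + 1L]] <-
        list(x = p[1], y = p[2], r = r[k], class = "nsg", edge = FALSE,
             area_um2 = pi * r[k]^2 * mpp^2)
      note("nsg", p[1], p[2], pi * r[k]^2 * mpp^2)
    }
  }
  if (spec$n_gsg > 0) {
    r <- 0.85 * draw_glom_r(spec$n_gsg)   # sclerosed tufts shrink
    for (k in seq_len(spec$n_gsg)) {
      p <- place(r[k], cortex_x, cortex_y, "globally sclerosed glomerulus")
      gloms[[length(gloms) + 1L]] <-
        list(x = p[1], y = p[2], r = r[k], class = "gsg", edge = FALSE,
             area_um2 = pi * r[k]^2 * mpp^2)
      note("gsg", p[1], p[2], pi * r[k]^2 * mpp^2)
    }
  }
  if (spec$n_empty > 0) {
    r <- sqrt(px_area(pmax(1500, .rlnorm_ms(
      spec$n_empty, spec$empty_area_mean_um2,
      0.3 * spec$empty_area_mean_um2))) / pi)
    for (k in seq_len(spec$n_empty)) {
      p <- place(r[k], cortex_x, cortex_y, "empty capsule")
      gloms[[length(gloms) + 1L]] <-
        list(x = p[1], y = p[2], r = r[k], class = "empty", edge = FALSE,
             area_um2 = pi * r[k]^2 * mpp^2)
      note("empty_capsule", p[1], p[2], pi * r[k]^2 * mpp^2)
    }
  }

  # ---- arterioles and AH lesions -------------------------------------------
  arterioles <- list()  # x, y, r, ah (NULL or list(x, y, r))
  ah_x <- numeric(0); ah_y <- numeric(0); ah_r <- numeric(0)
  min_ah_sep_px <- um2px(600)
  pair_gap_px <- function() um2px(stats::runif(1, 150, 350))
  draw_arteriole_r <- function() sqrt(px_area(
    min(6000, max(700, stats::rnorm(1, spec$arteriole_area_mean_um2,
                                    spec$arteriole_area_sd_um2)))) / pi)
  draw_ah_r <- function() sqrt(px_area(
    max(30, .rlnorm_ms(1, spec$ah_area_mean_um2, spec$ah_area_sd_um2))) / pi)
  ah_clear <- function(x, y, r, except = 0) {
    if (!length(ah_x)) return(TRUE)
    d <- sqrt((ah_x - x)^2 + (ah_y - y)^2) - ah_r - r
    d[seq_along(d) == except] <- Inf
    all(d >= min_ah_sep_px)
  }
  n_paired <- 2L * spec$n_ah_close_pairs
  n_single_ah <- spec$n_ah - n_paired
  place_ah_arteriole <- function(partner = NULL) {
    ra <- draw_arteriole_r()
    rh <- draw_ah_r()
    if (rh > 0.7 * ra) ra <- rh / 0.7
    for (i in 1:600) {
      if (is.null(partner)) {
        p <- rand_pos(cortex_x, cortex_y, ra)
        if (is.null(p)) break
      } else {
        gap <- pair_gap_px()
        dcc <- gap + rh + partner$ah$r
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(partner$x + dcc * cos(th), partner$y + dcc * sin(th))
        if (p[1] < cortex_x[1] + ra + 5 || p[1] > cortex_x[2] - ra - 5 ||
            p[2] < cortex_y[1] + ra + 5 || p[2] > cortex_y[2] - ra - 5) next
      }
      if (!clear_of_blockers(p[1], p[2], ra)) next
      if (is.null(partner)) {
        if (!ah_clear(p[1], p[2], rh)) next
      } else {
        if (!ah_clear(p[1], p[2], rh, except = length(ah_x))) next
      }
      add_blocker(p[1], p[2], ra)
      ah_x[length(ah_x) + 1L] <<- p[1]; ah_y[length(ah_y) + 1L] <<- p[2]
      ah_r[length(ah_r) + 1L] <<- rh
      art <- list(x = p[1], y = p[2], r = ra,
                  ah = list(x = p[1], y = p[2], r = rh))
      arterioles[[length(arterioles) + 1L]] <<- art
      note("arteriole", p[1], p[2], pi * ra^2 * mpp^2,
           extra = list(ah_area_um2 = pi * rh^2 * mpp^2))
      return(art)
    }
    .packing_error("AH-bearing arteriole")
  }
  if (spec$n_ah_close_pairs > 0)
    for (k in seq_len(spec$n_ah_close_pairs)) {
      first <- place_ah_arteriole()
      place_ah_arteriole(partner = first)
    }
  if (n_single_ah > 0) for (k in seq_len(n_single_ah)) place_ah_arteriole()
  n_plain <- spec$n_arterioles - spec$n_ah
  if (n_plain > 0) for (k in seq_len(n_plain)) {
    ra <- draw_arteriole_r()
    p <- place(ra, cortex_x, cortex_y, "arteriole")
    arterioles[[length(arterioles) + 1L]] <-
      list(x = p[1], y = p[2], r = ra, ah = NULL)
    note("arteriole", p[1], p[2], pi * ra^2 * mpp^2)
  }

  # ---- tubules (random sequential packing in the remaining cortex) ---------
  tub <- list(x = numeric(0), y = numeric(0), r = numeric(0),
              prox = logical(0))
  ti_area_px_approx <- diff(cortex_x + c(0, 1)) * diff(cortex_y + c(0, 1)) -
    sum(vapply(gloms, function(g) pi * g$r^2, numeric(1))) -
    sum(vapply(arteries, function(a) pi * a$R^2, numeric(1))) -
    sum(vapply(arterioles, function(a) pi * a$r^2, numeric(1)))
  mean_tub_px <- px_area(spec$prox_frac * spec$prox_area_mean_um2 +
                           (1 - spec$prox_frac) * spec$dist_area_mean_um2)
  n_target <- floor(spec$tubule_fill * ti_area_px_approx / mean_tub_px)
  if (n_target > 0) {
    tries <- 0; max_tries <- 150 * n_target
    fails <- 0
    while (length(tub$x) < n_target && tries < max_tries && fails < 8000) {
      tries <- tries + 1; fails <- fails + 1
      prox <- stats::runif(1) < spec$prox_frac
      a_um2 <- if (prox)
        max(500, .rlnorm_ms(1, spec$prox_area_mean_um2, spec$prox_area_sd_um2))
      else
        max(300, .rlnorm_ms(1, spec$dist_area_mean_um2, spec$dist_area_sd_um2))
      r <- sqrt(px_area(a_um2) / pi)
      p <- rand_pos(cortex_x, cortex_y, r, edge_buffer = 5)
      if (is.null(p)) break
      if (!clear_of_blockers(p[1], p[2], r, gap = 3)) next
      if (length(tub$x) &&
          any((tub$x - p[1])^2 + (tub$y - p[2])^2 < (tub$r + r + 3)^2)) next
      tub$x <- c(tub$x, p[1]); tub$y <- c(tub$y, p[2])
      tub$r <- c(tub$r, r); tub$prox <- c(tub$prox, prox)
      fails <- 0
    }
  }

  # ---- rasterization --------------------------------------------------------
  disc_idx <- function(cx, cy, r) {
    xs <- max(0, floor(cx - r)):min(nx - 1, ceiling(cx + r))
    ys <- max(0, floor(cy - r)):min(ny - 1, ceiling(cy + r))
    if (!length(xs) || !length(ys)) return(integer(0))
    inside <- outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2
    (rep(xs, times = length(ys)) + 1L +
        nx * rep(ys, each = length(xs)))[as.vector(inside)]
  }
  annulus_idx <- function(cx, cy, r_out, r_in) {
    xs <- max(0, floor(cx - r_out)):min(nx - 1, ceiling(cx + r_out))
    ys <- max(0, floor(cy - r_out)):min(ny - 1, ceiling(cy + r_out))
    if (!length(xs) || !length(ys)) return(integer(0))
    d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    inside <- d2 <= r_out^2 & d2 > r_in^2
    (rep(xs, times = length(ys)) + 1L +
        nx * rep(ys, each = length(xs)))[as.vector(inside)]
  }
  ellipse_idx <- function(cx, cy, a, b, th) {
    xs <- max(0, floor(cx - a)):min(nx - 1, ceiling(cx + a))
    ys <- max(0, floor(cy - a)):min(ny - 1, ceiling(cy + a))
    if (!length(xs) || !length(ys)) return(integer(0))
    dx <- outer(xs - cx, rep(1, length(ys)))
    dy <- outer(rep(1, length(xs)), ys - cy)
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    inside <- u^2 + v^2 <= 1
    (rep(xs, times = length(ys)) + 1L +
        nx * rep(ys, each = length(xs)))[as.vector(inside)]
  }
  from_idx <- function(idx_list) {
    m <- matrix(FALSE, nx, ny)
    idx <- unlist(idx_list, use.names = FALSE)
    if (length(idx)) m[idx] <- TRUE
    m
  }

  tissue <- matrix(TRUE, nx, ny)
  cortex <- matrix(FALSE, nx, ny)
  cortex[(cortex_x[1]:cortex_x[2]) + 1L, (cortex_y[1]:cortex_y[2]) + 1L] <- TRUE
  medulla <- matrix(FALSE, nx, ny)
  if (!is.null(medulla_x))
    medulla[(medulla_x[1]:medulla_x[2]) + 1L,
            (medulla_y[1]:medulla_y[2]) + 1L] <- TRUE

  glom_idx <- lapply(gloms, function(g) disc_idx(g$x, g$y, g$r))
  glom_class_v <- vapply(gloms, `[[`, character(1), "class")
  nsg_m <- from_idx(glom_idx[glom_class_v == "nsg"])
  gsg_m <- from_idx(glom_idx[glom_class_v == "gsg"])
  emp_m <- from_idx(glom_idx[glom_class_v == "empty"])
  glom_m <- from_idx(glom_idx)

  vessels_m <- from_idx(c(
    lapply(arteries, function(a) disc_idx(a$x, a$y, a$R)),
    lapply(arterioles, function(a) disc_idx(a$x, a$y, a$r))))
  lumen_m <- from_idx(lapply(arteries, function(a) disc_idx(a$x, a$y, a$r_l)))
  intima_m <- from_idx(lapply(Filter(function(a) a$s > 0, arteries),
                              function(a) annulus_idx(a$x, a$y, a$r_i, a$r_l)))
  ah_m <- from_idx(lapply(Filter(function(a) !is.null(a$ah), arterioles),
                          function(a) disc_idx(a$ah$x, a$ah$y, a$ah$r)))

  inter_m <- from_idx(lapply(interlobar, function(a) disc_idx(a$x, a$y, a$R)))
  lumen_med_m <- from_idx(lapply(interlobar,
                                 function(a) disc_idx(a$x, a$y, a$r_l)))
  intima_med_m <- from_idx(lapply(Filter(function(a) a$s > 0, interlobar),
                                  function(a)
                                    annulus_idx(a$x, a$y, a$r_i, a$r_l)))

  ta_m <- from_idx(lapply(ta_foci, function(f)
    ellipse_idx(f$x, f$y, f$a, f$b, f$th)))

  prox_m <- from_idx(lapply(which(tub$prox), function(k)
    disc_idx(tub$x[k], tub$y[k], tub$r[k])))
  dist_m <- from_idx(lapply(which(!tub$prox), function(k)
    disc_idx(tub$x[k], tub$y[k], tub$r[k])))
  tubules_m <- prox_m | dist_m

  ti_m <- cortex & !glom_m & !vessels_m
  cortex_excl_m <- cortex & !vessels_m & !ta_m

  edge <- .mask_edge(tissue)
  ei <- which(edge)
  capsule <- matrix(FALSE, nx, ny)
  if (spec$kind == "core") {
    capsule[ei[(ei - 1L) %% nx < cap_px]] <- TRUE
  } else {
    capsule[ei[(ei - 1L) %/% nx < cap_px]] <- TRUE
  }

  masks <- setNames(list(
    tissue, cortex, ta_m, cortex_excl_m, ti_m, tubules_m, dist_m, prox_m,
    glom_m, gsg_m, emp_m, nsg_m, vessels_m, ah_m, intima_m, lumen_m,
    medulla, inter_m, intima_med_m, lumen_med_m),
    unlist(.cls, use.names = FALSE))
  section <- labeled_section(masks, calibration(mpp, spec$section_thickness),
                             kind = spec$kind, capsule = capsule,
                             validate = FALSE)

  # ---- ground truth ---------------------------------------------------------
  glom_class <- vapply(gloms, `[[`, character(1), "class")
  glom_edge <- vapply(gloms, `[[`, logical(1), "edge")
  glom_area <- vapply(gloms, `[[`, numeric(1), "area_um2")
  ti_area_um2 <- cortex_area_mm2 * 1e6 - sum(glom_area) -
    sum(vapply(arteries, function(a) pi * a$R^2, numeric(1))) * mpp^2 -
    sum(vapply(arterioles, function(a) pi * a$r^2, numeric(1))) * mpp^2
  tub_area_um2 <- sum(pi * tub$r^2) * mpp^2
  prox_areas <- pi * tub$r[tub$prox]^2 * mpp^2
  dist_areas <- pi * tub$r[!tub$prox]^2 * mpp^2
  nsg_interior_areas <- glom_area[glom_class == "nsg" & !glom_edge]
  mean_nsg <- if (length(nsg_interior_areas)) mean(nsg_interior_areas) else NA

  # merge AH lesions by analytic boundary distance (< 500 um, strict)
  ah_area_all <- pi * ah_r^2 * mpp^2
  merged <- .merge_clusters_by_distance(
    n = length(ah_x),
    dist_fun = function(i, j)
      (sqrt((ah_x[i] - ah_x[j])^2 + (ah_y[i] - ah_y[j])^2) -
         ah_r[i] - ah_r[j]) * mpp,
    threshold = 500)
  rep_areas <- if (length(ah_x))
    vapply(split(seq_along(ah_x), merged), function(ix)
      max(ah_area_all[ix]), numeric(1)) else numeric(0)

  n_glom_profiles <- sum(glom_class %in% c("nsg", "gsg"))
  vol <- if (is.na(mean_nsg)) NA else glomerular_volume(mean_nsg)
  cpg <- if (n_glom_profiles > 0 && !is.na(vol))
    cortex_per_glomerulus(cortex_area_mm2, n_glom_profiles, vol,
                          spec$section_thickness) else NA
  qual_s <- artery_s  # all generated arteries exceed the 7850 um2 gate
  tub_denom_um2 <- tub_area_um2 + ta_area_true
  measures <- list(
    cortex_area_mm2 = cortex_area_mm2,
    medulla_area_mm2 = medulla_area_mm2,
    nsg_count = sum(glom_class == "nsg"),
    gsg_count = sum(glom_class == "gsg"),
    empty_capsule_count = sum(glom_class == "empty"),
    ta_foci_count = spec$n_ta,
    ah_lesion_count = length(rep_areas),
    glomerular_volume_mm3 = vol,
    cortex_per_glomerulus_mm3 = cpg,
    mean_proximal_tubular_area_um2 =
      if (length(prox_areas)) mean(prox_areas) else NA,
    mean_distal_tubular_area_um2 =
      if (length(dist_areas)) mean(dist_areas) else NA,
    pct_gsg = if (n_glom_profiles > 0)
      100 * sum(glom_class == "gsg") / n_glom_profiles else NA,
    pct_ta_per_tubular = if (tub_denom_um2 > 0)
      100 * ta_area_true / tub_denom_um2 else NA,
    pct_ita_per_tubulointerstitial = if (ti_area_um2 > 0)
      100 * (ti_area_um2 - tub_area_um2) / ti_area_um2 else NA,
    ta_foci_density_per_mm2 = if (tub_denom_um2 > 0)
      spec$n_ta / (tub_denom_um2 / 1e6) else NA,
    ah_density_per_cortex_mm2 = length(rep_areas) / cortex_area_mm2,
    pct_arterioles_with_ah = if (length(arterioles))
      100 * spec$n_ah / length(arterioles) else NA,
    mean_ah_area_um2 = if (length(rep_areas)) mean(rep_areas) else NA,
    pct_luminal_stenosis = if (length(qual_s)) 100 * mean(qual_s) else NA)

  truth <- structure(list(
    counts = list(
      nsg = sum(glom_class == "nsg"), gsg = sum(glom_class == "gsg"),
      empty_capsule = sum(glom_class == "empty"),
      ta_foci = spec$n_ta,
      ah_placed = length(ah_x), ah_merged = length(rep_areas),
      arteries = length(arteries), arterioles = length(arterioles),
      arterioles_with_ah = spec$n_ah,
      interlobar = length(interlobar),
      tubules = length(tub$x),
      edge_bisected_glomeruli = spec$n_edge_glomeruli),
    areas = list(
      cortex_mm2 = cortex_area_mm2, medulla_mm2 = medulla_area_mm2,
      tubulointerstitium_um2 = ti_area_um2, tubules_um2 = tub_area_um2,
      ta_um2 = ta_area_true, mean_nsg_area_um2 = mean_nsg,
      ah_lesion_areas_um2 = ah_area_all,
      ah_representative_areas_um2 = rep_areas),
    measures = measures,
    structures = data.frame(
      type = vapply(structures, `[[`, character(1), "type"),
      x_um = vapply(structures, `[[`, numeric(1), "x_um"),
      y_um = vapply(structures, `[[`, numeric(1), "y_um"),
      area_um2 = vapply(structures, `[[`, numeric(1), "area_um2"),
      edge_bisected = vapply(structures, `[[`, logical(1),
                             "edge_bisected"))),
    class = "scene_truth")

  list(section = section, truth = truth)
}

# single-linkage clustering by pairwise distance below a strict threshold;
# returns integer cluster membership (union-find over all pairs)
.merge_clusters_by_distance <- function(n, dist_fun, threshold) {
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      if (dist_fun(i, j) < threshold) {
        a <- find(i); b <- find(j)
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
  root <- vapply(seq_len(n), find, integer(1))
  match(root, sort(unique(root)))
}

#' Simulate a degraded second annotation of a section
#'
#' Produces a perturbed copy of a section standing in for an imperfect second
#' annotator: per-class boundary dilation or erosion (disc structuring
#' element) and whole-component class flips. A zero-magnitude perturbation
#' returns an identical section. The perturbed copy is not re-validated for
#' nesting (a dilated child may legitimately escape its parent layer).
#'
#' @param section a [labeled_section()].
#' @param dilate_px,erode_px boundary perturbation radius in pixels (>= 0).
#' @param classes class names to perturb (default: all present layers).
#' @param flip optional data.frame with columns `from`, `to`, `rate`:
#'   connected components of class `from` are relabeled `to` with probability
#'   `rate`.
#' @param seed RNG seed for the flips.
#' @return A perturbed `labeled_section`.
#' @export
perturb_annotation <- function(section, dilate_px = 0, erode_px = 0,
                               classes = NULL, flip = NULL, seed = 1) {
  stopifnot(dilate_px >= 0, erode_px >= 0)
  if (dilate_px == 0 && erode_px == 0 && is.null(flip)) return(section)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  if (is.null(classes)) classes <- names(section$masks)
  masks <- section$masks
  for (nm in intersect(classes, names(masks))) {
    m <- masks[[nm]]
    if (!any(m)) next
    if (dilate_px > 0) m <- .dilate(m, dilate_px)
    if (erode_px > 0) {
      er <- EBImage::erode(m * 1, EBImage::makeBrush(2 * erode_px + 1, "disc"))
      m <- matrix(as.vector(er) > 0, nrow(m), ncol(m))
    }
    masks[[nm]] <- m
  }
  if (!is.null(flip)) {
    stopifnot(all(c("from", "to", "rate") %in% names(flip)))
    for (k in seq_len(nrow(flip))) {
      from <- flip$from[k]; to <- flip$to[k]; rate <- flip$rate[k]
      m <- masks[[from]]
      if (is.null(m) || !any(m)) next
      L <- .label_mask(m, 8)
      tgt <- if (is.null(masks[[to]]))
        matrix(FALSE, nrow(m), ncol(m)) else masks[[to]]
      for (id in seq_len(max(L))) {
        if (stats::runif(1) < rate) {
          sel <- L == id
          m <- m & !sel
          tgt <- tgt | sel
        }
      }
      masks[[from]] <- m
      masks[[to]] <- tgt
    }
  }
  out <- section
  out$masks <- masks
  out
}
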