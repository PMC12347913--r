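# readers/writers: PNG label-raster directories and GeoJSON feature sets

.slug <- function(x) gsub("[^A-Za-z0-9]+", "_", tolower(x))

#' Write a section to a raster directory
#'
#' Writes one 8-bit grayscale PNG per non-empty class layer plus a sidecar
#' `meta.json` carrying format version, calibration, section kind, taxonomy
#' (codes, names, containment, compartments) and the layer-file map. The
#' capsule mask, when present, is written as `capsule.png`.
#'
#' @param section a [labeled_section()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_section <- function(section, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tax <- section$taxonomy
  files <- setNames(rep(NA_character_, nrow(tax)), tax$name)
  for (nm in names(section$masks)) {
    if (!any(section$masks[[nm]])) next
    code <- tax$code[match(nm, tax$name)]
    f <- sprintf("layer_%02d_%s.png", code, .slug(nm))
    png::writePNG(t(section$masks[[nm]]) * 1, file.path(dir, f))
    files[nm] <- f
  }
  capsule_file <- NULL
  if (!is.null(section$capsule) && any(section$capsule)) {
    capsule_file <- "capsule.png"
    png::writePNG(t(section$capsule) * 1, file.path(dir, capsule_file))
  }
  meta <- list(
    format = "nephromorph-section",
    format_version = "1.0",
    microns_per_pixel = section$calibration$microns_per_pixel,
    section_thickness = section$calibration$section_thickness,
    kind = section$kind,
    width = section$dim[1],
    height = section$dim[2],
    taxonomy = data.frame(code = tax$code, name = tax$name,
                          parent = tax$parent, compartment = tax$compartment),
    layers = as.list(files[!is.na(files)]),
    capsule_file = capsule_file)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}

#' Read a section from a raster directory
#'
#' @param dir directory written by [write_section()] (or following its
#'   documented `meta.json` schema).
#' @param validate check layer nesting after reading.
#' @return A [labeled_section()].
#' @export
read_section <- function(dir, validate = TRUE) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tax <- class_taxonomy(meta$taxonomy)
  cal <- calibration(meta$microns_per_pixel, meta$section_thickness)
  read_mask <- function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    t(img) > 0.5
  }
  masks <- lapply(meta$layers, read_mask)
  unknown <- setdiff(names(masks), tax$name)
  if (length(unknown))
    stop("layer classes not in taxonomy: ", paste(unknown, collapse = ", "))
  capsule <- if (!is.null(meta$capsule_file)) read_mask(meta$capsule_file)
  labeled_section(masks, cal, taxonomy = tax, kind = meta$kind,
                  capsule = capsule, validate = validate)
}

# ---- polygon <-> raster -----------------------------------------------------

# Even-odd scanline rasterization of polygon rings given in pixel units
# (pixel centres at integer coordinates 0, 1, ...). A pixel is filled when its
# centre lies strictly inside under the even-odd rule; centres exactly on a
# boundary edge are excluded (half-open convention).
.rasterize_rings <- function(rings, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  if (!length(rings)) return(out)
  x1 <- numeric(0); y1 <- numeric(0); x2 <- numeric(0); y2 <- numeric(0)
  for (r in rings) {
    r <- round(r, 6)
    n <- nrow(r)
    if (n < 3) next
    if (r[1, 1] != r[n, 1] || r[1, 2] != r[n, 2]) r <- rbind(r, r[1, ])
    x1 <- c(x1, r[-nrow(r), 1]); y1 <- c(y1, r[-nrow(r), 2])
    x2 <- c(x2, r[-1, 1]);       y2 <- c(y2, r[-1, 2])
  }
  keep <- y1 != y2           # horizontal edges never cross a scanline
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (!length(x1)) return(out)
  ylo <- max(0L, floor(min(y1, y2)))
  yhi <- min(dim[2] - 1L, ceiling(max(y1, y2)))
  for (yc in seq(ylo, yhi)) {
    cross <- (y1 <= yc) != (y2 <= yc)
    if (!any(cross)) next
    xs <- x1[cross] + (yc - y1[cross]) * (x2[cross] - x1[cross]) /
      (y2[cross] - y1[cross])
    xs <- sort(round(xs, 6))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- max(0L, floor(xs[k]) + 1L)
      hi <- min(dim[1] - 1L, ceiling(xs[k + 1]) - 1L)
      if (lo <= hi) out[(lo:hi) + 1L, yc + 1L] <- TRUE
    }
  }
  out
}

# Trace the boundary rings of a pixel mask. Rings run along pixel-cell edges
# (corners at half-integers in pixel units) with the foreground kept on the
# left; outer rings and hole rings are both emitted and are interpreted under
# the even-odd rule. Exact inverse of .rasterize_rings at fixed resolution.
.trace_rings <- function(mask) {
  if (!any(mask)) return(list())
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  px <- (idx - 1L) %% nr      # 0-based pixel x
  py <- (idx - 1L) %/% nr
  shift_has <- function(dx, dy) {
    qx <- px + dx; qy <- py + dy
    ok <- qx >= 0L & qx < nr & qy >= 0L & qy < nc
    has <- rep(FALSE, length(px))
    has[ok] <- mask[cbind(qx[ok] + 1L, qy[ok] + 1L)]
    has
  }
  # directed boundary edges: (start corner a,b; direction 1:+x 2:+y 3:-x 4:-y)
  ea <- integer(0); eb <- integer(0); ed <- integer(0)
  add <- function(sel, a, b, d) {
    ea <<- c(ea, a[sel]); eb <<- c(eb, b[sel]); ed <<- c(ed, rep(d, sum(sel)))
  }
  add(!shift_has(0L, -1L), px,      py,      1L)  # top edge, heading +x
  add(!shift_has(1L, 0L),  px + 1L, py,      2L)  # right edge, heading +y
  add(!shift_has(0L, 1L),  px + 1L, py + 1L, 3L)  # bottom edge, heading -x
  add(!shift_has(-1L, 0L), px,      py + 1L, 4L)  # left edge, heading -y
  dxs <- c(1L, 0L, -1L, 0L); dys <- c(0L, 1L, 0L, -1L)
  key <- ea + (nr + 2L) * eb
  by_start <- split(seq_along(ea), key)
  used <- rep(FALSE, length(ea))
  rings <- list()
  for (e0 in seq_along(ea)) {
    if (used[e0]) next
    ring_a <- integer(0); ring_b <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_a <- c(ring_a, ea[e]); ring_b <- c(ring_b, eb[e])
      na <- ea[e] + dxs[ed[e]]; nb <- eb[e] + dys[ed[e]]
      if (na == ea[e0] && nb == eb[e0]) break
      cand <- by_start[[as.character(na + (nr + 2L) * nb)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break  # defensive; boundary edges always chain
      if (length(cand) > 1L) {
        # ambiguous (checkerboard) corner: prefer right turn, then straight
        pref <- c((ed[e] %% 4L) + 1L, ed[e], ((ed[e] + 2L) %% 4L) + 1L)
        cand <- cand[order(match(ed[cand], pref))]
      }
      e <- cand[1L]
    }
    # drop collinear intermediate corners
    n <- length(ring_a)
    if (n >= 3) {
      pa <- c(ring_a[n], ring_a[-n]); pb <- c(ring_b[n], ring_b[-n])
      na2 <- c(ring_a[-1], ring_a[1]); nb2 <- c(ring_b[-1], ring_b[1])
      turn <- (ring_a - pa) * (nb2 - ring_b) != (ring_b - pb) * (na2 - ring_a)
      ring_a <- ring_a[turn]; ring_b <- ring_b[turn]
    }
    rings[[length(rings) + 1L]] <- cbind(x = ring_a - 0.5, y = ring_b - 0.5)
  }
  rings
}

#' Vectorize a mask into boundary polygons
#'
#' Traces the boundary of every connected component (8-connectivity) of a
#' logical mask into closed polygon rings running along pixel-cell edges.
#' Hole rings are included; rings are interpreted under the even-odd rule, so
#' rasterizing them back at the same resolution reproduces the mask exactly.
#'
#' @param mask logical matrix (`[x, y]` convention).
#' @return List with one element per component, each a list of `n x 2` ring
#'   matrices in pixel units (pixel centres at integer coordinates).
#' @export
vectorize_mask <- function(mask) {
  L <- .label_mask(mask, 8)
  n <- max(L)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(k) .trace_rings(L == k))
}

#' Write a section as a GeoJSON feature collection
#'
#' Each connected component of each class becomes one `Polygon` feature
#' (outer ring plus hole rings, even-odd semantics) with properties
#' `class_name` and `class_code`; coordinates are in micrometers. Calibration,
#' kind and raster frame are stored in the top-level `properties` member, and
#' capsule boundary pixels are written as features with `capsule = true`.
#'
#' @param section a [labeled_section()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_section_geojson <- function(section, path) {
  mpp <- section$calibration$microns_per_pixel
  feats <- list()
  ring_coords <- function(r) lapply(seq_len(nrow(r)), function(i)
    c(r[i, 1] * mpp, r[i, 2] * mpp))
  add_feature <- function(rings, props) {
    rings <- lapply(rings, function(r) {
      cc <- ring_coords(r)
      c(cc, cc[1])  # close the ring
    })
    feats[[length(feats) + 1L]] <<- list(
      type = "Feature", properties = props,
      geometry = list(type = "Polygon", coordinates = rings))
  }
  for (nm in names(section$masks)) {
    if (!any(section$masks[[nm]])) next
    code <- section$taxonomy$code[match(nm, section$taxonomy$name)]
    for (comp in vectorize_mask(section$masks[[nm]]))
      add_feature(comp, list(class_name = nm, class_code = code))
  }
  if (!is.null(section$capsule) && any(section$capsule)) {
    for (comp in vectorize_mask(section$capsule))
      add_feature(comp, list(capsule = TRUE))
  }
  gj <- list(
    type = "FeatureCollection",
    properties = list(format = "nephromorph-geojson", format_version = "1.0",
                      microns_per_pixel = mpp,
                      section_thickness = section$calibration$section_thickness,
                      kind = section$kind,
                      width = section$dim[1], height = section$dim[2]),
    features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON annotation set into a section
#'
#' Accepts feature collections written by [write_section_geojson()] or
#' QuPath-style exports: `Polygon`/`MultiPolygon` features carrying a
#' `class_name` property (micrometer coordinates). Features with a truthy
#' `capsule` property populate the capsule mask. Polygons are rasterized at
#' the calibration resolution under the even-odd rule.
#'
#' @param path GeoJSON file.
#' @param taxonomy a [class_taxonomy()]; default [kidney_taxonomy()].
#' @param calibration a [calibration()]; when `NULL`, taken from the file's
#'   top-level `properties`.
#' @param dim raster frame `c(nx, ny)`; when `NULL`, taken from the file or
#'   inferred from the coordinate extent.
#' @param kind section kind override; when `NULL`, from the file (default
#'   `"core"`).
#' @param validate check layer nesting after rasterization.
#' @return A [labeled_section()].
#' @export
read_section_geojson <- function(path, taxonomy = kidney_taxonomy(),
                                 calibration = NULL, dim = NULL, kind = NULL,
                                 validate = TRUE) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  props <- gj$properties
  if (is.null(calibration)) {
    if (is.null(props$microns_per_pixel))
      stop("no calibration given and none stored in the file")
    calibration <- calibration(props$microns_per_pixel,
                               props$section_thickness %||% 2.5)
  }
  mpp <- calibration$microns_per_pixel
  if (is.null(kind)) kind <- props$kind %||% "core"
  poly_rings <- function(geom) {
    rings_um <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type))
    lapply(rings_um, function(r)
      matrix(unlist(r), ncol = 2, byrow = TRUE) / mpp)
  }
  parsed <- lapply(gj$features, function(f)
    list(class_name = f$properties$class_name,
         capsule = isTRUE(f$properties$capsule),
         rings = poly_rings(f$geometry)))
  for (p in parsed) {
    if (!p$capsule && is.null(p$class_name))
      stop("feature lacks a class_name property")
    if (!p$capsule && !(p$class_name %in% taxonomy$name))
      stop("unknown class in taxonomy: ", p$class_name)
  }
  if (is.null(dim)) {
    if (!is.null(props$width)) {
      dim <- c(props$width, props$height)
    } else {
      xy <- do.call(rbind, unlist(lapply(parsed, `[[`, "rings"),
                                  recursive = FALSE))
      dim <- c(ceiling(max(xy[, 1])) + 2L, ceiling(max(xy[, 2])) + 2L)
    }
  }
  dim <- as.integer(dim)
  masks <- list()
  capsule <- NULL
  for (p in parsed) {
    m <- .rasterize_rings(p$rings, dim)
    if (p$capsule) {
      capsule <- if (is.null(capsule)) m else capsule | m
    } else {
      masks[[p$class_name]] <-
        if (is.null(masks[[p$class_name]])) m else masks[[p$class_name]] | m
    }
  }
  root <- taxonomy$name[is.na(taxonomy$parent)]
  if (is.null(masks[[root]]) && length(masks)) {
    # no explicit tissue silhouette: use the union of all annotations
    masks[[root]] <- Reduce(`|`, masks)
  }
  labeled_section(masks, calibration, taxonomy = taxonomy, kind = kind,
                  capsule = capsule, validate = validate)
}

#' Load a section from a raster directory or GeoJSON file
#'
#' Dispatches on the input: a directory containing `meta.json` is read with
#' [read_section()]; a `.geojson`/`.json` file with [read_section_geojson()].
#'
#' @param path section directory or GeoJSON file.
#' @param ... passed to the underlying reader.
#' @return A [labeled_section()].
#' @export
load_section <- function(path, ...) {
  if (dir.exists(path)) return(read_section(path, ...))
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE))
    return(read_section_geojson(path, ...))
  stop("cannot load section from ", path,
       ": expected a raster directory with meta.json or a GeoJSON file")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
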