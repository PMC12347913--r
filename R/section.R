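#' Spatial calibration of a section
#'
#' @param microns_per_pixel physical pixel pitch in micrometers per pixel.
#'   Defaults to 0.5, the usual pitch of a 20x whole-slide scan.
#' @param section_thickness section thickness in micrometers (default 2.5,
#'   the middle of the usual 2-3 um PAS section range); used by the
#'   areal-to-volumetric density conversion in [cortex_per_glomerulus()].
#' @return A `calibration` object.
#' @export
calibration <- function(microns_per_pixel = 0.5, section_thickness = 2.5) {
  stopifnot(is.numeric(microns_per_pixel), microns_per_pixel > 0,
            is.numeric(section_thickness), section_thickness > 0)
  structure(list(microns_per_pixel = microns_per_pixel,
                 section_thickness = section_thickness),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4g um/px, section thickness %.4g um\n",
              x$microns_per_pixel, x$section_thickness))
  invisible(x)
}

#' Calibrated multilayer label raster of one tissue section
#'
#' A `labeled_section` holds one logical mask per taxonomy class (layers may
#' overlap where the taxonomy nests them), the calibration, the section kind
#' (needle core or wedge), and an optional capsule mask marking the part of
#' the tissue boundary that is anatomical kidney capsule rather than a cut
#' edge. Masks are stored as `[x, y]` matrices: first index runs along x
#' (rightwards), second along y (downwards); pixel `(i, j)` is centred at the
#' 0-based micron coordinate `((i-1) * mpp, (j-1) * mpp)`.
#'
#' @param masks named list of logical matrices, one per class present; all the
#'   same dimension. Names must be class names of `taxonomy`. Classes with no
#'   pixels may be omitted.
#' @param calibration a [calibration()].
#' @param taxonomy a [class_taxonomy()]; default [kidney_taxonomy()].
#' @param kind `"core"` (needle biopsy) or `"wedge"`.
#' @param capsule optional logical matrix marking capsule boundary pixels.
#' @param validate check layer nesting (child pixels inside parent, zero
#'   tolerance) and that all labels lie inside the Tissue silhouette.
#' @return A `labeled_section`.
#' @export
labeled_section <- function(masks, calibration, taxonomy = kidney_taxonomy(),
                            kind = c("core", "wedge"), capsule = NULL,
                            validate = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  unknown <- setdiff(names(masks), taxonomy$name)
  if (length(unknown))
    stop("mask classes not in taxonomy: ", paste(unknown, collapse = ", "))
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stop("all masks must share the same dimension")
  masks <- lapply(masks, function(m) {storage.mode(m) <- "logical"; m})
  if (!is.null(capsule)) {
    storage.mode(capsule) <- "logical"
    if (!identical(dim(capsule), dims[[1]]))
      stop("capsule mask dimension differs from layer dimension")
  }
  section <- structure(list(masks = masks, calibration = calibration,
                            taxonomy = taxonomy, kind = kind,
                            capsule = capsule, dim = dims[[1]]),
                       class = "labeled_section")
  if (validate) validate_section(section)
  section
}

#' Retrieve the mask of one class (empty if the class has no pixels)
#'
#' @param section a `labeled_section`.
#' @param class class name or code.
#' @return Logical matrix of the section's dimension.
#' @export
class_mask <- function(section, class) {
  name <- taxonomy_class(section$taxonomy, class)$name
  m <- section$masks[[name]]
  if (is.null(m)) m <- matrix(FALSE, section$dim[1], section$dim[2])
  m
}

#' Calibrated area of one class
#'
#' @inheritParams class_mask
#' @return Area in square micrometers (pixel count times `mpp^2`).
#' @export
class_area_um2 <- function(section, class) {
  sum(class_mask(section, class)) * section$calibration$microns_per_pixel^2
}

#' Validate layer nesting of a section
#'
#' Checks that every labeled pixel lies inside the Tissue silhouette and that
#' every child-class pixel lies inside its parent-class mask (tolerance 0
#' pixels). Violations raise an error listing the offending classes and pixel
#' counts.
#'
#' @param section a `labeled_section`.
#' @return The section, invisibly.
#' @export
validate_section <- function(section) {
  tax <- section$taxonomy
  root <- tax$name[is.na(tax$parent)]
  offenders <- character(0)
  for (nm in names(section$masks)) {
    if (nm == root) next
    parent <- tax$name[match(tax$parent[match(nm, tax$name)], tax$code)]
    child_mask <- section$masks[[nm]]
    parent_mask <- section$masks[[parent]]
    n_out <- if (is.null(parent_mask)) sum(child_mask)
             else sum(child_mask & !parent_mask)
    if (n_out > 0)
      offenders <- c(offenders,
                     sprintf("%s outside %s (%d px)", nm, parent, n_out))
  }
  if (length(offenders))
    stop("nesting violation: ", paste(offenders, collapse = "; "))
  invisible(section)
}

#' @export
print.labeled_section <- function(x, ...) {
  mpp <- x$calibration$microns_per_pixel
  cat(sprintf("<labeled_section> %s, %d x %d px @ %.3g um/px\n",
              x$kind, x$dim[1], x$dim[2], mpp))
  present <- names(x$masks)[vapply(x$masks, any, logical(1))]
  cat("  classes with pixels:", length(present), "\n")
  for (nm in present)
    cat(sprintf("    %-46s %.3g mm2\n", nm, sum(x$masks[[nm]]) * mpp^2 / 1e6))
  if (!is.null(x$capsule)) cat("  capsule boundary: marked\n")
  invisible(x)
}
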