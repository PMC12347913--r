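# connected-component labeling and per-structure bookkeeping

# 4-connected labeling via EBImage::bwlabel; 8-connectivity is obtained by
# union-find merging of diagonally adjacent 4-connected labels.
.label_mask <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(L), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(L) > 1L) {
    nr <- nrow(L); nc <- ncol(L)
    pos <- which(L > 0L)
    r <- (pos - 1L) %% nr; cc <- (pos - 1L) %/% nr
    # each unordered diagonal pair is seen once, from its left member
    diag_pairs <- function(offset, ok) {
      p <- pos[ok]
      a <- L[p]; b <- L[p + offset]
      keep <- b > 0L & a != b
      cbind(a[keep], b[keep])
    }
    pr <- rbind(
      diag_pairs(nr + 1L, r < nr - 1L & cc < nc - 1L),   # down-right
      diag_pairs(nr - 1L, r > 0L & cc < nc - 1L))        # up-right

    if (nrow(pr)) {
      n <- max(L)
      parent <- seq_len(n)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pr))) {
        a <- find(pr[k, 1]); b <- find(pr[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(n), find, integer(1))
      relab <- match(root, sort(unique(root)))
      pos <- L > 0L
      L[pos] <- relab[L[pos]]
    }
  }
  L
}

# boundary pixels of a mask: foreground with a 4-neighbour outside the mask
# (the image frame counts as outside)
.mask_edge <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  f <- rep(FALSE, nc)
  n_up    <- rbind(f, m[-nr, , drop = FALSE])      # neighbour at x-1
  n_down  <- rbind(m[-1, , drop = FALSE], f)       # neighbour at x+1
  g <- rep(FALSE, nr)
  n_left  <- cbind(g, m[, -nc, drop = FALSE])      # neighbour at y-1
  n_right <- cbind(m[, -1, drop = FALSE], g)       # neighbour at y+1
  m & !(n_up & n_down & n_left & n_right)
}

# binary dilation with a Euclidean disc of radius r pixels
.dilate <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- EBImage::dilate(mask * 1, EBImage::makeBrush(2 * r + 1, "disc"))
  matrix(as.vector(out) > 0, nrow(mask), ncol(mask))
}

#' Extract connected structure instances of one class
#'
#' Labels the class mask into connected components and returns one row per
#' structure with its calibrated area, centroid and pixel set. Components are
#' ordered by area descending, ties broken by centroid (x, then y), so the
#' ordering is deterministic.
#'
#' @param section a [labeled_section()].
#' @param class class name or code.
#' @param connectivity 8 (default) or 4. Thin PAS-stained structures fragment
#'   under 4-connectivity, hence the 8-connected default.
#' @return data.frame with columns `class_code`, `class_name`, `id`, `n_px`,
#'   `area_um2`, `centroid_x_um`, `centroid_y_um`, `edge_bisected` (NA until
#'   [flag_edge_bisected()] is applied) and a list-column `pixels` of linear
#'   pixel indices into the section's masks. Zero rows when the class is empty.
#' @export
extract_components <- function(section, class, connectivity = 8) {
  cl <- taxonomy_class(section$taxonomy, class)
  mask <- class_mask(section, cl$name)
  mpp <- section$calibration$microns_per_pixel
  empty <- data.frame(class_code = integer(0), class_name = character(0),
                      id = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), edge_bisected = logical(0))
  empty$pixels <- list()
  attr(empty, "mask_nrow") <- nrow(mask)
  fg <- which(mask)
  if (!length(fg)) return(empty)
  # label inside the foreground bounding box, then map indices back
  nr <- nrow(mask)
  fx <- (fg - 1L) %% nr; fy <- (fg - 1L) %/% nr
  x0 <- min(fx); x1 <- max(fx); y0 <- min(fy); y1 <- max(fy)
  sub <- mask[(x0:x1) + 1L, (y0:y1) + 1L, drop = FALSE]
  L <- .label_mask(sub, connectivity)
  n <- max(L)
  snr <- nrow(sub)
  spos <- which(L > 0L)
  gpos <- (((spos - 1L) %% snr) + x0 + 1L) +
    (((spos - 1L) %/% snr) + y0) * nr
  pix <- split(gpos, L[spos])
  n_px <- lengths(pix)
  cx <- vapply(pix, function(i) mean((i - 1L) %% nr), numeric(1))
  cy <- vapply(pix, function(i) mean((i - 1L) %/% nr), numeric(1))
  out <- data.frame(class_code = cl$code, class_name = cl$name,
                    id = seq_len(n), n_px = as.integer(n_px),
                    area_um2 = n_px * mpp^2,
                    centroid_x_um = cx * mpp, centroid_y_um = cy * mpp,
                    edge_bisected = NA)
  out$pixels <- pix
  ord <- order(-out$area_um2, out$centroid_x_um, out$centroid_y_um)
  out <- out[ord, , drop = FALSE]
  out$id <- seq_len(n)
  rownames(out) <- NULL
  attr(out, "mask_nrow") <- nrow(mask)
  out
}

# boundary pixel coordinates (0-based px) of one component given its linear
# pixel indices; computed inside the bounding box for speed
.component_boundary_xy <- function(pixels, dim) {
  nr <- dim[1]
  x <- (pixels - 1L) %% nr
  y <- (pixels - 1L) %/% nr
  x0 <- min(x); y0 <- min(y)
  sub <- matrix(FALSE, max(x) - x0 + 3L, max(y) - y0 + 3L)
  sub[cbind(x - x0 + 2L, y - y0 + 2L)] <- TRUE
  eb <- .mask_edge(sub)
  idx <- which(eb)
  cbind(x = (idx - 1L) %% nrow(sub) + x0 - 1L,
        y = (idx - 1L) %/% nrow(sub) + y0 - 1L)
}

#' Flag structures bisected by the biopsy cut edge
#'
#' A structure is edge-bisected when it lies within `eps_px` pixels of the
#' tissue-silhouette boundary, excluding boundary segments marked as kidney
#' capsule: a glomerulus clipped by the needle-cut edge is flagged, one merely
#' touching the anatomical capsule is not. Edge-bisected profiles underestimate
#' the true structure, so downstream mean-area computations exclude them by
#' default while counts retain them.
#'
#' @param section a [labeled_section()]; must contain a Tissue mask. When the
#'   section lacks a capsule mask a warning is raised and the whole tissue
#'   boundary is treated as cut edge (conservative: more structures flagged).
#' @param components data.frame from [extract_components()].
#' @param eps_px adjacency tolerance in pixels (default 1).
#' @return `components` with the `edge_bisected` column filled.
#' @export
flag_edge_bisected <- function(section, components, eps_px = 1) {
  if (nrow(components) == 0L) return(components)
  tissue <- class_mask(section, "Tissue")
  if (!any(tissue)) stop("section has no Tissue silhouette")
  edge <- .mask_edge(tissue)
  if (is.null(section$capsule)) {
    warning("section has no capsule mask; treating the entire tissue ",
            "boundary as cut edge")
  } else {
    edge <- edge & !section$capsule
  }
  zone <- .dilate(edge, eps_px)
  components$edge_bisected <-
    vapply(components$pixels, function(idx) any(zone[idx]), logical(1))
  components
}
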