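# shared fixtures and independent oracles

# logical [x, y] matrix with a filled disc (pixel centres, 0-based coords)
disc_mask <- function(nx, ny, cx, cy, r) {
  xs <- matrix(0:(nx - 1), nx, ny)
  ys <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

rect_mask <- function(nx, ny, x0, x1, y0, y1) {
  m <- matrix(FALSE, nx, ny)
  m[(x0:x1) + 1, (y0:y1) + 1] <- TRUE
  m
}

# build a section from partial class masks, auto-filling every ancestor layer
# as the union of its children (Tissue defaults to the full frame)
build_section <- function(masks, mpp = 0.5, kind = "core", capsule = NULL,
                          thickness = 2.5, tissue_full = TRUE) {
  tax <- kidney_taxonomy()
  dims <- dim(masks[[1]])
  full <- setNames(vector("list", nrow(tax)), tax$name)
  for (nm in names(masks)) full[[nm]] <- masks[[nm]]
  # propagate children upward, deepest classes first
  depth <- function(nm) {
    d <- 0; code <- tax$code[match(nm, tax$name)]
    repeat {
      p <- tax$parent[match(code, tax$code)]
      if (is.na(p)) return(d)
      d <- d + 1; code <- p
    }
  }
  ord <- names(full)[order(-vapply(names(full), depth, numeric(1)))]
  for (nm in ord) {
    if (is.null(full[[nm]])) next
    p <- tax$parent[match(nm, tax$name)]
    if (is.na(p)) next
    pname <- tax$name[match(p, tax$code)]
    full[[pname]] <- if (is.null(full[[pname]])) full[[nm]]
                     else full[[pname]] | full[[nm]]
  }
  if (tissue_full) full[["Tissue"]] <- matrix(TRUE, dims[1], dims[2])
  full <- Filter(Negate(is.null), full)
  labeled_section(full, calibration(mpp, thickness), kind = kind,
                  capsule = capsule)
}

# naive flood-fill connected components (BFS), independent of the package's
# union-find labeling
flood_fill_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  stack <- integer(sum(mask))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      x <- (p - 1L) %% nr; y <- (p - 1L) %/% nr
      for (k in seq_len(nrow(nb))) {
        qx <- x + nb[k, 1]; qy <- y + nb[k, 2]
        if (qx < 0 || qx >= nr || qy < 0 || qy >= nc) next
        q <- qx + 1L + qy * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  lab
}

# naive pixel-set agreement oracle
naive_agreement <- function(test_mask, ref_mask, region_mask) {
  t <- which(test_mask & region_mask)
  r <- which(ref_mask & region_mask)
  tp <- length(intersect(t, r))
  fp <- length(setdiff(t, r))
  fn <- length(setdiff(r, t))
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  s <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = p, sensitivity = s,
       f1 = if (!is.na(p) && !is.na(s) && p + s > 0) 2 * p * s / (p + s)
            else NA_real_,
       fp_pct = 100 * fp / sum(region_mask),
       fn_pct = 100 * fn / sum(region_mask))
}

# random blobby raster: union of random discs on a small frame
random_blob_mask <- function(nx, ny, n_blobs, r_range = c(2, 12)) {
  m <- matrix(FALSE, nx, ny)
  for (i in seq_len(n_blobs))
    m <- m | disc_mask(nx, ny, runif(1, 0, nx - 1), runif(1, 0, ny - 1),
                       runif(1, r_range[1], r_range[2]))
  m
}

# transitive-closure merge oracle over explicit pairwise distances
merge_count_oracle <- function(dists_um, n, threshold = 500) {
  # dists_um: matrix n x n of pairwise distances
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && dists_um[i, j] < threshold && grp[i] != grp[j]) {
        grp[grp == grp[max(i, j)]] <- grp[min(i, j)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(grp))
}

# a small fast scene used by several suites
small_scene <- function(seed = 1, cortex = 0.5, ...) {
  generate_section(donor_scene_spec(cortex_area_mm2 = cortex, seed = seed,
                                    ...))
}
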