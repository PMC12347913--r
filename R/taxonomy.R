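#' Class taxonomy for multi-class kidney segmentations
#'
#' A `class_taxonomy` declares the named segmentation classes, their integer
#' codes, a single-parent containment relation (e.g. arteriolar hyalinosis
#' lesions lie inside the arteries-and-arterioles layer, which lies inside the
#' cortex), and a compartment tag per class (`tissue`, `cortex` or `medulla`).
#'
#' @param classes data.frame with columns `code` (unique positive integers),
#'   `name` (unique non-empty strings), `parent` (code of the containing class,
#'   `NA` for the root) and `compartment` (one of `"tissue"`, `"cortex"`,
#'   `"medulla"`).
#' @return An object of class `class_taxonomy` (a validated data.frame).
#' @seealso [kidney_taxonomy()] for the default 20-class renal taxonomy.
#' @export
class_taxonomy <- function(classes) {
  stopifnot(is.data.frame(classes),
            all(c("code", "name", "parent", "compartment") %in% names(classes)))
  classes$code <- as.integer(classes$code)
  classes$parent <- as.integer(classes$parent)
  classes$name <- as.character(classes$name)
  if (anyDuplicated(classes$code)) stop("duplicate class codes")
  if (anyDuplicated(classes$name)) stop("duplicate class names")
  if (any(classes$code <= 0L)) stop("class codes must be positive integers")
  if (!all(classes$compartment %in% c("tissue", "cortex", "medulla")))
    stop("compartment must be one of 'tissue', 'cortex', 'medulla'")
  roots <- which(is.na(classes$parent))
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root class (parent = NA)")
  if (!all(stats::na.omit(classes$parent) %in% classes$code))
    stop("parent codes must refer to declared classes")
  # acyclicity: walk up from every class, must reach the root
  for (i in seq_len(nrow(classes))) {
    seen <- integer(0)
    code <- classes$code[i]
    while (!is.na(code)) {
      if (code %in% seen) stop("containment relation contains a cycle")
      seen <- c(seen, code)
      code <- classes$parent[match(code, classes$code)]
    }
  }
  structure(classes, class = c("class_taxonomy", "data.frame"))
}

#' Default 20-class renal histology taxonomy
#'
#' The multilayer class set used for PAS-stained kidney section segmentation:
#' tissue split into cortex and medulla; cortical layers for tubular atrophy
#' (TA) clusters, the tubulointerstitium with proximal/distal tubules, the
#' glomerular area with its three subclasses (non-sclerosed, globally
#' sclerosed, empty Bowman capsule), and arteries-and-arterioles with
#' arteriolar hyalinosis, intimal thickening and arterial lumen; medullary
#' layers for interlobar arteries with their intimal thickening and lumen.
#'
#' Layers are not mutually exclusive: a child-class pixel also belongs to all
#' of its ancestors, and sibling layers at the same depth may overlap where the
#' anatomy does (e.g. tubular atrophy clusters lie within the
#' tubulointerstitium).
#'
#' @return A `class_taxonomy` with 20 classes coded 1 to 20.
#' @export
kidney_taxonomy <- function() {
  class_taxonomy(data.frame(
    code = 1:20,
    name = c(
      "Tissue",
      "Cortex",
      "Tubular atrophy cluster",
      "Cortex excluding arteries and atrophic tubules",
      "Tubulointerstitium",
      "Tubules",
      "Distal tubule",
      "Proximal tubule",
      "Glomerular area",
      "Globally sclerosed glomeruli",
      "Empty capsule",
      "Nonglobally sclerosed glomeruli",
      "Arteries and arterioles",
      "Arteriolar hyalinosis",
      "Intimal thickening",
      "Arterial lumen",
      "Medulla",
      "Interlobar arteries",
      "Intimal thickening (medullary)",
      "Artery lumen"),
    parent = c(NA, 1L, 2L, 2L, 2L, 5L, 6L, 6L, 2L, 9L,
               9L, 9L, 2L, 13L, 13L, 13L, 1L, 17L, 18L, 18L),
    compartment = c("tissue", rep("cortex", 15), rep("medulla", 4))
  ))
}

# canonical class names, used throughout the package
.cls <- list(
  tissue        = "Tissue",
  cortex        = "Cortex",
  ta            = "Tubular atrophy cluster",
  cortex_excl   = "Cortex excluding arteries and atrophic tubules",
  ti            = "Tubulointerstitium",
  tubules       = "Tubules",
  distal        = "Distal tubule",
  proximal      = "Proximal tubule",
  glom          = "Glomerular area",
  gsg           = "Globally sclerosed glomeruli",
  empty_capsule = "Empty capsule",
  nsg           = "Nonglobally sclerosed glomeruli",
  vessels       = "Arteries and arterioles",
  ah            = "Arteriolar hyalinosis",
  intima        = "Intimal thickening",
  lumen         = "Arterial lumen",
  medulla       = "Medulla",
  interlobar    = "Interlobar arteries",
  intima_med    = "Intimal thickening (medullary)",
  lumen_med     = "Artery lumen")

#' Resolve a class reference to its row in a taxonomy
#'
#' @param taxonomy a `class_taxonomy`.
#' @param class class name (character) or integer code.
#' @return One-row data.frame for the class.
#' @keywords internal
taxonomy_class <- function(taxonomy, class) {
  i <- if (is.character(class)) match(class, taxonomy$name)
       else match(as.integer(class), taxonomy$code)
  if (is.na(i)) stop("unknown class in taxonomy: ", class)
  taxonomy[i, , drop = FALSE]
}

#' Containment pairs of a taxonomy
#'
#' @param taxonomy a `class_taxonomy`.
#' @return data.frame with columns `child`, `parent` (class names).
#' @export
taxonomy_containment <- function(taxonomy) {
  has_parent <- !is.na(taxonomy$parent)
  data.frame(
    child = taxonomy$name[has_parent],
    parent = taxonomy$name[match(taxonomy$parent[has_parent], taxonomy$code)])
}

#' @export
print.class_taxonomy <- function(x, ...) {
  cat("<class_taxonomy> ", nrow(x), " classes\n", sep = "")
  parent_name <- ifelse(is.na(x$parent), "-",
                        x$name[match(x$parent, x$code)])
  print(data.frame(code = x$code, name = x$name, parent = parent_name,
                   compartment = x$compartment), row.names = FALSE)
  invisible(x)
}
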