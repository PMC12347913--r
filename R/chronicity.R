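# ordinal banding and the two 0-12 chronicity scores

#' Banding specification for one measure
#'
#' Three ascending cut points split a measure into scores 0-3. Two boundary
#' rules reproduce the printed conventions:
#' `"upper_inclusive"` gives bands `[0, c1]`, `(c1, c2]`, `(c2, c3]`,
#' `(c3, Inf)` (used for TA focus density, AH area and cortex per
#' glomerulus, whose printed bands close at the upper edge, e.g. TA density
#' `0: <= 5, 1: 6-10, 2: 11-20, 3: > 20` per mm2); `"left_closed"` gives
#' `[0, c1)`, `[c1, c2)`, `[c2, c3]`, `(c3, Inf)` (used for %GSG and %ITA,
#' printed `< 10%, 10%-25%, 26%-50%, > 50%`; the half-open reading assigns
#' continuous values in (25, 26) to band 1).
#'
#' @param measure measure name the bands apply to.
#' @param cuts three strictly ascending cut points.
#' @param rule boundary rule, see above.
#' @return A `band_spec`.
#' @export
band_spec <- function(measure, cuts, rule = c("upper_inclusive",
                                              "left_closed")) {
  rule <- match.arg(rule)
  stopifnot(length(cuts) == 3)
  if (any(diff(cuts) <= 0)) stop("cut points must be strictly ascending")
  structure(list(measure = measure, cuts = as.numeric(cuts), rule = rule),
            class = "band_spec")
}

#' Default band specifications of the chronicity scores
#'
#' %GSG and %ITA use the commonly used glomerulosclerosis/fibrosis thresholds
#' (<10%, 10%-25%, 26%-50%, >50%); TA focus density, mean AH lesion area and
#' cortex per glomerulus use a-priori cut points (5/10/20 foci per mm2,
#' 500/750/1000 um2, 0.075/0.125/0.175 mm3).
#'
#' @return Named list of [band_spec()]s: `pct_gsg`,
#'   `pct_ita_per_tubulointerstitial`, `ta_foci_density_per_mm2`,
#'   `mean_ah_area_um2`, `cortex_per_glomerulus_mm3`.
#' @export
chronicity_bands <- function() {
  list(
    pct_gsg = band_spec("pct_gsg", c(10, 26, 50), "left_closed"),
    pct_ita_per_tubulointerstitial =
      band_spec("pct_ita_per_tubulointerstitial", c(10, 26, 50),
                "left_closed"),
    ta_foci_density_per_mm2 =
      band_spec("ta_foci_density_per_mm2", c(5, 10, 20), "upper_inclusive"),
    mean_ah_area_um2 =
      band_spec("mean_ah_area_um2", c(500, 750, 1000), "upper_inclusive"),
    cortex_per_glomerulus_mm3 =
      band_spec("cortex_per_glomerulus_mm3", c(0.075, 0.125, 0.175),
                "upper_inclusive"))
}

#' Band score of a measure value
#'
#' @param value measure value (>= 0), or `NA`.
#' @param spec a [band_spec()].
#' @return Integer score 0-3, or `NA` for a missing value.
#' @export
band_score <- function(value, spec) {
  stopifnot(inherits(spec, "band_spec"))
  if (is.na(value)) return(NA_integer_)
  stopifnot(value >= 0)
  cuts <- spec$cuts
  if (spec$rule == "upper_inclusive") {
    if (value <= cuts[1]) 0L
    else if (value <= cuts[2]) 1L
    else if (value <= cuts[3]) 2L
    else 3L
  } else {
    if (value < cuts[1]) 0L
    else if (value < cuts[2]) 1L
    else if (value <= cuts[3]) 2L
    else 3L
  }
}

.component_scores <- function(result, bands) {
  get_val <- function(nm) {
    v <- if (is.list(result)) result[[nm]] else result[nm]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  vapply(names(bands), function(nm) band_score(get_val(nm), bands[[nm]]),
         integer(1))
}

.sum_score <- function(scores, missing_policy) {
  if (anyNA(scores)) {
    if (missing_policy == "zero") return(sum(scores, na.rm = TRUE))
    return(NA_integer_)
  }
  sum(scores)
}

#' Nephrosclerosis chronicity score (0-12)
#'
#' Sum of four 0-3 band scores: %GSG, %ITA, TA focus density and mean AH
#' lesion area.
#'
#' @param result a [quantify()] result, or any list/named vector carrying the
#'   measure fields.
#' @param bands band specifications (default [chronicity_bands()]).
#' @param missing_policy `"propagate"` (default: any missing component makes
#'   the total missing, with the reason recorded) or `"zero"` (missing
#'   components score 0).
#' @return A `chronicity_score` with `$components` (named 0-3 scores),
#'   `$total` (0-12 or `NA`) and `$missing_policy`.
#' @export
nephrosclerosis_score <- function(result, bands = chronicity_bands(),
                                  missing_policy = c("propagate", "zero")) {
  missing_policy <- match.arg(missing_policy)
  use <- c("pct_gsg", "pct_ita_per_tubulointerstitial",
           "ta_foci_density_per_mm2", "mean_ah_area_um2")
  scores <- .component_scores(result, bands[use])
  structure(list(score = "nephrosclerosis", components = scores,
                 total = .sum_score(scores, missing_policy),
                 missing_policy = missing_policy),
            class = "chronicity_score")
}

#' Nephron hypertrophy and nephrosclerosis chronicity score (0-12)
#'
#' Same construction as [nephrosclerosis_score()] with the %ITA component
#' replaced by cortex per glomerulus.
#'
#' @inheritParams nephrosclerosis_score
#' @return A `chronicity_score`.
#' @export
hypertrophy_score <- function(result, bands = chronicity_bands(),
                              missing_policy = c("propagate", "zero")) {
  missing_policy <- match.arg(missing_policy)
  use <- c("cortex_per_glomerulus_mm3", "pct_gsg",
           "ta_foci_density_per_mm2", "mean_ah_area_um2")
  scores <- .component_scores(result, bands[use])
  structure(list(score = "hypertrophy_nephrosclerosis", components = scores,
                 total = .sum_score(scores, missing_policy),
                 missing_policy = missing_policy),
            class = "chronicity_score")
}

#' @export
print.chronicity_score <- function(x, ...) {
  cat(sprintf("<chronicity_score> %s\n", x$score))
  for (nm in names(x$components))
    cat(sprintf("  %-34s %s\n", nm,
                ifelse(is.na(x$components[nm]), "missing",
                       x$components[nm])))
  cat(sprintf("  total (0-12): %s\n",
              if (is.na(x$total)) paste0("missing (policy ",
                                         x$missing_policy, ")") else x$total))
  invisible(x)
}

#' Patient report against donor reference limits
#'
#' Compares a patient's measures with upper reference limits derived from a
#' reference cohort (living kidney donors): per measure, the patient value,
#' the reference limit (a percentile of the reference distribution, default
#' the 95th), and an out-of-range flag.
#'
#' @param result a [quantify()] result (or list/named vector of measures).
#' @param reference data.frame of reference-cohort measures, one row per
#'   section, columns named like the measures; at least 20 non-missing
#'   observations per reported measure.
#' @param measures measures to report (default: all measure columns shared by
#'   `result` and `reference`).
#' @param probs reference-limit percentile (default 0.95).
#' @return A `reference_report`: data.frame with `measure`, `value`,
#'   `upper_limit`, `flagged`, `note`; renders to text via `print()` and to
#'   JSON via [report_json()].
#' @export
reference_report <- function(result, reference, measures = NULL,
                             probs = 0.95) {
  stopifnot(is.data.frame(reference), probs > 0, probs < 1)
  vals <- if (inherits(result, "morphometry_result"))
    as.data.frame(result) else as.data.frame(as.list(result))
  if (is.null(measures))
    measures <- intersect(names(vals), names(reference))
  rows <- lapply(measures, function(nm) {
    v <- if (nm %in% names(vals)) vals[[nm]] else NA_real_
    ref <- if (nm %in% names(reference))
      reference[[nm]][!is.na(reference[[nm]])] else numeric(0)
    if (length(ref) < 20)
      return(data.frame(measure = nm, value = v, upper_limit = NA_real_,
                        flagged = NA,
                        note = "reference has fewer than 20 observations"))
    lim <- as.numeric(stats::quantile(ref, probs))
    data.frame(measure = nm, value = v, upper_limit = lim,
               flagged = !is.na(v) && v > lim, note = "")
  })
  structure(do.call(rbind, rows),
            probs = probs, class = c("reference_report", "data.frame"))
}

#' Serialize a reference report to JSON
#'
#' @param report a [reference_report()].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(reference_percentile = attr(report, "probs"),
                  measures = as.data.frame(report))
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            na = "null"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                             na = "null"))
}

#' @export
print.reference_report <- function(x, ...) {
  cat(sprintf("<reference_report> upper limit = %g percentile of reference\n",
              100 * attr(x, "probs")))
  for (i in seq_len(nrow(x))) {
    mark <- if (isTRUE(x$flagged[i])) " *" else ""
    lim <- if (is.na(x$upper_limit[i])) x$note[i]
           else format(x$upper_limit[i], digits = 4)
    cat(sprintf("  %-34s %-12s (limit %s)%s\n", x$measure[i],
                format(x$value[i], digits = 4), lim, mark))
  }
  invisible(x)
}
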