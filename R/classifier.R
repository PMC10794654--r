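# Topography class assignment from the optometrist grading rules:
#   Class I:   0 mm <= decentration <= 1 mm and EDCR > 3/4
#   Class II:  0 mm <= decentration <= 1 mm and 1/4 <= EDCR <= 3/4
#   Class III: decentration > 1 mm
#   Class IV:  decentration <= 0.5 mm and EDCR < 1/4
# The rules as stated leave decentration in (0.5, 1] with EDCR < 1/4
# unassigned; such inputs map to "UNCLASSIFIED" rather than silently to a
# neighbouring class.

topo_levels <- c("I", "II", "III", "IV", "UNCLASSIFIED")

classify_one <- function(d, e) {
  if (d > 1) return(c("III", "decentration > 1 mm"))
  if (e > 3 / 4) return(c("I", "decentration <= 1 mm and EDCR > 3/4"))
  if (e >= 1 / 4) return(c("II", "decentration <= 1 mm and 1/4 <= EDCR <= 3/4"))
  if (d <= 0.5) return(c("IV", "decentration <= 0.5 mm and EDCR < 1/4"))
  c("UNCLASSIFIED", "no rule: decentration in (0.5, 1] mm with EDCR < 1/4")
}

#' Classify a corneal topography from its indicators
#'
#' Applies the grading rules above, checking the distance rule (Class III)
#' first since it does not condition on EDCR. Class II's 1/4-3/4 band is
#' closed: EDCR exactly 3/4 or exactly 1/4 is Class II; decentration exactly
#' 1 mm is not Class III.
#'
#' @param ind an `indicator_set` (or any list with `decentration_mm` and
#'   `edcr`).
#' @return factor of length 1 with levels I, II, III, IV, UNCLASSIFIED and an
#'   attribute `rule_fired` describing the matched rule.
#' @export
classify <- function(ind) {
  d <- ind$decentration_mm
  e <- ind$edcr
  if (!is.finite(d) || d < 0) stop("decentration_mm must be a nonnegative number")
  if (!is.finite(e) || e < 0 || e > 1) stop("edcr must lie in [0, 1]")
  r <- classify_one(d, e)
  structure(factor(r[1], levels = topo_levels), rule_fired = r[2])
}

#' Vectorised rule evaluation over (decentration, EDCR) pairs
#'
#' @param decentration_mm,edcr equal-length numeric vectors.
#' @return character vector of class labels.
#' @export
classify_rules <- function(decentration_mm, edcr) {
  stopifnot(length(decentration_mm) == length(edcr),
            all(decentration_mm >= 0), all(edcr >= 0 & edcr <= 1))
  mapply(function(d, e) classify_one(d, e)[1], decentration_mm, edcr)
}

#' JSON grading report for one indicator set
#'
#' @param ind an `indicator_set`.
#' @return a JSON string with the class, both indicators and the rule that
#'   fired.
#' @export
classify_report <- function(ind) {
  cl <- classify(ind)
  jsonlite::toJSON(list(class = as.character(cl),
                        decentration_mm = ind$decentration_mm,
                        edcr = ind$edcr,
                        rule_fired = attr(cl, "rule_fired")),
                   auto_unbox = TRUE, digits = NA)
}

#' Batch classification accuracy against reference labels
#'
#' @param cases list of `indicator_set`s (or `NA` entries for ungradable
#'   cases, which count as wrong against any label).
#' @param truth character vector of reference class labels, same length.
#' @return list with `accuracy` (overall), `per_class` data.frame (reference
#'   label, sample count, predicted count, accuracy within the label) and
#'   `predicted` labels.
#' @export
classify_batch <- function(cases, truth) {
  if (length(cases) != length(truth)) stop("cases and truth differ in length")
  pred <- vapply(cases, function(cs) {
    if (length(cs) == 1L && is.na(cs)) NA_character_
    else as.character(classify(cs))
  }, "")
  ok <- !is.na(pred) & pred == truth
  lv <- topo_levels[topo_levels %in% c(truth, pred)]
  per <- data.frame(class = lv,
                    n_samples = vapply(lv, function(l) sum(truth == l), 0L),
                    n_predicted = vapply(lv, function(l) sum(pred == l, na.rm = TRUE), 0L),
                    accuracy = vapply(lv, function(l) {
                      n <- sum(truth == l)
                      if (n == 0L) NA_real_ else sum(ok & truth == l) / n
                    }, 0))
  list(accuracy = mean(ok), per_class = per, predicted = pred)
}
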