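# Medical indicators computed from binary region masks: connected-component
# denoising, bounding-box centers, decentration (Euclidean center distance at
# a fixed px/mm scale) and the effective defocusing contact range (EDCR), the
# fraction of the pupil boundary lying in the myopic defocus zone.

ungradable <- function(region, msg) {
  stop(structure(class = c("oktopo_ungradable", "error", "condition"),
                 list(message = msg, call = sys.call(-1), region = region)))
}

#' Keep only the largest connected component of a mask
#'
#' Post-segmentation denoising: every foreground component except the one of
#' maximal pixel area is zeroed. Equal-area ties are broken deterministically
#' in favour of the component whose minimal (row, col) pixel is
#' lexicographically smallest. An empty mask is returned unchanged.
#'
#' @param mask binary matrix.
#' @param connectivity pixel adjacency, 4 or 8 (default 8).
#' @return binary matrix of the same dimensions.
#' @export
largest_component <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- as_binary_matrix(mask)
  if (!any(m == 1L)) return(m)
  lab <- cpp_label_components(m, as.integer(connectivity))
  areas <- tabulate(lab[lab > 0L])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    keypos <- vapply(best, function(l) {
      px <- which(lab == l, arr.ind = TRUE)
      r0 <- min(px[, 1])
      c0 <- min(px[px[, 1] == r0, 2])
      r0 * (ncol(m) + 1) + c0
    }, 0)
    best <- best[which.min(keypos)]
  }
  matrix(as.integer(lab == best), nrow(m), ncol(m))
}

#' Locate a region's center via its circumscribed rectangle
#'
#' Detects the region's outer boundary, takes the axis-aligned bounding
#' rectangle of the foreground and returns its center. Coordinates are
#' x = column, y = row, 0-based, real-valued.
#'
#' @param mask binary matrix (apply [largest_component()] first for noisy
#'   segmentations).
#' @return list with `contour` (boundary pixels, ordered counter-clockwise by
#'   angle about the center; columns `x`, `y`), `bbox`
#'   (`x_min`,`y_min`,`x_max`,`y_max`) and `center_px` (`c(x, y)`).
#' @export
region_center <- function(mask) {
  m <- as_binary_matrix(mask)
  if (!any(m == 1L)) ungradable("region", "empty mask: region is ungradable")
  px <- which(m == 1L, arr.ind = TRUE)
  y <- px[, 1] - 1L; x <- px[, 2] - 1L
  bbox <- c(x_min = min(x), y_min = min(y), x_max = max(x), y_max = max(y))
  center <- c(x = unname((bbox["x_min"] + bbox["x_max"]) / 2),
              y = unname((bbox["y_min"] + bbox["y_max"]) / 2))
  b <- boundary_4n(m)
  bp <- which(b == 1L, arr.ind = TRUE)
  bx <- bp[, 2] - 1L; by <- bp[, 1] - 1L
  ord <- order(atan2(by - center["y"], bx - center["x"]), bx, by)
  list(contour = cbind(x = bx[ord], y = by[ord]), bbox = bbox, center_px = center)
}

#' Decentration between the pupil and treatment-zone centers
#'
#' Euclidean distance between the two region centers in pixels, converted to
#' millimetres by the topographer's scale (1 mm = 50 px by default).
#'
#' @param pupil_geom,tz_geom results of [region_center()].
#' @param px_per_mm pixels per millimetre.
#' @return list `decentration_px`, `decentration_mm`.
#' @export
decentration <- function(pupil_geom, tz_geom, px_per_mm = 50) {
  stopifnot(px_per_mm > 0)
  d <- sqrt(sum((pupil_geom$center_px - tz_geom$center_px)^2))
  list(decentration_px = d, decentration_mm = d / px_per_mm)
}

#' Defocus zone of a pupil under a treatment zone
#'
#' The part of the pupil not covered by the treatment zone: the intersection
#' of the two regions subtracted from the pupil, returned as a 0/1 mask.
#'
#' @param pupil,tz binary masks of identical dimensions.
#' @return binary matrix.
#' @export
defocus_zone <- function(pupil, tz) {
  p <- as_binary_matrix(pupil)
  t_ <- as_binary_matrix(tz)
  if (!identical(dim(p), dim(t_))) stop("defocus_zone: mask dimensions differ")
  matrix(as.integer(p == 1L & t_ == 0L), nrow(p), ncol(p))
}

#' Four-neighbourhood boundary of a mask
#'
#' A foreground pixel is a boundary pixel iff at least one of its four
#' neighbours (up/down/left/right) is background or outside the image (the
#' image edge counts as background).
#'
#' @param mask binary matrix.
#' @return binary matrix marking the boundary pixels.
#' @export
boundary_4n <- function(mask) {
  m <- as_binary_matrix(mask)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  up <- pad[1:H, 2:(W + 1L)]
  dn <- pad[3:(H + 2L), 2:(W + 1L)]
  lf <- pad[2:(H + 1L), 1:W]
  rt <- pad[2:(H + 1L), 3:(W + 2L)]
  matrix(as.integer(m == 1L & (up == 0L | dn == 0L | lf == 0L | rt == 0L)), H, W)
}

#' Effective defocusing contact range (EDCR)
#'
#' EDCR = ECV / C, where C is the pupil boundary length (count of
#' four-neighbourhood boundary pixels) and ECV (effective contact value) is
#' the number of boundary pixels the pupil shares with the defocus zone
#' (pupil minus treatment zone). EDCR is the fraction of the pupil boundary
#' receiving myopic defocus; a treatment zone that fully covers the pupil
#' gives 0, one disjoint from it gives 1.
#'
#' @param pupil,tz binary masks of identical dimensions; pupil must be
#'   non-empty.
#' @return list `edcr`, `ecv_px`, `pupil_boundary_len_px`.
#' @export
edcr <- function(pupil, tz) {
  p <- as_binary_matrix(pupil)
  if (!any(p == 1L)) ungradable("pupil", "empty pupil mask: ungradable")
  pb <- boundary_4n(p)
  db <- boundary_4n(defocus_zone(p, tz))
  C <- sum(pb)
  ecv <- sum(pb == 1L & db == 1L)
  list(edcr = ecv / C, ecv_px = ecv, pupil_boundary_len_px = C)
}

#' Compute the full indicator set from a pair of masks
#'
#' Denoises each mask with [largest_component()], locates both centers,
#' computes decentration and EDCR, and assembles an indicator set. If either
#' region is empty after denoising the image is ungradable and an error of
#' class `oktopo_ungradable` (carrying the failing region) is signalled.
#'
#' @param pupil,tz binary masks of identical dimensions.
#' @param px_per_mm pixels per millimetre (default 50).
#' @return an `indicator_set` list: `decentration_px`, `decentration_mm`,
#'   `edcr`, `ecv_px`, `pupil_boundary_len_px`, `px_per_mm`.
#' @export
compute_indicators <- function(pupil, tz, px_per_mm = 50) {
  p <- as_binary_matrix(pupil)
  t_ <- as_binary_matrix(tz)
  if (!identical(dim(p), dim(t_))) stop("compute_indicators: mask dimensions differ")
  p <- largest_component(p)
  t_ <- largest_component(t_)
  if (!any(p == 1L)) ungradable("pupil", "pupil region empty after denoising")
  if (!any(t_ == 1L)) ungradable("treatment_zone", "treatment_zone region empty after denoising")
  dec <- decentration(region_center(p), region_center(t_), px_per_mm)
  ed <- edcr(p, t_)
  structure(c(dec, ed, list(px_per_mm = px_per_mm)), class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("decentration %.2f px = %.3f mm | EDCR %.3f (ECV %d / C %d)\n",
              x$decentration_px, x$decentration_mm, x$edcr,
              x$ecv_px, x$pupil_boundary_len_px))
  invisible(x)
}

#' Serialise an indicator set to JSON
#'
#' @param ind an `indicator_set`.
#' @return a JSON string.
#' @export
indicators_json <- function(ind) {
  jsonlite::toJSON(unclass(ind), auto_unbox = TRUE, digits = NA)
}
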