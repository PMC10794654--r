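test_that("largest_component removes speckles and keeps single blobs intact", {
  m <- disk(64, 30, 30, 12)
  expect_identical(largest_component(m), m)
  noisy <- m
  noisy[2, 2] <- 1L; noisy[3, 2] <- 1L; noisy[60, 60] <- 1L
  expect_identical(largest_component(noisy), m)
  expect_identical(largest_component(matrix(0L, 8, 8)), matrix(0L, 8, 8))
})

test_that("largest_component breaks equal-area ties by smallest (row, col)", {
  m <- matrix(0L, 10, 10)
  m[7:8, 2:3] <- 1L   # area 4, top-left pixel (row 7, col 2)
  m[2:3, 6:7] <- 1L   # area 4, top-left pixel (row 2, col 6)
  kept <- largest_component(m)
  expect_equal(sum(kept), 4)
  expect_equal(kept[2, 6], 1L)
  expect_equal(kept[7, 2], 0L)
})

test_that("largest_component honours the connectivity argument", {
  m <- matrix(0L, 8, 8)
  m[2:3, 2:3] <- 1L
  m[4, 4] <- 1L  # diagonal neighbour of the blob corner
  expect_equal(sum(largest_component(m, connectivity = 8)), 5)
  expect_equal(sum(largest_component(m, connectivity = 4)), 4)
})

test_that("region_center returns the circumscribed-rectangle centre", {
  d <- disk(224, 112, 112, 30)
  g <- region_center(d)
  expect_lt(max(abs(g$center_px - c(112, 112))), 0.5 + 1e-9)
  # axis-aligned rectangle spanning rows 10-20, cols 30-50 (0-based)
  rect <- matrix(0L, 64, 64)
  rect[11:21, 31:51] <- 1L
  g2 <- region_center(rect)
  expect_equal(unname(g2$center_px), c(40, 15))
  expect_equal(unname(g2$bbox), c(30, 10, 50, 20))
  expect_error(region_center(matrix(0L, 8, 8)), class = "oktopo_ungradable")
})

test_that("region_center contour is the ordered outer boundary", {
  d <- disk(64, 30, 30, 10)
  g <- region_center(d)
  expect_equal(nrow(g$contour), sum(boundary_4n(d)))
  ang <- atan2(g$contour[, "y"] - g$center_px["y"],
               g$contour[, "x"] - g$center_px["x"])
  expect_true(all(diff(ang) >= 0))
})

test_that("decentration is the Euclidean centre distance at 50 px/mm", {
  gp <- list(center_px = c(x = 100, y = 100))
  gt <- list(center_px = c(x = 130, y = 140))
  d <- decentration(gp, gt)
  expect_equal(d$decentration_px, 50)
  expect_equal(d$decentration_mm, 1.0)
  expect_equal(decentration(gp, gp)$decentration_mm, 0)
  d2 <- decentration(list(center_px = c(x = 0, y = 0)),
                     list(center_px = c(x = 25, y = 0)))
  expect_equal(d2$decentration_px, 25)
  expect_equal(d2$decentration_mm, 0.5)
  d3 <- decentration(gp, gt, px_per_mm = 25)
  expect_equal(d3$decentration_mm, 2.0)
})

test_that("defocus_zone is pupil minus its intersection with the treatment zone", {
  p <- disk(64, 30, 30, 10)
  big <- disk(64, 30, 30, 20)
  expect_equal(sum(defocus_zone(p, big)), 0)
  far <- disk(64, 55, 55, 5)
  expect_identical(defocus_zone(p, far), p)
  half <- matrix(0L, 64, 64); half[, 1:30] <- 1L
  dz <- defocus_zone(p, half)
  expect_equal(sum(dz), sum(p) - sum(p == 1L & half == 1L))
  expect_true(all(dz %in% c(0L, 1L)))
  expect_error(defocus_zone(p, matrix(0L, 32, 32)), "dimensions")
})

test_that("boundary_4n matches hand-enumerated cases and the edge convention", {
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  b <- boundary_4n(sq)
  expect_equal(sum(b), 8)
  expect_equal(b[3, 3], 0L)
  one <- matrix(0L, 4, 4); one[2, 3] <- 1L
  expect_identical(boundary_4n(one), one)
  full <- matrix(1L, 6, 7)
  bf <- boundary_4n(full)
  expect_equal(sum(bf), 2 * 6 + 2 * 7 - 4)
  expect_equal(bf[3, 4], 0L)
})

test_that("edcr handles containment and disjoint treatment zones exactly", {
  p <- disk(128, 60, 60, 25)
  expect_equal(edcr(p, disk(128, 60, 60, 40))$edcr, 0)
  far <- disk(128, 110, 110, 10)
  r <- edcr(p, far)
  expect_equal(r$edcr, 1)
  expect_equal(r$ecv_px, r$pupil_boundary_len_px)
  expect_error(edcr(matrix(0L, 16, 16), matrix(0L, 16, 16)),
               class = "oktopo_ungradable")
})

test_that("edcr agrees exactly with the brute-force pixel oracle", {
  set.seed(101)
  for (i in 1:40) {
    size <- sample(24:64, 1)
    p <- disk(size, runif(1, 8, size - 9), runif(1, 8, size - 9), runif(1, 4, 9))
    t_ <- disk(size, runif(1, 4, size - 5), runif(1, 4, size - 5), runif(1, 3, 12))
    if (!any(p == 1L)) next
    got <- edcr(p, t_)
    want <- bf_edcr(p, t_)
    expect_identical(got, want)
  }
})

test_that("edcr tracks the analytic arc fraction for large pupils", {
  for (e_target in c(0.25, 0.5, 0.75)) {
    rp <- 44; d <- 30
    rt <- sqrt(d^2 + rp^2 - 2 * d * rp * cos(pi * (1 - e_target)))
    p <- disk(224, 90, 112, rp)
    t_ <- disk(224, 90 + d, 112, rt)
    expect_lt(abs(edcr(p, t_)$edcr - e_target), 0.05)
  }
})

test_that("EDCR decreases monotonically as a concentric treatment zone grows", {
  p <- disk(160, 80, 70, 30)
  vals <- vapply(seq(8, 110, by = 6),
                 function(rt) edcr(p, disk(160, 86, 70, rt))$edcr, 0)
  expect_true(all(diff(vals) <= 1e-12))
  expect_equal(vals[1], 1)
  expect_equal(vals[length(vals)], 0)
})

test_that("decentration is invariant under rigid motion of both masks", {
  p <- disk(128, 50, 60, 18)
  t_ <- disk(128, 72, 48, 24)
  base <- compute_indicators(p, t_)
  shift <- function(m, dy, dx) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  tr <- compute_indicators(shift(p, 9, 14), shift(t_, 9, 14))
  expect_equal(tr$decentration_px, base$decentration_px, tolerance = 1e-12)
  rot <- compute_indicators(t(p)[ncol(p):1, ], t(t_)[ncol(t_):1, ])
  expect_equal(rot$decentration_px, base$decentration_px, tolerance = 1e-12)
  expect_equal(tr$edcr, base$edcr, tolerance = 1e-12)
})

test_that("compute_indicators denoises, errors on empty regions, and matches truth", {
  cs <- generate_dataset(4, seed = 30)[[2]]
  ind <- compute_indicators(cs$pupil_mask, cs$tz_mask, cs$params$px_per_mm)
  expect_lt(abs(ind$decentration_px - cs$true_indicators$decentration_px), 1)
  expect_lt(abs(ind$edcr - cs$true_indicators$edcr), 0.05)
  noisy <- unclass(cs$pupil_mask)
  noisy[2, 2] <- 1L; noisy[2, 3] <- 1L
  ind2 <- compute_indicators(noisy, cs$tz_mask, cs$params$px_per_mm)
  expect_equal(ind2$edcr, ind$edcr)
  expect_equal(ind2$decentration_px, ind$decentration_px)
  err <- tryCatch(compute_indicators(cs$pupil_mask,
                                     matrix(0L, nrow(cs$tz_mask), ncol(cs$tz_mask))),
                  oktopo_ungradable = function(e) e)
  expect_s3_class(err, "oktopo_ungradable")
  expect_equal(err$region, "treatment_zone")
})
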