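# Shared fixtures, built in code.

# Independent disk rasterisation (kept separate from the package's internal
# helper on purpose: tests construct geometry by hand).
disk <- function(size, cx, cy, r) {
  m <- matrix(0L, size, size)
  for (row in seq_len(size)) {
    dy2 <- (row - 1 - cy)^2
    cols <- which((seq_len(size) - 1 - cx)^2 + dy2 <= r^2)
    m[row, cols] <- 1L
  }
  m
}

# Brute-force EDCR oracle, written as plain loops straight from the
# definition: for every pupil boundary pixel (a foreground pixel with a
# 4-neighbour that is background or off-image), test membership in the
# defocus-zone mask and defocus-zone boundary status.
bf_is_boundary <- function(m, r, c) {
  if (m[r, c] == 0L) return(FALSE)
  H <- nrow(m); W <- ncol(m)
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    rr <- r + d[1]; cc <- c + d[2]
    if (rr < 1 || rr > H || cc < 1 || cc > W || m[rr, cc] == 0L) return(TRUE)
  }
  FALSE
}

bf_edcr <- function(pupil, tz) {
  dz <- matrix(as.integer(pupil == 1L & tz == 0L), nrow(pupil), ncol(pupil))
  C <- 0L; ecv <- 0L
  for (r in seq_len(nrow(pupil))) for (c in seq_len(ncol(pupil))) {
    if (bf_is_boundary(pupil, r, c)) {
      C <- C + 1L
      if (dz[r, c] == 1L && bf_is_boundary(dz, r, c)) ecv <- ecv + 1L
    }
  }
  list(edcr = ecv / C, ecv_px = ecv, pupil_boundary_len_px = C)
}

# Small, fast synthetic cases for training smoke tests: 160 px images at
# 32 px/mm, regions occupying a default-like fraction of the frame, classes
# restricted to those that fit the reduced canvas.
tiny_ranges <- function() {
  list(image_size_px = 160L, px_per_mm = 32, pupil_radius_px = c(24, 36),
       center_jitter_px = 4, ring_width_px = c(4, 8),
       noise_sd = c(0.01, 0.03), min_crossing_speed = 4,
       min_tz_radius_px = 12, classes = c("I", "II", "IV"),
       class_regions = list(
         I  = list(d = c(0.15, 0.80), e = c(0.80, 0.95)),
         II = list(d = c(0.10, 0.80), e = c(0.45, 0.65)),
         IV = list(d = c(0.05, 0.40), e = c(0.00, 0.15))))
}

tiny_dataset <- function(n, seed = 1L) {
  generate_dataset(n, tiny_ranges(), seed = seed)
}
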