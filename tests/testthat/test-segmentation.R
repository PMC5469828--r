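# brute-force Otsu oracle: sweep all candidate cuts, maximize the
# between-class variance directly
otsu_bruteforce <- function(x) {
  xs <- sort(unique(as.numeric(x)))
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  bcv <- vapply(cuts, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) / length(x)^2 * (mean(hi) - mean(lo))^2
  }, 1)
  cuts[which.max(bcv)]
}

test_that("otsu matches a brute-force between-class-variance sweep", {
  set.seed(10)
  x <- array(c(rnorm(9000, 10, 1), rnorm(1000, 100, 5)), c(100, 10, 10))
  m <- threshold_mask(x, "otsu")
  thr <- attr(m, "threshold")
  oracle <- otsu_bruteforce(x)
  # both thresholds isolate the same (high) class
  expect_identical(unclass(m)[TRUE], (x > oracle)[TRUE])
  # bimodal two-level volume: the high level is isolated exactly
  y <- array(c(rep(10, 90), rep(100, 10)), c(10, 5, 2))
  my <- threshold_mask(y, "otsu")
  expect_identical(unclass(my)[TRUE], (y == 100)[TRUE])
})

test_that("quantile and fixed thresholds honour their contracts", {
  x <- array(runif(1000), c(10, 10, 10))
  expect_false(any(threshold_mask(x, "quantile", 1.0)))  # empty mask
  expect_true(all(threshold_mask(x, "fixed", min(x) - 1))) # full mask
  expect_error(threshold_mask(x, "fixed"), "requires")
  expect_error(threshold_mask(x, "quantile"), "requires")
})

test_that("hysteresis keeps dim response connected to strong seeds only", {
  x <- array(0, c(5, 5, 20))
  x[3, 3, 2:10] <- c(rep(100, 4), rep(30, 5))   # strong tube with dim tail
  x[3, 3, 15:18] <- 30                          # isolated dim fragment
  m <- threshold_mask(x, "hysteresis", value = 0.2)
  expect_true(all(m[3, 3, 2:10]))
  expect_false(any(m[3, 3, 15:18]))
})

test_that("a solid straight cylinder skeletonizes to one axial chain", {
  a <- digital_tube()
  sk <- skeletonize3d(a, 0.2)
  expect_equal(length(sk$chains), 1L)
  expect_equal(sum(sk$nodes$type == "junction"), 0L)
  expect_equal(sk$total_length_um, 18.2, tolerance = 0.05) # +/- ~2 voxels
})

test_that("an empty mask gives an empty graph", {
  sk <- skeletonize3d(array(FALSE, c(5, 5, 5)), 0.2)
  expect_equal(sk$total_length_um, 0)
  expect_equal(length(sk$chains), 0L)
})

test_that("a Y-shaped union yields one junction and three endpoints", {
  b <- array(FALSE, c(30, 40, 40))
  pl <- function(p1, p2) {
    t <- seq(0, 1, length.out = 200)
    cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]),
          p1[3] + t * (p2[3] - p1[3]))
  }
  ctr <- c(3, 4, 4)
  pts <- rbind(pl(ctr, c(3, 4, 7.5)), pl(ctr, c(3, 1, 1)), pl(ctr, c(3, 7, 1)))
  for (k in seq_len(nrow(pts))) {
    ii <- round(pts[k, ] / 0.2 + 0.5)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      jj <- ii + c(dz, dy, dx)
      if (all(jj >= 1) && all(jj <= c(30, 40, 40))) b[jj[1], jj[2], jj[3]] <- TRUE
    }
  }
  sk <- skeletonize3d(b, 0.2)
  expect_equal(sum(sk$nodes$type == "junction"), 1L)
  expect_equal(sum(sk$nodes$type == "endpoint"), 3L)
})

test_that("thinning preserves components and Euler characteristic", {
  # a loop (one cycle) plus a separate straight tube (two components)
  pl <- function(p1, p2) {
    t <- seq(0, 1, length.out = 300)
    cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]),
          p1[3] + t * (p2[3] - p1[3]))
  }
  l <- array(FALSE, c(12, 50, 50))
  seg <- rbind(pl(c(1.5, 2, 2), c(1.5, 2, 8)), pl(c(1.5, 2, 8), c(1.5, 8, 8)),
               pl(c(1.5, 8, 8), c(1.5, 8, 2)), pl(c(1.5, 8, 2), c(1.5, 2, 2)))
  for (k in seq_len(nrow(seg))) {
    ii <- round(seg[k, ] / 0.2 + 0.5)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      jj <- ii + c(dz, dy, dx)
      if (all(jj >= 1) && all(jj <= c(12, 50, 50))) l[jj[1], jj[2], jj[3]] <- TRUE
    }
  }
  l[8:9, 25:27, 10:40] <- TRUE
  dist <- distance_transform(!l, rep(0.2, 3))
  sk <- array(thglcn:::.thin3d(as.logical(l), dim(l), as.numeric(dist)), dim(l))
  expect_equal(attr(label_components(sk, 26L), "n"),
               attr(label_components(l, 26L), "n"))
  expect_equal(thglcn:::euler_characteristic3(sk),
               thglcn:::euler_characteristic3(l))
  expect_true(all(l[sk])) # skeleton is a subset of the mask
})

test_that("anisotropic masks are resampled before thinning", {
  # tube along x with voxels twice as coarse axially
  a <- array(FALSE, c(12, 20, 50))
  a[6:7, 10:11, 3:47] <- TRUE
  sk <- skeletonize3d(a, c(0.4, 0.2, 0.2))
  expect_equal(length(sk$chains), 1L)
  expect_equal(sk$total_length_um, 9.0, tolerance = 0.1)
})

test_that("lacunae are recovered with little canalicular leakage", {
  set.seed(1)
  cans <- lapply(1:30, function(i) {
    p0 <- c(runif(1, 1, 11), runif(1, 2, 22), runif(1, 2, 22))
    d0 <- c(rnorm(1, 0, 0.2), rnorm(1, 1, 0.3), rnorm(1, 0, 0.5))
    d0 <- d0 / sqrt(sum(d0^2))
    list(polyline_um = rbind(p0 - 6 * d0, p0 + 6 * d0), diameter_um = 0.57)
  })
  spec <- phantom_spec(volume_size_um = c(12, 24, 24), voxel_size_um = 0.2,
                       lacunae = list(list(center_um = c(6.1, 12.2, 11.9),
                                           semi_axes_um = c(2.5, 1.5, 4.0))),
                       canaliculi = cans, thg_sbr_target = 3.4,
                       noise_peak_photons = 100, seed = 5)
  tr <- build_phantom(spec)
  psf <- std_psf()
  # fluorescence (lumen contrast): classic threshold/fill/open/close recipe
  fl <- render_fluorescence(tr, spec, psf)
  lmf <- segment_lacunae(fl)
  leak_f <- sum(lmf & tr$canalicular_mask & !tr$lacuna_mask) /
    sum(tr$canalicular_mask & !tr$lacuna_mask)
  expect_gte(sum(lmf & tr$lacuna_mask) / sum(tr$lacuna_mask), 0.8)
  expect_lt(leak_f, 0.01)
  # THG (interface contrast): dark-cavity recipe
  thg <- render_thg(tr, spec, psf)
  lmt <- segment_lacunae(thg)
  leak_t <- sum(lmt & tr$canalicular_mask & !tr$lacuna_mask) /
    sum(tr$canalicular_mask & !tr$lacuna_mask)
  expect_gte(sum(lmt & tr$lacuna_mask) / sum(tr$lacuna_mask), 0.8)
  expect_lt(leak_t, 0.02)
})

test_that("segment_lacunae handles empty and multi-lacuna cases", {
  spec0 <- tube_spec(size = c(8, 12, 12), noise = 100)
  tr0 <- build_phantom(spec0)
  fl0 <- render_fluorescence(tr0, spec0, std_psf())
  expect_false(any(segment_lacunae(fl0)))
  spec2 <- phantom_spec(volume_size_um = c(12, 12, 30),
                        lacunae = list(
                          list(center_um = c(6, 6, 7), semi_axes_um = c(2, 1.5, 3)),
                          list(center_um = c(6, 6, 22), semi_axes_um = c(2, 1.5, 3))),
                        noise_peak_photons = NULL, seed = 2)
  tr2 <- build_phantom(spec2)
  fl2 <- render_fluorescence(tr2, spec2, std_psf())
  m2 <- segment_lacunae(fl2)
  expect_equal(attr(label_components(m2, 26L), "n"), 2L)
})

test_that("an opening radius below the canalicular radius warns about leakage", {
  spec <- tube_spec(size = c(6, 8, 8), noise = NULL)
  tr <- build_phantom(spec)
  fl <- render_fluorescence(tr, spec, std_psf(), noise = FALSE)
  expect_warning(segment_lacunae(fl, opening_radius_um = 0.2), "leak")
})
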