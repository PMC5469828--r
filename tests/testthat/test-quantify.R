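test_that("two-edge measurement resolves an analytic double-Gaussian profile", {
  # intensity depends on y only: two unit Gaussians (sigma 0.15 um) at
  # +/- 0.285 um around y0 - a noise-free symmetric wall pair
  d <- c(10, 40, 10)
  y <- (seq_len(d[2]) - 0.5) * 0.2
  y0 <- 4.03
  g <- exp(-(y - y0 - 0.285)^2 / (2 * 0.15^2)) +
       exp(-(y - y0 + 0.285)^2 / (2 * 0.15^2))
  a <- aperm(array(rep(g, d[1] * d[3]), c(d[2], d[1], d[3])), c(2, 1, 3))
  vol <- lcn_volume(a, 0.2, "THG")
  m <- measure_diameter(vol, c(1.0, y0, 1.0), c(0, 0, 1), n_average = 1)
  expect_equal(m$method, "two_edge")
  expect_equal(m$diameter_um, 0.57, tolerance = 0.02)
})

test_that("diameters are recovered within 0.1 um and increase monotonically", {
  psf <- std_psf()
  est <- vapply(c(0.4, 0.57, 0.8, 1.0), function(D) {
    spec <- tube_spec(D = D)
    tr <- build_phantom(spec)
    v <- render_thg(tr, spec, psf, noise = FALSE)
    m <- measure_diameter(v, c(4.03, 5.07, 10), c(0, 0, 1))
    expect_equal(m$method, "two_edge")
    expect_lt(abs(m$diameter_um - D), 0.1)
    m$diameter_um
  }, 1)
  expect_true(all(diff(est) > 0))
})

test_that("sub-resolution tubes fall back to the FWHM measure", {
  spec <- tube_spec(D = 0.2)
  tr <- build_phantom(spec)
  v <- render_thg(tr, spec, std_psf(), noise = FALSE)
  m <- measure_diameter(v, c(4.03, 5.07, 10), c(0, 0, 1))
  expect_equal(m$method, "fwhm_fallback")
})

test_that("near-axial tangents and empty profiles are rejected", {
  v <- lcn_volume(array(5, c(10, 10, 10)), 0.2)
  m <- measure_diameter(v, c(1, 1, 1), c(1, 0.1, 0))
  expect_equal(m$method, "undefined")
  expect_match(m$reason, "optical axis")
  m2 <- measure_diameter(v, c(1, 1, 1), c(0, 0, 1))
  expect_equal(m2$method, "undefined") # constant profile: nothing above background
})

test_that("diameter sampling along a skeleton is seeded and homogeneous", {
  spec <- tube_spec(size = c(8, 10, 24))
  tr <- build_phantom(spec)
  psf <- std_psf()
  v <- render_thg(tr, spec, psf, noise = FALSE)
  dec <- richardson_lucy(v, psf, 10)
  vm <- threshold_mask(vesselness(dec)$data, "hysteresis")
  sk <- skeletonize3d(vm, 0.2)
  d1 <- diameter_distribution(v, sk, 40, seed = 5)
  d2 <- diameter_distribution(v, sk, 40, seed = 5)
  expect_identical(vapply(d1$measurements, `[[`, 1, "diameter_um"),
                   vapply(d2$measurements, `[[`, 1, "diameter_um"))
  # homogeneous truth: all defined, small spread
  expect_lt(d1$undefined_fraction, 0.05)
  expect_lt(d1$diameter_sd_um, 0.05)
  expect_lt(abs(d1$diameter_mean_um - 0.57), 0.1)
  d3 <- diameter_distribution(v, sk, 40, seed = 6)
  expect_false(identical(vapply(d1$measurements, function(m) m$position_um, numeric(3)),
                         vapply(d3$measurements, function(m) m$position_um, numeric(3))))
})

test_that("porosity fractions count voxels and integrate the cylinder model", {
  # 1000 lacuna voxels of (0.2 um)^3 in a (20 um)^3 volume -> exactly 0.001
  d <- c(100, 100, 100)
  m <- array(FALSE, d)
  m[1:10, 1:10, 1:10] <- TRUE
  pf <- porosity_fractions(m, empty_skeleton(d, rep(0.2, 3)), 0.57, 0.2)
  expect_identical(pf[["lacunar"]], 0.001)
  expect_identical(pf[["canalicular"]], 0)
  # skeleton length 100 um, D = 0.57, volume 50 000 um^3
  d2 <- c(40, 100, 100)
  sk <- empty_skeleton(d2, rep(0.5, 3))
  sk$chains <- list(cbind(rep(10, 201), rep(10, 201), seq(0, 100, by = 0.5)))
  pf2 <- porosity_fractions(array(FALSE, d2), sk, 0.57, 0.5)
  expect_equal(pf2[["canalicular"]], 100 * pi * 0.285^2 / 50000, tolerance = 1e-12)
  # linear in length, quadratic in diameter
  sk3 <- sk
  sk3$chains <- list(cbind(rep(10, 101), rep(10, 101), seq(0, 50, by = 0.5)))
  pf3 <- porosity_fractions(array(FALSE, d2), sk3, 0.57, 0.5)
  expect_equal(pf3[["canalicular"]], pf2[["canalicular"]] / 2, tolerance = 1e-12)
  pf4 <- porosity_fractions(array(FALSE, d2), sk, 2 * 0.57, 0.5)
  expect_equal(pf4[["canalicular"]], 4 * pf2[["canalicular"]], tolerance = 1e-12)
  # skeleton length inside the lacuna mask is excluded
  lm <- array(FALSE, d2); lm[, , 1:40] <- TRUE # first 20 um of the chain
  pf5 <- porosity_fractions(lm, sk, 0.57, 0.5)
  expect_equal(attr(pf5, "length_um"), 80, tolerance = 0.5)
})

test_that("signal-to-background matches the configured contrast", {
  spec <- dense_spec(size = c(10, 20, 20), seed = 13, noise = NULL)
  tr <- build_phantom(spec)
  psf <- std_psf()
  thg <- render_thg(tr, spec, psf, noise = FALSE)
  cls <- lapply(tr$centerlines, `[[`, "polyline_um")
  sbr <- signal_to_background(thg, cls, tr$pore_mask, 1.0)
  expect_equal(as.numeric(sbr), 3.4, tolerance = 0.1 * 3.4)
  # invariance under global multiplicative scaling
  thg2 <- thg; thg2$data <- thg$data * 12.3
  expect_equal(as.numeric(signal_to_background(thg2, cls, tr$pore_mask, 1.0)),
               as.numeric(sbr), tolerance = 1e-12)
})

test_that("constant images give unit SBR and CT contrast is inverted", {
  v <- lcn_volume(array(8, c(10, 20, 20)), 0.2, "THG")
  cls <- list(rbind(c(1, 2, 1), c(1, 2, 3.8)))
  sm <- array(FALSE, c(10, 20, 20)); sm[5:6, 9:11, 5:15] <- TRUE
  expect_equal(as.numeric(signal_to_background(v, cls, sm, 1.0)), 1)
  # CT-like: dark tube lumen on bright matrix, true contrast 1.4
  spec <- tube_spec(D = 1.0, size = c(8, 10, 20))
  tr <- build_phantom(spec)
  a <- array(140, tr$dims)
  a[tr$pore_mask] <- 100
  ct <- lcn_volume(thglcn:::gauss_smooth3(a, 0.15, rep(0.2, 3)), 0.2, "CT")
  cls2 <- lapply(tr$centerlines, `[[`, "polyline_um")
  expect_equal(as.numeric(signal_to_background(ct, cls2, tr$pore_mask, 1.0)),
               1.4, tolerance = 0.05)
  # empty background region fails informatively
  expect_error(signal_to_background(v, cls, array(TRUE, c(10, 20, 20)), 1.0),
               "background")
})

test_that("the resolution estimator recovers the blurring FWHM", {
  psf <- std_psf()
  a <- array(0, c(50, 50, 50))
  a[25, 25, 25] <- 1000 # point source
  v <- lcn_volume(conv_with_psf(a, psf), 0.2, "THG")
  res <- estimate_resolution(v, c(4.9, 4.9, 4.9))
  expect_equal(res[["fwhm_lateral_um"]], 0.35, tolerance = 0.05 * 0.35)
  expect_equal(res[["fwhm_axial_um"]], 1.35, tolerance = 0.05 * 1.35)
  # unblurred single voxel: sampling-limited floor
  v0 <- lcn_volume(a, 0.2, "THG")
  res0 <- estimate_resolution(v0, c(4.9, 4.9, 4.9))
  expect_lte(res0[["fwhm_lateral_um"]], 1.5 * 0.2)
  # known sigma = 0.2 um Gaussian -> FWHM = 0.471 um (2.355 sigma)
  x <- (seq_len(50) - 0.5) * 0.2
  g <- exp(-(x - 4.9)^2 / (2 * 0.2^2))
  va <- lcn_volume(aperm(array(rep(g, 2500), c(50, 50, 50)), c(2, 3, 1)), 0.2)
  resg <- estimate_resolution(va, c(4.9, 4.9, 4.9), line_axis = "y")
  expect_equal(resg[["fwhm_lateral_um"]], 2 * sqrt(2 * log(2)) * 0.2,
               tolerance = 0.02 * 0.471)
})

test_that("the lamellar period is read off the autocorrelation", {
  # pure sinusoid, period 5.6 um sampled at 0.2 um
  d <- c(5, 250, 10)
  y <- (seq_len(d[2]) - 0.5) * 0.2
  a <- aperm(array(rep(50 + 20 * sin(2 * pi * y / 5.6), d[1] * d[3]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  v <- lcn_volume(a, 0.2, "SHG")
  p <- lamellar_period(v, c(0.5, 1, 1), c(0, 1, 0), 45)
  expect_false(p$aperiodic)
  expect_equal(p$period_mean_um, 5.6, tolerance = 0.2 / 5.6)
  # constant profile -> aperiodic flag
  vc <- lcn_volume(array(30, c(5, 100, 5)), 0.2, "SHG")
  pc <- lamellar_period(vc, c(0.5, 1, 1), c(0, 1, 0), 15)
  expect_true(pc$aperiodic)
  # period 4.8 um + Poisson noise at SNR ~ 5
  set.seed(12)
  base <- 50 + 25 * sin(2 * pi * y / 4.8)
  an <- aperm(array(rpois(prod(d), rep(base, d[1] * d[3])), c(d[2], d[1], d[3])),
              c(2, 1, 3))
  vn <- lcn_volume(an, 0.2, "SHG")
  pn <- lamellar_period(vn, c(0.5, 1, 1), c(0, 1, 0), 45)
  expect_equal(pn$period_mean_um, 4.8, tolerance = 0.1 * 4.8)
})

test_that("the correlation coefficient obeys its identities", {
  set.seed(3)
  a <- array(runif(8000), c(20, 20, 20))
  expect_equal(image_correlation(a, a), 1, tolerance = 1e-15)
  expect_equal(image_correlation(a, 5 - 2 * a), -1, tolerance = 1e-12)
  # independent noise decorrelates as 1/sqrt(n)
  n <- 1e6
  x <- array(rnorm(n), c(100, 100, 100))
  y <- array(rnorm(n), c(100, 100, 100))
  expect_lt(abs(image_correlation(x, y)), 0.01)
  # invariant under affine rescaling of either input (sign flips with slope)
  c0 <- image_correlation(a, x[1:20, 1:20, 1:20])
  expect_equal(image_correlation(2 + 3 * a, x[1:20, 1:20, 1:20]), c0,
               tolerance = 1e-12)
  expect_equal(image_correlation(2 - 3 * a, x[1:20, 1:20, 1:20]), -c0,
               tolerance = 1e-12)
  # agrees with the standard sample correlation (independent route)
  expect_equal(image_correlation(a, x[1:20, 1:20, 1:20]),
               cor(as.numeric(a), as.numeric(x[1:20, 1:20, 1:20])),
               tolerance = 1e-12)
  expect_error(image_correlation(a, array(1, c(20, 20, 20))), "constant")
  expect_error(image_correlation(a, array(1, c(10, 20, 20))), "grid")
})
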