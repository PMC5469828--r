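gauss_tube_volume <- function(radius_um = 0.3, dims = c(30, 30, 60), voxel = 0.2) {
  # ideal bright cylinder with Gaussian cross-section along x
  zc <- (seq_len(dims[1]) - 0.5) * voxel
  yc <- (seq_len(dims[2]) - 0.5) * voxel
  cs <- exp(-outer((zc - 2.97)^2, (yc - 3.05)^2, "+") / (2 * radius_um^2))
  a <- array(rep(cs, dims[3]), dims)
  lcn_volume(a * 100, voxel, "THG")
}

test_that("a spatially uniform volume has identically zero response", {
  v <- lcn_volume(array(17, c(10, 10, 10)), 0.2)
  r <- vesselness(v)
  expect_true(all(r$data == 0))
})

test_that("tubes outrank planes and the matched scale wins", {
  vt <- gauss_tube_volume(0.3)
  params <- vesselness_params(scales_um = c(0.2, 0.3, 0.45, 0.68))
  rt <- vesselness(vt, params)
  axis_idx <- cbind(round(2.97 / 0.2 + 0.5), round(3.05 / 0.2 + 0.5), 10:50)
  tube_resp <- mean(rt$data[axis_idx])
  # per-scale responses peak at the scale nearest the radius
  per_scale <- vapply(params$scales_um, function(sg) {
    r1 <- vesselness(vt, vesselness_params(scales_um = sg, c = 20))
    mean(r1$data[axis_idx])
  }, 1)
  expect_equal(params$scales_um[which.max(per_scale)], 0.3)
  # bright plane of equal peak intensity: response at its centre is lower
  zc <- (seq_len(30) - 0.5) * 0.2
  pl <- array(rep(exp(-(zc - 2.97)^2 / (2 * 0.3^2)), 30 * 60), c(30, 30, 60)) * 100
  vp <- lcn_volume(pl, 0.2)
  rp <- vesselness(vp, params)
  plane_resp <- mean(rp$data[cbind(round(2.97 / 0.2 + 0.5), 5:25, 30)])
  expect_gt(tube_resp, plane_resp)
})

test_that("the dark-tube flag reproduces the bright response of the inverted image", {
  vt <- gauss_tube_volume(0.3)
  dark <- vt
  dark$data <- max(vt$data) - vt$data
  p_dark <- vesselness_params(bright_on_dark = FALSE)
  p_bright <- vesselness_params()
  r1 <- vesselness(dark, p_dark)
  r2 <- vesselness(lcn_volume(max(dark$data) - dark$data, 0.2), p_bright)
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("the response with automatic c is invariant under intensity scaling", {
  set.seed(6)
  spec <- tube_spec(size = c(6, 8, 10), noise = 80)
  tr <- build_phantom(spec)
  v <- render_thg(tr, spec, std_psf())
  r1 <- vesselness(v)
  v2 <- v
  v2$data <- v$data * 37.5
  r2 <- vesselness(v2)
  expect_lt(max(abs(r1$data - r2$data)) / max(max(r1$data), 1e-12), 1e-6)
})

test_that("degenerate inputs are handled per contract", {
  expect_error(vesselness(lcn_volume(array(1, c(3, 10, 10)), 0.2)), "5 voxels")
  expect_error(vesselness_params(scales_um = c(0.3, 0.2)), "sorted")
  expect_error(vesselness_params(alpha = 0), "alpha")
  expect_error(vesselness_params(c = -1), "c must be")
})
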