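test_that("empty geometry gives an empty pore mask and zero porosity", {
  spec <- phantom_spec(volume_size_um = c(5, 5, 5), noise_peak_photons = NULL)
  tr <- build_phantom(spec)
  expect_false(any(tr$pore_mask))
  expect_equal(unname(tr$porosity_fractions), c(0, 0, 0))
})

test_that("voxel-counted fractions match closed-form volumes", {
  # axis-aligned cylinder, D = 0.57 um, length 20 um in a 20^3 um^3 grid;
  # at 0.2 um voxels the radius is only 1.4 voxels, so the voxelization
  # tolerance is generous
  spec <- tube_spec(D = 0.57, size = c(20, 20, 20), center = c(10.07, 9.93))
  tr <- build_phantom(spec)
  analytic <- pi * 0.285^2 * 20 / 8000
  expect_lt(abs(mean(tr$canalicular_mask) - analytic) / analytic, 0.45)

  # ellipsoid with semi-axes (5, 2.5, 1.5) um (x, y, z) in the same grid
  spec2 <- phantom_spec(volume_size_um = c(20, 20, 20),
                        lacunae = list(list(center_um = c(10.06, 9.97, 10.02),
                                            semi_axes_um = c(1.5, 2.5, 5))),
                        noise_peak_photons = NULL)
  tr2 <- build_phantom(spec2)
  analytic2 <- 4 / 3 * pi * 5 * 2.5 * 1.5 / 8000
  expect_lt(abs(mean(tr2$lacuna_mask) - analytic2) / analytic2, 0.05)
})

test_that("voxelization error shrinks to half or better at twice the resolution", {
  err <- vapply(c(0.2, 0.1), function(h) {
    spec <- phantom_spec(volume_size_um = c(12, 12, 12), voxel_size_um = h,
                         lacunae = list(list(center_um = c(6.03, 5.95, 6.08),
                                             semi_axes_um = c(1.5, 2.5, 4))),
                         noise_peak_photons = NULL)
    tr <- build_phantom(spec)
    analytic <- 4 / 3 * pi * 1.5 * 2.5 * 4 / 12^3
    abs(mean(tr$lacuna_mask) - analytic)
  }, 1)
  expect_lt(err[2], 0.55 * err[1] + 1e-6)
})

test_that("phantom construction honours its invariants", {
  spec <- dense_spec(size = c(8, 16, 16),
                     lacunae = list(list(center_um = c(4.1, 8.2, 7.9),
                                         semi_axes_um = c(2, 1.2, 3))))
  tr <- build_phantom(spec)
  # lacuna_mask is a subset of pore_mask
  expect_true(all(tr$pore_mask[tr$lacuna_mask]))
  # porosity fractions lie in [0, 1]; components are consistent with total
  pf <- tr$porosity_fractions
  expect_true(all(pf >= 0 & pf <= 1))
  expect_lte(pf[["lacunar"]] + pf[["canalicular"]], pf[["total"]] + 1e-9)
  # every canalicular centerline voxelization lies inside the pore mask
  for (cl in tr$centerlines) {
    idx <- thglcn:::centerline_voxel_idx(list(cl$polyline_um),
                                         tr$voxel_size_um, tr$dims)
    expect_true(all(tr$pore_mask[idx]))
  }
})

test_that("degenerate zero-length centerlines are rejected", {
  expect_error(phantom_spec(canaliculi = list(list(
    polyline_um = rbind(c(1, 1, 1), c(1, 1, 1)), diameter_um = 0.5))),
    "degenerate")
  expect_error(phantom_spec(canaliculi = list(list(
    polyline_um = rbind(c(1, 1, 1)), diameter_um = 0.5))), "degenerate")
})

test_that("builds and renders are reproducible for a fixed seed", {
  spec <- dense_spec(size = c(6, 12, 12), seed = 11)
  tr1 <- build_phantom(spec)
  tr2 <- build_phantom(spec)
  expect_identical(tr1$pore_mask, tr2$pore_mask)
  psf <- std_psf()
  expect_identical(render_thg(tr1, spec, psf)$data,
                   render_thg(tr2, spec, psf)$data)
  expect_identical(render_fluorescence(tr1, spec, psf)$data,
                   render_fluorescence(tr2, spec, psf)$data)
})

test_that("a pore-free phantom renders as flat background plus noise", {
  spec <- phantom_spec(volume_size_um = c(6, 6, 6),
                       amplitudes = list(interface_amp = 10,
                                         matrix_background = 50),
                       noise_peak_photons = NULL)
  tr <- build_phantom(spec)
  psf <- std_psf()
  img <- render_thg(tr, spec, psf, noise = FALSE)
  # interface component identically zero: the image is exactly constant
  expect_equal(max(img$data) - min(img$data), 0)
  expect_equal(mean(img$data), 50)
})

test_that("a delta PSF with zero background reproduces the interface shell exactly", {
  spec <- tube_spec(amp = 7, size = c(6, 8, 10))
  spec$amplitudes$matrix_background <- 0
  tr <- build_phantom(spec)
  delta <- psf_model(array(1, c(1, 1, 1)), 0.2, 0.2, 0.2)
  img <- render_thg(tr, spec, delta, noise = FALSE)
  shell <- 7 * thglcn:::interface_shell(tr$sdf, tr$voxel_size_um)
  expect_equal(img$data, shell, tolerance = 1e-12)
})

test_that("a noise-free canaliculus shows the double-edge THG signature", {
  spec <- tube_spec()
  tr <- build_phantom(spec)
  img <- render_thg(tr, spec, std_psf(), noise = FALSE)
  prof <- img$data[round(4.03 / 0.2 + 0.5), , 50]
  pk <- thglcn:::find_peaks(prof - min(prof), min_height = 0.3 * max(prof - min(prof)))
  expect_gte(length(pk$pos), 2)
})

test_that("SHG renders carry the lamellar period and dark pores", {
  spec <- phantom_spec(volume_size_um = c(4, 40, 8),
                       lamellar = list(period_um = 5.6, direction = c(0, 1, 0),
                                       amplitude = 0.5),
                       amplitudes = list(shg_base = 40),
                       noise_peak_photons = NULL, seed = 3)
  tr <- build_phantom(spec)
  img <- render_shg(tr, spec, std_psf(), noise = FALSE)
  prof <- img$data[10, , 20]
  # dominant frequency of the mean-subtracted profile = 1/5.6 um^-1
  sp <- Mod(fft(prof - mean(prof)))[2:(length(prof) %/% 2)]
  f <- (seq_along(sp)) / (length(prof) * 0.2)
  expect_equal(f[which.max(sp)], 1 / 5.6, tolerance = 0.1)

  # uniform (amplitude 0) render is flat
  spec0 <- phantom_spec(volume_size_um = c(4, 10, 8),
                        lamellar = list(amplitude = 0),
                        amplitudes = list(shg_base = 40),
                        noise_peak_photons = NULL)
  tr0 <- build_phantom(spec0)
  img0 <- render_shg(tr0, spec0, std_psf(), noise = FALSE)
  expect_equal(max(img0$data) - min(img0$data), 0)

  # pore voxels are darker than the background
  spec2 <- tube_spec(D = 1.0, size = c(6, 8, 10))
  spec2$amplitudes$shg_base <- 40
  tr2 <- build_phantom(spec2)
  img2 <- render_shg(tr2, spec2, std_psf(), noise = FALSE)
  expect_lt(mean(img2$data[tr2$pore_mask]), 0.8 * mean(img2$data[!tr2$pore_mask]))
})

test_that("fluorescence renders are lumen-filled with configurable contrast", {
  spec <- tube_spec()
  spec$amplitudes$lumen_fluorescence_amp <- 9.3
  spec$amplitudes$fluo_matrix_amp <- 1
  tr <- build_phantom(spec)
  psf <- std_psf()
  img <- render_fluorescence(tr, spec, psf, noise = FALSE)
  # single central peak at the tube centre (not the THG double edge)
  prof <- img$data[round(4.03 / 0.2 + 0.5), , 50]
  expect_equal(which.max(prof), round(5.07 / 0.2 + 0.5), tolerance = 1)
  # empty pore mask -> near-zero contrast
  spec0 <- phantom_spec(volume_size_um = c(5, 5, 5),
                        amplitudes = list(fluo_matrix_amp = 0),
                        noise_peak_photons = NULL)
  tr0 <- build_phantom(spec0)
  img0 <- render_fluorescence(tr0, spec0, psf, noise = FALSE)
  expect_equal(max(img0$data), 0)
  # mean lumen / matrix ratio tracks the configured 9.3:1 before blurring
  delta <- psf_model(array(1, c(1, 1, 1)), 0.2, 0.2, 0.2)
  imgd <- render_fluorescence(tr, spec, delta, noise = FALSE)
  core <- tr$sdf < -0.2
  bg <- tr$sdf > 0.4
  expect_equal(mean(imgd$data[core]) / mean(imgd$data[bg]), 9.3, tolerance = 0.05)
})

test_that("THG and SHG matrix modulations are anticorrelated", {
  spec <- phantom_spec(volume_size_um = c(4, 30, 8),
                       lamellar = list(period_um = 5.6, direction = c(0, 1, 0),
                                       amplitude = 0.5),
                       amplitudes = list(matrix_background = 20, shg_base = 40),
                       noise_peak_photons = NULL, seed = 4)
  tr <- build_phantom(spec) # pore-free, cement-free
  psf <- std_psf()
  thg <- render_thg(tr, spec, psf, noise = FALSE)
  shg <- render_shg(tr, spec, psf, noise = FALSE)
  expect_lt(image_correlation(thg, shg), -0.9)
})

test_that("Poisson sampling is unbiased around the noise-free render", {
  spec <- tube_spec(size = c(4, 5, 6), amp = 10, noise = 100, seed = 9)
  tr <- build_phantom(spec)
  psf <- std_psf()
  clean <- render_thg(tr, spec, psf, noise = FALSE)$data
  ref <- thglcn:::reference_peak(spec, psf, "THG", interface_amp = 10)
  mu <- clean * 100 / ref
  n <- 1000
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + render_thg(tr, spec, psf, noise = TRUE, seed = 5000L + i)$data
  se <- sqrt(pmax(mu, 1e-9) / n)
  frac_in <- mean(abs(acc / n - mu) <= 3 * se)
  expect_gte(frac_in, 0.99)
})

test_that("clipping at the volume border is flagged", {
  spec <- phantom_spec(volume_size_um = c(10, 10, 10),
                       lacunae = list(list(center_um = c(5, 5, 9.5),
                                           semi_axes_um = c(1, 1, 2))),
                       noise_peak_photons = NULL)
  tr <- build_phantom(spec)
  expect_true(tr$clipped)
})
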