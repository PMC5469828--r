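test_that("a delta PSF is a Richardson-Lucy fixed point", {
  set.seed(1)
  v <- lcn_volume(array(runif(6 * 7 * 8) * 50 + 5, c(6, 7, 8)), 0.2)
  delta <- psf_model(array(1, c(1, 1, 1)), 0.2, 0.2, 0.2)
  for (it in c(1, 7)) {
    r <- richardson_lucy(v, delta, it)
    expect_lt(max(abs(r$data - v$data)) / max(v$data), 1e-6)
  }
})

test_that("total intensity is conserved under reflective boundaries", {
  set.seed(2)
  base <- array(20, c(20, 24, 24))
  base[8:12, 10:14, 6:18] <- 80
  v <- lcn_volume(thglcn:::gauss_smooth3(base, 0.3, rep(0.2, 3)), 0.2)
  psf <- std_psf()
  r <- richardson_lucy(v, psf, 20)
  expect_lt(abs(sum(r$data) - sum(v$data)) / sum(v$data), 1e-3)
})

test_that("deconvolution restores the gap between two merged canaliculi", {
  # two parallel 0.57 um tubes, wall-to-wall gap 0.3 um
  gap <- 0.3; D <- 0.57
  y1 <- 5.07 - (D + gap) / 2; y2 <- 5.07 + (D + gap) / 2
  spec <- phantom_spec(volume_size_um = c(6, 10, 12),
                       canaliculi = list(
                         list(polyline_um = rbind(c(3.03, y1, 0), c(3.03, y1, 12)),
                              diameter_um = D),
                         list(polyline_um = rbind(c(3.03, y2, 0), c(3.03, y2, 12)),
                              diameter_um = D)),
                       amplitudes = list(interface_amp = 10),
                       noise_peak_photons = NULL, seed = 3)
  tr <- build_phantom(spec)
  psf <- std_psf()
  blurred <- render_thg(tr, spec, psf, noise = FALSE)
  dec <- richardson_lucy(blurred, psf, 20)
  prof <- dec$data[round(3.03 / 0.2 + 0.5), , 30]
  # the inter-tube minimum reappears: at least two maxima with a dip between
  pk <- thglcn:::find_peaks(prof, min_height = 0.3 * max(prof))
  expect_gte(length(pk$pos), 2)
  mid <- round(5.07 / 0.2 + 0.5)
  expect_lt(prof[mid], 0.8 * max(prof))
})

test_that("the Poisson likelihood of the blurred estimate is non-decreasing", {
  set.seed(4)
  truth <- array(0, c(10, 14, 14))
  truth[5, 7, 4:11] <- 60
  psf <- gaussian_psf(0.4, 0.8, 0.2)
  y <- conv_with_psf(truth, psf)
  v <- lcn_volume(y, 0.2)
  ll <- numeric(10)
  x <- array(mean(y), dim(y))
  for (it in 1:10) {
    r <- richardson_lucy(v, psf, it)
    ll[it] <- thglcn:::rl_poisson_loglik(y, r$data, psf)
  }
  expect_true(all(diff(ll) > -1e-6))
})

test_that("estimated PSF + deconvolution reconcentrates point sources", {
  pf <- make_point_field(n = 20, seed = 8)
  est <- estimate_psf_from_canaliculi(pf$vol, pf$pts_um)
  dec <- richardson_lucy(pf$vol, est, 20)
  for (i in seq_len(nrow(pf$true_idx))) {
    p <- pf$true_idx[i, ]
    nb <- dec$data[(p[1] - 1):(p[1] + 1), (p[2] - 1):(p[2] + 1),
                   (p[3] - 1):(p[3] + 1)]
    # >= 60 % of each point's flux back inside a 3x3x3 neighborhood
    expect_gte(sum(nb) / 100, 0.6)
  }
})

test_that("invalid kernels and iteration counts are rejected", {
  v <- lcn_volume(array(1, c(4, 4, 4)), 0.2)
  psf <- std_psf()
  expect_error(richardson_lucy(v, psf, 0), "n_iterations")
  bad <- std_psf(); bad$kernel[1] <- -0.2; bad$sep <- NULL
  expect_error(richardson_lucy(v, bad, 2), "non-negative")
})
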