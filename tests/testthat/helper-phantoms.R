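# Shared fixtures: all phantoms are generated in code at test time.

std_psf <- function(voxel = 0.2) gaussian_psf(0.35, 1.35, voxel)

# single straight canaliculus along x through a generic off-lattice point
tube_spec <- function(D = 0.57, size = c(8, 10, 20), center = c(4.03, 5.07),
                      amp = 10, noise = NULL, seed = 2) {
  phantom_spec(volume_size_um = size,
               canaliculi = list(list(
                 polyline_um = rbind(c(center[1], center[2], 0),
                                     c(center[1], center[2], size[3])),
                 diameter_um = D)),
               amplitudes = list(interface_amp = amp),
               noise_peak_photons = noise, seed = seed)
}

# fixture-style dense phantom at a reduced size (keeps tests fast)
dense_spec <- function(size = c(10, 24, 24), seed = 7, lacunae = NULL,
                       noise = 100) {
  phantom_spec(volume_size_um = size, voxel_size_um = 0.2,
               lacunae = lacunae,
               canalicular_density_um_per_um3 = 0.139,
               canalicular_diameter_um = 0.57,
               orientation_mode = "lamellar",
               lamellar = list(period_um = 5.6, direction = c(0, 1, 0),
                               amplitude = 0.4),
               thg_sbr_target = 3.4, noise_peak_photons = noise, seed = seed)
}

true_length_um <- function(truth) {
  sum(vapply(truth$centerlines, `[[`, 1, "length_um"))
}

# tolerance-1 agreement between a skeleton and the true centerlines:
# fraction of skeleton length within `tol_um` of a true centerline, and
# fraction of true centerline points within `tol_um` of the skeleton
skeleton_agreement <- function(skeleton, truth, tol_um = 0.3) {
  h <- truth$voxel_size_um
  d <- truth$dims
  cl <- do.call(rbind, lapply(truth$centerlines, function(c0)
    thglcn:::densify_polyline(c0$polyline_um, 0.1)))
  clm <- array(FALSE, d)
  ii <- unique(round(sweep(cl, 2, h, "/") + 0.5))
  ok <- ii[, 1] >= 1 & ii[, 2] >= 1 & ii[, 3] >= 1 &
        ii[, 1] <= d[1] & ii[, 2] <= d[2] & ii[, 3] <= d[3]
  clm[ii[ok, , drop = FALSE]] <- TRUE
  dtrue <- distance_transform(clm, h)
  # skeleton -> truth
  msk <- 0; tot <- 0
  for (ch in skeleton$chains) {
    if (nrow(ch) < 2) next
    mid <- (ch[-1, , drop = FALSE] + ch[-nrow(ch), , drop = FALSE]) / 2
    dv <- thglcn:::trilinear(dtrue, sweep(mid, 2, h, "/") + 0.5)
    st <- sqrt(rowSums((ch[-1, , drop = FALSE] - ch[-nrow(ch), , drop = FALSE])^2))
    msk <- msk + sum(st[dv <= tol_um]); tot <- tot + sum(st)
  }
  # truth -> skeleton
  if (any(skeleton$mask)) {
    dsk <- distance_transform(skeleton$mask, skeleton$spacing_um)
    dvals <- thglcn:::trilinear(dsk, sweep(cl, 2, h, "/") + 0.5)
    truth_cov <- mean(dvals <= tol_um)
  } else truth_cov <- 0
  c(skeleton_precision = if (tot > 0) msk / tot else NA_real_,
    truth_recall = truth_cov)
}

# thick digital tube mask along x (for skeleton unit tests)
digital_tube <- function(dims = c(30, 30, 100), radius_um = 0.5,
                         center = c(3.03, 2.97), x_range = c(5, 95),
                         voxel = 0.2) {
  a <- array(FALSE, dims)
  zc <- (seq_len(dims[1]) - 0.5) * voxel
  yc <- (seq_len(dims[2]) - 0.5) * voxel
  disc <- outer((zc - center[1])^2, (yc - center[2])^2, "+") <= radius_um^2
  for (k in x_range[1]:x_range[2]) a[, , k][disc] <- TRUE
  a
}

make_point_field <- function(fwhm = c(0.35, 1.35), n = 20, seed = 5,
                             dims = c(60, 80, 80)) {
  # isolated single-voxel points blurred with a known Gaussian
  a <- array(0, dims)
  set.seed(seed)
  pts <- cbind(sample(15:(dims[1] - 15), n),
               sample(10:(dims[2] - 10), n),
               sample(10:(dims[3] - 10), n))
  # enforce isolation
  keep <- rep(TRUE, n)
  for (i in 2:n) for (j in 1:(i - 1))
    if (all(abs(pts[i, ] - pts[j, ]) < c(22, 12, 12))) keep[i] <- FALSE
  pts <- pts[keep, , drop = FALSE]
  a[pts] <- 100
  psf <- gaussian_psf(fwhm[1], fwhm[2], 0.2)
  vol <- lcn_volume(conv_with_psf(a, psf), 0.2, "THG")
  list(vol = vol, pts_um = (pts - 0.5) * 0.2, true_idx = pts)
}
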