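#' Point-spread-function model
#'
#' A normalized 3D blurring kernel on the image voxel grid together with
#' its lateral/axial full widths at half maximum.
#'
#' @param kernel 3D non-negative array (odd extents), summing to 1.
#' @param voxel_size_um voxel size of the kernel grid, scalar or triple.
#' @param fwhm_lateral_um,fwhm_axial_um FWHMs in micrometres; when missing
#'   they are measured from the kernel's central profiles.
#' @return An object of class `lcn_psf` with elements `kernel`,
#'   `voxel_size_um`, `fwhm_lateral_um`, `fwhm_axial_um` and (for separable
#'   kernels) `sep = list(kz, ky, kx)`.
#' @export
psf_model <- function(kernel, voxel_size_um, fwhm_lateral_um = NULL,
                      fwhm_axial_um = NULL) {
  vs <- setNames(rep_len(as.numeric(voxel_size_um), 3L), c("z", "y", "x"))
  if (any(kernel < 0)) stop("PSF kernel must be non-negative")
  s <- sum(kernel)
  if (s <= 0) stop("PSF kernel must have positive sum")
  if (abs(s - 1) > 1e-6) kernel <- kernel / s
  d <- dim(kernel)
  # centroid within half a voxel of the geometric centre
  ctr <- (d + 1) / 2
  idx <- lapply(1:3, function(i) seq_len(d[i]))
  cz <- sum(kernel * array(idx[[1]], d))
  cy <- sum(kernel * array(rep(idx[[2]], each = d[1]), d))
  cx <- sum(kernel * array(rep(idx[[3]], each = d[1] * d[2]), d))
  if (max(abs(c(cz, cy, cx) - ctr)) > 0.5)
    warning("PSF centroid is more than half a voxel from the kernel centre")
  if (is.null(fwhm_lateral_um) || is.null(fwhm_axial_um)) {
    fw <- kernel_fwhm(kernel, vs)
    if (is.null(fwhm_lateral_um)) fwhm_lateral_um <- mean(fw[c("y", "x")])
    if (is.null(fwhm_axial_um)) fwhm_axial_um <- fw[["z"]]
  }
  structure(list(kernel = kernel, voxel_size_um = vs,
                 fwhm_lateral_um = fwhm_lateral_um,
                 fwhm_axial_um = fwhm_axial_um, sep = NULL),
            class = "lcn_psf")
}

#' @export
print.lcn_psf <- function(x, ...) {
  d <- dim(x$kernel)
  cat(sprintf("<lcn_psf> %d x %d x %d kernel, FWHM %.3g um lateral x %.3g um axial%s\n",
              d[1], d[2], d[3], x$fwhm_lateral_um, x$fwhm_axial_um,
              if (!is.null(x$sep)) " (separable)" else ""))
  invisible(x)
}

# FWHM of the central profiles of a kernel, interpolated half-max crossings
kernel_fwhm <- function(kernel, vs) {
  d <- dim(kernel)
  ctr <- (d + 1) %/% 2
  profs <- list(z = kernel[, ctr[2], ctr[3]],
                y = kernel[ctr[1], , ctr[3]],
                x = kernel[ctr[1], ctr[2], ])
  vapply(seq_along(profs), function(i) {
    profile_fwhm(profs[[i]], vs[i])
  }, 1) |> setNames(c("z", "y", "x"))
}

# FWHM of a sampled profile by linear interpolation of half-max crossings
profile_fwhm <- function(p, spacing, baseline = 0) {
  p <- p - baseline
  im <- which.max(p)
  half <- p[im] / 2
  if (p[im] <= 0 || im == 1L || im == length(p)) return(NA_real_)
  left <- NA_real_
  for (i in seq(im, 2)) {
    if (p[i - 1] < half) {
      left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(im, length(p) - 1)) {
    if (p[i + 1] < half) {
      right <- i + (p[i] - half) / (p[i] - p[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * spacing
}

#' Separable anisotropic Gaussian PSF
#'
#' Parametric point-spread function used when no empirical estimate is
#' available: an anisotropic Gaussian with the given lateral (x, y) and
#' axial (z) FWHMs, truncated at three standard deviations per axis and
#' normalized to unit sum.
#'
#' @param fwhm_lateral_um,fwhm_axial_um full widths at half maximum in
#'   micrometres (FWHM = 2 sqrt(2 ln 2) sigma).
#' @param voxel_size_um voxel size, scalar or `(z, y, x)` triple.
#' @return An `lcn_psf` with a separable kernel (fast convolution path).
#' @examples
#' psf <- gaussian_psf(0.35, 1.35, 0.2)
#' sum(psf$kernel)
#' @export
gaussian_psf <- function(fwhm_lateral_um = 0.35, fwhm_axial_um = 1.35,
                         voxel_size_um = 0.2) {
  if (fwhm_lateral_um <= 0 || fwhm_axial_um <= 0) stop("FWHMs must be > 0")
  vs <- setNames(rep_len(as.numeric(voxel_size_um), 3L), c("z", "y", "x"))
  if (fwhm_lateral_um < min(vs[2:3]) || fwhm_axial_um < vs[1])
    warning("PSF FWHM below one voxel; kernel collapses toward a delta")
  f2s <- 1 / (2 * sqrt(2 * log(2)))
  sig <- c(fwhm_axial_um, fwhm_lateral_um, fwhm_lateral_um) * f2s / vs
  kz <- gauss_kernel1d(sig[1]); ky <- gauss_kernel1d(sig[2]); kx <- gauss_kernel1d(sig[3])
  if (length(kz) == 1) kz <- 1
  kern <- outer(outer(kz, ky), kx)
  dim(kern) <- c(length(kz), length(ky), length(kx))
  psf <- psf_model(kern, vs, fwhm_lateral_um, fwhm_axial_um)
  psf$sep <- list(kz = kz, ky = ky, kx = kx)
  psf
}

#' Estimate an effective PSF from canalicular cross-sections
#'
#' Canaliculi are sub-resolution; an axially oriented canaliculus imaged in
#' cross-section is effectively a point source, so averaging aligned patches
#' around such cross-sections yields an empirical estimate of the effective
#' 3D point-spread function of the acquisition.
#'
#' Each candidate patch is background-subtracted (local median), rejected if
#' its intensity centroid is more than two voxels off-centre or if another
#' structure intrudes on the patch border, recentred on its centroid with
#' sub-voxel (trilinear) interpolation, and averaged. Negative values are
#' clipped and the result normalized to unit sum.
#'
#' @param vol an [lcn_volume()].
#' @param candidate_points_um matrix (n x 3) of `(z, y, x)` positions (µm)
#'   marking isolated, axially oriented canalicular cross-sections.
#' @param patch_radius_um patch half-extents `(z, y, x)` in micrometres.
#' @param max_shift_vox maximum tolerated centroid offset (voxels).
#' @param border_max_frac reject patches whose border intensity exceeds this
#'   fraction of the peak (another structure in the patch).
#' @return An `lcn_psf`; fails with an informative error if fewer than 5
#'   usable candidates survive (use [gaussian_psf()] as fallback).
#' @export
estimate_psf_from_canaliculi <- function(vol, candidate_points_um,
                                         patch_radius_um = c(2.0, 1.0, 1.0),
                                         max_shift_vox = 2, border_max_frac = 0.35) {
  stopifnot(inherits(vol, "lcn_volume"))
  candidate_points_um <- rbind(candidate_points_um)
  if (nrow(candidate_points_um) < 5)
    stop("need at least 5 candidate canalicular cross-sections")
  a <- vol$data
  vs <- vol$voxel_size_um
  rad <- pmax(1L, round(rep_len(patch_radius_um, 3L) / vs))
  pd <- 2L * rad + 1L
  d <- dim(a)
  acc <- array(0, pd)
  used <- 0L
  ctr <- rad + 1L
  grid_z <- array(seq_len(pd[1]), pd)
  grid_y <- array(rep(seq_len(pd[2]), each = pd[1]), pd)
  grid_x <- array(rep(seq_len(pd[3]), each = pd[1] * pd[2]), pd)
  border <- grid_z == 1 | grid_z == pd[1] | grid_y == 1 | grid_y == pd[2] |
            grid_x == 1 | grid_x == pd[3]
  for (n in seq_len(nrow(candidate_points_um))) {
    ci <- round(um_to_index(candidate_points_um[n, ], vs))
    if (any(ci - rad < 1) || any(ci + rad > d)) next
    patch <- a[(ci[1] - rad[1]):(ci[1] + rad[1]),
               (ci[2] - rad[2]):(ci[2] + rad[2]),
               (ci[3] - rad[3]):(ci[3] + rad[3])]
    patch <- patch - median(patch)
    pk <- max(patch)
    if (pk <= 0) next
    if (max(patch[border]) > border_max_frac * pk) next # touches another structure
    pos <- pmax(patch, 0)
    w <- sum(pos)
    cen <- c(sum(pos * grid_z), sum(pos * grid_y), sum(pos * grid_x)) / w
    if (max(abs(cen - ctr)) > max_shift_vox) next
    # sub-voxel recentre: sample the patch at positions shifted by the
    # centroid offset
    off <- cen - ctr
    pts <- cbind(as.numeric(grid_z) + off[1], as.numeric(grid_y) + off[2],
                 as.numeric(grid_x) + off[3])
    shifted <- array(trilinear(patch, pts), pd)
    acc <- acc + shifted / pk
    used <- used + 1L
  }
  if (used < 5)
    stop(sprintf(paste("only %d usable PSF candidates after rejection;",
                       "consider the parametric fallback gaussian_psf()"), used))
  acc[acc < 0] <- 0
  psf <- psf_model(acc / sum(acc), vs)
  attr(psf, "n_candidates") <- used
  psf
}
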