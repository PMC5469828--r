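#' Image volume container
#'
#' A 3D scalar intensity grid with anisotropic voxel size and a modality
#' tag; the common currency of all analysis stages.
#'
#' @param data 3D numeric array, dim `c(nz, ny, nx)` (axial axis first).
#'   A matrix is promoted to a single-slice volume.
#' @param voxel_size_um voxel size in micrometres; scalar (isotropic) or
#'   triple `(z, y, x)`.
#' @param modality one of `"THG"`, `"SHG"`, `"FLUO"`, `"CT"`.
#' @return An object of class `lcn_volume`: a list with elements `data`,
#'   `voxel_size_um` (named triple) and `modality`.
#' @examples
#' v <- lcn_volume(array(1, c(4, 5, 6)), 0.2, "THG")
#' dim(v$data)
#' @export
lcn_volume <- function(data, voxel_size_um = 0.2, modality = c("THG", "SHG", "FLUO", "CT")) {
  modality <- match.arg(modality)
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array (z, y, x)")
  if (anyNA(data) || any(!is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be non-negative")
  vs <- rep_len(as.numeric(voxel_size_um), 3L)
  if (any(vs <= 0)) stop("voxel sizes must be > 0")
  structure(list(data = data, voxel_size_um = setNames(vs, c("z", "y", "x")),
                 modality = modality),
            class = "lcn_volume")
}

#' @export
print.lcn_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lcn_volume> %s  %d x %d x %d voxels (z,y,x)  voxel %.3g x %.3g x %.3g um\n",
              x$modality, d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

as_volume_array <- function(vol) {
  if (inherits(vol, "lcn_volume")) vol$data else vol
}

vol_spacing <- function(vol, voxel_size_um = NULL) {
  if (inherits(vol, "lcn_volume")) vol$voxel_size_um
  else setNames(rep_len(as.numeric(voxel_size_um), 3L), c("z", "y", "x"))
}

# physical voxel-centre coordinates along one axis (1-based index i -> (i-0.5)*h)
axis_coords <- function(n, h) (seq_len(n) - 0.5) * h

# µm position (z,y,x) -> fractional 1-based array index
um_to_index <- function(pos, spacing) pos / spacing + 0.5

index_to_um <- function(idx, spacing) (idx - 0.5) * spacing

# --- separable convolution -------------------------------------------------

conv3_sep <- function(a, kz = NULL, ky = NULL, kx = NULL) {
  d <- dim(a)
  x <- as.numeric(a)
  if (!is.null(kz) && length(kz) > 1L) x <- .conv3_axis(x, d, kz, 0L)
  if (!is.null(ky) && length(ky) > 1L) x <- .conv3_axis(x, d, ky, 1L)
  if (!is.null(kx) && length(kx) > 1L) x <- .conv3_axis(x, d, kx, 2L)
  array(x, d)
}

gauss_kernel1d <- function(sigma_vox, min_radius = 1L) {
  # below a tenth of a voxel the discrete kernel is indistinguishable from
  # a delta (the +/-1 taps underflow): collapse explicitly
  if (sigma_vox <= 0.1) return(1)
  r <- max(min_radius, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Gaussian smoothing with physical sigma (µm), anisotropy-aware
gauss_smooth3 <- function(a, sigma_um, spacing) {
  s <- rep_len(sigma_um, 3L) / spacing
  conv3_sep(a, gauss_kernel1d(s[1]), gauss_kernel1d(s[2]), gauss_kernel1d(s[3]))
}

# --- FFT convolution (general kernels, reflective padding) -----------------

good_size <- function(n) {
  # smallest 5-smooth integer >= n
  while (TRUE) {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

pad_reflect <- function(a, pad) {
  d <- dim(a)
  ix <- lapply(1:3, function(i) {
    n <- d[i]; p <- pad[i]
    idx <- c(rev(seq_len(min(p, n))), seq_len(n), n + 1 - rev(seq_len(min(p, n))))
    # if pad > n, recycle reflection (rare; tiny volumes)
    while (length(idx) < n + 2 * p) idx <- c(idx[1], idx, idx[length(idx)])
    idx
  })
  a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

conv3_fft <- function(a, kern, correlate = FALSE) {
  d <- dim(a); dk <- dim(kern)
  if (correlate) kern <- kern[rev(seq_len(dk[1])), rev(seq_len(dk[2])), rev(seq_len(dk[3])), drop = FALSE]
  pad <- dk %/% 2
  ap <- pad_reflect(a, pad)
  dp <- dim(ap)
  df <- pmax(vapply(dp + dk - 1, good_size, 1), dp)
  A <- array(0, df); A[seq_len(dp[1]), seq_len(dp[2]), seq_len(dp[3])] <- ap
  K <- array(0, df); K[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  conv <- Re(fft(fft(A) * fft(K), inverse = TRUE)) / prod(df)
  # kernel centre offset: pad + centre of kernel aligns with original origin
  off <- pad + (dk %/% 2)
  conv[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3]), drop = FALSE]
}

#' Convolve a volume with a PSF
#'
#' Reflective boundary handling; separable kernels use the fast
#' axis-by-axis path, general kernels an FFT.
#'
#' @param a 3D numeric array or [lcn_volume()].
#' @param psf an `lcn_psf`.
#' @return Array (or `lcn_volume`, matching the input) of the same size.
#' @export
conv_with_psf <- function(a, psf) {
  if (inherits(a, "lcn_volume")) {
    a$data <- conv3_psf(a$data, psf)
    a
  } else conv3_psf(a, psf)
}

# Convolve a volume array with a PSF (separable fast path, FFT otherwise)
conv3_psf <- function(a, psf, correlate = FALSE) {
  if (!is.null(psf$sep)) {
    # separable Gaussian kernels are symmetric: convolution == correlation
    conv3_sep(a, psf$sep$kz, psf$sep$ky, psf$sep$kx)
  } else {
    conv3_fft(a, psf$kernel, correlate = correlate)
  }
}

# --- distance transforms, labeling, morphology -----------------------------

#' Euclidean distance transform
#'
#' Distance (in micrometres, anisotropy-aware) from every voxel to the
#' nearest `TRUE` voxel of a mask.
#'
#' @param mask 3D logical array.
#' @param voxel_size_um scalar or `(z, y, x)` triple, micrometres.
#' @return 3D numeric array of distances in micrometres (`Inf` if the mask
#'   is empty).
#' @export
distance_transform <- function(mask, voxel_size_um) {
  d <- dim(mask)
  sp <- rep_len(as.numeric(voxel_size_um), 3L)
  if (!any(mask)) return(array(Inf, d))
  array(sqrt(.edt3_sq(as.logical(mask), d, sp)), d)
}

#' Label connected components of a 3D mask
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of component labels (0 = background) with
#'   attribute `"n"` giving the number of components.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- dim(mask)
  lab <- .label3d(as.logical(mask), d, as.integer(connectivity))
  n <- attr(lab, "n")
  lab <- array(lab, d)
  attr(lab, "n") <- n
  lab
}

# ball erosion/dilation through the distance transform (exact Euclidean ball)
mask_erode <- function(mask, radius_um, spacing) {
  if (radius_um <= 0) return(mask)
  mask & !(distance_transform(!mask, spacing) <= radius_um)
}

mask_dilate <- function(mask, radius_um, spacing) {
  if (radius_um <= 0) return(mask)
  if (!any(mask)) return(mask)
  distance_transform(mask, spacing) <= radius_um
}

mask_open <- function(mask, radius_um, spacing)
  mask_dilate(mask_erode(mask, radius_um, spacing), radius_um, spacing)

mask_close <- function(mask, radius_um, spacing)
  mask_erode(mask_dilate(mask, radius_um, spacing), radius_um, spacing)

# fill interior cavities: background components not touching the border
# (faces along singleton axes are not borders: a 1-voxel-thick volume is a
# 2D section and holes are filled in-plane)
fill_holes3 <- function(mask) {
  lab <- label_components(!mask, connectivity = 6L)
  d <- dim(mask)
  border <- c(if (d[1] > 1) lab[c(1, d[1]), , ],
              if (d[2] > 1) lab[, c(1, d[2]), ],
              if (d[3] > 1) lab[, , c(1, d[3])])
  border <- unique(border[border > 0])
  mask | (lab > 0 & !(lab %in% border))
}

# slice-wise (per z-plane) hole filling: fills structures whose enclosing
# shell is only closed in-plane (e.g. lacunae whose axial caps are dim).
# closed_border treats out-of-field as structure, so cavities clipped by
# the volume border are still filled (the caller's darkness criterion then
# decides whether they are genuine lumina).
fill_holes_slicewise <- function(mask, closed_border = FALSE) {
  d <- dim(mask)
  for (i in seq_len(d[1])) {
    sl <- mask[i, , ]
    if (closed_border) {
      frame <- sl
      frame[c(1, d[2]), ] <- TRUE
      frame[, c(1, d[3])] <- TRUE
      filled <- fill_holes3(array(frame, c(1L, d[2], d[3])))[1, , ]
      mask[i, , ] <- sl | (filled & !frame)
    } else {
      mask[i, , ] <- fill_holes3(array(sl, c(1L, d[2], d[3])))[1, , ]
    }
  }
  mask
}

# --- Otsu threshold --------------------------------------------------------
# (volume-wide; frame-wise 2D implementations elsewhere do not apply to 3D stacks)
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  # threshold between bin argmax and the next: use upper edge of argmax bin
  k <- which.max(bcv)
  rng[1] + k / n_bins * diff(rng)
}

# --- misc helpers ----------------------------------------------------------

# run code with a local RNG state (restores the caller's stream)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# trilinear interpolation of a 3D array at fractional 1-based indices
# pts: matrix n x 3 of (i, j, k); outside values -> 0
trilinear <- function(a, pts) {
  d <- dim(a)
  i0 <- floor(pts)
  f <- pts - i0
  val <- numeric(nrow(pts))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- i0[, 1] + dz; jj <- i0[, 2] + dy; kk <- i0[, 3] + dx
    w <- (if (dz) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dx) f[, 3] else 1 - f[, 3])
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3] & w > 0
    if (any(ok))
      val[ok] <- val[ok] + w[ok] * a[cbind(ii[ok], jj[ok], kk[ok])]
  }
  val
}

# Euler characteristic of the cubical complex of a 3D binary mask
# (vertices - edges + faces - cubes); used for topology assertions.
euler_characteristic3 <- function(mask) {
  m <- array(FALSE, dim(mask) + 2L)
  m[2:(dim(mask)[1] + 1), 2:(dim(mask)[2] + 1), 2:(dim(mask)[3] + 1)] <- mask
  d <- dim(m)
  or_shift <- function(a, sh) {
    # OR of a with itself shifted by sh (grid of lower-dim cells)
    out <- a
    idx <- lapply(1:3, function(i) {
      if (sh[i] == 0) seq_len(d[i]) else c(seq_len(d[i])[-1], NA)
    })
    b <- array(FALSE, d)
    src <- lapply(1:3, function(i) if (sh[i] == 0) seq_len(d[i]) else seq_len(d[i] - 1))
    dst <- lapply(1:3, function(i) if (sh[i] == 0) seq_len(d[i]) else seq_len(d[i] - 1))
    b[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]] + sh[1], src[[2]] + sh[2], src[[3]] + sh[3]]
    out | b
  }
  cell_count <- function(shifts) {
    acc <- m
    for (sh in shifts) acc <- or_shift(acc, sh)
    sum(acc)
  }
  cubes <- sum(m)
  faces <- cell_count(list(c(1, 0, 0))) + cell_count(list(c(0, 1, 0))) + cell_count(list(c(0, 0, 1)))
  edges <- cell_count(list(c(1, 0, 0), c(0, 1, 0))) +
           cell_count(list(c(1, 0, 0), c(0, 0, 1))) +
           cell_count(list(c(0, 1, 0), c(0, 0, 1)))
  verts <- cell_count(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  verts - edges + faces - cubes
}
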