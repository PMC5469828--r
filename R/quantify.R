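#' Measure a canalicular diameter from a two-edge intensity profile
#'
#' THG highlights the two walls of a canaliculus; the diameter is the
#' distance between the two edge peaks of an intensity profile taken
#' perpendicular to the local centerline tangent, in the lateral (image)
#' plane. Profiles are sampled with sub-voxel (trilinear) spacing, the
#' local background (median of the profile tails) is subtracted, the two
#' most prominent maxima flanking the centre are located and refined by
#' three-point parabolic interpolation. If only one peak is found (walls
#' unresolved) the full width at half maximum of the single peak is
#' returned instead, tagged `"fwhm_fallback"`.
#'
#' Profiles whose tangent lies within 30 degrees of the optical axis are
#' rejected: the axial PSF is about four times wider than the lateral one,
#' and the two edges are only resolved laterally.
#'
#' @param vol an [lcn_volume()].
#' @param position_um `(z, y, x)` sample point (µm) on the centerline.
#' @param tangent_um local centerline tangent `(z, y, x)` (any norm).
#' @param profile_length_um length of the sampled profile.
#' @param min_prominence_frac peak prominence floor, as a fraction of the
#'   profile amplitude.
#' @param n_average number of parallel profiles averaged along the
#'   tangent (spaced one voxel apart, centred on the sample point) to
#'   suppress shot noise; 1 disables averaging.
#' @return An object of class `lcn_diameter`: list with `diameter_um`
#'   (`NA` when undefined), `method` (`"two_edge"`, `"fwhm_fallback"` or
#'   `"undefined"`), `reason`, `edge_positions_um`, `profile`,
#'   `profile_spacing_um`, `position_um`, `direction`.
#' @export
measure_diameter <- function(vol, position_um, tangent_um,
                             profile_length_um = 3,
                             min_prominence_frac = 0.15,
                             n_average = 9L) {
  stopifnot(inherits(vol, "lcn_volume"))
  t <- tangent_um / sqrt(sum(tangent_um^2))
  if (!all(is.finite(t))) stop("tangent must be non-zero")
  res <- list(position_um = position_um, diameter_um = NA_real_,
              method = "undefined", reason = NULL,
              edge_positions_um = numeric(0))
  class(res) <- "lcn_diameter"
  if (abs(t[1]) > cos(pi / 6)) { # within 30 deg of the optical axis
    res$reason <- "tangent within 30 deg of optical axis"
    return(res)
  }
  # lateral in-plane direction perpendicular to the tangent: t x z-hat
  dvec <- c(0, -t[3], t[2]) # cross product with (1,0,0) in (z,y,x)
  dvec <- dvec / sqrt(sum(dvec^2))
  sp <- vol$voxel_size_um
  step <- min(sp) / 2
  s <- seq(-profile_length_um / 2, profile_length_um / 2, by = step)
  offs <- (seq_len(max(1L, n_average)) - (max(1L, n_average) + 1) / 2) * min(sp)
  prof <- 0
  for (o in offs) {
    pts_um <- outer(s, dvec) + rep(position_um + o * t, each = length(s))
    idx <- sweep(pts_um, 2, sp, "/") + 0.5
    prof <- prof + trilinear(vol$data, idx)
  }
  prof <- prof / length(offs)
  res$profile <- prof
  res$profile_spacing_um <- step
  res$direction <- dvec
  # local background: median of the outer quartiles
  nq <- max(2L, length(s) %/% 4)
  bg <- median(c(head(prof, nq), tail(prof, nq)))
  p0 <- prof - bg
  # peaks are sought near the centre: the walls sit within about one
  # diameter, and distant bright neighbours must not set the scale
  search_halfwidth_um <- 0.8
  ctr0 <- (length(s) + 1) / 2
  winpk <- round(search_halfwidth_um / step)
  pk_rng <- max(1, ctr0 - winpk):min(length(s), ctr0 + winpk)
  amp <- max(p0[pk_rng])
  if (amp <= 0) {
    res$reason <- "no signal above local background"
    return(res)
  }
  pk <- find_peaks(p0, min_prominence = min_prominence_frac * amp,
                   min_height = 0.25 * amp)
  pk$pos <- pk$pos[pk$pos %in% pk_rng]
  if (!length(pk$pos)) {
    res$reason <- "no peak above background"
    return(res)
  }
  # recentre on the lumen: local minimum within +/- 0.3 um of the
  # nominal centre (skeleton positions are accurate to about one voxel)
  win <- round(0.3 / step)
  ctr_rng <- max(1, ctr0 - win):min(length(s), ctr0 + win)
  ctr <- ctr_rng[which.min(p0[ctr_rng])]
  left <- pk$pos[pk$pos < ctr]
  right <- pk$pos[pk$pos > ctr]
  if (length(left) && length(right)) {
    # the wall peaks are the nearest maxima flanking the lumen centre
    li <- max(left)
    ri <- min(right)
    lref <- refine_peak(p0, li)
    rref <- refine_peak(p0, ri)
    res$edge_positions_um <- (c(lref, rref) - ctr) * step
    res$diameter_um <- (rref - lref) * step
    res$method <- "two_edge"
  } else {
    # unresolved walls: FWHM of the single ridge
    fw <- profile_fwhm(p0, step)
    if (is.na(fw)) {
      res$reason <- "FWHM not measurable"
    } else {
      res$diameter_um <- fw
      res$method <- "fwhm_fallback"
    }
  }
  res
}

#' @export
print.lcn_diameter <- function(x, ...) {
  if (is.na(x$diameter_um))
    cat(sprintf("<lcn_diameter> undefined (%s)\n", x$reason %||% "unknown"))
  else
    cat(sprintf("<lcn_diameter> %.3f um (%s)\n", x$diameter_um, x$method))
  invisible(x)
}

# local maxima with a simple prominence measure
find_peaks <- function(p, min_prominence = 0, min_height = -Inf) {
  n <- length(p)
  pos <- which(diff(sign(diff(p))) == -2) + 1L
  if (!length(pos)) return(list(pos = integer(), height = numeric()))
  keep <- logical(length(pos))
  prom <- numeric(length(pos))
  for (i in seq_along(pos)) {
    pp <- pos[i]
    h <- p[pp]
    if (h < min_height) next
    # prominence: drop to the highest saddle separating from a higher peak
    lmin <- h; j <- pp
    while (j > 1 && p[j - 1] <= h) { j <- j - 1; lmin <- min(lmin, p[j]) }
    ldrop <- h - if (j == 1) min(lmin, min(p[1:pp])) else lmin
    rmin <- h; j <- pp
    while (j < n && p[j + 1] <= h) { j <- j + 1; rmin <- min(rmin, p[j]) }
    rdrop <- h - if (j == n) min(rmin, min(p[pp:n])) else rmin
    prom[i] <- min(ldrop, rdrop)
    keep[i] <- prom[i] >= min_prominence
  }
  list(pos = pos[keep], height = p[pos[keep]], prominence = prom[keep])
}

# three-point parabolic sub-sample peak refinement
refine_peak <- function(p, i) {
  if (i <= 1 || i >= length(p)) return(as.numeric(i))
  denom <- p[i - 1] - 2 * p[i] + p[i + 1]
  if (denom >= 0) return(as.numeric(i))
  as.numeric(i) + 0.5 * (p[i - 1] - p[i + 1]) / denom
}

#' Canalicular diameter distribution along a skeleton
#'
#' Samples positions uniformly by length along the skeleton chains
#' (seeded), measures the two-edge diameter perpendicular to the local
#' chain tangent, and aggregates the defined two-edge measurements.
#'
#' @param vol an [lcn_volume()] (typically the raw THG stack).
#' @param skeleton an [skeletonize3d()] result (non-empty).
#' @param n_samples number of sample positions (>= 1).
#' @param seed RNG seed for the sampling.
#' @param ... passed to [measure_diameter()].
#' @return List of class `lcn_diameters`: `diameter_mean_um`,
#'   `diameter_sd_um`, `diameter_histogram`, `n_measurements`,
#'   `fallback_fraction`, `undefined_fraction`, `measurements`.
#' @export
diameter_distribution <- function(vol, skeleton, n_samples = 100L, seed = 1L, ...) {
  stopifnot(inherits(skeleton, "lcn_skeleton"))
  if (!length(skeleton$chains)) stop("skeleton is empty")
  if (n_samples < 1) stop("n_samples must be >= 1")
  segs <- list()
  for (ch in skeleton$chains) {
    if (nrow(ch) < 2) next
    for (i in seq_len(nrow(ch) - 1))
      segs[[length(segs) + 1]] <- ch[i:(i + 1), ]
  }
  seg_len <- vapply(segs, function(sg) sqrt(sum((sg[2, ] - sg[1, ])^2)), 1)
  segs <- segs[seg_len > 1e-9]
  seg_len <- seg_len[seg_len > 1e-9]
  if (!length(segs)) stop("skeleton has no usable chain segments")
  cum <- cumsum(seg_len)
  meas <- with_seed(seed, {
    u <- runif(n_samples) * cum[length(cum)]
    lapply(u, function(ui) {
      si <- findInterval(ui, c(0, cum), rightmost.closed = TRUE)
      si <- min(max(si, 1L), length(segs))
      sg <- segs[[si]]
      frac <- (ui - c(0, cum)[si]) / seg_len[si]
      pos <- sg[1, ] + frac * (sg[2, ] - sg[1, ])
      measure_diameter(vol, pos, sg[2, ] - sg[1, ], ...)
    })
  })
  dia <- vapply(meas, function(m) m$diameter_um, 1)
  mth <- vapply(meas, function(m) m$method, "")
  two <- dia[mth == "two_edge"]
  if (!length(two) && !any(mth == "fwhm_fallback"))
    stop("all diameter measurements undefined")
  # robust aggregation: profiles that lock onto a neighbouring structure
  # produce gross outliers, so measurements beyond 2.5 MAD of the median
  # are excluded from the summary statistics (all are still reported)
  keep <- two
  if (length(two) > 4) {
    md <- median(two)
    s <- mad(two)
    if (s > 0) keep <- two[abs(two - md) <= 2.5 * s]
  }
  structure(list(diameter_mean_um = mean(keep),
                 diameter_sd_um = if (length(keep) > 1) sd(keep) else 0,
                 n_outliers = length(two) - length(keep),
                 diameter_histogram = if (length(two))
                   table(cut(two, breaks = seq(0, max(two) + 0.1, by = 0.1)))
                 else NULL,
                 n_measurements = length(two),
                 fallback_fraction = mean(mth == "fwhm_fallback"),
                 undefined_fraction = mean(mth == "undefined"),
                 n_samples = n_samples, seed = seed,
                 measurements = meas),
            class = "lcn_diameters")
}

#' @export
print.lcn_diameters <- function(x, ...) {
  cat(sprintf("<lcn_diameters> %d two-edge measurements: %.3f +/- %.3f um (fallback %.0f%%, undefined %.0f%%)\n",
              x$n_measurements, x$diameter_mean_um, x$diameter_sd_um,
              100 * x$fallback_fraction, 100 * x$undefined_fraction))
  invisible(x)
}

#' Porosity fractions from lacuna mask and canalicular skeleton
#'
#' Lacunar porosity is the voxel-counted lacuna volume fraction; the
#' canalicular porosity models each canaliculus as a cylinder of the mean
#' measured diameter swept along the skeleton (skeleton length inside the
#' lacuna mask is excluded to avoid double counting).
#'
#' @param lacuna_mask 3D logical array.
#' @param skeleton an [skeletonize3d()] result on the same physical volume.
#' @param mean_diameter_um mean canalicular diameter (> 0).
#' @param voxel_size_um grid voxel size, scalar or triple.
#' @return Named numeric: `lacunar`, `canalicular`, `total` (fractions of
#'   the imaged volume), with attribute `"length_um"` (canalicular
#'   centerline length used).
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1] <- TRUE
#' porosity_fractions(m, empty_skeleton(dim(m), rep(0.2, 3)), 0.57, 0.2)
#' @export
porosity_fractions <- function(lacuna_mask, skeleton, mean_diameter_um,
                               voxel_size_um) {
  sp <- rep_len(as.numeric(voxel_size_um), 3L)
  if (mean_diameter_um <= 0) stop("mean diameter must be > 0")
  if (!is.null(dim(skeleton$mask)) &&
      abs(prod(dim(lacuna_mask)) * prod(sp) -
          prod(skeleton$dims) * prod(skeleton$spacing_um)) >
        0.02 * prod(dim(lacuna_mask)) * prod(sp))
    stop("lacuna mask and skeleton do not cover the same physical volume")
  vtot <- prod(dim(lacuna_mask)) * prod(sp)
  lacunar <- sum(lacuna_mask) * prod(sp) / vtot
  # chain length outside the lacuna mask
  len <- 0
  for (ch in skeleton$chains) {
    if (nrow(ch) < 2) next
    mid <- (ch[-1, , drop = FALSE] + ch[-nrow(ch), , drop = FALSE]) / 2
    idx <- round(sweep(mid, 2, sp, "/") + 0.5)
    d <- dim(lacuna_mask)
    idx[, 1] <- pmin(pmax(idx[, 1], 1), d[1])
    idx[, 2] <- pmin(pmax(idx[, 2], 1), d[2])
    idx[, 3] <- pmin(pmax(idx[, 3], 1), d[3])
    inlac <- lacuna_mask[idx]
    steps <- sqrt(rowSums((ch[-1, , drop = FALSE] - ch[-nrow(ch), , drop = FALSE])^2))
    len <- len + sum(steps[!inlac])
  }
  canalicular <- len * pi * (mean_diameter_um / 2)^2 / vtot
  out <- c(lacunar = lacunar, canalicular = canalicular,
           total = lacunar + canalicular)
  attr(out, "length_um") <- len
  out
}

#' Signal-to-background ratio
#'
#' Mean intensity at the canalicular centerline voxels divided by the mean
#' intensity at least `min_distance_um` away (Euclidean, anisotropy-aware)
#' from any structure. For CT-like contrast (dark lumina on a bright
#' matrix) the reciprocal is returned so ratios are comparable across
#' modalities.
#'
#' @param vol an [lcn_volume()].
#' @param centerlines_um list of n x 3 polylines (µm), or an
#'   `lcn_skeleton`.
#' @param structure_mask logical array of all structures (pores, lacunae,
#'   channels, cement); the background region excludes its
#'   `min_distance_um` dilation.
#' @param min_distance_um background clearance in micrometres.
#' @return Ratio (scalar) with attributes `"signal"` and `"background"`.
#' @export
signal_to_background <- function(vol, centerlines_um, structure_mask,
                                 min_distance_um = 1.0) {
  stopifnot(inherits(vol, "lcn_volume"))
  if (inherits(centerlines_um, "lcn_skeleton")) centerlines_um <- centerlines_um$chains
  if (!length(centerlines_um)) stop("centerlines must be non-empty")
  sp <- vol$voxel_size_um
  d <- dim(vol$data)
  idx <- centerline_voxel_idx(centerlines_um, sp, d)
  if (!nrow(idx)) stop("no centerline voxels inside the volume")
  sig <- mean(vol$data[idx])
  dist <- distance_transform(structure_mask, sp)
  bg_vox <- dist >= min_distance_um
  if (!any(bg_vox))
    stop(sprintf("empty background region (distance map range %.2f-%.2f um)",
                 min(dist), max(dist)))
  bg <- mean(vol$data[bg_vox])
  ratio <- sig / bg
  if (vol$modality == "CT") ratio <- 1 / ratio
  structure(ratio, signal = sig, background = bg)
}

# unique voxel indices traversed by a set of polylines (µm)
centerline_voxel_idx <- function(centerlines_um, sp, d) {
  pts <- do.call(rbind, lapply(centerlines_um, densify_polyline,
                               step = min(sp) / 2))
  idx <- unique(round(sweep(pts, 2, sp, "/") + 0.5))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  idx[ok, , drop = FALSE]
}

densify_polyline <- function(pl, step) {
  if (nrow(pl) < 2) return(pl)
  out <- list()
  for (i in seq_len(nrow(pl) - 1)) {
    p1 <- pl[i, ]; p2 <- pl[i + 1, ]
    n <- max(2L, ceiling(sqrt(sum((p2 - p1)^2)) / step))
    t <- seq(0, 1, length.out = n)
    out[[i]] <- cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]),
                      p1[3] + t * (p2[3] - p1[3]))
  }
  do.call(rbind, out)
}

#' Estimate the optical resolution from an isolated sub-resolution structure
#'
#' Fits a Gaussian plus constant to the lateral (x) and axial (z)
#' intensity profiles through an isolated point- or line-like structure
#' and returns the FWHM (`2 sqrt(2 ln 2) sigma`) per axis.
#'
#' @param vol an [lcn_volume()].
#' @param position_um `(z, y, x)` location of the structure (µm).
#' @param line_axis `"none"` for a point source, else `"z"`, `"y"` or
#'   `"x"`: the profile along the line axis carries no width information
#'   and the corresponding FWHM is `NA`.
#' @return Named numeric `c(fwhm_lateral_um, fwhm_axial_um)`; lateral is
#'   the mean of the available x/y fits.
#' @export
estimate_resolution <- function(vol, position_um, line_axis = c("none", "z", "y", "x")) {
  stopifnot(inherits(vol, "lcn_volume"))
  line_axis <- match.arg(line_axis)
  sp <- vol$voxel_size_um
  d <- dim(vol$data)
  ci <- round(um_to_index(position_um, sp))
  ci <- pmin(pmax(ci, 1), d)
  profs <- list(z = vol$data[, ci[2], ci[3]],
                y = vol$data[ci[1], , ci[3]],
                x = vol$data[ci[1], ci[2], ])
  fit_axis <- function(axis) {
    if (axis == line_axis) return(NA_real_)
    p <- profs[[axis]]
    h <- sp[[axis]]
    s <- (seq_along(p) - 0.5) * h
    c0 <- min(p); a0 <- max(p) - c0
    if (a0 <= 0) return(NA_real_)
    mu0 <- s[which.max(p)]
    sd0 <- max(profile_fwhm(p, h, baseline = c0) / 2.355, h / 2, na.rm = TRUE)
    fit <- tryCatch(
      minpack.lm::nlsLM(p ~ C + A * exp(-(s - mu)^2 / (2 * sg^2)),
                        start = list(C = c0, A = a0, mu = mu0, sg = sd0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # sampling-limited structures (single-voxel spikes) defeat the
      # nonlinear fit; fall back to the interpolated direct FWHM
      return(profile_fwhm(p, h, baseline = c0))
    }
    sg <- abs(coef(fit)[["sg"]])
    fw <- 2 * sqrt(2 * log(2)) * sg
    if (fw > (length(p) * h) / 2) {
      warning(sprintf("fitted FWHM along %s exceeds half the profile length", axis))
      return(NA_real_)
    }
    fw
  }
  lat <- c(fit_axis("y"), fit_axis("x"))
  lat <- lat[!is.na(lat)]
  c(fwhm_lateral_um = if (length(lat)) mean(lat) else NA_real_,
    fwhm_axial_um = fit_axis("z"))
}

#' Lamellar modulation period along a profile
#'
#' Extracts an intensity profile, detrends it by subtracting a moving mean
#' (window twice the largest expected period), and estimates the period as
#' the lag of the first positive-lag autocorrelation maximum, refined by
#' parabolic interpolation. The quoted spread is the standard deviation of
#' successive peak-to-peak distances of the detrended profile.
#'
#' @param vol an [lcn_volume()] (typically SHG).
#' @param start_um profile start `(z, y, x)` in µm.
#' @param direction profile direction `(z, y, x)` (any norm).
#' @param length_um profile length (should cover >= 3 periods).
#' @param max_period_um largest expected period (detrending window is
#'   twice this).
#' @return List of class `lcn_period`: `period_mean_um`, `period_sd_um`,
#'   `aperiodic` flag, `profile`, `spacing_um`.
#' @export
lamellar_period <- function(vol, start_um, direction, length_um,
                            max_period_um = 8) {
  stopifnot(inherits(vol, "lcn_volume"))
  dvec <- direction / sqrt(sum(direction^2))
  sp <- vol$voxel_size_um
  step <- min(sp) / 2
  s <- seq(0, length_um, by = step)
  pts <- outer(s, dvec) + rep(start_um, each = length(s))
  prof <- trilinear(vol$data, sweep(pts, 2, sp, "/") + 0.5)
  # detrend: subtract moving mean over 2 x the largest expected period
  w <- max(3L, round(2 * max_period_um / step))
  if (w %% 2 == 0) w <- w + 1L
  pad <- w %/% 2
  pp <- c(rep(prof[1], pad), prof, rep(prof[length(prof)], pad))
  mov <- stats::filter(pp, rep(1 / w, w), sides = 2)
  trend <- as.numeric(mov)[(pad + 1):(pad + length(prof))]
  det <- prof - trend
  out <- list(period_mean_um = NA_real_, period_sd_um = NA_real_,
              aperiodic = TRUE, profile = prof, detrended = det,
              spacing_um = step)
  class(out) <- "lcn_period"
  if (sd(det) < 1e-12 * max(1, mean(prof))) return(out) # constant profile
  ac <- acf(det, lag.max = min(length(det) - 2, round(2.5 * max_period_um / step)),
            plot = FALSE, demean = TRUE)$acf[, 1, 1]
  pk <- find_peaks(ac[-1], min_prominence = 0.05, min_height = 0.1)
  if (!length(pk$pos)) return(out)
  lag <- refine_peak(ac[-1], pk$pos[1]) # first positive-lag maximum
  out$period_mean_um <- lag * step
  out$aperiodic <- FALSE
  ppk <- find_peaks(det, min_prominence = 0.2 * sd(det))
  if (length(ppk$pos) >= 3) {
    gaps <- diff(vapply(ppk$pos, function(i) refine_peak(det, i), 1)) * step
    out$period_sd_um <- sd(gaps)
  } else out$period_sd_um <- 0
  out
}

#' @export
print.lcn_period <- function(x, ...) {
  if (x$aperiodic) cat("<lcn_period> aperiodic (no autocorrelation maximum)\n")
  else cat(sprintf("<lcn_period> %.2f +/- %.2f um\n", x$period_mean_um, x$period_sd_um))
  invisible(x)
}

#' Correlation coefficient between two images
#'
#' `c(I1, I2) = <(I1 - <I1>)(I2 - <I2>)> / sqrt(<(I1 - <I1>)^2> <(I2 - <I2>)^2>)`
#' with brackets averaging over all voxels: 1 for perfect correlation, -1
#' for perfect anti-correlation, 0 in the absence of correlation.
#'
#' @param vol1,vol2 [lcn_volume()]s or arrays on identical grids, both
#'   non-constant.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' a <- array(runif(27), c(3, 3, 3))
#' image_correlation(a, 2 - a)
#' @export
image_correlation <- function(vol1, vol2) {
  a <- as_volume_array(vol1)
  b <- as_volume_array(vol2)
  if (!identical(dim(a), dim(b))) stop("volumes must share one grid")
  da <- a - mean(a)
  db <- b - mean(b)
  va <- mean(da^2)
  vb <- mean(db^2)
  if (va == 0 || vb == 0) stop("correlation undefined for constant input (zero variance)")
  mean(da * db) / sqrt(va * vb)
}
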