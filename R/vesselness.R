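#' Parameters for the multiscale Hessian vesselness filter
#'
#' @param scales_um Gaussian scales sigma (µm), strictly positive and
#'   sorted; defaults span the canalicular radius.
#' @param alpha plate/line discrimination constant (penalizes sheet-like
#'   structures).
#' @param beta blob discrimination constant.
#' @param c structureness constant in intensity units, or `"auto"` (half
#'   the maximum Frobenius norm of the Hessian at each scale, which makes
#'   the response invariant under global intensity scaling).
#' @param bright_on_dark `TRUE` enhances bright tubes on a dark background.
#' @return An object of class `lcn_vesselness_params`.
#' @export
vesselness_params <- function(scales_um = c(0.2, 0.3, 0.45, 0.68),
                              alpha = 0.5, beta = 0.5, c = "auto",
                              bright_on_dark = TRUE) {
  if (any(scales_um <= 0)) stop("scales must be > 0")
  if (is.unsorted(scales_um)) stop("scales must be sorted increasingly")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (!identical(c, "auto") && (!is.numeric(c) || c <= 0))
    stop("c must be a positive number or \"auto\"")
  structure(list(scales_um = scales_um, alpha = alpha, beta = beta, c = c,
                 bright_on_dark = bright_on_dark),
            class = "lcn_vesselness_params")
}

#' Multiscale Hessian (Frangi) vesselness filter
#'
#' Enhances bright (or dark) tubular structures. At each scale sigma the
#' volume is Gaussian-smoothed, the Hessian computed with physical-unit
#' derivatives and sigma^2 normalization, and its eigenvalues ordered
#' |l1| <= |l2| <= |l3|. The response is zero where `l2 > 0` or `l3 > 0`
#' (for bright tubes) and otherwise
#' `(1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))`
#' with `Ra = |l2|/|l3|`, `Rb = |l1|/sqrt(|l2 l3|)` and
#' `S = sqrt(l1^2 + l2^2 + l3^2)`; the final response is the per-voxel
#' maximum over scales. Anisotropic voxels are handled by computing
#' derivatives in micrometres.
#'
#' @param vol an [lcn_volume()] with at least 5 voxels per axis.
#' @param params an [vesselness_params()] object.
#' @return An [lcn_volume()] holding the vesselness response, with
#'   attribute `"realized_c"` recording the per-scale structureness
#'   constants actually used.
#' @export
vesselness <- function(vol, params = vesselness_params()) {
  stopifnot(inherits(vol, "lcn_volume"))
  d <- dim(vol$data)
  if (any(d < 5)) stop("volume must have at least 5 voxels per axis")
  if (any(params$scales_um < min(vol$voxel_size_um) - 1e-9))
    warning("scales below the voxel size are under-resolved")
  a <- vol$data
  if (!params$bright_on_dark) a <- max(a) - a
  sp <- vol$voxel_size_um
  resp <- array(0, d)
  realized_c <- numeric(length(params$scales_um))
  for (si in seq_along(params$scales_um)) {
    sg <- params$scales_um[si]
    sm <- gauss_smooth3(a, sg, sp)
    hm <- .hessian_measures(as.numeric(sm), d, sp, sg)
    # auto c: half the strong-structure Frobenius norm. A high quantile of
    # the positive norms rather than the absolute maximum: the maximum
    # grows with volume size (extreme-value effect) and with any single
    # bright object, which would depress the response of every tube.
    cc <- if (identical(params$c, "auto")) {
      # restrict to tube-like voxels (tube eigenvalue signs, Ra > 0.5):
      # plate-like populations (lacuna shells) and lone bright objects
      # would otherwise set the scale and depress every tube response
      sp_pos <- hm$s[hm$tube & hm$ra > 0.5]
      sp_pos <- sp_pos[sp_pos > 0]
      if (length(sp_pos)) as.numeric(quantile(sp_pos, 0.995)) / 2
      else {
        sp_all <- hm$s[hm$s > 0]
        if (length(sp_all)) as.numeric(quantile(sp_all, 0.995)) / 2 else 0
      }
    } else params$c
    realized_c[si] <- cc
    if (cc <= 0) next # zero-variance volume: response stays 0
    r <- (1 - exp(-hm$ra^2 / (2 * params$alpha^2))) *
      exp(-hm$rb^2 / (2 * params$beta^2)) *
      (1 - exp(-hm$s^2 / (2 * cc^2)))
    r[!hm$tube] <- 0
    resp <- pmax(resp, array(r, d))
  }
  out <- vol
  out$data <- resp
  attr(out, "realized_c") <- realized_c
  out
}
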