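#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy restoration for Poisson-noise
#' imaging, iterated from a flat positive initialization. Boundary handling
#' is reflective, which keeps the total intensity conserved to well below
#' 0.1 % relative. Deconvolution sharpens the double-edge canalicular
#' signature of THG stacks before vesselness filtering.
#'
#' @param vol an [lcn_volume()] (non-negative).
#' @param psf an `lcn_psf` (normalized, non-negative kernel).
#' @param n_iterations number of multiplicative updates (>= 1). The number
#'   of iterations trades contrast against noise amplification; 20 is
#'   stable on phantom data.
#' @return The restored [lcn_volume()].
#' @examples
#' v <- lcn_volume(array(runif(4^3) + 1, c(4, 4, 4)), 0.2)
#' delta <- psf_model(array(1, c(1, 1, 1)), 0.2)
#' r <- richardson_lucy(v, delta, 5)
#' max(abs(r$data - v$data))
#' @export
richardson_lucy <- function(vol, psf, n_iterations = 20L) {
  stopifnot(inherits(vol, "lcn_volume"), inherits(psf, "lcn_psf"))
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (any(psf$kernel < 0) || sum(psf$kernel) <= 0)
    stop("PSF kernel must be non-negative with positive sum")
  y <- vol$data
  if (all(y == 0)) return(vol)
  if (!is.null(psf$sep)) {
    # separable symmetric kernel: full iteration loop in compiled code
    x <- array(.rl_sep(as.numeric(y), dim(y), psf$sep$kz, psf$sep$ky,
                       psf$sep$kx, as.integer(n_iterations), mean(y)),
               dim(y))
  } else {
    eps <- 1e-12
    x <- array(mean(y), dim(y))
    for (it in seq_len(n_iterations)) {
      est <- conv3_psf(x, psf)
      ratio <- y / pmax(est, eps)
      x <- x * conv3_psf(ratio, psf, correlate = TRUE)
      x[x < 0] <- 0
    }
  }
  out <- vol
  out$data <- x
  out
}

# Poisson log-likelihood of observing y under blurred estimate (up to the
# y-dependent constant); used to assert RL monotonicity on test instances.
rl_poisson_loglik <- function(y, x, psf) {
  mu <- pmax(conv3_psf(x, psf), 1e-12)
  sum(y * log(mu) - mu)
}
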