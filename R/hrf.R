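#' Canonical double-gamma hemodynamic response parameters
#'
#' The kernel is a difference of two gamma densities parameterized by their
#' modes: the response peaks `peak_delay` seconds after neural onset and the
#' undershoot trough lies at `undershoot_delay` seconds, with peak-to-
#' undershoot amplitude ratio `ratio`.  Defaults follow the canonical shape
#' used throughout fMRI analysis (peak 6 s, undershoot 16 s, ratio 6:1).
#'
#' @param peak_delay Mode of the positive lobe, seconds.
#' @param peak_dispersion Dispersion (gamma scale) of the positive lobe.
#' @param undershoot_delay Mode of the undershoot lobe, seconds.
#' @param undershoot_dispersion Dispersion of the undershoot lobe.
#' @param ratio Peak:undershoot amplitude ratio.
#' @return A list of HRF parameters.
#' @export
hrf_parameters <- function(peak_delay = 6, peak_dispersion = 1,
                           undershoot_delay = 16, undershoot_dispersion = 1,
                           ratio = 6) {
  p <- list(peak_delay = peak_delay, peak_dispersion = peak_dispersion,
            undershoot_delay = undershoot_delay,
            undershoot_dispersion = undershoot_dispersion, ratio = ratio)
  if (any(unlist(p) <= 0)) stop("all HRF shape parameters must be positive")
  if (undershoot_delay <= peak_delay) {
    stop("undershoot_delay must exceed peak_delay")
  }
  p
}

#' Sample a double-gamma HRF kernel on a regular grid
#'
#' The kernel is evaluated on `seq(0, duration, by = grid_step)` and scaled
#' so its maximum equals `amplitude`.  With the gamma lobes parameterized by
#' their modes, the kernel maximum sits at `peak_delay` (within one grid
#' step) and a negative undershoot follows the peak.
#'
#' @param grid_step Grid spacing in seconds.
#' @param params HRF parameters from [hrf_parameters()].
#' @param duration Kernel support in seconds; the canonical kernel has
#'   decayed to ~0 by 32 s.
#' @param amplitude Peak amplitude of the returned kernel.
#' @return Numeric vector of kernel samples with attribute `"times"`.
#' @export
hrf_kernel <- function(grid_step = 0.1, params = hrf_parameters(),
                       duration = 32, amplitude = 1) {
  stopifnot(grid_step > 0, duration > 0)
  t <- seq(0, duration, by = grid_step)
  shape1 <- params$peak_delay / params$peak_dispersion + 1
  shape2 <- params$undershoot_delay / params$undershoot_dispersion + 1
  h <- dgamma(t, shape = shape1, rate = 1 / params$peak_dispersion) -
    dgamma(t, shape = shape2, rate = 1 / params$undershoot_dispersion) /
      params$ratio
  h <- h / max(h) * amplitude
  attr(h, "times") <- t
  h
}

# Convolve a neural indicator sampled on a fine grid with the HRF kernel,
# returning a series of the same length (causal convolution, grid-step
# scaled so the result approximates the continuous-time integral).
convolve_hrf <- function(neural, grid_step, params) {
  k <- hrf_kernel(grid_step = grid_step, params = params)
  out <- stats::convolve(neural, rev(k), type = "open")[seq_along(neural)]
  out * grid_step
}
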