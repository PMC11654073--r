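#' Double-gamma hemodynamic response function
#'
#' Canonical double-gamma HRF: a gamma-density peak minus a later, wider
#' gamma-density undershoot scaled by `1/undershoot_ratio`, sampled on a
#' fine time grid and normalized to a peak amplitude of 1. With the default
#' parameters the response peaks near 5 s and the undershoot near 15 s.
#'
#' @param dt_s sampling step of the kernel grid in seconds.
#' @param duration_s kernel length in seconds; must cover the undershoot
#'   (at least 28 s).
#' @param peak_delay_s,peak_disp_s gamma delay (shape x scale) and dispersion
#'   (scale) of the positive lobe, seconds.
#' @param undershoot_delay_s,undershoot_disp_s same for the undershoot lobe.
#' @param undershoot_ratio peak-to-undershoot amplitude ratio.
#'
#' @return An object of class `hrf_kernel`: list with `dt_s`, `values`
#'   (kernel samples at `t = 0, dt_s, 2*dt_s, ...`), and `params`.
#' @export
double_gamma_hrf <- function(dt_s = 0.1, duration_s = 32,
                             peak_delay_s = 6, peak_disp_s = 1,
                             undershoot_delay_s = 16, undershoot_disp_s = 1,
                             undershoot_ratio = 6) {
  assert_scalar_positive(dt_s, "dt_s")
  assert_scalar_positive(peak_delay_s, "peak_delay_s")
  assert_scalar_positive(peak_disp_s, "peak_disp_s")
  assert_scalar_positive(undershoot_delay_s, "undershoot_delay_s")
  assert_scalar_positive(undershoot_disp_s, "undershoot_disp_s")
  assert_scalar_positive(undershoot_ratio, "undershoot_ratio")
  if (duration_s < 28) stop("duration_s must be at least 28 s", call. = FALSE)

  t <- seq(0, duration_s, by = dt_s)
  h <- stats::dgamma(t, shape = peak_delay_s / peak_disp_s, scale = peak_disp_s) -
    stats::dgamma(t, shape = undershoot_delay_s / undershoot_disp_s,
                  scale = undershoot_disp_s) / undershoot_ratio
  h <- h / max(h)
  structure(
    list(dt_s = dt_s, values = h,
         params = list(peak_delay_s = peak_delay_s, peak_disp_s = peak_disp_s,
                       undershoot_delay_s = undershoot_delay_s,
                       undershoot_disp_s = undershoot_disp_s,
                       undershoot_ratio = undershoot_ratio),
         duration_s = duration_s),
    class = "hrf_kernel"
  )
}
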