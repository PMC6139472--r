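#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF -- the difference of two gamma densities, with a
#' positive response peaking near 5 s and a later undershoot -- at the run's
#' repetition time. The kernel is normalized to unit sum, so convolution
#' preserves the scale of sustained signals.
#'
#' @param tr sampling interval in seconds (must be positive).
#' @param peak_delay delay of the response gamma in seconds (default 6).
#' @param undershoot_delay delay of the undershoot gamma in seconds
#'   (default 16).
#' @param peak_disp dispersion of the response gamma (default 1).
#' @param undershoot_disp dispersion of the undershoot gamma (default 1).
#' @param ratio response-to-undershoot amplitude ratio (default 6).
#' @param duration kernel length in seconds (default 32; samples run from 0 to
#'   `duration` inclusive).
#' @return an object of class `fc_hrf`: list with `values` (the sampled
#'   kernel), `tr`, `times`, and the parameters.
#' @examples
#' h <- canonical_hrf(tr = 2)
#' length(h$values)  # 17 samples, 0..32 s
#' @export
canonical_hrf <- function(tr, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          ratio = 6, duration = 32) {
  if (!is.numeric(tr) || length(tr) != 1 || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a positive number")
  t <- seq(0, duration, by = tr)
  h <- dgamma(t, shape = peak_delay / peak_disp, rate = 1 / peak_disp) -
    dgamma(t, shape = undershoot_delay / undershoot_disp,
           rate = 1 / undershoot_disp) / ratio
  s <- sum(h)
  if (!is.finite(s) || s <= 0) stop("degenerate HRF parameterization: kernel sum not positive")
  structure(
    list(values = h / s, tr = tr, times = t,
         params = list(peak_delay = peak_delay,
                       undershoot_delay = undershoot_delay,
                       peak_disp = peak_disp,
                       undershoot_disp = undershoot_disp,
                       ratio = ratio, duration = duration)),
    class = "fc_hrf")
}

# Accept either an fc_hrf or a bare numeric kernel.
hrf_values <- function(hrf) {
  if (inherits(hrf, "fc_hrf")) hrf$values else as.numeric(hrf)
}

#' @export
print.fc_hrf <- function(x, ...) {
  cat(sprintf("Canonical double-gamma HRF: %d samples at TR = %g s (0..%g s)\n",
              length(x$values), x$tr, max(x$times)))
  invisible(x)
}
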