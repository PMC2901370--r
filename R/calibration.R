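#' Washing-corrected calibration of probe intensities
#'
#' Inverts the washed adsorption isotherm to convert a net intensity into
#' the specific binding strength. Working in washed (apparent) strengths
#' `X(t) = X * w(t)` with `y = I / M`:
#' \deqn{X_S(t) = \frac{y (1 + X_N(t)/w_N) - X_N(t)}{1 - y / w_S}}
#' The Langmuir estimate neglects washing (`w = 1` throughout):
#' \deqn{X_S(t)_{Langmuir} = \frac{y (1 + X_N(t)) - X_N(t)}{1 - y}}
#' and the reported bias `log10 X_Langmuir - log10 X_washed` is negative:
#' neglecting washing underestimates the binding strength, most strongly at
#' both ends of the expression range.
#'
#' @param I net intensity (vectorized), `0 < I < M`.
#' @param M saturation intensity.
#' @param logX_N log10 apparent (washed) non-specific binding strength of
#'   the probe (what the hook width reports; see [probe_background()]).
#' @param w_S,w_N survival fractions of the specific and non-specific
#'   duplexes; either scalars or vectors along `I`.
#' @return data.frame of class `calibration_result`: `logX_S_washed` (the
#'   washed specific strength `log10 X_S w_S`), `logX_S` (the unwashed
#'   strength `log10 X_S`), `logX_S_langmuir`, `bias`, and `clipped` (TRUE
#'   where a negative strength was clipped to zero, reported as `-Inf`).
#' @examples
#' # washing-free limit: washed and Langmuir estimates coincide
#' calibrate_probe(1000, 10^4.5, -2.5, w_S = 1, w_N = 1)
#' @export
calibrate_probe <- function(I, M, logX_N, w_S = 0.95, w_N = 0.1) {
  if (any(I <= 0)) stop("net intensity must be positive")
  if (any(I >= M)) stop("saturation: I must lie below M")
  if (any(w_S <= 0 | w_S > 1) || any(w_N <= 0 | w_N > 1))
    stop("survival fractions must lie in (0, 1]")
  y <- I / M
  if (any(y >= w_S))
    stop("saturation: I/M must lie below the specific survival w_S")
  X_Nt <- 10^logX_N
  X_St <- (y * (1 + X_Nt / w_N) - X_Nt) / (1 - y / w_S)
  X_L <- (y * (1 + X_Nt) - X_Nt) / (1 - y)
  clipped <- X_St <= 0 | X_L <= 0
  X_St <- pmax(X_St, 0)
  X_L <- pmax(X_L, 0)
  out <- data.frame(logX_S_washed = log10(X_St),
                    logX_S = log10(X_St / w_S),
                    logX_S_langmuir = log10(X_L),
                    bias = log10(X_L) - log10(X_St),
                    clipped = clipped)
  class(out) <- c("calibration_result", class(out))
  out
}

#' Occupancy-driven washing function
#'
#' The sigmoidal survival model takes the intensity before washing as its
#' argument, but a calibrated experiment only observes washed intensities.
#' Substituting `I(0) = I(t) / w` into the survival function yields the
#' implicit equation `w = f(I(t)/w)`, solved here for the survival as a
#' function of the washed occupancy `theta = I(t)/M`:
#' `w = w_min + (w_max - w_min) exp(-(a'(w - theta)/theta)^gamma)`.
#' The root is unique on `[theta, w_max]` and is found to `tol` by damped
#' fixed-point iteration with a bracketing (bisection-type) fallback.
#'
#' @param theta washed occupancy in `(0, 1)`; values at or above `w_max`
#'   return `w_max` (fully resistant probes).
#' @param wp a [washing_params()].
#' @param t washing cycles of the protocol (default 6, the standard
#'   fluidics script); scales `a' = a t^(1/gamma)`.
#' @param tol convergence tolerance (default 1e-10).
#' @return Survival fraction(s), monotone increasing in `theta`.
#' @export
occupancy_washing_function <- function(theta, wp, t = 6, tol = 1e-10) {
  stopifnot(inherits(wp, "washing_params"))
  if (any(theta <= 0) || any(theta >= 1)) stop("theta must lie in (0, 1)")
  ap <- a_prime_at(wp, t)
  vapply(theta, function(th) {
    if (th >= wp$w_max) return(wp$w_max)
    f <- function(w) wp$w_min + (wp$w_max - wp$w_min) *
      exp(-(ap * (w - th) / th)^wp$gamma)
    lo <- max(wp$w_min, th); hi <- wp$w_max
    w <- hi
    for (i in seq_len(200L)) {
      w_new <- 0.5 * (w + f(w))                  # damped fixed point
      if (w_new < lo) w_new <- lo
      if (abs(w_new - w) < tol) return(w_new)
      w <- w_new
    }
    root <- stats::uniroot(function(w) w - f(w), c(lo, hi),
                           tol = tol, extendInt = "no")
    root$root
  }, numeric(1L))
}

#' Estimate the saturation intensity from the brightest PM probes
#'
#' The brightest probes of a chip almost completely resist washing and are
#' assumed saturated, so the mean of their logged intensities estimates
#' `log10 M`. A few tens of probes suffice; the estimate typically lies at
#' or slightly above the hook-fitted `logM`.
#'
#' @param series a `chip_series`.
#' @param n_top number of brightest PM probes to average (20 to 100).
#' @param timepoint timepoint whose intensities are used (default 0).
#' @param hook_logM optional hook-fitted `logM`; a warning is emitted when
#'   the bright-probe estimate falls below it (suggesting no saturated
#'   probes are present and the estimate is biased low).
#' @return `log10` saturation estimate.
#' @export
estimate_logM <- function(series, n_top = 50L, timepoint = 0,
                          hook_logM = NULL) {
  stopifnot(inherits(series, "chip_series"))
  if (n_top < 20L || n_top > 100L) stop("n_top must lie in [20, 100]")
  col <- paste0("I_t", timepoint)
  ipm <- series$intensities[series$probes$probe_type == "PM", col]
  ipm <- ipm[ipm > 0]
  if (length(ipm) < n_top) stop("fewer positive PM probes than n_top")
  est <- mean(log10(sort(ipm, decreasing = TRUE)[seq_len(n_top)]))
  if (!is.null(hook_logM) && est < hook_logM)
    warning(sprintf(
      "bright-probe logM %.3f below hook logM %.3f: no saturated probes; estimate biased low",
      est, hook_logM))
  est
}

#' Probe-specific non-specific background strengths
#'
#' Combines the hook-level mean background, `<log X_N(t)> = Sigma_start -
#' logM = -beta`, with the sequence-specific increment predicted by the
#' N-ensemble sensitivity profile. Predictions are centered over the
#' supplied sequences so that their mean reproduces the hook-level mean
#' exactly.
#'
#' @param fit a `hook_fit`.
#' @param profile N-ensemble `sensitivity_profile` (or `NULL` for a flat
#'   background).
#' @param sequences probe 25-mers.
#' @return Numeric vector of per-probe `log10 X_N(t)`.
#' @export
probe_background <- function(fit, profile, sequences) {
  mean_level <- fit$sigma_start - fit$logM
  if (is.null(profile)) return(rep(mean_level, length(sequences)))
  inc <- predict_delta_logI(sequences, profile)
  mean_level + inc - mean(inc)
}
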