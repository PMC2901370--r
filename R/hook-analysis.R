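#' Set-level hook coordinates from probe intensities
#'
#' Transforms PM/MM probe intensities at one wash timepoint into the hook
#' (difference-versus-sum) coordinates, averaging over the pairs of each
#' probe set: `Delta = <log10 I_PM - log10 I_MM>` and
#' `Sigma = 1/2 <log10 I_PM + log10 I_MM>`. Pairs with a non-positive
#' intensity are excluded (with a warning when more than 1 percent drop out).
#'
#' @param series a `chip_series`.
#' @param timepoint washing-cycle count; must be one of `series$timepoints`.
#' @return data.frame of class `hook_points` with `set_id`, `sigma`, `delta`
#'   and `n_pairs` (pairs used).
#' @export
sigma_delta <- function(series, timepoint) {
  stopifnot(inherits(series, "chip_series"))
  col <- paste0("I_t", timepoint)
  if (!col %in% colnames(series$intensities))
    stop(sprintf("timepoint %s not present (have: %s)", timepoint,
                 paste(series$timepoints, collapse = ", ")))
  p <- series$probes
  I <- series$intensities[, col]
  key <- paste(p$set_id, p$pair_index)
  pm <- p$probe_type == "PM"
  pm_idx <- which(pm)
  mm_idx <- which(!pm)[match(key[pm_idx], key[!pm])]
  if (anyNA(mm_idx)) stop("PM/MM pairing incomplete")
  ipm <- I[pm_idx]; imm <- I[mm_idx]
  ok <- ipm > 0 & imm > 0
  n_bad <- sum(!ok)
  if (n_bad > 0.01 * length(ok))
    warning(sprintf("%d of %d pairs excluded for non-positive intensity",
                    n_bad, length(ok)))
  lpm <- log10(ipm[ok]); lmm <- log10(imm[ok])
  sid <- factor(p$set_id[pm_idx][ok], levels = unique(p$set_id))
  delta <- tapply(lpm - lmm, sid, mean)
  sigma <- tapply((lpm + lmm) / 2, sid, mean)
  n_pairs <- tapply(lpm, sid, length)
  keep <- !is.na(sigma)
  out <- data.frame(set_id = names(sigma)[keep],
                    sigma = as.numeric(sigma[keep]),
                    delta = as.numeric(delta[keep]),
                    n_pairs = as.integer(n_pairs[keep]),
                    stringsAsFactors = FALSE)
  class(out) <- c("hook_points", class(out))
  out
}

.roll_mean <- function(x, window) {
  n <- length(x)
  if (window <= 1L) return(x)
  cs <- cumsum(c(0, x))
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

#' Smooth hook points into a hook curve
#'
#' Orders the points by `sigma` and applies a moving average of `window`
#' consecutive sets to both coordinates. The smoothed abscissa is monotone.
#'
#' @param points a `hook_points` data.frame.
#' @param window moving-average window (number of sets, default 100).
#' @return data.frame of class `hook_curve` with `sigma`, `delta`.
#' @export
smooth_hook <- function(points, window = 100L) {
  if (nrow(points) < window)
    stop(sprintf("need at least %d points for window %d", window, window))
  ord <- order(points$sigma)
  s <- points$sigma[ord]; d <- points$delta[ord]
  out <- data.frame(sigma = .roll_mean(s, window),
                    delta = .roll_mean(d, window))
  class(out) <- c("hook_curve", class(out))
  out
}

#' Theoretical hook coordinates as a function of the S/N ratio
#'
#' Evaluates the model hook at set-level S/N ratios `R`. In `"standard"`
#' mode the washed binding strengths obey the hyperbolic isotherm (washing
#' folded into numerator and denominator alike); in `"exact"` mode the
#' denominator keeps the unwashed equilibrium strengths, which requires the
#' mode-specific survival fractions in `washing`. Parameters: `sigma_start`
#' and `delta_start` (start coordinates), `alpha` (height: log10 PM/MM gain
#' after washing) and `beta` (width: `logM = sigma_start + beta`).
#'
#' @param R S/N ratios (of the PM probes, after washing), `>= 0`.
#' @param params list or `hook_fit` with `sigma_start`, `delta_start`,
#'   `alpha`, `beta`.
#' @param washing list `w_PM_S`, `w_MM_S`, `w_N` (exact mode only).
#' @param mode `"standard"` or `"exact"`.
#' @return data.frame `R`, `sigma`, `delta`. Limits: `R = 0` gives the start
#'   coordinates; `R -> Inf` gives `sigma = logM + log10(w_PM_S *
#'   w_MM_S)/2`, `delta = delta_start + log10(w_PM_S / w_MM_S)` (exact) or
#'   `logM`, `delta_start` (standard).
#' @export
hook_theory <- function(R, params, washing = NULL,
                        mode = c("standard", "exact")) {
  mode <- match.arg(mode)
  if (any(R < 0)) stop("R must be non-negative")
  x <- 10^(-params$beta)
  q <- 10^(-params$alpha)
  logM <- params$sigma_start + params$beta
  num_pm <- x * (1 + R)
  num_mm <- x * (1 + R * q)
  if (mode == "standard") {
    th_pm <- num_pm / (1 + num_pm)
    th_mm <- num_mm / (1 + num_mm)
  } else {
    w <- washing
    if (is.null(w) || anyNA(match(c("w_PM_S", "w_MM_S", "w_N"), names(w))))
      stop("exact mode needs washing = list(w_PM_S, w_MM_S, w_N)")
    alpha0 <- params$alpha - log10(w$w_PM_S / w$w_MM_S)
    X_N <- x / w$w_N
    X_S_pm <- R * x / w$w_PM_S
    X_S_mm <- X_S_pm * 10^(-alpha0)
    th_pm <- num_pm / (1 + X_N + X_S_pm)
    th_mm <- num_mm / (1 + X_N + X_S_mm)
  }
  l_pm <- logM + log10(th_pm) + params$delta_start / 2
  l_mm <- logM + log10(th_mm) - params$delta_start / 2
  data.frame(R = R, sigma = (l_pm + l_mm) / 2, delta = l_pm - l_mm)
}

.hook_start_guess <- function(curve) {
  qs <- stats::quantile(curve$sigma, c(0.02, 0.05))
  left <- curve$delta[curve$sigma <= qs[2L]]
  list(sigma_start = as.numeric(qs[1L]),
       delta_start = stats::median(left))
}

#' Fit the theoretical hook to a smoothed curve
#'
#' Estimates the four geometry parameters (`sigma_start`, `delta_start`,
#' `alpha`, `beta`) by nonlinear least squares: for candidate parameters the
#' theory curve is evaluated on a dense `R` grid and interpolated onto the
#' observed abscissa, and the `delta` residuals are minimized with
#' Levenberg-Marquardt. Start coordinates are initialized from the
#' lower-percentile plateau of the curve. The end-level `delta_end` (the
#' PM/MM log-ratio of surviving saturation intensities) is estimated
#' empirically from the upper tail of the curve.
#'
#' @param curve a `hook_curve` (see [smooth_hook()]); `hook_points` are
#'   accepted and smoothed with the default window.
#' @param mode `"standard"` (hyperbolic isotherm, default) or `"exact"`
#'   (full washed isotherm; requires `washing`).
#' @param washing survival fractions for exact mode, see [hook_theory()].
#' @param end_quantile upper `sigma` quantile defining the end-level
#'   estimate (default 0.99).
#' @param min_height minimum curve height for a fit; below it the chip is
#'   flagged as having no specific branch.
#' @return Object of class `hook_fit`: the fitted parameters plus `logM =
#'   sigma_start + beta`, `delta_end`, residual `rms`, `converged`, `flags`,
#'   and the data `curve`.
#' @export
fit_hook <- function(curve, mode = c("standard", "exact"), washing = NULL,
                     end_quantile = 0.99, min_height = 0.1) {
  mode <- match.arg(mode)
  if (inherits(curve, "hook_points") && !inherits(curve, "hook_curve"))
    curve <- smooth_hook(curve)
  st <- .hook_start_guess(curve)
  height <- max(curve$delta) - st$delta_start
  top <- curve$sigma >= stats::quantile(curve$sigma, end_quantile)
  # empirical anchors: quantile statistics of the curve ends; immune to
  # compromises of the global fit, hence preferred for kinetic slopes
  anchors <- list(sigma_start_emp = st$sigma_start,
                  delta_start_emp = st$delta_start,
                  sigma_end_emp = mean(curve$sigma[top]),
                  delta_end = mean(curve$delta[top]))
  if (height < min_height) {
    out <- c(list(sigma_start = st$sigma_start,
                  delta_start = st$delta_start,
                  alpha = 0, beta = NA_real_, logM = NA_real_),
             anchors,
             list(mode = mode, washing = washing,
                  rms = NA_real_, converged = FALSE,
                  flags = "no specific branch", curve = curve))
    class(out) <- "hook_fit"
    return(out)
  }
  R_grid <- 10^seq(-2.5, 6, length.out = 400L)
  resid_fun <- function(p) {
    pars <- list(sigma_start = p[1L], delta_start = p[2L],
                 alpha = p[3L], beta = p[4L])
    th <- hook_theory(R_grid, pars, washing = washing, mode = mode)
    pred <- stats::approx(th$sigma, th$delta, xout = curve$sigma,
                          rule = 2L)$y
    curve$delta - pred
  }
  p0 <- c(st$sigma_start, st$delta_start, max(height, 0.2),
          max(max(curve$sigma) - st$sigma_start, 0.5))
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun,
    lower = c(-Inf, -Inf, 0.01, 0.2),
    upper = c(Inf, Inf, 5, 8),
    control = minpack.lm::nls.lm.control(maxiter = 200L))
  p <- fit$par
  logM <- p[1L] + p[4L]
  # the non-specific cloud constrains the start only through its centroid
  # (its delta residuals are flat there), so the reported start abscissa and
  # width are re-expressed against the delta ~ 0 plateau centroid while the
  # saturation level comes from the shape fit
  plateau <- curve$delta < st$delta_start + 0.1 * height
  sigma_anchor <- if (sum(plateau) >= 5L) mean(curve$sigma[plateau])
                  else p[1L]
  out <- c(list(sigma_start = sigma_anchor, delta_start = p[2L],
                alpha = p[3L], beta = logM - sigma_anchor, logM = logM),
           anchors,
           list(mode = mode, washing = washing,
                rms = sqrt(mean(fit$fvec^2)),
                converged = fit$info %in% 1:3,
                flags = character(0), curve = curve))
  if (!out$converged)
    out$flags <- sprintf("nls.lm info %d: %s", fit$info, fit$message)
  class(out) <- "hook_fit"
  out
}

#' @export
print.hook_fit <- function(x, ...) {
  cat(sprintf(
    paste0("hook_fit (%s): Sigma_start = %.3f, Delta_start = %.3f, ",
           "alpha = %.3f, beta = %.3f, logM = %.3f, Delta_end = %.3f, ",
           "rms = %.4f%s\n"),
    x$mode, x$sigma_start, x$delta_start, x$alpha, x$beta, x$logM,
    x$delta_end, x$rms,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
    else ""))
  invisible(x)
}

#' Per-set S/N ratios from the hook geometry
#'
#' Inverts the saturation-free hook height relation
#' `Delta - Delta_start = log10((1 + R) / (1 + R 10^-alpha))` for each set:
#' `R = (d - 1) / (1 - d 10^-alpha)` with `d = 10^(Delta - Delta_start)`.
#' Sets below the start level give `R = 0`; sets at or above the maximum
#' height are clipped to `R_max` and flagged.
#'
#' @param points `hook_points` (per-set, unsmoothed).
#' @param fit a `hook_fit`.
#' @param R_max clipping value for non-invertible sets (default 1e6).
#' @return list with `snr` (data.frame `set_id`, `R`, `flagged`), `mean_R`
#'   (mean over unflagged sets with `R > 1`), `phi` (mean `log10 R` over the
#'   same sets) and `n_flagged`.
#' @export
per_set_snr <- function(points, fit, R_max = 1e6) {
  d <- 10^(points$delta - fit$delta_start)
  q <- 10^(-fit$alpha)
  denom <- 1 - d * q
  R <- ifelse(d <= 1, 0, (d - 1) / denom)
  flagged <- d > 1 & denom <= 0
  R[flagged] <- R_max
  R <- pmin(pmax(R, 0), R_max)
  sel <- !flagged & R > 1
  list(snr = data.frame(set_id = points$set_id, R = R, flagged = flagged,
                        stringsAsFactors = FALSE),
       mean_R = mean(R[sel]),
       phi = mean(log10(R[sel])),
       n_flagged = sum(flagged))
}

#' Classify probe sets into hybridization regimes
#'
#' Labels each set N / mix / S / sat / as using its inverted S/N ratio and
#' its apparent PM occupancy `10^(sigma + delta/2 - logM)`: `N` for
#' `R < R_lo`, `mix` for `R_lo <= R <= R_hi`, and for `R > R_hi` the labels
#' `S`, `sat`, `as` as the occupancy passes `sat_occupancy` and
#' `as_occupancy`. The partition is invariant under uniform intensity
#' rescaling (which shifts `sigma` and `logM` alike).
#'
#' @param points `hook_points`.
#' @param fit a `hook_fit`.
#' @param R_lo,R_hi S/N boundaries of the non-specific and specific
#'   ensembles (defaults 0.1 and 10).
#' @param sat_occupancy,as_occupancy PM-occupancy boundaries of the sat and
#'   asymptotic ranges (defaults 0.5, 0.9).
#' @return list with `labels` (factor per set), `snr`, and `breakpoints`
#'   (the `sigma` range of each occupied regime).
#' @export
classify_regimes <- function(points, fit, R_lo = 0.1, R_hi = 10,
                             sat_occupancy = 0.5, as_occupancy = 0.9) {
  snr <- per_set_snr(points, fit)
  R <- snr$snr$R
  occ <- 10^(points$sigma + points$delta / 2 - fit$logM)
  lab <- rep("mix", nrow(points))
  lab[R < R_lo] <- "N"
  lab[R > R_hi] <- "S"
  # saturation overrides the R label: the height inversion is blind to it
  lab[occ > sat_occupancy & R >= R_lo] <- "sat"
  lab[occ > as_occupancy & R >= R_lo] <- "as"
  lab <- factor(lab, levels = c("N", "mix", "S", "sat", "as"))
  bp <- lapply(split(points$sigma, lab), function(s)
    if (length(s)) range(s) else c(NA_real_, NA_real_))
  list(labels = stats::setNames(lab, points$set_id), snr = snr$snr,
       breakpoints = bp)
}

#' Select the non-specific and specific probe-set ensembles
#'
#' @param regimes result of [classify_regimes()].
#' @return list `N_sets` (labelled N) and `S_sets` (labelled S or sat).
#' @export
select_ensembles <- function(regimes) {
  lab <- regimes$labels
  list(N_sets = names(lab)[lab == "N"],
       S_sets = names(lab)[lab %in% c("S", "sat")])
}

#' Hook representation of the asymptotic washing level
#'
#' Builds the "washing hook": the set-level PM/MM log-ratio of asymptotic
#' survival fractions, `Delta_w = log10(w_inf_PM / w_inf_MM)`, against the
#' intensity abscissa `Sigma`, smoothed like the intensity hook. Sets with a
#' non-positive survival are excluded.
#'
#' @param w_inf_PM,w_inf_MM per-set asymptotic survival fractions.
#' @param sigma per-set hook abscissa (same order).
#' @param window moving-average window.
#' @return data.frame of class `hook_curve` with `sigma`, `delta` (=
#'   `Delta_w`).
#' @export
wash_level_hook <- function(w_inf_PM, w_inf_MM, sigma, window = 100L) {
  ok <- w_inf_PM > 0 & w_inf_MM > 0 & is.finite(sigma)
  pts <- data.frame(set_id = seq_along(sigma)[ok], sigma = sigma[ok],
                    delta = log10(w_inf_PM[ok] / w_inf_MM[ok]))
  class(pts) <- c("hook_points", class(pts))
  smooth_hook(pts, window = window)
}

#' Theoretical washing hook from mode-weighted survival averages
#'
#' Approximates the asymptotic washing level of each probe type as the
#' weighted average of its specific and non-specific survival,
#' `w_inf^P = x^P W_S^P + (1 - x^P) W_N` with weight
#' `x^P = (R^P / (1 + R^P))^gamma_f`, and `R^MM = R^PM 10^-alpha0`. The
#' curve has its maximum left of the intensity-hook maximum and a finite
#' positive asymptote `log10(W_S_PM / W_S_MM)` at `R -> Inf`.
#'
#' @param R PM S/N ratios, `>= 0`.
#' @param alpha0 log10 PM/MM specific-affinity gain (before washing).
#' @param W_S_PM,W_S_MM,W_N asymptotic survival fractions of PM-specific,
#'   MM-specific and non-specific duplexes.
#' @param gamma_f weighting exponent (default 1.5).
#' @return data.frame `R`, `w_inf_PM`, `w_inf_MM`, `delta_w`.
#' @export
wash_level_theory <- function(R, alpha0, W_S_PM, W_S_MM, W_N,
                              gamma_f = 1.5) {
  if (any(R < 0)) stop("R must be non-negative")
  x_pm <- (R / (1 + R))^gamma_f
  R_mm <- R * 10^(-alpha0)
  x_mm <- (R_mm / (1 + R_mm))^gamma_f
  w_pm <- x_pm * W_S_PM + (1 - x_pm) * W_N
  w_mm <- x_mm * W_S_MM + (1 - x_mm) * W_N
  data.frame(R = R, w_inf_PM = w_pm, w_inf_MM = w_mm,
             delta_w = log10(w_pm / w_mm))
}

#' Run the hook analysis at several wash timepoints
#'
#' Convenience pipeline: for each requested timepoint computes the hook
#' points, smooths them, fits the hook and inverts per-set S/N ratios.
#'
#' @param series a `chip_series`.
#' @param timepoints subset of `series$timepoints` (default: all).
#' @param window smoothing window.
#' @param mode fit mode, see [fit_hook()].
#' @param washing per-timepoint list of survival fractions for exact mode.
#' @return Object of class `hook_series`: lists `points`, `curves`, `fits`,
#'   `snr` indexed by timepoint, plus `timepoints`.
#' @export
hook_at_timepoints <- function(series, timepoints = series$timepoints,
                               window = 100L,
                               mode = c("standard", "exact"),
                               washing = NULL) {
  mode <- match.arg(mode)
  nm <- paste0("t", timepoints)
  points <- curves <- fits <- snr <- stats::setNames(
    vector("list", length(timepoints)), nm)
  for (i in seq_along(timepoints)) {
    pts <- sigma_delta(series, timepoints[i])
    crv <- smooth_hook(pts, window = window)
    fit <- fit_hook(crv, mode = mode, washing = washing[[nm[i]]])
    points[[i]] <- pts
    curves[[i]] <- crv
    fits[[i]] <- fit
    snr[[i]] <- per_set_snr(pts, fit)
  }
  structure(list(timepoints = timepoints, points = points, curves = curves,
                 fits = fits, snr = snr),
            class = "hook_series")
}
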