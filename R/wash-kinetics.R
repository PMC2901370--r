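#' Two-parameter decay fit of a probe's wash series
#'
#' Summarizes the multiphase intensity decay of one probe (or of all probes
#' of a series at once) by the asymptotic survival `w_inf = I(t_inf)/I(0)`
#' and the short-time decay constant `tau = -t_tau / ln(I(t_tau)/I(0))`
#' (cycles to 1/e). Ratios are clipped to `(0, 1]` before taking logs, since
#' scan noise can push `I(t)` above `I(0)`; a ratio of exactly 1 yields
#' `tau = Inf`. With `method = "fit"` the two-component decay
#' `w(t) = (1 - w_inf) exp(-t / tau) + w_inf` is instead least-squares
#' fitted to all timepoints.
#'
#' @param series a `chip_series` (all probes), or a numeric vector of
#'   intensities ordered as `timepoints`.
#' @param timepoints cycle counts of the intensity values (default: the
#'   series timepoints). Must contain 0, `t_tau` and `t_inf` for the ratio
#'   method.
#' @param t_inf,t_tau reference cycle counts (defaults 17 and 2).
#' @param method `"ratio"` (default) or `"fit"`.
#' @return data.frame of class `probe_decay_fit` with `w_inf`, `tau`,
#'   `logI0` (log10 initial net intensity), `probe_type` and `set_id` when
#'   available, plus attribute `n_clipped` (ratios above 1 that were
#'   clipped).
#' @export
probe_decay_fit <- function(series, timepoints = NULL, t_inf = 17,
                            t_tau = 2, method = c("ratio", "fit")) {
  method <- match.arg(method)
  if (inherits(series, "chip_series")) {
    I <- series$intensities
    timepoints <- series$timepoints
    probe_type <- series$probes$probe_type
    set_id <- series$probes$set_id
  } else {
    I <- matrix(series, nrow = 1L)
    if (is.null(timepoints)) stop("supply timepoints for a raw vector")
    probe_type <- NA_character_
    set_id <- NA_character_
  }
  need <- if (method == "ratio") c(0, t_tau, t_inf) else c(0)
  miss <- setdiff(need, timepoints)
  if (length(miss))
    stop(sprintf("missing timepoint(s): %s", paste(miss, collapse = ", ")))
  i0 <- I[, match(0, timepoints)]
  if (any(i0 <= 0)) stop("initial intensities must be positive")
  n_clipped <- 0L
  if (method == "ratio") {
    r_inf <- I[, match(t_inf, timepoints)] / i0
    r_tau <- I[, match(t_tau, timepoints)] / i0
    n_clipped <- sum(r_inf > 1) + sum(r_tau > 1)
    r_inf <- pmin(pmax(r_inf, .Machine$double.xmin), 1)
    r_tau <- pmin(pmax(r_tau, .Machine$double.xmin), 1)
    w_inf <- r_inf
    tau <- ifelse(r_tau >= 1, Inf, -t_tau / log(r_tau))
  } else {
    w_inf <- tau <- numeric(nrow(I))
    tt <- timepoints
    for (p in seq_len(nrow(I))) {
      y <- pmin(I[p, ] / i0[p], 1)
      fi <- try(minpack.lm::nlsLM(
        y ~ (1 - wi) * exp(-tt / tu) + wi,
        start = list(wi = max(min(y), 1e-3), tu = 2),
        lower = c(1e-6, 1e-3), upper = c(1, 1e3),
        control = minpack.lm::nls.lm.control(maxiter = 100L)),
        silent = TRUE)
      if (inherits(fi, "try-error")) {
        w_inf[p] <- min(y); tau[p] <- NA_real_
      } else {
        cf <- stats::coef(fi)
        w_inf[p] <- cf[["wi"]]; tau[p] <- cf[["tu"]]
      }
    }
  }
  out <- data.frame(set_id = set_id, probe_type = probe_type,
                    w_inf = w_inf, tau = tau, logI0 = log10(i0),
                    stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- n_clipped
  class(out) <- c("probe_decay_fit", class(out))
  out
}

#' Moving-average trends of the washing parameters versus initial intensity
#'
#' Sorts the probe-level decay fits by initial log-intensity and averages
#' `w_inf` and `tau` (and `logI0` itself) over windows of `window`
#' consecutive probes, extracting the mean intensity dependence of the
#' washing parameters from the noisy probe-level scatter.
#'
#' @param fits a `probe_decay_fit` data.frame.
#' @param window probes per window (default 1000; shrunk with a warning when
#'   fewer probes are available).
#' @return data.frame `logI0`, `w_inf`, `tau` (finite `tau` values only
#'   enter the `tau` average).
#' @export
moving_average_vs_logI0 <- function(fits, window = 1000L) {
  n <- nrow(fits)
  if (n < 2L) stop("need at least 2 probe fits")
  if (n < window) {
    warning(sprintf("only %d probes; shrinking window from %d", n, window))
    window <- n
  }
  ord <- order(fits$logI0)
  tau <- fits$tau[ord]
  tau[!is.finite(tau)] <- NA_real_
  data.frame(logI0 = .roll_mean(fits$logI0[ord], window),
             w_inf = .roll_mean(fits$w_inf[ord], window),
             tau = .roll_mean_na(tau, window))
}

.roll_mean_na <- function(x, window) {
  isna <- is.na(x)
  x[isna] <- 0
  s <- .roll_mean(x, window)
  cnt <- .roll_mean(as.numeric(!isna), window) * window
  ifelse(cnt > 0, s * window / cnt, NA_real_)
}

#' Fit the sigmoidal survival model to a smoothed washing trend
#'
#' Least-squares fit (on the log10 survival scale) of
#' `w(I0) = w_min + (w_max - w_min) exp(-(a'(M - I0)/I0)^gamma)` to a
#' smoothed `(logI0, w_inf)` curve, e.g. from [moving_average_vs_logI0()].
#'
#' @param curve data.frame with `logI0` and a survival column (`w_inf` by
#'   default).
#' @param M saturation intensity.
#' @param response name of the survival column.
#' @return list `w_min`, `w_max`, `gamma`, `a_prime`, `I_crit` (`= a' M /
#'   (1 + a')`), standard errors `se`, `rms` and the `fit` object.
#' @export
fit_sigmoid <- function(curve, M, response = "w_inf") {
  w <- curve[[response]]
  ok <- is.finite(w) & w > 0 & curve$logI0 < log10(M)
  w <- w[ok]
  I0 <- 10^curve$logI0[ok]
  if (length(w) < 10L) stop("too few points for a sigmoid fit")
  w_min0 <- max(stats::quantile(w, 0.02), 1e-4)
  w_max0 <- min(stats::quantile(w, 0.98), 1)
  mid <- (log(w_min0) + log(w_max0)) / 2
  i_mid <- I0[which.min(abs(log(w) - mid))]
  a0 <- min(max(i_mid / max(M - i_mid, M * 1e-4), 1e-4), 10)
  fit <- minpack.lm::nlsLM(
    log(w) ~ log(wmin + (wmax - wmin) * exp(-(ap * (M - I0) / I0)^g)),
    start = list(wmin = w_min0, wmax = w_max0, g = 1.5, ap = a0),
    lower = c(1e-6, 1e-3, 0.05, 1e-6),
    upper = c(0.999, 1, 20, 100),
    control = minpack.lm::nls.lm.control(maxiter = 400L))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4L))
  list(w_min = cf[["wmin"]], w_max = cf[["wmax"]], gamma = cf[["g"]],
       a_prime = cf[["ap"]],
       I_crit = cf[["ap"]] * M / (1 + cf[["ap"]]),
       se = se, rms = sqrt(mean(stats::resid(fit)^2)), fit = fit)
}

#' Power-law slopes of the hook parameters over washing time
#'
#' Regresses each hook summary parameter (all of which scale logarithmically
#' with intensity or binding strength) on `log10 t` over the timepoints with
#' `t >= 1`, yielding the kinetic exponent `eta` of each parameter:
#' `Psi(t) - Psi(1) = eta * log10 t`. The S/N ratio enters as `log10` of the
#' geometric-mean `R` over a fixed set ensemble (sets classified `mix` or
#' `S` at every used timepoint), so that changing ensemble membership cannot
#' masquerade as kinetics.
#'
#' @param hs a `hook_series` from [hook_at_timepoints()] whose timepoints
#'   include at least 3 with `t >= 1`.
#' @param O optional named optical-background vector (per timepoint) whose
#'   log10 slope is reported as `eta_O`.
#' @param R_lo,R_hi ensemble boundaries passed to [classify_regimes()].
#' @return Object of class `kinetic_slopes`: data.frame `slopes` with
#'   columns `eta` and `se` for rows `sigma_start`, `sigma_end`, `alpha`,
#'   `beta`, `R`, `phi` (and `O` when supplied), plus `timepoints_used` and
#'   `n_ensemble`.
#' @export
hook_param_kinetics <- function(hs, O = NULL, R_lo = 0.1, R_hi = 10) {
  stopifnot(inherits(hs, "hook_series"))
  use <- which(hs$timepoints >= 1)
  if (length(use) < 3L)
    stop("need >= 3 timepoints with t >= 1 for slope fits")
  tp <- hs$timepoints[use]
  lt <- log10(tp)

  # fixed ensemble for the R- and phi-kinetics
  keep <- NULL
  for (i in use) {
    reg <- classify_regimes(hs$points[[i]], hs$fits[[i]],
                            R_lo = R_lo, R_hi = R_hi)
    ids <- names(reg$labels)[reg$labels %in% c("mix", "S")]
    keep <- if (is.null(keep)) ids else intersect(keep, ids)
  }
  logR <- phi <- numeric(length(use))
  for (j in seq_along(use)) {
    i <- use[j]
    snr <- hs$snr[[i]]$snr
    sel <- snr$set_id %in% keep & !snr$flagged & snr$R > 0
    logR[j] <- mean(log10(snr$R[sel]))
    over1 <- sel & snr$R > 1
    phi[j] <- if (any(over1)) mean(log10(snr$R[over1])) else NA_real_
  }

  psi <- rbind(
    sigma_start = vapply(use, function(i) hs$fits[[i]]$sigma_start_emp, 0),
    sigma_end = vapply(use, function(i) hs$fits[[i]]$sigma_end_emp, 0),
    alpha = vapply(use, function(i) hs$fits[[i]]$alpha, 0),
    delta_end = vapply(use, function(i)
      hs$fits[[i]]$delta_end - hs$fits[[i]]$delta_start_emp, 0),
    beta = vapply(use, function(i) hs$fits[[i]]$beta, 0),
    R = logR,
    phi = phi)
  if (!is.null(O)) {
    Ov <- if (!is.null(names(O))) O[paste0("I_t", tp)] else O[use]
    psi <- rbind(psi, O = log10(as.numeric(Ov)))
  }
  slopes <- t(apply(psi, 1L, function(y) {
    if (anyNA(y)) return(c(eta = NA_real_, se = NA_real_))
    fit <- stats::lm(y ~ lt)
    c(eta = unname(stats::coef(fit)[2L]),
      se = unname(suppressWarnings(summary(fit))$coefficients[2L, 2L]))
  }))
  structure(list(slopes = as.data.frame(slopes),
                 timepoints_used = tp, n_ensemble = length(keep)),
            class = "kinetic_slopes")
}

#' @export
print.kinetic_slopes <- function(x, ...) {
  cat(sprintf("kinetic slopes over t = {%s} (ensemble of %d sets):\n",
              paste(x$timepoints_used, collapse = ", "), x$n_ensemble))
  print(round(x$slopes, 4))
  invisible(x)
}

#' Invert hook-parameter slopes into per-mode washing exponents
#'
#' Under power-law washing, `log10 w^(P,h)(t) = -eta^(P,h) log10 t`, the
#' hook-parameter slopes are linear combinations of the three washing
#' exponents `(eta_N, eta_PM_S, eta_MM_S)`:
#' \describe{
#'   \item{start point}{`eta(sigma_start) = -eta_N`}
#'   \item{S/N ratio}{`eta(R) = eta_N - eta_PM_S`}
#'   \item{height / end level}{`eta(alpha) = eta(delta_end) = eta_MM_S -
#'     eta_PM_S`}
#'   \item{end point}{`eta(sigma_end) = -(eta_PM_S + eta_MM_S) / 2`}
#' }
#' The system is over-determined; the primary solution is its least-squares
#' solution over all supplied relations. The two substitution solutions
#' (through the R-slope and through the end-point slope) are also reported,
#' and their disagreement `-2 eta(sigma_end) - (eta_PM_S + eta_MM_S)` is the
#' consistency residual (warning above `residual_warn`).
#'
#' @param slopes a `kinetic_slopes` object, or a named vector/list with at
#'   least `sigma_start`, `sigma_end`, `alpha`, `R` (optionally
#'   `delta_end`).
#' @param residual_warn residual threshold for the consistency warning.
#' @return Object of class `washing_exponents`: `eta_N`, `eta_PM_S`,
#'   `eta_MM_S` (least-squares solution), `via_R` and `via_endpoint`
#'   substitution solutions, the consistency `residual`, and `tstar`
#'   extrapolations for all three modes.
#' @export
invert_washing_exponents <- function(slopes, residual_warn = 0.1) {
  s <- if (inherits(slopes, "kinetic_slopes"))
    stats::setNames(slopes$slopes$eta, rownames(slopes$slopes))
  else unlist(slopes)
  need <- c("sigma_start", "sigma_end", "alpha", "R")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop(sprintf("missing slope(s): %s", paste(miss, collapse = ", ")))
  rows <- list(                       # coefficients for (eta_N, PM_S, MM_S)
    sigma_start = c(-1, 0, 0),
    R = c(1, -1, 0),
    alpha = c(0, -1, 1),
    delta_end = c(0, -1, 1),
    sigma_end = c(0, -0.5, -0.5))
  use <- intersect(names(rows), names(s)[is.finite(s)])
  A <- do.call(rbind, rows[use])
  b <- s[use]
  ls <- stats::lm.fit(A, b)$coefficients
  exps <- c(eta_N = unname(ls[1L]), eta_PM_S = unname(ls[2L]),
            eta_MM_S = unname(ls[3L]))
  # substitution solutions
  eta_N0 <- -s[["sigma_start"]]
  via_R <- c(eta_N = eta_N0, eta_PM_S = eta_N0 - s[["R"]],
             eta_MM_S = eta_N0 - s[["R"]] + s[["alpha"]])
  sum_S <- -2 * s[["sigma_end"]]
  via_end <- c(eta_N = eta_N0, eta_PM_S = (sum_S - s[["alpha"]]) / 2,
               eta_MM_S = (sum_S + s[["alpha"]]) / 2)
  residual <- abs(sum_S - (via_R[["eta_PM_S"]] + via_R[["eta_MM_S"]]))
  if (is.finite(residual) && residual > residual_warn)
    warning(sprintf(
      "washing-exponent consistency residual %.3f exceeds %.3f; substitution solutions reported",
      residual, residual_warn))
  if (!(exps[["eta_N"]] >= exps[["eta_MM_S"]] &&
        exps[["eta_MM_S"]] >= exps[["eta_PM_S"]]))
    warning("expected ordering eta_N >= eta_MM_S >= eta_PM_S violated")
  structure(list(
    eta_N = exps[["eta_N"]], eta_PM_S = exps[["eta_PM_S"]],
    eta_MM_S = exps[["eta_MM_S"]],
    via_R = via_R, via_endpoint = via_end,
    residual = unname(residual),
    tstar = c(N = extrapolate_tstar(exps[["eta_N"]]),
              PM_S = extrapolate_tstar(exps[["eta_PM_S"]]),
              MM_S = extrapolate_tstar(exps[["eta_MM_S"]]))),
    class = "washing_exponents")
}

#' @export
print.washing_exponents <- function(x, ...) {
  cat(sprintf(
    "washing exponents: eta_N = %.3f, eta_PM_S = %.3f, eta_MM_S = %.3f (residual %.3f)\n",
    x$eta_N, x$eta_PM_S, x$eta_MM_S, x$residual))
  cat(sprintf("t* (cycles to 10%% survival): N %.3g, PM_S %.3g, MM_S %.3g\n",
              x$tstar[["N"]], x$tstar[["PM_S"]], x$tstar[["MM_S"]]))
  invisible(x)
}
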