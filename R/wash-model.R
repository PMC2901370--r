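#' washhook: hook analysis of PM/MM microarrays under post-hybridization washing
#'
#' The package models probe intensities of GeneChip-type arrays as the product
#' of a two-species (specific + non-specific) Langmuir adsorption isotherm and
#' mode-specific survival ("washing") functions, and provides estimators that
#' run the model backwards: from multi-timepoint wash series to washing
#' kinetics, from Delta-vs-Sigma hook curves to hybridization summary
#' parameters, from probe sequences to positional sensitivity profiles, and
#' from intensities to washing-corrected specific binding strengths.
#'
#' @section Module map:
#' \describe{
#'   \item{physics}{[occupancy_after_wash()], [probe_intensity()],
#'     [dissociation_rate()], [washing_kernel()], [survival_vs_intensity()],
#'     [sigmoid_washing_parameters()], [powerlaw_survival()],
#'     [extrapolate_tstar()], [enrichment_two_rounds()]}
#'   \item{simulator}{[generate_sequences()], [planted_affinities()],
#'     [generate_chip_series()], [apply_relabeling()], [write_chip_table()]}
#'   \item{hook}{[sigma_delta()], [smooth_hook()], [hook_theory()],
#'     [fit_hook()], [per_set_snr()], [classify_regimes()], [wash_level_hook()]}
#'   \item{kinetics}{[probe_decay_fit()], [moving_average_vs_logI0()],
#'     [fit_sigmoid()], [hook_param_kinetics()], [invert_washing_exponents()]}
#'   \item{sequence}{[fit_profile()], [difference_profile()],
#'     [predict_delta_logI()]}
#'   \item{calibration}{[calibrate_probe()], [occupancy_washing_function()],
#'     [estimate_logM()], [probe_background()]}
#' }
#'
#' All hook-facing logarithms are decadic (log10); the washing kernels use
#' natural exponentials.
#'
#' @name washhook-package
"_PACKAGE"

.check_nonneg <- function(..., .names = NULL) {
  vals <- list(...)
  nm <- if (is.null(.names)) as.character(substitute(list(...)))[-1L] else .names
  for (i in seq_along(vals)) {
    if (any(!is.finite(vals[[i]])) || any(vals[[i]] < 0))
      stop(sprintf("'%s' must be finite and non-negative", nm[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Hybridization parameters of the two-species adsorption model
#'
#' Container for the physical constants of probe hybridization: the saturation
#' intensity `M`, optical background `O`, bleaching factor `b` (held at 1; the
#' repeated-scanning data show no measurable bleaching, so it is exposed only
#' as an override), binding constants `K` and binding strengths `X = K * conc`
#' for the specific (S) and non-specific (N) hybridization modes.
#'
#' @param M saturation intensity (linear intensity units), `M > O`.
#' @param O optical background intensity, `>= 0`.
#' @param b bleaching factor in `[0, 1]`; default 1 (bleaching neglected).
#' @param K_S_PM,K_S_MM,K_N binding constants (1/concentration), `>= 0`.
#' @param conc_S,conc_N transcript concentrations (pM), `>= 0`.
#' @return An object of class `hyb_params` with the fields above plus the
#'   derived binding strengths `X_S_PM`, `X_S_MM`, `X_N`.
#' @export
hyb_params <- function(M, O = 0, b = 1,
                       K_S_PM = 0, K_S_MM = 0, K_N = 0,
                       conc_S = 0, conc_N = 0) {
  .check_nonneg(M, O, b, K_S_PM, K_S_MM, K_N, conc_S, conc_N,
                .names = c("M", "O", "b", "K_S_PM", "K_S_MM", "K_N",
                           "conc_S", "conc_N"))
  if (M <= O) stop("saturation intensity M must exceed the background O")
  if (b > 1) stop("bleaching factor b must lie in [0, 1]")
  structure(list(M = M, O = O, b = b,
                 K_S_PM = K_S_PM, K_S_MM = K_S_MM, K_N = K_N,
                 conc_S = conc_S, conc_N = conc_N,
                 X_S_PM = K_S_PM * conc_S,
                 X_S_MM = K_S_MM * conc_S,
                 X_N = K_N * conc_N),
            class = "hyb_params")
}

#' Washing parameters: kernels, sigmoid survival and power-law kinetics
#'
#' Bundles the empirical washing constants: the limiting survival fractions
#' `w_min < w_max` (complete wash-off and no-wash are not observed in real
#' data), the critical exponent `gamma` of the power law relating the
#' dissociation rate to the binding constant, the kernel scale `a` (with
#' `a_prime = a * t^(1/gamma)` for `t` washing cycles), and optionally a
#' per-mode power-law exponent `eta` for the long-time kinetics.
#'
#' @param w_min,w_max limiting survival fractions, `0 <= w_min < w_max <= 1`.
#' @param gamma critical exponent, `> 0`.
#' @param a kernel scale at one washing cycle (`a_prime = a * t^(1/gamma)`).
#'   Give either `a` or `a_prime` (with `t_ref`).
#' @param a_prime kernel scale at `t_ref` cycles; overrides `a`.
#' @param t_ref reference cycle count at which `a_prime` applies (default 17,
#'   the asymptotic estimate of the wash series).
#' @param K0 reference binding constant of the rate power law.
#' @param eta power-law survival exponent, `>= 0` (optional).
#' @return Object of class `washing_params`.
#' @seealso [survival_vs_intensity()], [washing_kernel()], [powerlaw_survival()]
#' @export
washing_params <- function(w_min = 0.06, w_max = 0.9, gamma = 1.6,
                           a = NULL, a_prime = NULL, t_ref = 17,
                           K0 = 1, eta = NULL) {
  if (w_min < 0 || w_max > 1 || w_min >= w_max)
    stop("need 0 <= w_min < w_max <= 1")
  if (gamma <= 0) stop("gamma must be positive")
  if (is.null(a)) {
    if (is.null(a_prime)) a_prime <- 0.1
    a <- a_prime / t_ref^(1 / gamma)
  }
  if (a <= 0) stop("kernel scale must be positive")
  if (!is.null(eta) && any(eta < 0)) stop("eta must be non-negative")
  structure(list(w_min = w_min, w_max = w_max, gamma = gamma,
                 a = a, t_ref = t_ref, K0 = K0, eta = eta),
            class = "washing_params")
}

#' Kernel scale a' at a given number of washing cycles
#' @param wp a [washing_params()] object.
#' @param t washing cycles (`>= 0`).
#' @return `a * t^(1/gamma)`.
#' @export
a_prime_at <- function(wp, t) {
  stopifnot(inherits(wp, "washing_params"))
  wp$a * t^(1 / wp$gamma)
}

#' Probe occupancy after washing
#'
#' Total fraction of probe oligomers still duplexed after washing: the
#' equilibrium numerator is down-weighted by the mode-specific survival
#' fractions while the denominator keeps the equilibrium binding strengths,
#' `Theta = (X_N w_N + X_S w_S) / (1 + X_N + X_S)`.
#' With `w_S = w_N = 1` this is the two-species Langmuir isotherm.
#'
#' @param X_S,X_N specific and non-specific binding strengths, `>= 0`.
#' @param w_S,w_N survival fractions in `[0, 1]`.
#' @return Occupancy in `[0, 1]`. Vectorized.
#' @examples
#' occupancy_after_wash(1, 0, 1, 1)            # X/(1+X) = 0.5
#' occupancy_after_wash(9, 1, 0.95, 0.1)       # 0.7864
#' @export
occupancy_after_wash <- function(X_S, X_N, w_S = 1, w_N = 1) {
  .check_nonneg(X_S, X_N, w_S, w_N,
                .names = c("X_S", "X_N", "w_S", "w_N"))
  if (any(w_S > 1) || any(w_N > 1)) stop("survival fractions must be <= 1")
  (X_N * w_N + X_S * w_S) / (1 + X_N + X_S)
}

#' Net probe intensity from occupancy
#'
#' `I = M * b * Theta` in linear intensity units (net scale: the optical
#' background is assumed already subtracted; add `params$O` for raw values).
#'
#' @param params a [hyb_params()] object.
#' @param occupancy occupancy in `[0, 1]`.
#' @return Net intensity in `[0, M]`.
#' @export
probe_intensity <- function(params, occupancy) {
  stopifnot(inherits(params, "hyb_params"))
  if (any(occupancy < 0) || any(occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  params$M * params$b * occupancy
}

#' Dissociation rate from the binding constant power law
#'
#' Weakly bound duplexes unbind fastest: the washing rate per cycle decays as
#' a power of the equilibrium binding constant, `k = (K0 / K)^gamma`, with
#' sequence-independent constants `K0` and `gamma`.
#'
#' @param K binding constant, `> 0`.
#' @param K0 reference binding constant, `> 0`.
#' @param gamma power-law exponent, `>= 0`.
#' @return Rate per washing cycle (`k = 1` at `K = K0`).
#' @export
dissociation_rate <- function(K, K0, gamma) {
  if (any(K <= 0) || any(K0 <= 0)) stop("binding constants must be positive")
  if (any(gamma < 0)) stop("gamma must be non-negative")
  (K0 / K)^gamma
}

#' First-order washing kernel and its bounded variant
#'
#' `washing_kernel(k, t)` is the single-exponential survival `exp(-k t)`;
#' `bounded = TRUE` maps it onto the empirically observed range,
#' `w = w_min + (w_max - w_min) * exp(-k t)`.
#'
#' @param k dissociation rate per cycle, `>= 0`.
#' @param t washing cycles, `>= 0`.
#' @param bounded clamp between the limiting survival fractions?
#' @param wp a [washing_params()] supplying `w_min`, `w_max` when `bounded`.
#' @return Survival fraction.
#' @export
washing_kernel <- function(k, t, bounded = FALSE, wp = washing_params()) {
  .check_nonneg(k, t, .names = c("k", "t"))
  base <- exp(-k * t)
  if (!bounded) return(base)
  wp$w_min + (wp$w_max - wp$w_min) * base
}

#' Survival fraction as a sigmoidal function of the initial intensity
#'
#' Inverting the single-mode isotherm for the binding constant and inserting
#' it into the rate power law gives the survival after `t` cycles as a
#' function of the initial net intensity `I0`:
#' `w(I0) = w_min + (w_max - w_min) * exp(-(a'(M - I0)/I0)^gamma)` with
#' `a' = a * t^(1/gamma)`. The kernel passes through `1/e` at the critical
#' intensity `I_crit = a' M / (1 + a')` independently of `gamma`.
#'
#' @param I0 initial net intensity, `0 < I0 <= M`.
#' @param M saturation intensity.
#' @param wp a [washing_params()].
#' @param t washing cycles used to scale `a' = a t^(1/gamma)` (default
#'   `wp$t_ref`).
#' @return Survival fraction in `[w_min, w_max]`, monotone increasing in `I0`.
#' @export
survival_vs_intensity <- function(I0, M, wp, t = wp$t_ref) {
  stopifnot(inherits(wp, "washing_params"))
  if (any(I0 <= 0) || any(I0 > M)) stop("need 0 < I0 <= M")
  ap <- a_prime_at(wp, t)
  kern <- exp(-(ap * (M - I0) / I0)^wp$gamma)
  wp$w_min + (wp$w_max - wp$w_min) * kern
}

#' Critical intensity of the sigmoidal survival step
#' @inheritParams survival_vs_intensity
#' @return `I_crit = a' M / (1 + a')` where the kernel equals `1/e`.
#' @export
critical_intensity <- function(M, wp, t = wp$t_ref) {
  ap <- a_prime_at(wp, t)
  ap * M / (1 + ap)
}

#' Asymptotic survival and initial decay time versus initial intensity
#'
#' Evaluates the sigmoidal survival model at the two reference cycle counts
#' of the two-component decay estimators: `w_inf(I0)` at `t = t_inf`
#' (default 17) and `tau(I0) = -t_tau / ln w(I0, t_tau)` at `t = t_tau`
#' (default 2). The decay-time limits are `tau_min = -t_tau/ln w_min` and
#' `tau_max = -t_tau/ln w_max`.
#'
#' @inheritParams survival_vs_intensity
#' @param t_inf cycle count of the asymptotic estimate (default 17).
#' @param t_tau cycle count of the short-time estimate (default 2).
#' @return List with vectors `w_inf`, `tau` and the scalars `tau_min`,
#'   `tau_max`. A survival of exactly 1 yields `tau = Inf`.
#' @export
sigmoid_washing_parameters <- function(I0, M, wp, t_inf = 17, t_tau = 2) {
  w_inf <- survival_vs_intensity(I0, M, wp, t = t_inf)
  w2 <- survival_vs_intensity(I0, M, wp, t = t_tau)
  tau <- ifelse(w2 >= 1, Inf, -t_tau / log(w2))
  list(w_inf = w_inf, tau = tau,
       tau_min = -t_tau / log(wp$w_min),
       tau_max = if (wp$w_max >= 1) Inf else -t_tau / log(wp$w_max))
}

#' Power-law survival and its slowly varying effective rate
#'
#' Long-time ensemble washing follows `log10 w = -eta * log10 t`, i.e.
#' `w(t) = t^-eta` for `t >= 1`. This equals `exp(-k(t) t)` with the
#' hyperbolically decaying effective rate `k(t) = eta * ln(t) / t`.
#'
#' @param eta power-law exponent, `>= 0`.
#' @param t washing cycles, `>= 1`.
#' @return `powerlaw_survival`: survival fraction; `effective_rate`: rate per
#'   cycle.
#' @export
powerlaw_survival <- function(eta, t) {
  if (any(eta < 0)) stop("eta must be non-negative")
  if (any(t < 1)) stop("the power law applies for t >= 1")
  t^(-eta)
}

#' @rdname powerlaw_survival
#' @export
effective_rate <- function(eta, t) {
  if (any(eta < 0)) stop("eta must be non-negative")
  if (any(t < 1)) stop("the power law applies for t >= 1")
  eta * log(t) / t
}

#' Washing cycles needed for a tenfold target reduction
#'
#' Extrapolates the power-law kinetics to the number of cycles `t*` after
#' which the surviving bound-target fraction drops to 10 percent:
#' `t* = 0.1^(-1/eta)`.
#'
#' @param eta power-law exponent.
#' @return `t*` in cycles; `Inf` for `eta <= 0` (unwashable).
#' @examples
#' extrapolate_tstar(0.5)   # 100 cycles: non-specific targets
#' extrapolate_tstar(0.05)  # 1e20 cycles: PM-bound specific targets
#' @export
extrapolate_tstar <- function(eta) {
  ifelse(eta <= 0, Inf, 0.1^(-1 / eta))
}

#' Two-round staining/washing enrichment arithmetic
#'
#' A round of staining makes a fixed amount of bound targets fluorescent
#' ("bright"); washing then removes a duplex-class-specific fraction
#' `1 - w` of the bright targets only. If re-staining adds the same bright
#' amount again (`label_increment` of the initial level), the bright level
#' after the second wash is `(label_increment + w) * w` and the round-2/round-1
#' enrichment factor is `label_increment + w`.
#'
#' @param w survival fraction of the duplex class, in `[0, 1]`.
#' @param label_increment bright amount added by re-staining, as a fraction of
#'   the initial bright level (default 1, i.e. 100 percent).
#' @return List with `bright_round1 = w`, `bright_round2 = (label_increment +
#'   w) * w` (both as fractions of the initial bright level) and
#'   `enrichment = label_increment + w`.
#' @examples
#' enrichment_two_rounds(0.9)  # bright_round2 = 1.71, enrichment = 1.9
#' enrichment_two_rounds(0.1)  # weak background enrichment, 1.1
#' @export
enrichment_two_rounds <- function(w, label_increment = 1.0) {
  if (any(w < 0) || any(w > 1)) stop("survival fraction w must lie in [0, 1]")
  .check_nonneg(label_increment, .names = "label_increment")
  list(bright_round1 = w,
       bright_round2 = (label_increment + w) * w,
       enrichment = label_increment + w)
}
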