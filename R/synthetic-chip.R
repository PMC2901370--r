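#' Generate PM/MM probe-pair sequences
#'
#' Draws random 25-mer PM sequences and derives each MM partner by
#' complementing the middle (13th) base, the GeneChip pairing convention.
#'
#' @param n_sets number of probe sets (one interrogated transcript each).
#' @param n_pairs PM/MM pairs per set (default 11).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return data.frame with columns `set_id`, `pair_index`, `probe_type`
#'   (`"PM"`/`"MM"`) and `sequence` (25 letters over ACGT); `2 * n_sets *
#'   n_pairs` rows.
#' @export
generate_sequences <- function(n_sets, n_pairs = 11, seed = NULL) {
  if (n_sets < 1 || n_pairs < 1) stop("need n_sets >= 1 and n_pairs >= 1")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_pm <- n_sets * n_pairs
  mat <- matrix(sample(bases, 25L * n_pm, replace = TRUE), nrow = n_pm)
  pm_seq <- apply(mat, 1L, paste0, collapse = "")
  mat[, 13L] <- comp[mat[, 13L]]
  mm_seq <- apply(mat, 1L, paste0, collapse = "")
  set_id <- sprintf("set%05d", rep(seq_len(n_sets), each = n_pairs))
  pair_index <- rep(seq_len(n_pairs), times = n_sets)
  out <- data.frame(
    set_id = rep(set_id, each = 2L),
    pair_index = rep(pair_index, each = 2L),
    probe_type = rep(c("PM", "MM"), times = n_pm),
    sequence = as.vector(rbind(pm_seq, mm_seq)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.seq_base_matrix <- function(sequences) {
  n <- length(sequences)
  idx <- match(unlist(strsplit(sequences, "", fixed = TRUE)),
               c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("sequences must use letters A, C, G, T only")
  m <- matrix(idx, nrow = n, byrow = TRUE)
  if (ncol(m) != 25L) stop("sequences must be 25 letters long")
  m
}

.epsilon_sum <- function(base_idx, epsilon) {
  acc <- numeric(nrow(base_idx))
  for (k in seq_len(25L)) acc <- acc + epsilon[k, base_idx[, k]]
  acc
}

.epsilon_nn_sum <- function(base_idx, epsilon_nn) {
  acc <- numeric(nrow(base_idx))
  for (k in seq_len(24L)) {
    pair <- (base_idx[, k] - 1L) * 4L + base_idx[, k + 1L]
    acc <- acc + epsilon_nn[k, pair]
  }
  acc
}

.check_profile_matrix <- function(epsilon, n_pos, n_letter, what) {
  if (!is.matrix(epsilon) || nrow(epsilon) != n_pos ||
      ncol(epsilon) != n_letter)
    stop(sprintf("%s must be a %d x %d matrix", what, n_pos, n_letter))
  if (any(abs(rowSums(epsilon)) > 1e-8))
    stop(sprintf("%s rows must sum to zero at each position", what))
  invisible(TRUE)
}

#' Default positional base-energy profile
#'
#' Parabola-shaped single-base affinity increments peaking mid-sequence, with
#' cytosine the strongest binder and adenine the weakest, qualitatively
#' matching profiles observed on real chips. Rows (positions) sum to zero
#' over the four letters.
#'
#' @param amplitude peak contribution of a mid-sequence cytosine to log10 K.
#' @return 25 x 4 matrix, columns `A`, `C`, `G`, `T`.
#' @export
default_epsilon_profile <- function(amplitude = 0.12) {
  k <- seq_len(25L)
  shape <- 4 * (k / 26) * (1 - k / 26)      # 0 at the ends, ~1 mid-sequence
  eps <- cbind(A = -amplitude * shape,
               C = amplitude * shape,
               G = 0.35 * amplitude * shape,
               T = -0.35 * amplitude * shape)
  rownames(eps) <- paste0("pos", k)
  eps
}

#' Plant per-probe binding affinities from a positional energy model
#'
#' Builds log10 binding constants as `set mean + sum_k eps_k(B_pk)`, i.e. a
#' sum of positional base-specific terms on top of a set-level random offset.
#' The specific affinity of each MM probe is reduced by the fixed decrement
#' `alpha0` (its central mismatch); the non-specific affinity is shared
#' between the PM and MM of a pair (computed from the PM sequence), since
#' both probe types hybridize identically with non-specific transcripts.
#'
#' @param records sequence table from [generate_sequences()].
#' @param epsilon_profile 25 x 4 positional base profile with zero row sums
#'   (see [default_epsilon_profile()]).
#' @param logK_S_mean,logK_N_mean grand means of log10 K for the specific and
#'   non-specific mode (defaults place the specific binding strengths of
#'   expressed sets across the typical -4 < log10 X_S < 1 working range).
#' @param sigma_set s.d. of the set-level log10 K offsets.
#' @param alpha0 log10 decrement of MM specific affinity (PM/MM gain).
#' @param epsilon_nn optional 24 x 16 nearest-neighbour profile (zero row
#'   sums; pair order AA, AC, ..., TT) added to the specific affinity.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return data.frame `logK_S`, `logK_N` aligned with `records`.
#' @export
planted_affinities <- function(records,
                               epsilon_profile = default_epsilon_profile(),
                               logK_S_mean = 0, logK_N_mean = -2.5,
                               sigma_set = 0.25, alpha0 = 1,
                               epsilon_nn = NULL, seed = NULL) {
  .check_profile_matrix(epsilon_profile, 25L, 4L, "epsilon_profile")
  if (!is.null(epsilon_nn))
    .check_profile_matrix(epsilon_nn, 24L, 16L, "epsilon_nn")
  if (!is.null(seed)) set.seed(seed)
  base_idx <- .seq_base_matrix(records$sequence)
  is_mm <- records$probe_type == "MM"
  # pair id: set/pair combination; the MM row inherits the PM sequence terms
  # for the shared non-specific affinity
  pm_rows <- which(!is_mm)
  pair_key <- paste(records$set_id, records$pair_index)
  pm_of_pair <- pm_rows[match(pair_key, pair_key[pm_rows])]

  sets <- unique(records$set_id)
  off_S <- stats::rnorm(length(sets), 0, sigma_set)
  off_N <- stats::rnorm(length(sets), 0, sigma_set)
  set_i <- match(records$set_id, sets)

  eps_own <- .epsilon_sum(base_idx, epsilon_profile)
  if (!is.null(epsilon_nn))
    eps_own <- eps_own + .epsilon_nn_sum(base_idx, epsilon_nn)
  eps_pm <- eps_own[pm_of_pair]

  logK_S <- logK_S_mean + off_S[set_i] + eps_own - alpha0 * is_mm
  logK_N <- logK_N_mean + off_N[set_i] + eps_pm
  data.frame(logK_S = logK_S, logK_N = logK_N)
}

#' Simulator configuration
#'
#' Assembles and validates the configuration of [generate_chip_series()].
#' Defaults emulate the structure of a washed GeneChip experiment at desk
#' scale: 5000 probe sets of 11 PM/MM pairs, 35 percent of sets expressed
#' with log-normal specific concentrations spanning roughly 1e-2 to 1e3 pM,
#' wash timepoints 0/2/3/7/17 cycles, and 15 percent multiplicative scan
#' noise.
#'
#' @param n_sets,n_pairs chip dimensions.
#' @param expressed_fraction fraction of sets with specific transcript.
#' @param logS_mean,logS_sd log10 pM concentration distribution of expressed
#'   sets.
#' @param conc_N pooled non-specific transcript concentration (pM).
#' @param logK_S_mean,logK_N_mean,sigma_set,alpha0 affinity model, see
#'   [planted_affinities()].
#' @param epsilon_profile,epsilon_nn positional energy profiles.
#' @param M saturation intensity.
#' @param O optical background per timepoint (recycled; must be
#'   non-increasing in t).
#' @param washing list: `driver = "sigmoid"` with a [washing_params()] in
#'   `params` (one survival kernel for all probes, driven by their t = 0
#'   intensity); `driver = "kernel"` with a [washing_params()] (per-probe,
#'   per-mode bounded exponential kernel, rate from the planted binding
#'   constant through the power law; optional `K0` reference constant); or
#'   `driver = "powerlaw"` with `eta = c(N=, PM_S=, MM_S=)` (per-mode
#'   power-law survival).
#' @param noise_cv multiplicative log-normal noise coefficient of variation
#'   per probe per scan.
#' @param timepoints washing-cycle counts; must include 0.
#' @param seed integer seed.
#' @return Validated config list of class `chip_config`.
#' @export
chip_config <- function(n_sets = 5000, n_pairs = 11,
                        expressed_fraction = 0.35,
                        logS_mean = -0.5, logS_sd = 1.2,
                        conc_N = 1,
                        logK_S_mean = -1, logK_N_mean = -2.5,
                        sigma_set = 0.25, alpha0 = 1,
                        epsilon_profile = default_epsilon_profile(),
                        epsilon_nn = NULL,
                        M = 10^4.5,
                        O = 500 * pmax(timepoints, 1)^(-0.3),
                        washing = list(driver = "sigmoid",
                                       params = washing_params()),
                        noise_cv = 0.15,
                        timepoints = c(0, 2, 3, 7, 17),
                        seed = 1L) {
  if (!0 %in% timepoints) stop("timepoints must include 0 (the unwashed scan)")
  if (is.unsorted(timepoints)) stop("timepoints must be increasing")
  if (expressed_fraction < 0 || expressed_fraction > 1)
    stop("expressed_fraction must lie in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  O <- rep_len(O, length(timepoints))
  if (is.unsorted(rev(O))) stop("O(t) must be non-increasing in t")
  driver <- match.arg(washing$driver, c("sigmoid", "powerlaw", "kernel"))
  if (driver %in% c("sigmoid", "kernel")) {
    if (!inherits(washing$params, "washing_params"))
      stop(sprintf("%s washing needs washing$params of class washing_params",
                   driver))
  } else {
    eta <- washing$eta
    if (is.null(eta) || !all(c("N", "PM_S", "MM_S") %in% names(eta)))
      stop("powerlaw washing needs washing$eta = c(N=, PM_S=, MM_S=)")
    if (any(eta < 0)) stop("washing exponents must be non-negative")
  }
  washing$driver <- driver
  cfg <- list(n_sets = n_sets, n_pairs = n_pairs,
              expressed_fraction = expressed_fraction,
              logS_mean = logS_mean, logS_sd = logS_sd, conc_N = conc_N,
              logK_S_mean = logK_S_mean, logK_N_mean = logK_N_mean,
              sigma_set = sigma_set, alpha0 = alpha0,
              epsilon_profile = epsilon_profile, epsilon_nn = epsilon_nn,
              M = M, O = O, washing = washing, noise_cv = noise_cv,
              timepoints = timepoints, seed = as.integer(seed))
  class(cfg) <- "chip_config"
  cfg
}

.survival_matrices <- function(cfg, I0_clean, is_mm, aff) {
  nt <- length(cfg$timepoints)
  n <- length(I0_clean)
  w_S <- matrix(1, n, nt)
  w_N <- matrix(1, n, nt)
  driver <- cfg$washing$driver
  if (driver == "kernel") {
    wp <- cfg$washing$params
    # reference constant placed half a decade below the mean non-specific
    # affinity so that non-specific duplexes are mid-decay within the
    # experiment's wash window while bright specific duplexes resist
    K0 <- cfg$washing$K0 %||% 10^(cfg$logK_N_mean - 0.5)
    k_S <- dissociation_rate(10^aff$logK_S, K0, wp$gamma)
    k_N <- dissociation_rate(10^aff$logK_N, K0, wp$gamma)
  }
  for (j in seq_len(nt)) {
    t <- cfg$timepoints[j]
    if (t <= 0) next
    if (driver == "sigmoid") {
      w <- survival_vs_intensity(pmin(I0_clean, cfg$M), cfg$M,
                                 cfg$washing$params, t = t)
      w_S[, j] <- w
      w_N[, j] <- w
    } else if (driver == "kernel") {
      wp <- cfg$washing$params
      w_S[, j] <- washing_kernel(k_S, t, bounded = TRUE, wp = wp)
      w_N[, j] <- washing_kernel(k_N, t, bounded = TRUE, wp = wp)
    } else {
      tt <- max(t, 1)
      eta <- cfg$washing$eta
      w_N[, j] <- powerlaw_survival(eta[["N"]], tt)
      w_S[, j] <- ifelse(is_mm,
                         powerlaw_survival(eta[["MM_S"]], tt),
                         powerlaw_survival(eta[["PM_S"]], tt))
    }
  }
  list(w_S = w_S, w_N = w_N)
}

#' Simulate a washed chip series with planted physical truth
#'
#' Draws probe sequences and affinities, assigns specific transcript
#' concentrations to expressed sets, computes the equilibrium (t = 0, w = 1)
#' intensities from the two-species isotherm, applies the configured washing
#' driver at each later timepoint, and adds multiplicative log-normal scan
#' noise. The full generating truth (affinities, binding strengths, survival
#' fractions, clean intensities) is attached for oracle-style validation.
#'
#' @param config a [chip_config()].
#' @return Object of class `chip_series`: list with `probes` (sequence
#'   table), `intensities` (net-intensity matrix, probes x timepoints),
#'   `timepoints`, `M`, `O`, `seed` and `truth`.
#' @export
generate_chip_series <- function(config = chip_config()) {
  stopifnot(inherits(config, "chip_config"))
  cfg <- config
  set.seed(cfg$seed)
  probes <- generate_sequences(cfg$n_sets, cfg$n_pairs, seed = NULL)
  aff <- planted_affinities(probes, cfg$epsilon_profile,
                            logK_S_mean = cfg$logK_S_mean,
                            logK_N_mean = cfg$logK_N_mean,
                            sigma_set = cfg$sigma_set, alpha0 = cfg$alpha0,
                            epsilon_nn = cfg$epsilon_nn, seed = NULL)
  sets <- unique(probes$set_id)
  expressed <- stats::runif(length(sets)) < cfg$expressed_fraction
  conc_S_set <- ifelse(expressed,
                       10^stats::rnorm(length(sets), cfg$logS_mean,
                                       cfg$logS_sd), 0)
  set_i <- match(probes$set_id, sets)
  conc_S <- conc_S_set[set_i]
  X_S <- 10^aff$logK_S * conc_S
  X_N <- 10^aff$logK_N * cfg$conc_N
  is_mm <- probes$probe_type == "MM"

  den <- 1 + X_S + X_N
  I0_clean <- cfg$M * (X_S + X_N) / den
  w <- .survival_matrices(cfg, I0_clean, is_mm, aff)
  nt <- length(cfg$timepoints)
  I_clean <- cfg$M * (X_S * w$w_S + X_N * w$w_N) / den
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log1p(cfg$noise_cv^2))
    noise <- matrix(exp(stats::rnorm(length(I_clean), 0, sdlog)),
                    nrow = nrow(I_clean))
    intens <- I_clean * noise
  } else {
    intens <- I_clean
  }
  tp_names <- paste0("I_t", cfg$timepoints)
  colnames(intens) <- colnames(I_clean) <- tp_names
  colnames(w$w_S) <- colnames(w$w_N) <- tp_names
  O <- stats::setNames(cfg$O, tp_names)
  structure(list(
    probes = probes,
    intensities = intens,
    timepoints = cfg$timepoints,
    M = cfg$M, O = O, seed = cfg$seed,
    config = cfg,
    truth = list(logK_S = aff$logK_S, logK_N = aff$logK_N,
                 X_S = X_S, X_N = X_N, conc_S = conc_S,
                 expressed = stats::setNames(expressed, sets),
                 w_S = w$w_S, w_N = w$w_N,
                 I_clean = I_clean,
                 epsilon_profile = cfg$epsilon_profile,
                 epsilon_nn = cfg$epsilon_nn,
                 alpha0 = cfg$alpha0)),
    class = "chip_series")
}

#' @export
print.chip_series <- function(x, ...) {
  cat(sprintf(
    "chip_series: %d probes (%d sets), timepoints {%s} cycles, M = %.3g%s\n",
    nrow(x$probes), length(unique(x$probes$set_id)),
    paste(x$timepoints, collapse = ", "), x$M,
    if (isTRUE(x$relabeled)) ", relabeled (2nd series)" else ""))
  invisible(x)
}

#' Re-label a washed series (second staining/washing round)
#'
#' Applies the two-round enrichment model: re-staining adds
#' `label_increment` of the initial bright level per duplex class, so every
#' mode-specific intensity component of the first series scales by
#' `label_increment + w_mode(T)` where `w_mode(T)` is the planted survival at
#' the final timepoint. Optionally clips at the scanner ceiling `clip_at`,
#' producing the point mass of optically saturated probes at the upper end
#' of the intensity distribution.
#'
#' @param series a `chip_series` carrying truth fields.
#' @param clip_at optional scanner ceiling (net intensity); `NULL` = none.
#' @param label_increment bright amount added by re-staining (fraction of the
#'   initial bright level; default 1).
#' @param noise_cv scan noise of the second series (default: same as the
#'   first series).
#' @param seed seed for the fresh scan noise.
#' @return A new `chip_series` with enriched (and possibly clipped)
#'   intensities; `relabeled = TRUE`.
#' @export
apply_relabeling <- function(series, clip_at = NULL, label_increment = 1,
                             noise_cv = series$config$noise_cv, seed = NULL) {
  stopifnot(inherits(series, "chip_series"))
  if (is.null(series$truth)) stop("apply_relabeling needs planted truth fields")
  if (!is.null(clip_at) && clip_at <= 0) stop("clip_at must be positive")
  tr <- series$truth
  cfg <- series$config
  last <- length(series$timepoints)
  enrich_S <- label_increment + tr$w_S[, last]
  enrich_N <- label_increment + tr$w_N[, last]
  den <- 1 + tr$X_S + tr$X_N
  I_S <- series$M * tr$X_S * tr$w_S / den
  I_N <- series$M * tr$X_N * tr$w_N / den
  I2_clean <- I_S * enrich_S + I_N * enrich_N
  if (!is.null(seed)) set.seed(seed)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    I2 <- I2_clean * matrix(exp(stats::rnorm(length(I2_clean), 0, sdlog)),
                            nrow = nrow(I2_clean))
  } else I2 <- I2_clean
  if (!is.null(clip_at)) {
    I2 <- pmin(I2, clip_at)
    I2_clean <- pmin(I2_clean, clip_at)
  }
  out <- series
  out$intensities <- I2
  out$truth$I_clean <- I2_clean
  out$truth$enrichment <- list(S = enrich_S, N = enrich_N)
  out$relabeled <- TRUE
  out$clip_at <- clip_at
  out
}

#' Write / read a chip series as a tab-delimited probe table
#'
#' The main file holds one row per probe with columns `set_id`,
#' `pair_index`, `probe_type`, `sequence` and one net-intensity column per
#' timepoint (`I_t0`, `I_t2`, ...), preceded by `#key\tvalue` metadata lines
#' (timepoints, M, O, seed). Planted truth, when present, goes to a sidecar
#' `<path>.truth` in the same layout.
#'
#' @param series a `chip_series`.
#' @param path output path for the probe table.
#' @return `write_chip_table`: `path`, invisibly. `read_chip_table`: a
#'   `chip_series` (without truth unless the sidecar exists).
#' @export
write_chip_table <- function(series, path) {
  stopifnot(inherits(series, "chip_series"))
  meta <- c(
    sprintf("#timepoints\t%s", paste(series$timepoints, collapse = ",")),
    sprintf("#M\t%.10g", series$M),
    sprintf("#O\t%s", paste(sprintf("%.10g", series$O), collapse = ",")),
    sprintf("#seed\t%d", as.integer(series$seed)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  tab <- cbind(series$probes,
               as.data.frame(series$intensities, check.names = FALSE))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  if (!is.null(series$truth)) {
    tr <- series$truth
    sidecar <- data.frame(logK_S = tr$logK_S, logK_N = tr$logK_N,
                          X_S = tr$X_S, X_N = tr$X_N, conc_S = tr$conc_S)
    sidecar <- cbind(sidecar,
                     stats::setNames(as.data.frame(tr$w_S),
                                     paste0("w_S_", colnames(tr$w_S))),
                     stats::setNames(as.data.frame(tr$w_N),
                                     paste0("w_N_", colnames(tr$w_N))))
    utils::write.table(sidecar, paste0(path, ".truth"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_chip_table
#' @export
read_chip_table <- function(path) {
  lines <- readLines(path, n = 50L, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop(sprintf("malformed metadata line %d: '%s'",
                   which(lines == ln)[1L], ln))
    meta[[kv[1L]]] <- kv[2L]
  }
  for (key in c("timepoints", "M"))
    if (is.null(meta[[key]]))
      stop(sprintf("missing metadata line '#%s' in %s", key, path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("set_id", "pair_index", "probe_type", "sequence")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("probe table %s lacks column(s): %s (header is line %d)",
                 path, paste(miss, collapse = ", "), length(meta_lines) + 1L))
  timepoints <- as.numeric(strsplit(meta$timepoints, ",")[[1L]])
  icols <- paste0("I_t", timepoints)
  miss <- setdiff(icols, names(tab))
  if (length(miss))
    stop(sprintf("probe table %s lacks intensity column(s): %s",
                 path, paste(miss, collapse = ", ")))
  intens <- as.matrix(tab[icols])
  O <- if (!is.null(meta$O)) as.numeric(strsplit(meta$O, ",")[[1L]])
       else rep(0, length(timepoints))
  truth <- NULL
  sidecar <- paste0(path, ".truth")
  if (file.exists(sidecar)) {
    tr <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                            check.names = FALSE)
    wS <- as.matrix(tr[grep("^w_S_", names(tr))])
    wN <- as.matrix(tr[grep("^w_N_", names(tr))])
    colnames(wS) <- sub("^w_S_", "", colnames(wS))
    colnames(wN) <- sub("^w_N_", "", colnames(wN))
    truth <- list(logK_S = tr$logK_S, logK_N = tr$logK_N,
                  X_S = tr$X_S, X_N = tr$X_N, conc_S = tr$conc_S,
                  w_S = wS, w_N = wN)
  }
  structure(list(
    probes = tab[need],
    intensities = intens,
    timepoints = timepoints,
    M = as.numeric(meta$M),
    O = stats::setNames(O, icols),
    seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_,
    config = NULL,
    truth = truth),
    class = "chip_series")
}
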