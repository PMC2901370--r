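.BASES <- c("A", "C", "G", "T")
.NN_PAIRS <- as.vector(outer(.BASES, .BASES, function(a, b) paste0(a, b)))
# pair order AA, CA, GA, TA, AC, ... from outer(); reorder to AA, AC, ...
.NN_PAIRS <- as.vector(t(matrix(.NN_PAIRS, 4L, 4L)))

.nn_index <- function(base_idx, k) (base_idx[, k] - 1L) * 4L + base_idx[, k + 1L]

#' Fit a positional nucleotide sensitivity profile
#'
#' Models the probe-specific intensity increment (log10 intensity minus the
#' set mean, computed within probe type) as a sum of positional base-specific
#' sensitivities: `delta logI_p = sum_k sigma_k(B_pk)` for the single-base
#' model, or a sum over nearest-neighbour pairs for `model = "nn"`. The
#' sum-to-zero constraint over letters at each position is imposed through
#' sum contrasts; profiles are fit per ensemble and timepoint. The
#' nearest-neighbour design is inherently aliased (adjacent pairs share
#' their middle base), so its coefficients are the minimum-norm
#' least-squares solution and only its predictions are fully identifiable.
#'
#' @param series a `chip_series`.
#' @param set_ids probe sets forming the ensemble (e.g. from
#'   [select_ensembles()]).
#' @param timepoint washing-cycle count.
#' @param model `"single"` (25 x 4) or `"nn"` (24 x 16 nearest-neighbour
#'   pairs).
#' @param probe_type probe types to include (default both).
#' @param max_probes cap on rows entering the least-squares fit (random
#'   subsample above it, for memory; default 60000).
#' @return Object of class `sensitivity_profile`: `values` (position x
#'   letter matrix with zero row sums), `model`, `ensemble_size`,
#'   `timepoint`, `r_squared`, `n_probes`.
#' @export
fit_profile <- function(series, set_ids, timepoint,
                        model = c("single", "nn"),
                        probe_type = c("PM", "MM"), max_probes = 60000L) {
  model <- match.arg(model)
  stopifnot(inherits(series, "chip_series"))
  col <- paste0("I_t", timepoint)
  sel <- series$probes$set_id %in% set_ids &
    series$probes$probe_type %in% probe_type &
    series$intensities[, col] > 0
  n_par <- if (model == "single") 25L * 3L else 24L * 15L
  if (sum(sel) < 10L * n_par)
    stop(sprintf("ensemble too small: %d probes for %d parameters (need %d)",
                 sum(sel), n_par, 10L * n_par))
  if (sum(sel) > max_probes) {
    keep <- sample(which(sel), max_probes)
    sel <- rep(FALSE, length(sel)); sel[keep] <- TRUE
  }
  logI <- log10(series$intensities[sel, col])
  grp <- paste(series$probes$set_id[sel], series$probes$probe_type[sel])
  dlogI <- logI - stats::ave(logI, grp)
  base_idx <- .seq_base_matrix(series$probes$sequence[sel])

  if (model == "single") {
    n_pos <- 25L; n_lev <- 4L
    fac <- lapply(seq_len(n_pos), function(k)
      factor(.BASES[base_idx[, k]], levels = .BASES))
    lev_names <- .BASES
  } else {
    n_pos <- 24L; n_lev <- 16L
    fac <- lapply(seq_len(n_pos), function(k)
      factor(.NN_PAIRS[.nn_index(base_idx, k)], levels = .NN_PAIRS))
    lev_names <- .NN_PAIRS
  }
  incomplete <- which(vapply(fac, function(f) any(table(f) == 0L), TRUE))
  if (length(incomplete))
    stop(sprintf("degenerate design: position(s) %s lack some letters",
                 paste(incomplete, collapse = ", ")))
  names(fac) <- paste0("p", seq_len(n_pos))
  df <- as.data.frame(fac)
  X <- stats::model.matrix(
    ~ ., df, contrasts.arg = lapply(df, function(.) "contr.sum"))
  # the nearest-neighbour design is inherently aliased (adjacent pair
  # factors share their middle base), so take the minimum-norm least-squares
  # solution via a vanishing ridge
  XtX <- crossprod(X)
  lam <- 1e-8 * max(diag(XtX))
  cf <- solve(XtX + diag(lam, ncol(X)), crossprod(X, dlogI))[, 1L]
  fitted <- drop(X %*% cf)
  cf <- cf[-1L]                                 # drop intercept
  values <- matrix(0, n_pos, n_lev,
                   dimnames = list(paste0("pos", seq_len(n_pos)), lev_names))
  for (k in seq_len(n_pos)) {
    ck <- cf[((k - 1L) * (n_lev - 1L) + 1L):(k * (n_lev - 1L))]
    values[k, ] <- c(ck, -sum(ck))              # contr.sum reconstruction
  }
  rss <- sum((dlogI - fitted)^2)
  tss <- sum(dlogI^2)
  structure(list(values = values, model = model,
                 ensemble_size = length(unique(set_ids)),
                 timepoint = timepoint,
                 r_squared = 1 - rss / tss, n_probes = length(dlogI)),
            class = "sensitivity_profile")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf(
    "sensitivity_profile (%s model, t = %s): %d probes, R^2 = %.3f, |sigma| max = %.4f\n",
    x$model, x$timepoint, x$n_probes, x$r_squared, max(abs(x$values))))
  invisible(x)
}

#' Washing difference profile
#'
#' Element-wise difference of two sensitivity profiles ("washed minus
#' unwashed"); the per-position zero-sum constraint is preserved. Under
#' power-law washing of the binding constant the difference profile is
#' proportional to the underlying positional affinity profile.
#'
#' @param after,before `sensitivity_profile` objects of matching model.
#' @return Object of class `difference_profile` with `values` and the two
#'   timepoints.
#' @export
difference_profile <- function(after, before) {
  stopifnot(inherits(after, "sensitivity_profile"),
            inherits(before, "sensitivity_profile"))
  if (after$model != before$model ||
      !identical(dim(after$values), dim(before$values)))
    stop("profiles must share the same model and shape")
  structure(list(values = after$values - before$values,
                 model = after$model,
                 timepoint_after = after$timepoint,
                 timepoint_before = before$timepoint),
            class = "difference_profile")
}

#' Predict the sequence-specific log-intensity increment
#'
#' Sums the profile entries along a 25-mer sequence: the single-base model
#' adds one term per position, the nearest-neighbour model one term per
#' adjacent pair.
#'
#' @param sequence character vector of 25-mers.
#' @param profile a `sensitivity_profile` (or `difference_profile`).
#' @return Numeric vector of log10-intensity increments.
#' @export
predict_delta_logI <- function(sequence, profile) {
  base_idx <- .seq_base_matrix(sequence)
  v <- profile$values
  acc <- numeric(length(sequence))
  if (profile$model == "single") {
    for (k in seq_len(25L)) acc <- acc + v[k, base_idx[, k]]
  } else {
    for (k in seq_len(24L)) acc <- acc + v[k, .nn_index(base_idx, k)]
  }
  unname(acc)
}

#' Write a sensitivity profile as a tab-delimited matrix
#'
#' Metadata (`model`, `timepoint`, `r_squared`, `n_probes`) goes into
#' `#key\tvalue` header lines; the body has position rows and letter
#' columns.
#'
#' @param profile a `sensitivity_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#model\t%s", profile$model),
               sprintf("#timepoint\t%s", profile$timepoint),
               sprintf("#r_squared\t%.6f", profile$r_squared),
               sprintf("#n_probes\t%d", profile$n_probes)), con)
  utils::write.table(
    data.frame(position = rownames(profile$values), profile$values,
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
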