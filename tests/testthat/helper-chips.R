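# shared synthetic chips, built once per session and reused read-only
.chip_cache <- new.env(parent = emptyenv())

.cached <- function(name, maker) {
  if (is.null(.chip_cache[[name]])) .chip_cache[[name]] <- maker()
  .chip_cache[[name]]
}

ETA_PLANTED <- c(N = 0.5, PM_S = 0.05, MM_S = 0.175)

chip_powerlaw_clean <- function() .cached("pl_clean", function()
  generate_chip_series(chip_config(
    n_sets = 2500, noise_cv = 0,
    washing = list(driver = "powerlaw", eta = ETA_PLANTED), seed = 101L)))

chip_kernel_clean <- function() .cached("kn_clean", function()
  generate_chip_series(chip_config(
    n_sets = 2500, noise_cv = 0,
    washing = list(driver = "kernel", params = washing_params()),
    seed = 102L)))

chip_sigmoid_clean <- function() .cached("sg_clean", function()
  generate_chip_series(chip_config(n_sets = 2500, noise_cv = 0,
                                   seed = 103L)))

hook_series_of <- function(series, key) .cached(key, function()
  hook_at_timepoints(series))

# tiny hand-made series for unit-level hook tests
tiny_series <- function(ipm, imm, set_id = "set00001", pair_index = NULL) {
  n <- length(ipm)
  if (is.null(pair_index)) pair_index <- seq_len(n)
  probes <- data.frame(
    set_id = rep(set_id, each = 2L * n / length(set_id)),
    pair_index = rep(pair_index, each = 2L),
    probe_type = rep(c("PM", "MM"), n),
    sequence = strrep("A", 25L))
  intens <- matrix(as.vector(rbind(ipm, imm)), ncol = 1L,
                   dimnames = list(NULL, "I_t0"))
  structure(list(probes = probes, intensities = intens, timepoints = 0,
                 M = 1e4, O = c(I_t0 = 0), seed = 1L, truth = NULL),
            class = "chip_series")
}
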