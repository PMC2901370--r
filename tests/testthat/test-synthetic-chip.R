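test_that("probe sequences come in complementary-middle PM/MM pairs", {
  rec <- generate_sequences(3, 11, seed = 5)
  expect_equal(nrow(rec), 66)
  expect_equal(sum(rec$probe_type == "PM"), 33)
  expect_true(all(nchar(rec$sequence) == 25))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pm <- rec[rec$probe_type == "PM", ]
  mm <- rec[rec$probe_type == "MM", ]
  for (i in seq_len(nrow(pm))) {
    a <- strsplit(pm$sequence[i], "")[[1]]
    b <- strsplit(mm$sequence[i], "")[[1]]
    expect_equal(which(a != b), 13L)
    expect_equal(b[13], unname(comp[a[13]]))
  }
  expect_identical(generate_sequences(2, 4, seed = 9),
                   generate_sequences(2, 4, seed = 9))
})

test_that("planted affinities follow the positional energy model", {
  rec <- generate_sequences(20, 11, seed = 6)
  zero_eps <- matrix(0, 25, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  aff <- planted_affinities(rec, zero_eps, sigma_set = 0.3, alpha0 = 1,
                            seed = 7)
  pm <- rec$probe_type == "PM"
  # zero profile: within a set all PM probes share log K exactly
  spread <- tapply(aff$logK_S[pm], rec$set_id[pm], function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # MM decrement is exactly alpha0
  expect_equal(aff$logK_S[pm] - aff$logK_S[!pm], rep(1, sum(pm)))
  # non-specific affinity shared within the pair
  expect_equal(aff$logK_N[pm], aff$logK_N[!pm])
  expect_error(planted_affinities(rec, matrix(1, 25, 4)), "sum to zero")
})

test_that("generated series obeys the isotherm at t = 0 and decays under washing", {
  ser <- chip_powerlaw_clean()
  tr <- ser$truth
  I0_expect <- ser$M * (tr$X_S + tr$X_N) / (1 + tr$X_S + tr$X_N)
  expect_equal(unname(ser$intensities[, "I_t0"]), unname(I0_expect),
               tolerance = 1e-12)
  # noise-free intensities are non-increasing across timepoints
  expect_true(all(diff(t(ser$intensities)) <= 1e-9))
  # set-level PM mean >= MM mean wherever specific transcript is present
  pm <- ser$probes$probe_type == "PM"
  lpm <- tapply(log10(ser$intensities[pm, "I_t0"]), ser$probes$set_id[pm],
                mean)
  lmm <- tapply(log10(ser$intensities[!pm, "I_t0"]), ser$probes$set_id[!pm],
                mean)
  expressed <- names(which(ser$truth$expressed))
  expect_true(all(lpm[expressed] >= lmm[expressed]))
})

test_that("a chip without expressed sets has identical PM and MM signals", {
  ser <- generate_chip_series(chip_config(n_sets = 100, noise_cv = 0,
                                          expressed_fraction = 0, seed = 8))
  pm <- ser$probes$probe_type == "PM"
  expect_equal(ser$intensities[pm, ], ser$intensities[!pm, ],
               tolerance = 1e-12)
})

test_that("washing shifts the intensity distribution like the real chips", {
  ser <- chip_sigmoid_clean()
  l0 <- log10(ser$intensities[, "I_t0"])
  l17 <- log10(ser$intensities[, "I_t17"])
  # right flank (top 1%) nearly fixed, left flank down by ~ -log10 w_min
  expect_lt(quantile(l0, 0.99) - quantile(l17, 0.99), 0.05)
  wp <- ser$config$washing$params
  expect_equal(unname(quantile(l0, 0.25) - quantile(l17, 0.25)),
               -log10(wp$w_min), tolerance = 0.05)
})

test_that("re-labelling scales duplex classes by their enrichment factors", {
  base <- chip_config(n_sets = 200, noise_cv = 0, seed = 9)
  ser <- generate_chip_series(base)
  r2 <- apply_relabeling(ser, noise_cv = 0)
  tr <- ser$truth
  pure_S <- tr$X_S > 100 * tr$X_N
  ratio <- r2$intensities[pure_S, "I_t17"] / ser$intensities[pure_S, "I_t17"]
  expect_equal(unname(ratio), unname(1 + tr$w_S[pure_S, "I_t17"]),
               tolerance = 1e-9)
  # lossless washing doubles every intensity
  nowash <- generate_chip_series(chip_config(
    n_sets = 50, noise_cv = 0, seed = 10,
    washing = list(driver = "powerlaw", eta = c(N = 0, PM_S = 0, MM_S = 0))))
  doubled <- apply_relabeling(nowash, noise_cv = 0)
  expect_equal(doubled$intensities, 2 * nowash$intensities,
               tolerance = 1e-12)
  # scanner ceiling clips and creates a point mass
  clip <- ser$M / 10
  r3 <- apply_relabeling(ser, clip_at = clip, noise_cv = 0)
  expect_equal(max(r3$intensities), clip)
  expect_gt(sum(r3$intensities == clip), 10)
  expect_error(apply_relabeling(ser, clip_at = -1), "positive")
})

test_that("probe tables round-trip through disk", {
  ser <- generate_chip_series(chip_config(n_sets = 40, seed = 11))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_chip_table(ser, f)
  back <- read_chip_table(f)
  expect_equal(unname(back$intensities), unname(ser$intensities))
  expect_identical(back$probes, ser$probes)
  expect_equal(back$timepoints, ser$timepoints)
  expect_equal(back$M, ser$M)
  expect_equal(unname(back$truth$w_S), unname(ser$truth$w_S))
  # malformed file: missing sequence column
  tab <- read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  tab$sequence <- NULL
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(sprintf("#timepoints\t%s",
                       paste(ser$timepoints, collapse = ",")),
               sprintf("#M\t%g", ser$M)), f2)
  suppressWarnings(write.table(tab, f2, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  expect_error(read_chip_table(f2), "sequence")
  # config validation
  expect_error(chip_config(timepoints = c(2, 17)), "include 0")
  expect_error(chip_config(expressed_fraction = 2), "expressed_fraction")
  expect_error(chip_config(washing = list(driver = "powerlaw")), "eta")
})
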