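test_that("single-signature simulation concentrates on the generating spectrum", {
  cat30 <- default_signature_catalog()
  sp <- simulate_spectrum(1, 10000, c("22" = 1), cat30, seed = 21)
  emp <- sp[1, ] / sum(sp[1, ])
  l1 <- sum(abs(emp - cat30$probs["22", ]))
  expect_lt(l1, 0.05)
  # direct resampling oracle: an independent multinomial draw from the truth
  # lands at a comparable distance, confirming the bound is the sampling one
  set.seed(99)
  oracle <- as.numeric(stats::rmultinom(1, 10000, cat30$probs["22", ]))
  l1_oracle <- sum(abs(oracle / 10000 - cat30$probs["22", ]))
  expect_lt(l1_oracle, 0.05)
})

test_that("an unbiased strand setting yields symmetric strand counts", {
  cfg <- tiny_cohort_config(seed = 5)
  cfg$strand_bias[] <- 0.5
  cfg$unknown_strand_fraction <- 0
  cfg$mutations_per_sample <- list(mean = 400, dispersion = Inf)
  b <- simulate_cohort(cfg)
  sb <- strand_bias_test(b$mutations, "T>A")
  n <- sb$n_transcribed + sb$n_untranscribed
  expect_lt(abs(sb$n_transcribed - n / 2), 3 * sqrt(n * 0.25) + 1)
})

test_that("identical seeds give identical bundles, different seeds differ", {
  b1 <- simulate_cohort(tiny_cohort_config(seed = 11))
  b2 <- simulate_cohort(tiny_cohort_config(seed = 11))
  expect_identical(b1[setdiff(names(b1), "config")],
                   b2[setdiff(names(b2), "config")])
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(b1, d1); write_cohort(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  b3 <- simulate_cohort(tiny_cohort_config(seed = 12))
  expect_false(identical(b1$mutations, b3$mutations))
  expect_false(identical(b1$control_segments$log2_value,
                         b3$control_segments$log2_value))
})

test_that("controls are aberration-free draws around the diploid baseline", {
  cfg <- cohort_config(n_controls = 10, seed = 31)
  ctrl <- simulate_controls(cfg)
  # Gaussian sampling oracle: the per-bin mean of 10 controls at noise sd
  # 0.1 is N(0, 0.1/sqrt(10)), so P(|mean| < 0.05) = 2*pnorm(1.581) - 1
  # = 0.886.  The observed fraction over the 200 bins must sit within
  # 3 binomial SEs of that value.
  bin_mean <- tapply(ctrl$log2_value, paste(ctrl$chrom, ctrl$start), mean)
  p_oracle <- 2 * pnorm(0.05 / (0.1 / sqrt(10))) - 1
  n_bins <- length(bin_mean)
  se <- sqrt(p_oracle * (1 - p_oracle) / n_bins)
  expect_lt(abs(mean(abs(bin_mean) < 0.05) - p_oracle), 3 * se)

  cfg0 <- tiny_cohort_config(seed = 31)
  cfg0$cnv$noise_sd <- 0
  ctrl0 <- simulate_controls(cfg0)
  expect_true(all(ctrl0$log2_value == 0))

  cfg_bad <- tiny_cohort_config(seed = 1)
  cfg_bad$n_controls <- 1L
  expect_validation_error(simulate_controls(cfg_bad))
})

test_that("degenerate requests fail loudly instead of emitting empty files", {
  expect_validation_error(cohort_config(mutations_per_sample = list(mean = 0, dispersion = 2)))
  expect_validation_error(
    cohort_config(tcr = list(zipf_exponent = c(primary_no_relapse = 1,
                                               primary_with_relapse = 1,
                                               relapsed = 1.3),
                             n_clones = 0L, n_reads = 100L,
                             length_mode = c(primary_no_relapse = 15,
                                             primary_with_relapse = 15,
                                             relapsed = 14),
                             length_sd = 1.5, productive_rate = 0.9)))
  expect_validation_error(simulate_spectrum(2, 0, c("1" = 1),
                                            default_signature_catalog()))
  expect_validation_error(
    cohort_config(group_exposures = list(primary_no_relapse = c("1" = 0.5),
                                         primary_with_relapse = c("1" = 1),
                                         relapsed = c("1" = 1))))
})

test_that("generated exposures are recoverable by NNLS refitting", {
  cat30 <- default_signature_catalog()
  sub <- signature_catalog(c("1", "13", "22"),
                           cat30$probs[c("1", "13", "22"), ])
  truth <- c("1" = 0.2, "13" = 0.5, "22" = 0.3)
  l1 <- vapply(1:20, function(s) {
    sp <- simulate_spectrum(1, 5000, truth, cat30, seed = 100 + s)
    refit <- refit_exposures(sp, sub)
    sum(abs(refit$contributions[1, ] - truth))
  }, numeric(1))
  expect_lte(mean(l1), 0.10)
})

test_that("simulated tables satisfy the io validators", {
  b <- simulate_cohort(tiny_cohort_config(seed = 3))
  expect_silent(validate_mutations(b$mutations))
  expect_true(all(b$clonotypes$read_count >= 1))
  expect_true(all(b$neoantigens$kd_mutant_nM > 0))
  expect_true(all(nchar(b$neoantigens$peptide) %in% 9:11))
  expect_true(all(b$segments$length_bp == b$segments$end - b$segments$start + 1))
  expect_false(anyDuplicated(b$meta$sample_id) > 0)
})
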