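test_that("TMB counts missense mutations over the targeted territory", {
  mut <- do.call(rbind, lapply(1:340, function(i) mut_row(pos = i)))
  expect_equal(tmb(mut)$tmb_per_mb, 10.0)
  silent <- mut_row(variant_class = "silent")
  expect_equal(tmb(silent)$tmb_per_mb, 0.0)
  mixed <- rbind(do.call(rbind, lapply(1:12, function(i) mut_row(pos = i))),
                 do.call(rbind, lapply(13:20, function(i)
                   mut_row(pos = i, variant_class = "silent"))))
  res <- tmb(mixed)
  expect_equal(res$n_missense, 12L)
  expect_equal(res$tmb_per_mb, 12 / 34)
  expect_validation_error(tmb(mixed, region_mb = 0))
})

test_that("MSI bands classify boundaries as stated", {
  expect_equal(classify_msi(2.9), "MSS")
  expect_equal(classify_msi(3), "indeterminate")
  expect_equal(classify_msi(10.0), "indeterminate")
  expect_equal(classify_msi(10.01), "MSI_high")
  expect_equal(classify_msi(c(0, 5, 11)),
               c("MSS", "indeterminate", "MSI_high"))
  expect_validation_error(classify_msi(-1))
})

test_that("neoantigen filter applies the K_D and mutant-tighter rules", {
  cand <- rbind(
    neo_row(mutation_key = "a", kd_mutant_nM = 400, kd_wildtype_nM = 600),
    neo_row(mutation_key = "b", kd_mutant_nM = 400, kd_wildtype_nM = 300),
    neo_row(mutation_key = "c", kd_mutant_nM = 600, kd_wildtype_nM = 900),
    neo_row(mutation_key = "d", kd_mutant_nM = NA, kd_wildtype_nM = 500),
    neo_row(mutation_key = "e", kd_mutant_nM = 100, kd_wildtype_nM = 100)
  )
  kept <- filter_neoantigens(cand)
  expect_equal(kept$mutation_key, "a")
  rej <- attr(kept, "rejected")
  expect_equal(rej$reason[match(c("b", "c", "d", "e"), rej$mutation_key)],
               c("not_tighter_than_wildtype", "kd_above_threshold",
                 "missing_kd", "not_tighter_than_wildtype"))
  # expression filter only when enabled
  cand2 <- neo_row(expressed = FALSE)
  expect_equal(nrow(filter_neoantigens(cand2)), 1L)
  expect_equal(nrow(filter_neoantigens(cand2, require_expressed = TRUE)), 0L)
})

test_that("the filter is idempotent and order-independent", {
  set.seed(31)
  cand <- do.call(rbind, lapply(1:50, function(i) {
    neo_row(mutation_key = paste0("m", i),
            kd_mutant_nM = exp(runif(1, log(10), log(2000))),
            kd_wildtype_nM = exp(runif(1, log(10), log(2000))))
  }))
  kept <- filter_neoantigens(cand)
  expect_equal(filter_neoantigens(kept), kept, ignore_attr = TRUE)
  perm <- cand[sample.int(nrow(cand)), ]
  kept_perm <- filter_neoantigens(perm)
  expect_equal(sort(kept_perm$mutation_key), sort(kept$mutation_key))
})

test_that("neoantigen percentage is a mutation-level rate, duplicate-proof", {
  mut <- do.call(rbind, lapply(1:10, function(i) mut_row(pos = i)))
  keys <- mutation_key(mut)[1:3]
  kept <- do.call(rbind, lapply(keys, function(k) neo_row(mutation_key = k)))
  expect_equal(neoantigen_percentage(mut, kept)$neoantigen_pct, 30.0)
  # duplicated candidate rows for one mutation do not inflate the rate
  expect_equal(neoantigen_percentage(mut, rbind(kept, kept))$neoantigen_pct, 30.0)
  all_kept <- do.call(rbind, lapply(mutation_key(mut), function(k)
    neo_row(mutation_key = k)))
  expect_equal(neoantigen_percentage(mut, all_kept)$neoantigen_pct, 100.0)
  silent_only <- mut_row(variant_class = "silent")
  res <- neoantigen_percentage(silent_only, kept[0, ])
  expect_true(res$flagged && is.na(res$neoantigen_pct))
  # secondary per-candidate basis
  cand <- rbind(kept, neo_row(mutation_key = "zz", kd_mutant_nM = 900))
  res2 <- neoantigen_percentage(mut, kept, all_candidates = cand)
  expect_equal(res2$candidate_pct, 100 * 3 / 4)
})

test_that("generator group rates are recovered within sampling error", {
  b <- simulate_cohort(cohort_config(seed = 23))
  kept <- filter_neoantigens(b$neoantigens)
  pct <- merge(neoantigen_percentage(b$mutations, kept), b$meta,
               by = "sample_id")
  for (g in c("primary_with_relapse", "relapsed")) {
    truth <- 100 * b$config$neo$p_neoantigen[[g]]
    x <- pct$neoantigen_pct[pct$group == g]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - truth), 3 * se + 1e-9)
  }
})

test_that("per-cluster fractions and ranking match the sort oracle", {
  mut <- do.call(rbind, lapply(1:4, function(i)
    mut_row(pos = i, cluster_id = "C1")))
  kept <- do.call(rbind, lapply(mutation_key(mut)[1:2], function(k)
    neo_row(mutation_key = k)))
  res <- cluster_neoantigen_fraction(mut, kept)
  expect_equal(res$fraction, 0.5)

  set.seed(17)
  mut2 <- random_mut_table(60, seed = 17)
  mut2$cluster_id <- sample(c("C1", "C2", "C3"), 60, replace = TRUE)
  mut2$cluster_id[1:5] <- NA
  kept2 <- do.call(rbind, lapply(sample(mutation_key(mut2), 20), function(k)
    neo_row(mutation_key = k)))
  res2 <- cluster_neoantigen_fraction(mut2, kept2)
  expect_equal(res2$fraction, sort(res2$fraction, decreasing = TRUE))
  expect_equal(res2$rank, rank(-res2$fraction, ties.method = "min"))
  expect_equal(nrow(attr(res2, "unassigned")), 5L)

  none <- mut_row()
  expect_warning(empty <- cluster_neoantigen_fraction(none, kept), "no cluster")
  expect_equal(nrow(empty), 0L)
})
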