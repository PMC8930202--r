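test_that("productive filter requires both flags", {
  cl <- rbind(clono_row(cdr3_aa = "CAAAF", productive = TRUE, in_frame = TRUE),
              clono_row(cdr3_aa = "CBBBF", productive = TRUE, in_frame = FALSE),
              clono_row(cdr3_aa = "CCCCF", productive = FALSE, in_frame = TRUE))
  expect_equal(productive_filter(cl)$cdr3_aa, "CAAAF")
  expect_equal(nrow(productive_filter(cl[0, ])), 0L)
})

test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon_diversity(clono_row()), 0.0)
  four <- do.call(rbind, lapply(c("CAAF", "CCAF", "CGAF", "CTAF"), function(s)
    clono_row(cdr3_aa = s, read_count = 25L)))
  expect_equal(shannon_diversity(four), log(4))
  mix <- rbind(clono_row(cdr3_aa = "CAAF", read_count = 2L),
               clono_row(cdr3_aa = "CCAF", read_count = 1L),
               clono_row(cdr3_aa = "CGAF", read_count = 1L))
  # frequencies (0.5, 0.25, 0.25)
  expect_equal(shannon_diversity(mix), 1.0397, tolerance = 1e-4)
  expect_equal(shannon_diversity(mix),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  # identical CDR3 rows are merged before frequencies are formed
  split_rows <- rbind(clono_row(read_count = 7L), clono_row(read_count = 3L))
  expect_equal(shannon_diversity(split_rows), 0.0)
  # clonotype-uniform weighting gives ln n regardless of counts
  expect_equal(shannon_diversity(mix, weighting = "clonotypes"), log(3))
})

test_that("SDI is maximal iff uniform and decreases under mass transfer", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    counts <- sample(1:50, n, replace = TRUE)
    cl <- do.call(rbind, lapply(seq_len(n), function(i)
      clono_row(cdr3_aa = paste0("C", paste(sample(LETTERS, 6, TRUE),
                                            collapse = ""), i, "F"),
                read_count = counts[i])))
    sdi <- shannon_diversity(cl)
    expect_lte(sdi, log(n) + 1e-12)
    # transfer mass from a rarer to a more common clone: diversity drops
    o <- order(counts)
    rare <- o[1]; common <- o[n]
    if (counts[common] > counts[rare]) {
      cl2 <- cl
      cl2$read_count[rare] <- cl2$read_count[rare] - 1L
      cl2$read_count[common] <- cl2$read_count[common] + 1L
      cl2 <- cl2[cl2$read_count > 0, ]
      expect_lt(shannon_diversity(cl2), sdi)
    }
  }
  uniform <- do.call(rbind, lapply(1:8, function(i)
    clono_row(cdr3_aa = paste0("CAA", i, "F"), read_count = 5L)))
  expect_equal(shannon_diversity(uniform), log(8), tolerance = 1e-12)
})

test_that("length distributions report modes with smallest-length tie-breaking", {
  cl <- rbind(clono_row(cdr3_aa = strrep("A", 15), read_count = 1L),
              clono_row(cdr3_aa = strrep("G", 15), read_count = 1L),
              clono_row(cdr3_aa = strrep("A", 14), read_count = 1L))
  ld <- length_distribution(cl)
  expect_equal(ld$mode, 15L)
  expect_false(ld$mode_tied)
  # reads vs clonotypes weighting differ on skewed counts
  skew <- rbind(clono_row(cdr3_aa = strrep("A", 14), read_count = 90L),
                clono_row(cdr3_aa = strrep("G", 15), read_count = 30L),
                clono_row(cdr3_aa = strrep("W", 15), read_count = 20L))
  expect_equal(length_distribution(skew, "reads")$mode, 14L)
  expect_equal(length_distribution(skew, "clonotypes")$mode, 15L)
  # tie -> smallest length with flag
  tie <- rbind(clono_row(cdr3_aa = strrep("A", 14), read_count = 5L),
               clono_row(cdr3_aa = strrep("G", 15), read_count = 5L))
  ldt <- length_distribution(tie)
  expect_equal(ldt$mode, 14L)
  expect_true(ldt$mode_tied)
  expect_equal(sum(ld$histogram$fraction), 1.0)
})

test_that("generator length modes are recovered across seeds", {
  # group-average length distribution (pooled productive clonotypes,
  # clonotype-weighted), the way per-group length spectra are summarised
  hits <- 0L
  for (s in 1:20) {
    b <- simulate_cohort(tiny_cohort_config(seed = 300 + s))
    cl <- merge(b$clonotypes, b$meta, by = "sample_id")
    pri <- productive_filter(cl[cl$group %in% c("primary_no_relapse",
                                                "primary_with_relapse"), ])
    rel <- productive_filter(cl[cl$group == "relapsed", ])
    if (length_distribution(pri, "clonotypes")$mode == 15 &&
        length_distribution(rel, "clonotypes")$mode == 14) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L)
})

test_that("abundance classes bin clonotype frequencies as declared", {
  four <- do.call(rbind, lapply(1:4, function(i)
    clono_row(cdr3_aa = paste0("CAA", i, "F"), read_count = 10L)))
  ab <- abundance_classes(four)   # every clone at 0.25 -> hyperexpanded
  expect_equal(unname(ab["hyperexpanded"]), 1.0)
  expect_equal(sum(ab), 1.0)

  many <- do.call(rbind, lapply(1:10000, function(i)
    clono_row(cdr3_aa = paste0("C", i, "F"), read_count = 1L)))
  expect_equal(unname(abundance_classes(many)["rare"]), 1.0)

  set.seed(71)
  counts <- sample(1:2000, 50)
  cl <- do.call(rbind, lapply(seq_along(counts), function(i)
    clono_row(cdr3_aa = paste0("CX", i, "F"), read_count = counts[i])))
  ab2 <- abundance_classes(cl)
  # brute-force binning oracle
  p <- counts / sum(counts)
  edges <- c(0, 1e-4, 1e-3, 1e-2, 1e-1, 1)
  oracle <- vapply(1:5, function(k)
    mean(p > edges[k] & p <= edges[k + 1]), numeric(1))
  expect_equal(unname(ab2), oracle)
  expect_validation_error(abundance_classes(cl, edges = c(0.5, 0.2, 1),
                                            class_names = c("a", "b", "c")))
})

test_that("relapsed repertoires are less diverse than primaries across cohorts", {
  wins <- 0L
  for (s in 1:10) {
    b <- simulate_cohort(tiny_cohort_config(seed = 400 + s))
    summ <- merge(repertoire_summary(b$clonotypes), b$meta, by = "sample_id")
    if (mean(summ$sdi[summ$group == "relapsed"]) <
        mean(summ$sdi[summ$group %in% c("primary_no_relapse",
                                        "primary_with_relapse")])) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 9L)
})

test_that("repertoire summaries apply the productive filter first", {
  cl <- rbind(clono_row(sample_id = "S1", cdr3_aa = "CAAAAAAAAF",
                        read_count = 10L),
              clono_row(sample_id = "S1", cdr3_aa = "CGGGGGGGGF",
                        read_count = 10L, productive = FALSE))
  summ <- repertoire_summary(cl)
  expect_equal(summ$n_clonotypes, 1L)
  expect_equal(summ$n_reads_productive, 10L)
  expect_equal(summ$sdi, 0.0)
})
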