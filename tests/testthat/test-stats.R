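# Independent brute-force oracles ------------------------------------------

brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- drop(signs %*% r)
  min(1, 2 * min(mean(W_all <= W_obs + 1e-9), mean(W_all >= W_obs - 1e-9)))
}

brute_rank_sum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  picks <- utils::combn(length(pooled), m)
  U_all <- apply(picks, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(U_all <= U_obs + 1e-9), mean(U_all >= U_obs - 1e-9)))
}

brute_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); k <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, k - (N - m)):min(k, m)
  pr <- choose(m, support) * choose(N - m, k - support) / choose(N, k)
  sum(pr[pr <= pr[support == tab[1, 1]] * (1 + 1e-7)])
}

# ---------------------------------------------------------------------------

test_that("eight uniformly signed pairs give the exact two-sided p 0.0078125", {
  res <- wilcoxon_signed_rank(c(3, 1, 4, 1, 5, 9, 2, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 2^8)
  expect_equal(round(res$p_value, 4), 0.0078)
  # antisymmetric differences are maximally null
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1.0)
})

test_that("exact signed-rank p matches 2^n enumeration, ties included", {
  set.seed(91)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)   # heavy ties
    expect_equal(wilcoxon_signed_rank(d)$p_value, brute_signed_rank_p(d),
                 tolerance = 1e-12, label = paste("seeded rep", rep))
  }
})

test_that("zeros are dropped before ranking; all-zero input errors", {
  expect_equal(wilcoxon_signed_rank(c(0, 0, 3, 1, 4))$n_used, 3L)
  expect_equal(wilcoxon_signed_rank(c(0, 0, 3, 1, 4))$p_value,
               wilcoxon_signed_rank(c(3, 1, 4))$p_value)
  expect_validation_error(wilcoxon_signed_rank(c(0, 0, 0)))
})

test_that("large-sample signed-rank approximation tracks the exact value", {
  set.seed(92)
  d <- rnorm(30) + 0.4
  approx <- wilcoxon_signed_rank(d)            # n > 25 -> normal approx
  exact <- wilcoxon_signed_rank(d, exact_limit = 30L)
  expect_false(approx$exact)
  expect_lt(abs(approx$p_value - exact$p_value) /
              max(exact$p_value, 1e-3), 0.25)
})

test_that("rank-sum test matches enumeration and handles degenerate input", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 6)
  expect_equal(wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7))$p_value, 1.0)
  set.seed(93)
  for (rep in 1:10) {
    x <- sample(1:100, sample(3:8, 1))
    y <- sample(101:200, sample(3:8, 1)) / 2.7   # no ties with x
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, brute_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
  expect_validation_error(wilcoxon_rank_sum(numeric(0), 1:3))
})

test_that("Fisher's exact test matches full table enumeration", {
  res <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(res$p_value, brute_fisher_p(matrix(c(5, 0, 0, 5), 2)),
               tolerance = 1e-12)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2))$p_value, 1.0)
  set.seed(94)
  for (rep in 1:15) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_value, brute_fisher_p(tab),
                 tolerance = 1e-12)
  }
  expect_validation_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)))
  # one-sided tail agrees with the hypergeometric survival function
  tab <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab, "greater")$p_value,
               sum(dhyper(8:10, 10, 10, 11)), tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up formula and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(95)
  p <- runif(40)
  adj <- bh_fdr(p)
  expect_equal(adj, p.adjust(p, "BH"))          # reference implementation
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_equal(bh_fdr(c(0.1, NA, 0.5)), c(0.2, NA, 0.5))
  expect_validation_error(bh_fdr(c(0.5, 1.2)))
})

test_that("Kaplan-Meier matches forced cases and the survival package", {
  skip_if_not_installed("survival")
  # 24 subjects: 12 events at t = 5, 12 censored later -> S(5) = 0.5
  time <- c(rep(5, 12), rep(20, 12))
  event <- c(rep(1, 12), rep(0, 12))
  km <- kaplan_meier(time, event)
  expect_equal(km$surv[km$time == 5], 0.5)
  # all censored -> flat at 1 with a flag
  km0 <- kaplan_meier(rep(10, 5), rep(0, 5))
  expect_true(km0$no_events)
  expect_length(km0$surv, 0L)
  # random data vs survival::survfit, including Greenwood CI
  set.seed(96)
  t2 <- rexp(40, 0.1); e2 <- rbinom(40, 1, 0.7)
  km2 <- kaplan_meier(t2, e2)
  ref <- survival::survfit(survival::Surv(t2, e2) ~ 1, conf.type = "log")
  at_events <- ref$n.event > 0
  expect_equal(km2$surv, ref$surv[at_events], tolerance = 1e-12)
  expect_equal(km2$lower, ref$lower[at_events], tolerance = 1e-9)
  expect_equal(km2$upper, ref$upper[at_events], tolerance = 1e-9)
  expect_validation_error(kaplan_meier(c(-1, 2), c(1, 1)))
})

test_that("log-rank agrees with survival::survdiff and is null-calibrated", {
  skip_if_not_installed("survival")
  set.seed(97)
  t <- rexp(60, 0.1); e <- rbinom(60, 1, 0.8)
  g <- rep(c("a", "b"), 30)
  lr <- log_rank(t, e, g)
  ref <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$statistic, ref$chisq, tolerance = 1e-9)
  expect_equal(lr$p_value, stats::pchisq(ref$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # two identical groups: mean chi-square ~ 1 over null simulations
  stats_null <- replicate(100, {
    tt <- rexp(40, 0.1); ee <- rbinom(40, 1, 0.8)
    log_rank(tt, ee, rep(c("a", "b"), 20))$statistic
  })
  expect_lt(abs(mean(stats_null) - 1), 3 * sqrt(2) / sqrt(100))
  expect_false(is.finite(log_rank(c(1, 2), c(0, 0), c("a", "b"))$p_value))
  expect_validation_error(log_rank(1:3, c(1, 1, 1), c("a", "b", "c")))
})

test_that("signed-rank type-I error is near-nominal and conservative", {
  set.seed(98)
  reps <- 10000
  rej <- 0L
  for (i in seq_len(reps)) {
    if (wilcoxon_signed_rank(rnorm(8))$p_value <= 0.05) rej <- rej + 1L
  }
  rate <- rej / reps
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.06)
})

test_that("compare_groups pairs by patient and reproduces the manual test", {
  meta <- data.frame(
    sample_id = c(paste0("P", 1:8, "_s0"), paste0("P", 1:8, "_s1")),
    patient_id = rep(paste0("P", 1:8), 2),
    group = rep(c("primary_with_relapse", "relapsed"), each = 8),
    timepoint_order = rep(0:1, each = 8), stringsAsFactors = FALSE
  )
  set.seed(99)
  v0 <- rnorm(8); v1 <- v0 + 1   # every pair increases
  values <- data.frame(sample_id = meta$sample_id, value = c(v0, v1))
  res <- compare_groups(values, meta, c("primary_with_relapse", "relapsed"),
                        paired = TRUE)
  expect_equal(res$p_value, wilcoxon_signed_rank(v0, v1)$p_value)
  expect_equal(res$p_value, 2 / 2^8)
  res_u <- compare_groups(values, meta, c("primary_with_relapse", "relapsed"),
                          paired = FALSE)
  expect_equal(res_u$p_value, wilcoxon_rank_sum(v0, v1)$p_value)
})
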