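test_that("a single generating signature is recovered at k = 1", {
  cat30 <- default_signature_catalog()
  sp <- simulate_spectrum(6, 3000, c("1" = 1), cat30, seed = 3)
  fit <- extract_signatures(sp, k_range = 1:3, n_restarts = 12, seed = 3)
  expect_equal(fit$selected_k, 1L)
  expect_true(fit$stable)
  cos <- match_to_catalog(fit$signatures$probs[1, ], cat30)
  expect_equal(cos$name, "1")
  expect_gte(cos$cosine, 0.99)
})

test_that("two well-separated signatures are recovered at k = 2", {
  cat30 <- default_signature_catalog()
  sp <- rbind(simulate_spectrum(3, 5000, c("1" = 0.8, "22" = 0.2), cat30, seed = 4),
              simulate_spectrum(3, 5000, c("1" = 0.2, "22" = 0.8), cat30, seed = 5))
  rownames(sp) <- paste0("S", 1:6)
  fit <- extract_signatures(sp, k_range = 1:3, n_restarts = 12, seed = 4)
  expect_equal(fit$selected_k, 2L)
  hits <- vapply(c("1", "22"), function(nm) {
    max(apply(fit$signatures$probs, 1, function(s)
      sum(s * cat30$probs[nm, ]) /
        sqrt(sum(s^2) * sum(cat30$probs[nm, ]^2))))
  }, numeric(1))
  expect_true(all(hits > 0.95))
  # nested model monotonicity: higher rank never fits worse
  expect_true(all(diff(fit$report$loss) <= 1e-6))
})

test_that("extraction is invariant to sample order", {
  cat30 <- default_signature_catalog()
  sp <- rbind(simulate_spectrum(3, 4000, c("2" = 0.9, "1" = 0.1), cat30, seed = 6),
              simulate_spectrum(3, 4000, c("2" = 0.2, "1" = 0.8), cat30, seed = 7))
  rownames(sp) <- paste0("S", 1:6)
  perm <- c(4, 2, 6, 1, 3, 5)
  f1 <- extract_signatures(sp, k_range = 1:2, n_restarts = 10, seed = 9)
  f2 <- extract_signatures(sp[perm, ], k_range = 1:2, n_restarts = 10, seed = 9)
  expect_equal(f1$selected_k, f2$selected_k)
  for (i in seq_len(f1$selected_k)) {
    best <- max(apply(f2$signatures$probs, 1, function(s)
      sum(s * f1$signatures$probs[i, ]) /
        sqrt(sum(s^2) * sum(f1$signatures$probs[i, ]^2))))
    expect_gte(best, 0.995)
  }
})

test_that("empty or invalid spectra are rejected", {
  expect_validation_error(extract_signatures(matrix(0L, 2, 96)))
  sp <- simulate_spectrum(2, 100, c("1" = 1), default_signature_catalog())
  expect_validation_error(extract_signatures(sp, k_range = 0:2))
  expect_validation_error(extract_signatures(sp, k_range = 1:50))
})

test_that("match_to_catalog equals the brute-force cosine maximum", {
  cat30 <- default_signature_catalog()
  expect_equal(match_to_catalog(cat30$probs["22", ], cat30),
               list(name = "22", cosine = 1, tie = FALSE))
  set.seed(10)
  for (rep in 1:5) {
    v <- stats::runif(96); v <- v / sum(v)
    m <- match_to_catalog(v, cat30)
    oracle <- apply(cat30$probs, 1, function(p)
      sum(v * p) / sqrt(sum(v^2) * sum(p^2)))
    expect_equal(m$cosine, max(oracle), tolerance = 1e-12)
    expect_equal(m$name, names(which.max(oracle)))
  }
  # orthogonal indicator vectors have cosine 0
  a <- numeric(96); a[1] <- 1
  b <- numeric(96); b[2] <- 1
  single <- signature_catalog("x", matrix(b, 1))
  expect_equal(match_to_catalog(a, single)$cosine, 0)
  expect_validation_error(match_to_catalog(numeric(96), cat30))
  # ties are reported, first catalog entry wins
  dup <- signature_catalog(c("a", "b"), rbind(b, b))
  md <- match_to_catalog(b, dup)
  expect_true(md$tie)
  expect_equal(md$name, "a")
})

test_that("nnls_fit is optimal among nonnegative candidates", {
  set.seed(12)
  A <- matrix(stats::runif(96 * 4), 96, 4)
  x_true <- c(2, 0, 1, 0.5)
  b <- drop(A %*% x_true)
  x <- nnls_fit(A, b)
  expect_equal(x, x_true, tolerance = 1e-8)
  # noisy case: residual no worse than any random nonnegative candidate
  b2 <- b + stats::rnorm(96, 0, 0.05)
  x2 <- nnls_fit(A, b2)
  res2 <- sum((A %*% x2 - b2)^2)
  for (i in 1:200) {
    cand <- pmax(0, x2 + stats::rnorm(4, 0, 0.1))
    expect_lte(res2, sum((A %*% cand - b2)^2) + 1e-12)
  }
})

test_that("refit_exposures recovers mixtures and handles degenerate rows", {
  cat30 <- default_signature_catalog()
  sub <- signature_catalog(c("2", "22"), cat30$probs[c("2", "22"), ])
  sp <- simulate_spectrum(1, 10000, c("2" = 0.7, "22" = 0.3), cat30, seed = 13)
  refit <- refit_exposures(sp, sub)
  expect_lt(sum(abs(refit$contributions[1, ] - c(0.7, 0.3))), 0.05)

  pure <- matrix(round(1000 * cat30$probs["22", ]), 1,
                 dimnames = list("s", mutation_channels()))
  r2 <- refit_exposures(pure, sub)
  expect_equal(unname(r2$contributions[1, "22"]), 1.0, tolerance = 1e-6)

  zero <- matrix(0L, 1, 96, dimnames = list("z", mutation_channels()))
  r3 <- refit_exposures(zero, sub)
  expect_equal(r3$flagged, "z")
  expect_true(all(r3$exposures == 0))
})
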