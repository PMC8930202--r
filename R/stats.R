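# Exact nonparametric tests, multiple-testing correction, and survival
# estimators.  Exactness conventions (documented because implementations
# differ): zero differences are dropped before ranking (Wilcoxon's original
# procedure); tied absolute values get mid-ranks; exact signed-rank p-values
# come from a dynamic program over doubled ranks, which enumerates the full
# 2^n sign-flip distribution even under ties; two-sided p = min(1, 2 * min
# tail); above the exact cutoff a normal approximation with tie correction
# and continuity correction is used.

.rk_test <- function(statistic, p_value, n_used, method, exact, ...) {
  structure(list(statistic = statistic, p_value = p_value, n_used = n_used,
                 method = method, exact = exact, ...), class = "rk_test")
}

#' @export
print.rk_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.6g, p = %.6g, n = %d, %s\n", x$method,
              x$statistic, x$p_value, x$n_used,
              if (x$exact) "exact" else "approximate"))
  invisible(x)
}

# Exact distribution of 2*W+ (signed-rank statistic over doubled mid-ranks).
# Returns the probability vector over support 0..sum(r2).
.signed_rank_pmf <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total - r + 1L)]
    f <- g
  }
  f / 2^length(r2)
}

#' Exact Wilcoxon signed-rank test for paired data
#'
#' @param x numeric vector: paired differences, or the first member of each
#'   pair when `y` is given.
#' @param y optional second member of each pair.
#' @param exact_limit maximum n (after dropping zero differences) for exact
#'   enumeration (default 25); larger samples use the normal approximation
#'   with continuity correction.
#' @return an `rk_test` with `statistic` = W (sum of positive signed ranks),
#'   two-sided `p_value`, and `n_used` after zero-dropping.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) rk_validation_error("paired samples differ in length")
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) rk_validation_error("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    pmf <- .signed_rank_pmf(r2)
    w2 <- as.integer(round(2 * W))
    lower <- sum(pmf[seq_len(w2 + 1L)])
    upper <- sum(pmf[(w2 + 1L):length(pmf)])
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  .rk_test(W, p, n, "Wilcoxon signed-rank test", exact)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact when there are no ties and `length(x) + length(y) <= exact_limit`;
#' otherwise a mid-rank normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_limit maximum combined size for exact computation (default 25).
#' @return an `rk_test` with `statistic` = U for `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 25L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) rk_validation_error("both samples must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && m + n <= exact_limit) {
    lower <- stats::pwilcox(U, m, n)
    upper <- 1 - if (U >= 1) stats::pwilcox(U - 1, m, n) else 0
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE
  } else {
    mu <- m * n / 2
    N <- m + n
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  .rk_test(U, p, m + n, "Wilcoxon rank-sum test", exact)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value sums all hypergeometric tables with probability no
#' larger than the observed one; one-sided alternatives sum the matching
#' tail.  The sample odds ratio (ad/bc) is reported.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param alternative `"two.sided"`, `"greater"` (association in the
#'   direction of the first cell) or `"less"`.
#' @return an `rk_test` with `statistic` = odds ratio and an `odds_ratio`
#'   field.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) rk_validation_error("fisher_exact_2x2 needs a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    rk_validation_error("table cells must be nonnegative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  k <- a + c_         # column 1 total
  N <- sum(tab)
  lo <- max(0, k - (N - m)); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, N - m, k)
  p_obs <- stats::dhyper(a, m, N - m, k)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a])
  )
  or <- (a * d) / (b * c_)
  .rk_test(or, min(1, p), N, sprintf("Fisher's exact test (%s)", alternative),
           TRUE, odds_ratio = or)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs passed through).
#' @return adjusted values in the input order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    rk_validation_error("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  if (n) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(n / seq(n, 1) * pv[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' Greenwood variance; confidence bounds on the log-survival scale,
#' S * exp(+/- z * sqrt(sum d / (n (n - d)))).
#'
#' @param time nonnegative follow-up times.
#' @param event 1/TRUE for events, 0/FALSE for censoring.
#' @param conf_level confidence level (default 0.95).
#' @return an `rk_survfit`: data.frame-like list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `lower`, `upper` at each distinct event
#'   time, plus `n` and a `no_events` flag.
#' @export
kaplan_meier <- function(time, event, conf_level = 0.95) {
  if (any(time < 0)) rk_validation_error("times must be nonnegative")
  event <- as.integer(as.logical(event))
  ut <- sort(unique(time[event == 1]))
  n <- length(time)
  if (!length(ut)) {
    return(structure(list(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), n_censor = integer(0),
                          surv = numeric(0), lower = numeric(0),
                          upper = numeric(0), n = n, no_events = TRUE),
                     class = "rk_survfit"))
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  gw[!is.finite(gw)] <- Inf
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- surv * exp(-z * sqrt(gw))
  upper <- pmin(1, surv * exp(z * sqrt(gw)))
  lower[surv == 0] <- NA_real_   # CI undefined once the curve hits zero
  upper[surv == 0] <- NA_real_
  structure(list(time = ut, n_risk = as.integer(n_risk),
                 n_event = as.integer(n_event),
                 n_censor = as.integer(n_censor), surv = surv,
                 lower = lower, upper = upper, n = n, no_events = FALSE),
            class = "rk_survfit")
}

#' @export
print.rk_survfit <- function(x, ...) {
  cat(sprintf("<Kaplan-Meier curve: n = %d, %d event times>\n", x$n,
              length(x$time)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time nonnegative follow-up times.
#' @param event 1/TRUE for events, 0/FALSE for censoring.
#' @param group two-level grouping vector.
#' @return an `rk_test` with the 1-df chi-square statistic; if no events are
#'   observed the p-value is NA and the test flagged undefined.
#' @export
log_rank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) rk_validation_error("log_rank supports exactly two groups")
  event <- as.integer(as.logical(event))
  if (sum(event) == 0L) {
    return(.rk_test(NA_real_, NA_real_, length(time),
                    "log-rank test (no events: undefined)", FALSE))
  }
  ut <- sort(unique(time[event == 1]))
  g1 <- group == levels(group)[1]
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g1)
    d_t <- sum(time == t & event == 1)
    d1_t <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1_t
    E1 <- E1 + d_t * n1_t / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else NA_real_
  p <- if (is.na(chisq)) NA_real_ else stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  .rk_test(chisq, p, length(time), "log-rank test", FALSE)
}

#' Compare a per-sample metric between two cohort groups
#'
#' Paired mode matches the two groups by `patient_id` (one sample per
#' patient per group) and runs the exact signed-rank test; unpaired mode
#' runs the rank-sum test.  Pairing must be declared explicitly.
#'
#' @param values data.frame with `sample_id` and `value`.
#' @param meta sample metadata (see [read_sample_meta()]).
#' @param groups length-2 character vector of group labels to compare.
#' @param paired logical; pair by patient?
#' @return an `rk_test`.
#' @export
compare_groups <- function(values, meta, groups, paired = FALSE) {
  stopifnot(length(groups) == 2L)
  df <- merge(values, meta, by = "sample_id")
  a <- df[df$group == groups[1], ]
  b <- df[df$group == groups[2], ]
  if (!nrow(a) || !nrow(b)) rk_validation_error("empty group in comparison")
  if (paired) {
    common <- intersect(a$patient_id, b$patient_id)
    if (!length(common)) rk_validation_error("no matched patients for paired comparison")
    a <- a[match(common, a$patient_id), ]
    b <- b[match(common, b$patient_id), ]
    wilcoxon_signed_rank(a$value, b$value)
  } else {
    wilcoxon_rank_sum(a$value, b$value)
  }
}
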