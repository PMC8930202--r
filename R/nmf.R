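# NMF signature extraction (KL-divergence multiplicative updates with
# multi-restart stability-based rank selection), catalog matching by cosine
# similarity, and non-negative least-squares exposure refitting.
#
# The rank-selection scheme: for each candidate k, run n_restarts random
# initialisations, match every restart's components to those of the
# best-loss restart by greedy cosine pairing, and call k stable when the
# mean matched cosine is at least `stability`.  Restart stability alone
# cannot reject overfit ranks on low-rank data: the surplus components
# converge, reproducibly, to near-duplicates of the dominant profile (they
# refit the same noise realisation in every restart).  A rank is therefore
# admissible only if it is stable AND its components are mutually distinct
# (maximum pairwise cosine within the best run <= `distinctness`).  The
# selected rank is the largest admissible k; if none, k = 1 with a flag.

.kl_div <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

.nmf_kl_once <- function(V, k, maxit = 1000, tol = 1e-8) {
  # V: channels x samples, W: channels x k, H: k x samples
  nr <- nrow(V); nc <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(nr * k, 0.2, 1), nr, k)
  H <- matrix(stats::runif(k * nc, 0.2, 1), k, nc)
  loss_prev <- Inf
  for (it in seq_len(maxit)) {
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / (matrix(1, nr, 1) %*% rowSums(H) + eps)
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / (colSums(W) %o% rep(1, nc) + eps)
    if (it %% 10L == 0L) {
      loss <- .kl_div(V, W %*% H + eps)
      if (is.finite(loss_prev) && abs(loss_prev - loss) < tol * (abs(loss_prev) + 1)) break
      loss_prev <- loss
    }
  }
  loss <- .kl_div(V, W %*% H + eps)
  # normalise signatures to probability vectors, push scale into H
  s <- colSums(W)
  s[s == 0] <- 1
  W <- sweep(W, 2, s, "/")
  H <- sweep(H, 1, s, "*")
  list(W = W, H = H, loss = loss)
}

# Greedy cosine pairing of the columns of A to the columns of B.
.match_components <- function(A, B) {
  k <- ncol(A)
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sim[i, j] <- cosine_similarity(A[, i], B[, j])
  }
  cos <- numeric(k)
  for (step in seq_len(k)) {
    ij <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    cos[step] <- sim[ij[1], ij[2]]
    sim[ij[1], ] <- -Inf
    sim[, ij[2]] <- -Inf
  }
  mean(cos)
}

#' Extract mutational signatures by NMF with stability-based rank selection
#'
#' KL-divergence multiplicative-update NMF with `n_restarts` random
#' initialisations per candidate rank; deterministic given `seed`.
#'
#' @param spectrum samples x 96 count matrix (see [build_spectrum()]).
#' @param k_range candidate ranks (default 1:4), within 1..min(samples, 96).
#' @param n_restarts restarts per rank (default 30).
#' @param seed integer seed.
#' @param stability minimum mean within-component cosine across restarts for
#'   a rank to count as stable (default 0.85).
#' @param distinctness maximum pairwise cosine allowed between the
#'   components of one rank (default 0.9); ranks whose components are
#'   near-duplicates of each other are overfit and rejected.
#' @return list with `signatures` (a `signature_catalog`, components named
#'   `"S1"`...), `exposures` (samples x k matrix), `contributions` (row-
#'   normalised exposures), `selected_k`, `stable` (FALSE when no rank met
#'   the stability bar and k = 1 was forced), and `report` (per-k loss,
#'   stability and component redundancy).
#' @export
extract_signatures <- function(spectrum, k_range = 1:4, n_restarts = 30L,
                               seed = 1L, stability = 0.85,
                               distinctness = 0.9) {
  V <- t(as.matrix(spectrum))          # channels x samples
  if (!nrow(spectrum) || sum(V) == 0) rk_validation_error("empty spectrum")
  if (any(V < 0)) rk_validation_error("spectrum entries must be nonnegative")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > min(dim(V))) {
    rk_validation_error("k_range must lie within 1..min(samples, 96)")
  }
  report <- data.frame(k = k_range, loss = NA_real_, stability = NA_real_,
                       redundancy = NA_real_)
  fits <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    runs <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      set.seed(child_seed(seed, 1000L * k + r))
      runs[[r]] <- .nmf_kl_once(V, k)
    }
    losses <- vapply(runs, `[[`, numeric(1), "loss")
    best <- runs[[which.min(losses)]]
    stab <- if (k == 1L) {
      mean(vapply(runs, function(r) cosine_similarity(r$W[, 1], best$W[, 1]),
                  numeric(1)))
    } else {
      mean(vapply(runs, function(r) .match_components(r$W, best$W), numeric(1)))
    }
    redund <- if (k == 1L) 0 else {
      Wn <- sweep(best$W, 2, sqrt(colSums(best$W^2)), "/")
      cc <- crossprod(Wn)
      max(cc[upper.tri(cc)])
    }
    report$loss[ki] <- min(losses)
    report$stability[ki] <- stab
    report$redundancy[ki] <- redund
    fits[[ki]] <- best
  }
  stable_ks <- report$k[report$stability >= stability &
                          report$redundancy <= distinctness]
  if (length(stable_ks)) {
    selected_k <- max(stable_ks)
    stable <- TRUE
  } else {
    selected_k <- 1L
    stable <- FALSE
    if (!1L %in% k_range) {
      set.seed(child_seed(seed, 999L))
      fits[[length(fits) + 1L]] <- .nmf_kl_once(V, 1L)
      k_range <- c(k_range, 1L)
    }
  }
  fit <- fits[[match(selected_k, k_range)]]
  signames <- paste0("S", seq_len(selected_k))
  sigs <- signature_catalog(signames, t(fit$W) / rowSums(t(fit$W)))
  exposures <- t(fit$H)
  colnames(exposures) <- signames
  rownames(exposures) <- rownames(spectrum)
  rs <- rowSums(exposures)
  contributions <- exposures / ifelse(rs == 0, 1, rs)
  list(signatures = sigs, exposures = exposures,
       contributions = contributions, selected_k = selected_k,
       stable = stable, report = report)
}

#' Match a signature to its best catalog entry by cosine similarity
#'
#' @param signature nonnegative 96-vector.
#' @param catalog a `signature_catalog`.
#' @return list with `name`, `cosine`, `tie` (TRUE when another entry ties
#'   the maximum within 1e-12; the first in catalog order is reported).
#' @export
match_to_catalog <- function(signature, catalog) {
  if (all(signature == 0)) rk_validation_error("cannot match an all-zero signature")
  cosines <- apply(catalog$probs, 1, function(p) {
    if (all(p == 0)) return(0)
    cosine_similarity(signature, p)
  })
  best <- which.max(cosines)
  tie <- sum(cosines >= cosines[best] - 1e-12) > 1L
  list(name = catalog$names[best], cosine = unname(cosines[best]), tie = tie)
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimises ||A x - b||_2 subject to x >= 0.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @return nonnegative coefficient vector of length n.
#' @export
nnls_fit <- function(A, b) {
  A <- as.matrix(A)
  n <- ncol(A)
  x <- numeric(n)
  P <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  tol <- 1e-10 * max(abs(w), 1)
  iter <- 0L
  while (any(!P) && max(w[!P]) > tol && iter < 30L * n) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      qrP <- qr(A[, P, drop = FALSE])
      s[P] <- qr.coef(qrP, b)
      s[P][is.na(s[P])] <- 0
      if (min(s[P]) > 0) { x <- s; break }
      neg <- P & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
      if (!any(P)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Refit per-sample signature exposures against a fixed catalog
#'
#' Each sample's 96-channel counts are decomposed by non-negative least
#' squares onto the catalog signatures; relative contributions are
#' normalised to sum to 1 per sample.
#'
#' @param spectrum samples x 96 count matrix.
#' @param catalog a `signature_catalog` (e.g. a subset of
#'   [default_signature_catalog()]).
#' @return list with `exposures` (samples x signatures, mutation-count
#'   scale), `contributions` (row-normalised; all-zero samples get zero rows
#'   and are listed in `flagged`).
#' @export
refit_exposures <- function(spectrum, catalog) {
  if (!length(catalog$names)) rk_validation_error("catalog is empty")
  A <- t(catalog$probs)                 # 96 x signatures
  S <- nrow(spectrum)
  expo <- matrix(0, S, length(catalog$names),
                 dimnames = list(rownames(spectrum), catalog$names))
  for (i in seq_len(S)) {
    b <- as.numeric(spectrum[i, ])
    if (sum(b) == 0) next
    expo[i, ] <- nnls_fit(A, b)
  }
  rs <- rowSums(expo)
  flagged <- rownames(spectrum)[rowSums(spectrum) == 0]
  contributions <- expo / ifelse(rs == 0, 1, rs)
  list(exposures = expo, contributions = contributions, flagged = flagged)
}
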