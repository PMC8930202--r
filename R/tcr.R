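# TCR-beta repertoire analysis: productive filtering, Shannon diversity,
# CDR3 length spectra, and clonotype abundance classes.  A clonotype is a
# unique CDR3 amino-acid sequence (V/J calls are ignored for diversity);
# counts of identical CDR3s are merged before any frequency is formed.

#' Keep only productive, in-frame clonotypes
#' @param clonotypes clonotype data.frame (see [read_clonotypes()]).
#' @return the subset with `productive` and `in_frame` both TRUE.
#' @export
productive_filter <- function(clonotypes) {
  clonotypes[clonotypes$productive %in% TRUE & clonotypes$in_frame %in% TRUE, ,
             drop = FALSE]
}

.merge_clonotypes <- function(clonotypes) {
  if (!nrow(clonotypes)) {
    return(data.frame(cdr3_aa = character(0), read_count = integer(0)))
  }
  agg <- stats::aggregate(list(read_count = clonotypes$read_count),
                          by = list(cdr3_aa = clonotypes$cdr3_aa), FUN = sum)
  agg
}

.clonotype_freqs <- function(clonotypes, weighting) {
  m <- .merge_clonotypes(clonotypes)
  if (!nrow(m) || sum(m$read_count) == 0) {
    rk_validation_error("no reads: clonotype frequencies undefined")
  }
  p <- switch(weighting,
              reads = m$read_count / sum(m$read_count),
              clonotypes = rep(1 / nrow(m), nrow(m)))
  data.frame(cdr3_aa = m$cdr3_aa, read_count = m$read_count, p = p,
             stringsAsFactors = FALSE)
}

#' Shannon diversity index of a clonotype repertoire
#'
#' SDI = -sum p_i ln p_i (natural log) over clonotype frequencies, with
#' clonotypes keyed by CDR3 amino-acid sequence.  With `weighting =
#' "reads"` (the primary definition) p_i is the read fraction; with
#' `"clonotypes"` every unique clonotype gets equal weight, so SDI = ln n.
#'
#' @param clonotypes clonotype data.frame (already productive-filtered if
#'   desired; this function does not filter).
#' @param weighting `"reads"` (default) or `"clonotypes"`.
#' @return the diversity index (0 for a single clonotype).
#' @export
shannon_diversity <- function(clonotypes, weighting = c("reads", "clonotypes")) {
  weighting <- match.arg(weighting)
  f <- .clonotype_freqs(clonotypes, weighting)
  -sum(f$p * log(f$p))
}

#' CDR3 amino-acid length distribution
#'
#' @param clonotypes clonotype data.frame.
#' @param weighting `"reads"` (fraction of reads per length, default) or
#'   `"clonotypes"` (fraction of unique clonotypes).
#' @return list with `histogram` (data.frame `length`, `fraction`),
#'   `mode` (smallest length on ties) and `mode_tied` flag.
#' @export
length_distribution <- function(clonotypes, weighting = c("reads", "clonotypes")) {
  weighting <- match.arg(weighting)
  f <- .clonotype_freqs(clonotypes, weighting)
  if (any(!nzchar(f$cdr3_aa))) rk_validation_error("empty CDR3 sequence")
  len <- nchar(f$cdr3_aa)
  agg <- stats::aggregate(list(fraction = f$p), by = list(length = len), FUN = sum)
  agg <- agg[order(agg$length), , drop = FALSE]
  mx <- max(agg$fraction)
  at_max <- agg$length[abs(agg$fraction - mx) < 1e-12]
  list(histogram = agg, mode = min(at_max), mode_tied = length(at_max) > 1L)
}

#' Clonotype abundance-class fractions
#'
#' Default classes on the read frequency of each unique clonotype:
#' rare (0, 1e-4], small (1e-4, 1e-3], medium (1e-3, 1e-2],
#' large (1e-2, 1e-1], hyperexpanded (1e-1, 1].  Reported fractions are of
#' unique clonotypes per class and sum to 1.
#'
#' @param clonotypes clonotype data.frame.
#' @param edges strictly increasing upper bin edges in (0, 1], the last
#'   equal to 1.
#' @param class_names names, one per bin.
#' @return named numeric vector of clonotype fractions per class.
#' @export
abundance_classes <- function(clonotypes,
                              edges = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                              class_names = c("rare", "small", "medium",
                                              "large", "hyperexpanded")) {
  if (any(diff(edges) <= 0) || any(edges <= 0) || edges[length(edges)] != 1) {
    rk_validation_error("edges must be strictly increasing in (0,1] ending at 1")
  }
  if (length(class_names) != length(edges)) {
    rk_validation_error("one class name per bin edge required")
  }
  f <- .clonotype_freqs(clonotypes, "reads")
  if (any(f$p <= 0 | f$p > 1)) {
    rk_validation_error("clonotype frequency outside (0,1]")
  }
  bin <- cut(f$p, breaks = c(0, edges), labels = class_names, right = TRUE)
  out <- as.numeric(table(bin)) / nrow(f)
  names(out) <- class_names
  out
}

#' Summarise one or many TCR repertoires
#'
#' Applies the productive/in-frame filter, then computes reads, unique
#' clonotypes, Shannon diversity, the CDR3 length mode and abundance-class
#' fractions per sample.
#'
#' @param clonotypes clonotype data.frame (multi-sample).
#' @param weighting frequency weighting for SDI and lengths (default reads).
#' @return data.frame, one row per sample.
#' @export
repertoire_summary <- function(clonotypes, weighting = c("reads", "clonotypes")) {
  weighting <- match.arg(weighting)
  rows <- lapply(sort(unique(clonotypes$sample_id)), function(s) {
    cl <- productive_filter(clonotypes[clonotypes$sample_id == s, , drop = FALSE])
    if (!nrow(cl)) {
      return(data.frame(sample_id = s, n_reads_productive = 0L,
                        n_clonotypes = 0L, sdi = NA_real_,
                        length_mode = NA_integer_, stringsAsFactors = FALSE))
    }
    ld <- length_distribution(cl, weighting)
    ab <- abundance_classes(cl)
    out <- data.frame(sample_id = s,
                      n_reads_productive = sum(cl$read_count),
                      n_clonotypes = nrow(.merge_clonotypes(cl)),
                      sdi = shannon_diversity(cl, weighting),
                      length_mode = ld$mode, stringsAsFactors = FALSE)
    for (nm in names(ab)) out[[paste0("frac_", nm)]] <- ab[[nm]]
    out
  })
  do.call(rbind, rows)
}
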