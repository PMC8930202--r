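# Chromosomal-instability scoring: control-referenced per-segment Z-scores,
# the CIN score sum(V_k * L_k), and the mean + 3*SD elevation threshold.
#
# The controls define, on a fixed genomic bin grid, a per-bin mean and SD of
# log2 copy ratio; a tumor segment's Z-score V is the length-weighted mean
# over the bins it covers of (segment value - bin mean) / bin SD.  The
# printed score formula is signed, so gains and losses can cancel; an
# absolute-value mode is provided for magnitude comparisons and each result
# records which mode produced it.

.bin_overlaps <- function(start, end, bin_size) {
  # bins are 1-based: bin b covers [(b-1)*bin_size + 1, b*bin_size]
  first <- (start - 1L) %/% bin_size + 1L
  last <- (end - 1L) %/% bin_size + 1L
  lapply(seq_along(start), function(i) {
    bins <- first[i]:last[i]
    bs <- (bins - 1) * bin_size + 1
    be <- bins * bin_size
    w <- pmin(end[i], be) - pmax(start[i], bs) + 1
    data.frame(bin = bins, w = w)
  })
}

# per-bin, per-sample length-weighted mean log2 value
.bin_values <- function(segments, bin_size) {
  out <- list()
  ov <- .bin_overlaps(segments$start, segments$end, bin_size)
  for (i in seq_len(nrow(segments))) {
    o <- ov[[i]]
    out[[i]] <- data.frame(sample_id = segments$sample_id[i],
                           chrom = segments$chrom[i], bin = o$bin, w = o$w,
                           value = segments$log2_value[i],
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  agg <- stats::aggregate(cbind(vw = df$value * df$w, w = df$w),
                          by = list(sample_id = df$sample_id,
                                    chrom = df$chrom, bin = df$bin), FUN = sum)
  agg$value <- agg$vw / agg$w
  agg
}

#' Control-referenced Z-scores for tumor copy-number segments
#'
#' @param tumor_segments segment data.frame (see [read_segments()]).
#' @param control_segments segments for >= 2 control samples.
#' @param bin_size genomic bin width in bp (default 1e6).
#' @param sd_floor lower bound applied to control per-bin SDs (default
#'   1e-6); bins floored are counted in the `n_floored_bins` attribute.
#' @return `tumor_segments` with the `zscore` column filled (NA, flagged,
#'   for segments covering no control-characterised bin).
#' @export
segment_zscores <- function(tumor_segments, control_segments, bin_size = 1e6,
                            sd_floor = 1e-6) {
  if (length(unique(control_segments$sample_id)) < 2L) {
    rk_validation_error("need >= 2 control samples to define the reference")
  }
  if (bin_size <= 0) rk_validation_error("bin_size must be positive")
  ctrl <- .bin_values(control_segments, bin_size)
  stats_tab <- stats::aggregate(ctrl$value,
                                by = list(chrom = ctrl$chrom, bin = ctrl$bin),
                                FUN = function(v) c(mean = mean(v),
                                                    sd = stats::sd(v),
                                                    n = length(v)))
  stats_df <- data.frame(chrom = stats_tab$chrom, bin = stats_tab$bin,
                         mean = stats_tab$x[, "mean"], sd = stats_tab$x[, "sd"],
                         n = stats_tab$x[, "n"], stringsAsFactors = FALSE)
  stats_df <- stats_df[stats_df$n >= 2, , drop = FALSE]
  floored <- is.na(stats_df$sd) | stats_df$sd < sd_floor
  stats_df$sd[floored] <- sd_floor
  key <- paste(stats_df$chrom, stats_df$bin)
  out <- tumor_segments
  out$zscore <- NA_real_
  ov <- .bin_overlaps(tumor_segments$start, tumor_segments$end, bin_size)
  for (i in seq_len(nrow(tumor_segments))) {
    o <- ov[[i]]
    k <- paste(tumor_segments$chrom[i], o$bin)
    hit <- match(k, key)
    keep <- !is.na(hit)
    if (!any(keep)) next
    z <- (tumor_segments$log2_value[i] - stats_df$mean[hit[keep]]) /
      stats_df$sd[hit[keep]]
    out$zscore[i] <- sum(z * o$w[keep]) / sum(o$w[keep])
  }
  attr(out, "n_floored_bins") <- sum(floored)
  out
}

#' The chromosomal-instability score of each sample
#'
#' CIN = sum over segments of V_k * L_k (mode `"as_printed"`, signed; gains
#' and losses can cancel) or of |V_k| * L_k (mode `"absolute"`, a
#' cancellation-free instability magnitude used for group comparisons).
#'
#' @param segments segment data.frame with `zscore` and `length_bp` set.
#' @param mode `"as_printed"` (default) or `"absolute"`.
#' @return data.frame per sample: `cin_score`, `n_segments`, `mode`.
#' @export
cin_score <- function(segments, mode = c("as_printed", "absolute")) {
  mode <- match.arg(mode)
  miss <- which(is.na(segments$zscore))
  if (length(miss)) {
    rk_validation_error("segment %d (%s:%d-%d) has no zscore", miss[1],
                        segments$chrom[miss[1]], segments$start[miss[1]],
                        segments$end[miss[1]])
  }
  v <- if (mode == "absolute") abs(segments$zscore) else segments$zscore
  contrib <- v * segments$length_bp
  samples <- unique(segments$sample_id)
  data.frame(
    sample_id = samples,
    cin_score = vapply(samples, function(s) sum(contrib[segments$sample_id == s]),
                       numeric(1)),
    n_segments = vapply(samples, function(s) sum(segments$sample_id == s),
                        numeric(1)),
    mode = mode, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Elevation threshold from control CIN scores
#'
#' threshold = mean(controls) + 3 * SD(controls), sample SD (n - 1
#' denominator); a score is elevated when strictly greater than the
#' threshold.
#'
#' @param control_scores numeric vector of >= 2 control CIN scores.
#' @param scores optional scores to flag.
#' @return list with `threshold` and, when `scores` is given, a logical
#'   `elevated` vector.
#' @export
cin_threshold <- function(control_scores, scores = NULL) {
  if (length(control_scores) < 2L) {
    rk_validation_error("need >= 2 control scores (SD undefined otherwise)")
  }
  thr <- mean(control_scores) + 3 * sample_sd(control_scores)
  out <- list(threshold = thr)
  if (!is.null(scores)) out$elevated <- scores > thr
  out
}
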