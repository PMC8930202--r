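# APOBEC tCw enrichment classification and the APOBEC-high / APOBEC-low
# differential gene analysis.
#
# Definitions (field standard): tCw = a mutated cytosine with 5' thymine and
# 3' adenine or thymine, in pyrimidine representation; APOBEC-type mutations
# counted are C>T and C>G at cytosines.  The background is a pair of
# context fractions (fraction of sites that are tCw, fraction that are C);
# the original +/-20 bp sequence window is not recoverable from a MAF-like
# table, so the fractions are an explicit parameter with a uniform-
# trinucleotide default, and the synthetic generator's truth matches it.

#' Default background context fractions
#'
#' Uniform-trinucleotide background: half of all sites carry a pyrimidine-
#' representable C, and 2 of the 16 flank combinations (T_C_A, T_C_T) are
#' tCw, so `ctx_tcw / ctx_c = 0.125`.
#'
#' @return list with `ctx_tcw` and `ctx_c`.
#' @export
default_context_freqs <- function() list(ctx_tcw = 0.0625, ctx_c = 0.5)

#' APOBEC tCw fold-enrichment classification
#'
#' Per sample: enrichment = (n_tcw_mut / n_c_mut) / (ctx_tcw / ctx_c), a
#' one-sided Fisher's exact test of mutated vs background context counts,
#' Benjamini-Hochberg correction across samples, and the classification
#' rule: APOBEC-high iff enrichment > 2 and FDR-adjusted p < 0.05 (both
#' conditions required), otherwise APOBEC-low.
#'
#' @param mutations internal mutation data.frame.
#' @param context_freqs list with `ctx_tcw`, `ctx_c` background fractions
#'   (default [default_context_freqs()]).
#' @param background_n background site total used to turn the fractions into
#'   Fisher counts (default 1e6).
#' @param enrichment_threshold classification threshold (default 2).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return data.frame with one row per sample: `n_tcw_mut`, `n_c_mut`,
#'   `ctx_tcw`, `ctx_c`, `enrichment`, `p_value`, `fdr`, `label`,
#'   `flagged` (TRUE when no cytosine mutations; excluded from the FDR).
#' @export
apobec_enrichment <- function(mutations, context_freqs = default_context_freqs(),
                              background_n = 1e6,
                              enrichment_threshold = 2,
                              fdr_threshold = 0.05) {
  validate_mutations(mutations)
  if (context_freqs$ctx_tcw <= 0 || context_freqs$ctx_c <= context_freqs$ctx_tcw) {
    rk_validation_error("need 0 < ctx_tcw < ctx_c")
  }
  snv <- .is_snv(mutations$ref_allele, mutations$alt_allele) &
    !is.na(mutations$context3)
  mut <- mutations[snv, , drop = FALSE]
  samples <- sort(unique(mutations$sample_id))
  if (nrow(mut)) {
    idx <- channel_of(mut$ref_allele, mut$alt_allele, mut$context3)
    parts <- channel_parts(idx)
    is_c_mut <- parts$class %in% c("C>T", "C>G")
    is_tcw <- is_c_mut & parts$p5 == "T" & parts$p3 %in% c("A", "T")
  } else {
    is_c_mut <- is_tcw <- logical(0)
  }
  bg_tcw <- round(context_freqs$ctx_tcw * background_n)
  bg_c_other <- round((context_freqs$ctx_c - context_freqs$ctx_tcw) * background_n)
  out <- do.call(rbind, lapply(samples, function(s) {
    sel <- nrow(mut) > 0 & mut$sample_id == s
    n_c <- sum(is_c_mut[sel])
    n_tcw <- sum(is_tcw[sel])
    if (n_c == 0L) {
      return(data.frame(sample_id = s, n_tcw_mut = n_tcw, n_c_mut = n_c,
                        ctx_tcw = context_freqs$ctx_tcw,
                        ctx_c = context_freqs$ctx_c,
                        enrichment = NA_real_, p_value = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    enr <- (n_tcw / n_c) / (context_freqs$ctx_tcw / context_freqs$ctx_c)
    ft <- fisher_exact_2x2(matrix(c(n_tcw, n_c - n_tcw, bg_tcw, bg_c_other),
                                  nrow = 2, byrow = TRUE),
                           alternative = "greater")
    data.frame(sample_id = s, n_tcw_mut = n_tcw, n_c_mut = n_c,
               ctx_tcw = context_freqs$ctx_tcw, ctx_c = context_freqs$ctx_c,
               enrichment = enr, p_value = ft$p_value, flagged = FALSE,
               stringsAsFactors = FALSE)
  }))
  out$fdr <- NA_real_
  out$fdr[!out$flagged] <- bh_fdr(out$p_value[!out$flagged])
  out$label <- ifelse(!out$flagged &
                        out$enrichment > enrichment_threshold &
                        out$fdr < fdr_threshold,
                      "APOBEC_high", "APOBEC_low")
  out$label[out$flagged] <- NA_character_
  rownames(out) <- NULL
  out[, c("sample_id", "n_tcw_mut", "n_c_mut", "ctx_tcw", "ctx_c",
          "enrichment", "p_value", "fdr", "label", "flagged")]
}

#' Differentially mutated genes between APOBEC-high and APOBEC-low samples
#'
#' Per gene, a 2x2 table of samples with/without a mutation in the gene by
#' APOBEC label, a two-sided Fisher's exact test, and Benjamini-Hochberg
#' adjustment across genes.  Genes mutated in no sample are excluded.
#'
#' @param mutations internal mutation data.frame.
#' @param labels data.frame with `sample_id` and `label`
#'   (`"APOBEC_high"`/`"APOBEC_low"`, e.g. from [apobec_enrichment()]).
#' @return data.frame per gene: mutated counts by label, `p_value`, `fdr`,
#'   sorted by p-value.
#' @export
apobec_group_genes <- function(mutations, labels) {
  labels <- labels[!is.na(labels$label), , drop = FALSE]
  hi <- labels$sample_id[labels$label == "APOBEC_high"]
  lo <- labels$sample_id[labels$label == "APOBEC_low"]
  if (!length(hi) || !length(lo)) {
    rk_validation_error("need at least one sample per APOBEC label")
  }
  mut <- mutations[mutations$sample_id %in% c(hi, lo), , drop = FALSE]
  genes <- sort(unique(mut$gene))
  rows <- lapply(genes, function(g) {
    carriers <- unique(mut$sample_id[mut$gene == g])
    a <- sum(hi %in% carriers); b <- length(hi) - a
    c_ <- sum(lo %in% carriers); d <- length(lo) - c_
    ft <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    data.frame(gene = g, n_high_mut = a, n_high_wt = b, n_low_mut = c_,
               n_low_wt = d, odds_ratio = ft$odds_ratio,
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out[order(out$p_value, out$gene), , drop = FALSE]
}
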