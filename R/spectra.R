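# 96-channel spectrum construction and transcriptional strand-bias testing.

#' Build the samples x 96 mutation spectrum matrix
#'
#' Only single-nucleotide variants with a valid trinucleotide context enter
#' the spectrum; everything else (indels, missing context) is excluded and
#' counted in the attached exclusion report.  Row sums equal each sample's
#' included SNV count.
#'
#' @param mutations internal mutation data.frame (see [read_mutations()]).
#' @param samples optional character vector fixing row set and order;
#'   defaults to the samples present, in order of first appearance.  Samples
#'   with zero usable SNVs get a zero row and a warning.
#' @return integer matrix samples x 96 with channel-label columns and an
#'   `excluded` attribute (data.frame sample_id, n_excluded).
#' @export
build_spectrum <- function(mutations, samples = NULL) {
  validate_mutations(mutations)
  if (is.null(samples)) samples <- unique(mutations$sample_id)
  usable <- .is_snv(mutations$ref_allele, mutations$alt_allele) &
    !is.na(mutations$context3) &
    mutations$sample_id %in% samples
  counts <- matrix(0L, nrow = length(samples), ncol = 96,
                   dimnames = list(samples, .CHANNELS))
  if (any(usable)) {
    idx <- channel_of(mutations$ref_allele[usable],
                      mutations$alt_allele[usable],
                      mutations$context3[usable])
    tab <- table(factor(mutations$sample_id[usable], levels = samples),
                 factor(idx, levels = 1:96))
    counts[] <- as.integer(tab)
  }
  in_scope <- mutations$sample_id %in% samples
  excl <- tapply(!usable[in_scope],
                 factor(mutations$sample_id[in_scope], levels = samples), sum)
  excl[is.na(excl)] <- 0L
  zero_rows <- samples[rowSums(counts) == 0L]
  if (length(zero_rows)) {
    warning(sprintf("sample(s) with zero usable SNVs: %s",
                    paste(zero_rows, collapse = ", ")), call. = FALSE)
  }
  attr(counts, "excluded") <- data.frame(sample_id = samples,
                                         n_excluded = as.integer(excl),
                                         row.names = NULL)
  counts
}

#' Exact binomial test of transcriptional strand bias
#'
#' For one pyrimidine substitution class, counts mutations annotated on the
#' transcribed vs untranscribed strand (records with unknown strand are
#' excluded, never guessed) and tests the 50:50 null with an exact
#' two-sided binomial test.
#'
#' @param mutations internal mutation data.frame.
#' @param class one of `"C>A"`, `"C>G"`, `"C>T"`, `"T>A"`, `"T>C"`, `"T>G"`.
#' @return list with `n_transcribed`, `n_untranscribed`, `p_value`.
#' @export
strand_bias_test <- function(mutations, class) {
  if (!class %in% .SUB_CLASSES) {
    rk_validation_error("class must be one of: %s", paste(.SUB_CLASSES, collapse = ", "))
  }
  snv <- .is_snv(mutations$ref_allele, mutations$alt_allele) &
    !is.na(mutations$context3)
  mut <- mutations[snv & mutations$tx_strand != "unknown", , drop = FALSE]
  if (!nrow(mut)) rk_validation_error("no strand-annotated SNVs available")
  cls <- channel_class(channel_of(mut$ref_allele, mut$alt_allele, mut$context3))
  mut <- mut[cls == class, , drop = FALSE]
  if (!nrow(mut)) rk_validation_error("no usable records for class %s", class)
  n_t <- sum(mut$tx_strand == "transcribed")
  n_u <- sum(mut$tx_strand == "untranscribed")
  p <- stats::binom.test(n_t, n_t + n_u, p = 0.5,
                         alternative = "two.sided")$p.value
  list(n_transcribed = n_t, n_untranscribed = n_u, p_value = p)
}
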