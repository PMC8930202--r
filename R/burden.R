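# Tumor mutation burden, MSI classification bands, neoantigen filtering and
# percentages, and per-cluster neoantigen fractions.

.NONSYN_CLASSES <- c("missense", "nonsense", "splice", "frameshift", "inframe")

#' Canonical mutation key
#'
#' Identity of a mutation across samples: `chrom:pos:ref>alt` (gene
#' annotation deliberately excluded, so annotation-version drift cannot
#' split identical variants).
#'
#' @param mutations internal mutation data.frame.
#' @return character vector of keys.
#' @export
mutation_key <- function(mutations) {
  if (!nrow(mutations)) return(character(0))  # paste0 would recycle "" rows
  paste0(mutations$chrom, ":", mutations$pos, ":", mutations$ref_allele,
         ">", mutations$alt_allele)
}

#' Tumor mutation burden per megabase
#'
#' Counts somatic missense mutations only and divides by the size of the
#' targeted coding territory (34 Mb by default, the conventional exome
#' capture footprint).
#'
#' @param mutations internal mutation data.frame.
#' @param region_mb coding territory in Mb (default 34).
#' @return data.frame per sample: `n_missense`, `tmb_per_mb`.
#' @export
tmb <- function(mutations, region_mb = 34) {
  if (region_mb <= 0) rk_validation_error("region_mb must be positive")
  samples <- sort(unique(mutations$sample_id))
  n_mis <- vapply(samples, function(s) {
    sum(mutations$sample_id == s & mutations$variant_class == "missense")
  }, numeric(1))
  data.frame(sample_id = samples, n_missense = as.integer(n_mis),
             tmb_per_mb = n_mis / region_mb, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify a microsatellite-instability score
#'
#' Bands: score < 3 -> MSS (stable); 3 to 10 inclusive -> indeterminate;
#' score > 10 -> MSI-high.
#'
#' @param score numeric MSI score(s), nonnegative.
#' @return character vector: `"MSS"`, `"indeterminate"` or `"MSI_high"`.
#' @export
classify_msi <- function(score) {
  if (any(is.na(score)) || any(score < 0)) {
    rk_validation_error("MSI scores must be nonnegative")
  }
  ifelse(score < 3, "MSS", ifelse(score <= 10, "indeterminate", "MSI_high"))
}

#' Filter neoantigen candidates by MHC binding
#'
#' Keeps candidates with predicted mutant K_D at most 500 nM (tunable) that
#' bind more tightly than their wild-type counterpart (strictly lower K_D),
#' and, when expression filtering is enabled, are expressed.  Candidates
#' with missing K_D are rejected with a reason code, never silently dropped.
#'
#' @param candidates neoantigen data.frame (see [read_neoantigens()]).
#' @param kd_threshold_nM K_D cutoff in nM (default 500).
#' @param require_expressed apply the expression flag (default FALSE).
#' @return kept rows, with a `rejected` attribute (data.frame of dropped
#'   rows and a `reason` column).
#' @export
filter_neoantigens <- function(candidates, kd_threshold_nM = 500,
                               require_expressed = FALSE) {
  reason <- rep(NA_character_, nrow(candidates))
  miss <- is.na(candidates$kd_mutant_nM) | is.na(candidates$kd_wildtype_nM)
  reason[miss] <- "missing_kd"
  weak <- !miss & candidates$kd_mutant_nM > kd_threshold_nM
  reason[weak] <- "kd_above_threshold"
  not_tighter <- !miss & !weak &
    candidates$kd_mutant_nM >= candidates$kd_wildtype_nM
  reason[not_tighter] <- "not_tighter_than_wildtype"
  if (require_expressed) {
    unexpr <- is.na(reason) & !(candidates$expressed %in% TRUE)
    reason[unexpr] <- "not_expressed"
  }
  kept <- candidates[is.na(reason), , drop = FALSE]
  rejected <- candidates[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  attr(kept, "rejected") <- rejected
  kept
}

#' Percentage of nonsynonymous mutations that yield a neoantigen
#'
#' 100 x (distinct nonsynonymous mutations with at least one kept candidate)
#' / (nonsynonymous mutations of the sample).  Duplicate candidate rows for
#' the same mutation do not inflate the numerator.  Samples with zero
#' nonsynonymous mutations get NA and a flag.
#'
#' @param mutations internal mutation data.frame.
#' @param kept kept candidates (see [filter_neoantigens()]).
#' @param all_candidates optional full candidate table; when given, a
#'   per-candidate rate (`candidate_pct` = 100 x kept / all candidates of
#'   the sample) is reported alongside the primary per-mutation rate.
#' @return data.frame per sample: `n_nonsynonymous`, `n_neoantigenic`,
#'   `neoantigen_pct`, `flagged` (and `candidate_pct` when requested).
#' @export
neoantigen_percentage <- function(mutations, kept, all_candidates = NULL) {
  samples <- sort(unique(mutations$sample_id))
  rows <- lapply(samples, function(s) {
    mut <- mutations[mutations$sample_id == s, , drop = FALSE]
    nonsyn <- mut[mut$variant_class %in% .NONSYN_CLASSES, , drop = FALSE]
    keys <- unique(mutation_key(nonsyn))
    n_ns <- length(keys)
    kept_keys <- unique(kept$mutation_key[kept$sample_id == s])
    n_neo <- sum(keys %in% kept_keys)
    out <- data.frame(sample_id = s, n_nonsynonymous = n_ns,
                      n_neoantigenic = n_neo,
                      neoantigen_pct = if (n_ns == 0) NA_real_ else 100 * n_neo / n_ns,
                      flagged = n_ns == 0, stringsAsFactors = FALSE)
    if (!is.null(all_candidates)) {
      n_all <- sum(all_candidates$sample_id == s)
      out$candidate_pct <- if (n_all == 0) NA_real_ else
        100 * sum(kept$sample_id == s) / n_all
    }
    out
  })
  do.call(rbind, rows)
}

#' Per-cluster neoantigen fractions
#'
#' For each clonal cluster of each patient: neoantigenic mutations /
#' cluster mutations, ranked by decreasing fraction.  Mutations without a
#' cluster assignment are reported in the `unassigned` attribute.
#'
#' @param mutations internal mutation data.frame with `cluster_id` set.
#' @param kept kept neoantigen candidates.
#' @return data.frame per (patient, cluster): `n_mutations`,
#'   `n_neoantigenic`, `fraction`, `rank` (within patient); empty with a
#'   warning when no cluster assignments exist.
#' @export
cluster_neoantigen_fraction <- function(mutations, kept) {
  assigned <- mutations[!is.na(mutations$cluster_id), , drop = FALSE]
  unassigned <- mutations[is.na(mutations$cluster_id), , drop = FALSE]
  if (!nrow(assigned)) {
    warning("no cluster assignments present", call. = FALSE)
    out <- data.frame(patient_id = character(0), cluster_id = character(0),
                      n_mutations = integer(0), n_neoantigenic = integer(0),
                      fraction = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "unassigned") <- unassigned
    return(out)
  }
  kept_keys <- unique(paste(kept$sample_id, kept$mutation_key))
  is_neo <- paste(assigned$sample_id, mutation_key(assigned)) %in% kept_keys
  grp <- paste(assigned$patient_id, assigned$cluster_id, sep = "\r")
  ug <- unique(grp)
  out <- do.call(rbind, lapply(ug, function(g) {
    sel <- grp == g
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    data.frame(patient_id = parts[1], cluster_id = parts[2],
               n_mutations = sum(sel), n_neoantigenic = sum(is_neo & sel),
               fraction = sum(is_neo & sel) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$patient_id, -out$fraction, out$cluster_id), , drop = FALSE]
  out$rank <- stats::ave(-out$fraction, out$patient_id,
                         FUN = function(x) rank(x, ties.method = "min"))
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  out
}
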