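# Cluster retention on clonal-inference output, and mutation-sharing
# classification across a patient's serial samples.  Clonal clusters are
# consumed (long table: one row per cluster x sample with a cellular
# prevalence in [0,1]); no posterior inference happens here.

#' Read a clonal cluster table
#' @param path TSV with columns `patient_id`, `cluster_id`, `n_variants`,
#'   `sample_id`, `prevalence`, `contains_driver`.
#' @return validated data.frame (long format).
#' @export
read_clusters <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "cluster_id", "n_variants", "sample_id",
                      "prevalence", "contains_driver"), "cluster table")
  out <- data.frame(patient_id = df$patient_id, cluster_id = df$cluster_id,
                    n_variants = .as_int(df$n_variants),
                    sample_id = df$sample_id,
                    prevalence = .as_num(df$prevalence),
                    contains_driver = .as_flag(df$contains_driver),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$prevalence) | out$prevalence < 0 | out$prevalence > 1)
  if (length(bad)) {
    rk_validation_error("cluster table row %d: prevalence outside [0,1]", bad[1])
  }
  if (any(is.na(out$n_variants) | out$n_variants < 1)) {
    rk_validation_error("cluster table: n_variants must be >= 1")
  }
  out
}

#' Write a clonal cluster table
#' @param clusters data.frame as returned by [read_clusters()].
#' @param path output TSV path.
#' @export
write_clusters <- function(clusters, path) .write_tsv(clusters, path)

#' Retain clonal clusters for downstream analysis
#'
#' A cluster is kept iff it contains two or more variants, OR contains a
#' driver-gene variant, OR its cellular prevalence is the per-sample maximum
#' in more than one sample (ties count every tied cluster as top).
#' Idempotent; output is a subset of the input rows.
#'
#' @param clusters long cluster data.frame for one or more patients
#'   (see [read_clusters()]).
#' @return the retained subset, with a `retained` column added per row's
#'   cluster (all TRUE in the subset).
#' @export
retain_clusters <- function(clusters) {
  if (!nrow(clusters)) return(clusters)
  keep_key <- character(0)
  for (pat in unique(clusters$patient_id)) {
    cl <- clusters[clusters$patient_id == pat, , drop = FALSE]
    # per-sample top prevalence, ties inclusive
    top_count <- stats::setNames(numeric(length(unique(cl$cluster_id))),
                                 unique(cl$cluster_id))
    for (s in unique(cl$sample_id)) {
      rows <- cl[cl$sample_id == s, , drop = FALSE]
      mx <- max(rows$prevalence)
      tops <- unique(rows$cluster_id[rows$prevalence == mx])
      top_count[tops] <- top_count[tops] + 1
    }
    for (cid in unique(cl$cluster_id)) {
      rows <- cl[cl$cluster_id == cid, , drop = FALSE]
      keep <- rows$n_variants[1] >= 2L ||
        isTRUE(any(rows$contains_driver)) ||
        top_count[[cid]] > 1
      if (keep) keep_key <- c(keep_key, paste(pat, cid, sep = "\r"))
    }
  }
  out <- clusters[paste(clusters$patient_id, clusters$cluster_id, sep = "\r")
                  %in% keep_key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify mutation sharing across a patient's serial samples
#'
#' Mutation identity is `(chrom, pos, ref, alt)`.  A mutation present in all
#' of the patient's samples is `common`, in more than one but not all is
#' `shared`, in exactly one is `private`.  The classes partition the
#' patient's distinct mutation set.
#'
#' @param mutations internal mutation data.frame for one patient with >= 2
#'   samples.
#' @return list with `classes` (data.frame `mutation_key`, `n_samples`,
#'   `class`) and `private_counts` (data.frame `sample_id`, `n_private`).
#' @export
classify_sharing <- function(mutations) {
  samples <- unique(mutations$sample_id)
  if (length(samples) < 2L) {
    rk_validation_error("patient has < 2 samples; sharing classes undefined (skip this patient)")
  }
  if (length(unique(mutations$patient_id)) != 1L) {
    rk_validation_error("classify_sharing expects mutations of a single patient")
  }
  key <- mutation_key(mutations)
  pres <- unique(data.frame(key = key, sample_id = mutations$sample_id,
                            stringsAsFactors = FALSE))
  counts <- table(pres$key)
  cls <- ifelse(counts == length(samples), "common",
                ifelse(counts > 1, "shared", "private"))
  classes <- data.frame(mutation_key = names(counts),
                        n_samples = as.integer(counts),
                        class = as.character(cls), row.names = NULL,
                        stringsAsFactors = FALSE)
  private_keys <- classes$mutation_key[classes$class == "private"]
  n_priv <- vapply(samples, function(s) {
    sum(unique(pres$key[pres$sample_id == s]) %in% private_keys)
  }, numeric(1))
  list(classes = classes,
       private_counts = data.frame(sample_id = samples,
                                   n_private = as.integer(n_priv),
                                   row.names = NULL, stringsAsFactors = FALSE))
}

#' Cohort-level private-mutation summary
#'
#' Applies [classify_sharing()] to every patient with >= 2 samples and
#' summarises per-sample private counts per group as mean and SD.
#'
#' @param mutations internal mutation data.frame (whole cohort).
#' @param meta sample metadata.
#' @return data.frame per group: `n_samples`, `mean_private`, `sd_private`.
#' @export
sharing_summary <- function(mutations, meta) {
  per_sample <- list()
  for (pat in unique(mutations$patient_id)) {
    mut <- mutations[mutations$patient_id == pat, , drop = FALSE]
    if (length(unique(mut$sample_id)) < 2L) next
    per_sample[[pat]] <- classify_sharing(mut)$private_counts
  }
  if (!length(per_sample)) {
    rk_validation_error("no patient has >= 2 samples")
  }
  pc <- do.call(rbind, per_sample)
  df <- merge(pc, meta, by = "sample_id")
  groups <- unique(df$group)
  data.frame(
    group = groups,
    n_samples = vapply(groups, function(g) sum(df$group == g), numeric(1)),
    mean_private = vapply(groups, function(g) mean(df$n_private[df$group == g]),
                          numeric(1)),
    sd_private = vapply(groups, function(g) sample_sd(df$n_private[df$group == g]),
                        numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
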