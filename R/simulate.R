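# Seeded synthetic-cohort generator.  Produces a paired primary/relapsed
# cohort plus healthy controls with the statistical structure the analyses
# assume: mutation catalogs drawn from group-specific signature mixtures,
# transcriptional strand-bias structure, control-vs-tumor CNV segments,
# group-shifted neoantigen fractions, and group-shifted clonotype frequency
# distributions and CDR3 lengths.  One master seed fans out to fixed
# per-table child seeds (see child_seed()), so identical seeds give
# byte-identical outputs.
#
# Defaults state the cohort the pipeline targets: 24 patients of whom 11
# relapse, 10 healthy CNV controls, ~230 somatic SNVs per exome (6.8/Mb on
# a 34 Mb territory), APOBEC-dominated primaries and a relapse mixture in
# which the APOBEC C>G-type signature carries 72.4% and the aristolochic-
# acid-like signature 16.2% of mutations, T>A strand bias toward the
# untranscribed strand, more and larger copy-number aberrations after
# relapse, halved neoantigen yield in relapses, and a more clonal (steeper
# Zipf) relapse TCR repertoire peaking at CDR3 length 14 aa vs 15 aa.

.GENE_POOL <- c("FDFT1", "KRT4", "TP53", "TTN", "AHNAK2", "ARID1A", "KMT2D",
                "HAUS5", "STOX1", "CDKN1A", "AKAP13", "PIK3CA", "MTOR",
                "CDKN2A", "E2F3", "PPARG", "FGFR3", "GFRA2", "DOK2",
                sprintf("GENE%03d", 1:60))
.DRIVER_GENES <- c("TP53", "PIK3CA", "CDKN1A", "FGFR3", "MTOR", "CDKN2A")
.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build and validate a synthetic cohort configuration
#'
#' All arguments have cohort-scale defaults (see the methods vignette for
#' the rationale behind each number); override any subset.
#'
#' @param n_patients number of patients (default 24).
#' @param relapse_fraction fraction of patients who relapse (default 11/24).
#' @param n_controls healthy CNV control samples (default 10).
#' @param mutations_per_sample list `mean`, `dispersion` of the negative-
#'   binomial SNV count (dispersion = Inf means exactly `mean`).
#' @param group_exposures per-group named signature-mixture weights over the
#'   packaged catalog; each must sum to 1 within 1e-9.
#' @param strand_bias named per-class probability that a mutation lies on
#'   the untranscribed strand (0.5 = no bias).
#' @param unknown_strand_fraction fraction of records with unknown strand.
#' @param share_fraction fraction of a relapsing patient's primary mutations
#'   carried into the relapse sample.
#' @param cnv list: `n_chrom`, `chrom_length`, `bin_size`, `noise_sd`,
#'   per-group `n_aberrant` and `mean_shift`, `aberration_bins` (min/max
#'   aberration span in bins).
#' @param neo list: per-group `p_neoantigen` (probability a nonsynonymous
#'   mutation yields a passing candidate), `kd_meanlog`, `kd_sdlog`
#'   (log-normal mutant K_D, truncated at the 500 nM filter for passing
#'   candidates), `decoy_rate` (failing candidates emitted for realism).
#' @param tcr list: per-group `zipf_exponent` and `length_mode`; `n_clones`,
#'   `n_reads`, `length_sd`, `productive_rate`.
#' @param survival list: per-status monthly exponential `hazard`
#'   (relapse/no_relapse) and `censor_months`.
#' @param catalog signature catalog supplying the mixture components
#'   (default the packaged synthetic catalog).
#' @param seed master seed.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(
    n_patients = 24L,
    relapse_fraction = 11 / 24,
    n_controls = 10L,
    mutations_per_sample = list(mean = 230, dispersion = 2),
    group_exposures = list(
      primary_no_relapse = c("1" = 0.3, "2" = 0.7),
      primary_with_relapse = c("1" = 0.3, "2" = 0.7),
      relapsed = c("1" = 0.114, "13" = 0.724, "22" = 0.162)
    ),
    strand_bias = c("C>A" = 0.5, "C>G" = 0.5, "C>T" = 0.5,
                    "T>A" = 0.7, "T>C" = 0.5, "T>G" = 0.5),
    unknown_strand_fraction = 0.05,
    share_fraction = 0.3,
    cnv = list(n_chrom = 4L, chrom_length = 5e7, bin_size = 1e6,
               noise_sd = 0.1,
               n_aberrant = c(primary_no_relapse = 4, primary_with_relapse = 5,
                              relapsed = 12),
               mean_shift = c(primary_no_relapse = 0.5,
                              primary_with_relapse = 0.5, relapsed = 0.8),
               aberration_bins = c(3L, 10L)),
    neo = list(p_neoantigen = c(primary_no_relapse = 0.30,
                                primary_with_relapse = 0.30, relapsed = 0.15),
               kd_meanlog = log(120), kd_sdlog = 0.9, decoy_rate = 0.15),
    tcr = list(zipf_exponent = c(primary_no_relapse = 1.0,
                                 primary_with_relapse = 1.0, relapsed = 1.3),
               n_clones = 800L, n_reads = 5000L,
               length_mode = c(primary_no_relapse = 15, primary_with_relapse = 15,
                               relapsed = 14),
               length_sd = 1.5, productive_rate = 0.9),
    survival = list(hazard = c(relapse = 0.025, no_relapse = 0.004),
                    censor_months = 60),
    catalog = NULL,
    seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              relapse_fraction = relapse_fraction,
              n_controls = as.integer(n_controls),
              mutations_per_sample = mutations_per_sample,
              group_exposures = group_exposures, strand_bias = strand_bias,
              unknown_strand_fraction = unknown_strand_fraction,
              share_fraction = share_fraction, cnv = cnv, neo = neo,
              tcr = tcr, survival = survival,
              catalog = catalog %||% default_signature_catalog(),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Validate a cohort configuration
#' @param cfg a `cohort_config` list.
#' @return cfg invisibly; errors on invalid settings.
#' @export
validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1L) rk_validation_error("n_patients must be >= 1")
  probs <- c(cfg$relapse_fraction, cfg$unknown_strand_fraction,
             cfg$share_fraction, cfg$strand_bias, cfg$neo$p_neoantigen,
             cfg$neo$decoy_rate, cfg$tcr$productive_rate)
  if (any(probs < 0 | probs > 1)) {
    rk_validation_error("all probabilities must lie in [0, 1]")
  }
  if (cfg$mutations_per_sample$mean <= 0) {
    rk_validation_error("zero mutations requested: mutations_per_sample$mean must be > 0")
  }
  if (cfg$tcr$n_clones < 1L) {
    rk_validation_error("zero clones requested: tcr$n_clones must be >= 1")
  }
  for (g in names(cfg$group_exposures)) {
    w <- cfg$group_exposures[[g]]
    if (abs(sum(w) - 1) > 1e-9) {
      rk_validation_error("group_exposures[%s] must sum to 1 within 1e-9", g)
    }
    if (!all(names(w) %in% cfg$catalog$names)) {
      rk_validation_error("group_exposures[%s] names a signature missing from the catalog", g)
    }
  }
  invisible(cfg)
}

.mixture_probs <- function(weights, catalog) {
  p <- colSums(weights * catalog$probs[names(weights), , drop = FALSE])
  p / sum(p)
}

#' Simulate a samples x 96 spectrum from a signature mixture
#'
#' Multinomial draw of mutation channels per sample from the mixture
#' `sum_g w_g * signature_g`.
#'
#' @param n_samples number of samples (rows).
#' @param n_mutations SNVs per sample.
#' @param exposures named mixture weights over catalog signatures (sum 1).
#' @param catalog a `signature_catalog`.
#' @param seed integer seed.
#' @return integer matrix n_samples x 96.
#' @export
simulate_spectrum <- function(n_samples, n_mutations, exposures, catalog,
                              seed = 1L) {
  if (n_mutations < 1L) rk_validation_error("zero mutations requested")
  if (abs(sum(exposures) - 1) > 1e-9) rk_validation_error("exposures must sum to 1")
  p <- .mixture_probs(exposures, catalog)
  set.seed(as.integer(seed))
  counts <- t(stats::rmultinom(n_samples, n_mutations, p))
  dimnames(counts) <- list(sprintf("SIM%02d", seq_len(n_samples)), .CHANNELS)
  counts
}

# one sample's mutation rows (SNVs realised from the channel mixture)
.sim_mutation_rows <- function(n, sample_id, patient_id, timepoint, weights,
                               cfg) {
  p <- .mixture_probs(weights, cfg$catalog)
  idx <- sample.int(96, n, replace = TRUE, prob = p)
  parts <- channel_parts(idx)
  # half the records presented in purine (reverse-complement) orientation
  flip <- stats::runif(n) < 0.5
  ref <- parts$ref; alt <- parts$alt; ctx <- parts$context3
  ref[flip] <- .comp(ref[flip]); alt[flip] <- .comp(alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  cls_probs <- c(missense = 0.55, silent = 0.25, nonsense = 0.10, splice = 0.10)
  vclass <- sample(names(cls_probs), n, replace = TRUE, prob = cls_probs)
  bias <- cfg$strand_bias[parts$class]
  strand <- ifelse(stats::runif(n) < bias, "untranscribed", "transcribed")
  strand[stats::runif(n) < cfg$unknown_strand_fraction] <- "unknown"
  data.frame(
    sample_id = sample_id, patient_id = patient_id,
    timepoint_label = timepoint,
    chrom = paste0("chr", sample.int(cfg$cnv$n_chrom, n, replace = TRUE)),
    pos = sample.int(cfg$cnv$chrom_length, n, replace = TRUE),
    ref_allele = ref, alt_allele = alt, variant_class = vclass,
    gene = sample(.GENE_POOL, n, replace = TRUE), context3 = ctx,
    tx_strand = strand, cluster_id = NA_character_, is_neoantigenic = NA,
    stringsAsFactors = FALSE
  )
}

.draw_count <- function(mean, dispersion) {
  if (is.infinite(dispersion)) return(as.integer(round(mean)))
  max(1L, stats::rnbinom(1, mu = mean, size = dispersion))
}

# per-bin segment rows for one sample: baseline noise + optional aberrations
.sim_segment_rows <- function(sample_id, cfg, n_aberr = 0, mean_shift = 0) {
  n_bins <- as.integer(cfg$cnv$chrom_length %/% cfg$cnv$bin_size)
  rows <- list()
  shifts <- vector("list", cfg$cnv$n_chrom)
  for (ch in seq_len(cfg$cnv$n_chrom)) shifts[[ch]] <- numeric(n_bins)
  if (n_aberr > 0) {
    for (a in seq_len(n_aberr)) {
      ch <- sample.int(cfg$cnv$n_chrom, 1)
      span <- sample(cfg$cnv$aberration_bins[1]:cfg$cnv$aberration_bins[2], 1)
      start_bin <- sample.int(max(1L, n_bins - span + 1L), 1)
      mag <- abs(stats::rnorm(1, mean_shift, 0.1)) * sample(c(-1, 1), 1)
      shifts[[ch]][start_bin:(start_bin + span - 1L)] <-
        shifts[[ch]][start_bin:(start_bin + span - 1L)] + mag
    }
  }
  for (ch in seq_len(cfg$cnv$n_chrom)) {
    noise <- if (cfg$cnv$noise_sd > 0) stats::rnorm(n_bins, 0, cfg$cnv$noise_sd) else numeric(n_bins)
    rows[[ch]] <- data.frame(
      sample_id = sample_id, chrom = paste0("chr", ch),
      start = as.integer((seq_len(n_bins) - 1) * cfg$cnv$bin_size + 1),
      end = as.integer(seq_len(n_bins) * cfg$cnv$bin_size),
      log2_value = noise + shifts[[ch]], zscore = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$length_bp <- out$end - out$start + 1L
  out
}

#' Simulate aberration-free control copy-number samples
#'
#' @param config a `cohort_config`.
#' @return segment data.frame for `n_controls` control samples, drawn from
#'   the diploid baseline (Gaussian noise only).
#' @export
simulate_controls <- function(config) {
  validate_cohort_config(config)
  if (config$n_controls < 2L) {
    rk_validation_error("n_controls must be >= 2 (control SD undefined)")
  }
  set.seed(child_seed(config$seed, 4L))
  do.call(rbind, lapply(seq_len(config$n_controls), function(i) {
    .sim_segment_rows(sprintf("CTRL%02d", i), config)
  }))
}

.random_cdr3 <- function(n, mode, sd) {
  len <- pmin(24L, pmax(8L, as.integer(round(stats::rnorm(n, mode, sd)))))
  inner <- vapply(len - 2L, function(k) {
    paste(sample(.AA_ALPHABET, k, replace = TRUE), collapse = "")
  }, character(1))
  paste0("C", inner, "F")
}

.sim_clonotype_rows <- function(sample_id, group, cfg) {
  tc <- cfg$tcr
  s <- tc$zipf_exponent[[group]]
  freq <- (seq_len(tc$n_clones))^(-s)
  freq <- freq / sum(freq)
  counts <- as.integer(stats::rmultinom(1, tc$n_reads, freq))
  keep <- counts > 0
  n <- sum(keep)
  cdr3 <- .random_cdr3(n, tc$length_mode[[group]], tc$length_sd)
  while (anyDuplicated(cdr3)) {
    dup <- duplicated(cdr3)
    cdr3[dup] <- .random_cdr3(sum(dup), tc$length_mode[[group]], tc$length_sd)
  }
  productive <- stats::runif(n) < tc$productive_rate
  in_frame <- productive | stats::runif(n) < 0.5
  nt_len <- ifelse(in_frame, 3L * nchar(cdr3), 3L * nchar(cdr3) + 1L)
  cdr3_nt <- vapply(nt_len, function(k) {
    paste(sample(.BASES, k, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(sample_id = sample_id, cdr3_aa = cdr3, cdr3_nt = cdr3_nt,
             v_gene = sprintf("TRBV%d", sample.int(30, n, replace = TRUE)),
             j_gene = sprintf("TRBJ%d", sample.int(14, n, replace = TRUE)),
             read_count = counts[keep], productive = productive,
             in_frame = in_frame, stringsAsFactors = FALSE)
}

.sim_neo_rows <- function(mut, group, cfg) {
  ns <- mut[mut$variant_class %in% .NONSYN_CLASSES, , drop = FALSE]
  if (!nrow(ns)) return(NULL)
  p_pass <- cfg$neo$p_neoantigen[[group]]
  pass <- stats::runif(nrow(ns)) < p_pass
  decoy <- !pass & stats::runif(nrow(ns)) < cfg$neo$decoy_rate
  sel <- pass | decoy
  if (!any(sel)) return(list(rows = NULL, passing_keys = character(0)))
  ns <- ns[sel, , drop = FALSE]
  pass <- pass[sel]
  n <- nrow(ns)
  # passing: mutant K_D log-normal truncated at the 500 nM cutoff, wild type looser
  u <- stats::runif(n)
  kd_cap <- stats::plnorm(500, cfg$neo$kd_meanlog, cfg$neo$kd_sdlog)
  kd_mut <- stats::qlnorm(u * kd_cap, cfg$neo$kd_meanlog, cfg$neo$kd_sdlog)
  kd_wt <- kd_mut * exp(stats::runif(n, 0.2, 2.5))
  # decoys violate exactly one rule
  if (any(!pass)) {
    flip <- stats::runif(sum(!pass)) < 0.5
    kd_mut[!pass][flip] <- 500 * exp(stats::runif(sum(flip), 0.1, 2))
    kd_wt[!pass][!flip] <- kd_mut[!pass][!flip] * exp(stats::runif(sum(!flip), -2, -0.1))
  }
  pep_len <- sample(9:11, n, replace = TRUE)
  rows <- data.frame(
    sample_id = ns$sample_id, mutation_key = mutation_key(ns),
    peptide = vapply(pep_len, function(k) {
      paste(sample(.AA_ALPHABET, k, replace = TRUE), collapse = "")
    }, character(1)),
    hla_allele = sample(c("HLA-A*02:01", "HLA-A*11:01", "HLA-B*07:02",
                          "HLA-B*40:01"), n, replace = TRUE),
    kd_mutant_nM = kd_mut, kd_wildtype_nM = kd_wt,
    expressed = stats::runif(n) < 0.8, stringsAsFactors = FALSE
  )
  list(rows = rows, passing_keys = unique(rows$mutation_key[pass]))
}

#' Simulate a full paired cohort
#'
#' @param config a `cohort_config` (see [cohort_config()]).
#' @return list of tables: `meta`, `mutations`, `segments` (tumors),
#'   `control_segments`, `neoantigens`, `clonotypes`, `clusters`,
#'   `survival`, plus the resolved `config`.  Identical seeds give
#'   identical bundles.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config

  # --- sample sheet -------------------------------------------------------
  set.seed(child_seed(cfg$seed, 1L))
  n_rel <- round(cfg$n_patients * cfg$relapse_fraction)
  relapsers <- sort(sample.int(cfg$n_patients, n_rel))
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  meta <- do.call(rbind, lapply(seq_len(cfg$n_patients), function(i) {
    g0 <- if (i %in% relapsers) "primary_with_relapse" else "primary_no_relapse"
    rows <- data.frame(sample_id = paste0(patients[i], "_s0"),
                       patient_id = patients[i], group = g0,
                       timepoint_order = 0L, stringsAsFactors = FALSE)
    if (i %in% relapsers) {
      rows <- rbind(rows, data.frame(sample_id = paste0(patients[i], "_s1"),
                                     patient_id = patients[i],
                                     group = "relapsed", timepoint_order = 1L,
                                     stringsAsFactors = FALSE))
    }
    rows
  }))
  ctrl_meta <- data.frame(sample_id = sprintf("CTRL%02d", seq_len(cfg$n_controls)),
                          patient_id = sprintf("CTRL%02d", seq_len(cfg$n_controls)),
                          group = "control", timepoint_order = 0L,
                          stringsAsFactors = FALSE)
  meta <- rbind(meta, ctrl_meta)

  # --- mutations (with shared trunk for relapsing patients) ---------------
  set.seed(child_seed(cfg$seed, 2L))
  mut_list <- list()
  for (i in seq_len(cfg$n_patients)) {
    pat <- patients[i]
    g0 <- if (i %in% relapsers) "primary_with_relapse" else "primary_no_relapse"
    n0 <- .draw_count(cfg$mutations_per_sample$mean,
                      cfg$mutations_per_sample$dispersion)
    m0 <- .sim_mutation_rows(n0, paste0(pat, "_s0"), pat, "s0",
                             cfg$group_exposures[[g0]], cfg)
    if (i %in% relapsers) {
      n_shared <- stats::rbinom(1, n0, cfg$share_fraction)
      shared_idx <- if (n_shared > 0) sample.int(n0, n_shared) else integer(0)
      m0$cluster_id <- "C2"
      m0$cluster_id[shared_idx] <- "C1"
      n1 <- .draw_count(cfg$mutations_per_sample$mean,
                        cfg$mutations_per_sample$dispersion)
      n1_new <- max(1L, n1 - n_shared)
      m1_new <- .sim_mutation_rows(n1_new, paste0(pat, "_s1"), pat, "s1",
                                   cfg$group_exposures[["relapsed"]], cfg)
      m1_new$cluster_id <- "C3"
      m1_shared <- m0[shared_idx, , drop = FALSE]
      if (nrow(m1_shared)) {
        m1_shared$sample_id <- paste0(pat, "_s1")
        m1_shared$timepoint_label <- "s1"
      }
      mut_list[[pat]] <- rbind(m0, m1_shared, m1_new)
    } else {
      m0$cluster_id <- sample(c("C1", "C2"), n0, replace = TRUE,
                              prob = c(0.6, 0.4))
      mut_list[[pat]] <- m0
    }
  }
  mutations <- do.call(rbind, mut_list)
  rownames(mutations) <- NULL

  # --- clonal cluster table ----------------------------------------------
  set.seed(child_seed(cfg$seed, 8L))
  cl_list <- list()
  for (pat in patients) {
    mut <- mutations[mutations$patient_id == pat, , drop = FALSE]
    samples <- unique(mut$sample_id)
    for (cid in sort(unique(mut$cluster_id))) {
      sel <- mut$cluster_id == cid
      nv <- length(unique(mutation_key(mut[sel, , drop = FALSE])))
      drv <- any(mut$gene[sel] %in% .DRIVER_GENES)
      for (s in samples) {
        in_sample <- any(sel & mut$sample_id == s)
        base <- switch(cid, C1 = 0.85, C2 = 0.55, C3 = 0.55, 0.4)
        prev <- if (in_sample) {
          min(1, max(0, stats::rnorm(1, base, 0.05)))
        } else {
          min(1, abs(stats::rnorm(1, 0.02, 0.02)))
        }
        cl_list[[length(cl_list) + 1L]] <- data.frame(
          patient_id = pat, cluster_id = cid, n_variants = nv,
          sample_id = s, prevalence = prev, contains_driver = drv,
          stringsAsFactors = FALSE)
      }
    }
  }
  clusters <- do.call(rbind, cl_list)

  # --- copy number --------------------------------------------------------
  set.seed(child_seed(cfg$seed, 3L))
  tumor_meta <- meta[meta$group != "control", , drop = FALSE]
  segments <- do.call(rbind, lapply(seq_len(nrow(tumor_meta)), function(r) {
    g <- tumor_meta$group[r]
    .sim_segment_rows(tumor_meta$sample_id[r], cfg,
                      n_aberr = cfg$cnv$n_aberrant[[g]],
                      mean_shift = cfg$cnv$mean_shift[[g]])
  }))
  control_segments <- simulate_controls(cfg)

  # --- neoantigens --------------------------------------------------------
  set.seed(child_seed(cfg$seed, 5L))
  neo_list <- list()
  for (r in seq_len(nrow(tumor_meta))) {
    s <- tumor_meta$sample_id[r]
    res <- .sim_neo_rows(mutations[mutations$sample_id == s, , drop = FALSE],
                         tumor_meta$group[r], cfg)
    if (is.null(res) || is.null(res$rows)) next
    neo_list[[s]] <- res$rows
    hit <- mutations$sample_id == s &
      mutation_key(mutations) %in% res$passing_keys
    mutations$is_neoantigenic[mutations$sample_id == s] <- FALSE
    mutations$is_neoantigenic[hit] <- TRUE
  }
  neoantigens <- if (length(neo_list)) do.call(rbind, neo_list) else
    data.frame(sample_id = character(0), mutation_key = character(0),
               peptide = character(0), hla_allele = character(0),
               kd_mutant_nM = numeric(0), kd_wildtype_nM = numeric(0),
               expressed = logical(0), stringsAsFactors = FALSE)
  rownames(neoantigens) <- NULL

  # --- TCR repertoires ----------------------------------------------------
  set.seed(child_seed(cfg$seed, 6L))
  clonotypes <- do.call(rbind, lapply(seq_len(nrow(tumor_meta)), function(r) {
    .sim_clonotype_rows(tumor_meta$sample_id[r], tumor_meta$group[r], cfg)
  }))

  # --- survival -----------------------------------------------------------
  set.seed(child_seed(cfg$seed, 7L))
  haz <- ifelse(seq_len(cfg$n_patients) %in% relapsers,
                cfg$survival$hazard[["relapse"]],
                cfg$survival$hazard[["no_relapse"]])
  t_raw <- stats::rexp(cfg$n_patients, rate = haz)
  survival <- data.frame(
    patient_id = patients,
    time_months = pmin(t_raw, cfg$survival$censor_months),
    event = as.integer(t_raw <= cfg$survival$censor_months),
    relapser = seq_len(cfg$n_patients) %in% relapsers,
    stringsAsFactors = FALSE
  )

  list(meta = meta, mutations = mutations, segments = segments,
       control_segments = control_segments, neoantigens = neoantigens,
       clonotypes = clonotypes, clusters = clusters, survival = survival,
       config = cfg)
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits every table in its interchange format (MAF-like TSV, SEG, AIRR
#' TSV, neoantigen TSV, cluster TSV, metadata TSV) plus a JSON echo of the
#' resolved configuration (seed included).
#'
#' @param bundle output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sample_meta(bundle$meta, file.path(dir, "samples.tsv"))
  write_mutations(bundle$mutations, file.path(dir, "mutations.maf.tsv"))
  write_segments(bundle$segments, file.path(dir, "tumor_segments.seg"))
  write_segments(bundle$control_segments, file.path(dir, "control_segments.seg"))
  write_neoantigens(bundle$neoantigens, file.path(dir, "neoantigens.tsv"))
  write_clonotypes(bundle$clonotypes, file.path(dir, "clonotypes.airr.tsv"))
  write_clusters(bundle$clusters, file.path(dir, "clusters.tsv"))
  .write_tsv(bundle$survival, file.path(dir, "survival.tsv"))
  cfg <- unclass(bundle$config)
  cfg$catalog <- NULL  # the catalog ships with the package, not the run
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
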