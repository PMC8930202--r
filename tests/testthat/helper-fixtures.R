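# Fixture builders used across the suite.  Everything is generated in code;
# no binary or large data ships with the tests.

# a minimal valid mutation row; override any field
mut_row <- function(sample_id = "P01_s0", patient_id = "P01",
                    timepoint_label = "s0", chrom = "chr1", pos = 100L,
                    ref_allele = "C", alt_allele = "T",
                    variant_class = "missense", gene = "TP53",
                    context3 = "ACG", tx_strand = "untranscribed",
                    cluster_id = NA_character_, is_neoantigenic = NA) {
  data.frame(sample_id = sample_id, patient_id = patient_id,
             timepoint_label = timepoint_label, chrom = chrom, pos = pos,
             ref_allele = ref_allele, alt_allele = alt_allele,
             variant_class = variant_class, gene = gene, context3 = context3,
             tx_strand = tx_strand, cluster_id = cluster_id,
             is_neoantigenic = is_neoantigenic, stringsAsFactors = FALSE)
}

mut_table <- function(...) do.call(rbind, list(...))

# n mutation rows spread over channels, all SNVs, one sample
random_mut_table <- function(n, sample_id = "P01_s0", seed = 1) {
  set.seed(seed)
  idx <- sample.int(96, n, replace = TRUE)
  parts <- channel_parts(idx)
  do.call(rbind, lapply(seq_len(n), function(i) {
    mut_row(sample_id = sample_id, pos = i,
            ref_allele = parts$ref[i], alt_allele = parts$alt[i],
            context3 = parts$context3[i])
  }))
}

neo_row <- function(sample_id = "P01_s0", mutation_key = "chr1:100:C>T",
                    peptide = "ACDEFGHIK", hla_allele = "HLA-A*02:01",
                    kd_mutant_nM = 100, kd_wildtype_nM = 1000,
                    expressed = TRUE) {
  data.frame(sample_id = sample_id, mutation_key = mutation_key,
             peptide = peptide, hla_allele = hla_allele,
             kd_mutant_nM = kd_mutant_nM, kd_wildtype_nM = kd_wildtype_nM,
             expressed = expressed, stringsAsFactors = FALSE)
}

clono_row <- function(sample_id = "S1", cdr3_aa = "CASSLGETQYF",
                      read_count = 10L, productive = TRUE, in_frame = TRUE,
                      cdr3_nt = NA_character_) {
  data.frame(sample_id = sample_id, cdr3_aa = cdr3_aa, cdr3_nt = cdr3_nt,
             v_gene = NA_character_, j_gene = NA_character_,
             read_count = read_count, productive = productive,
             in_frame = in_frame, stringsAsFactors = FALSE)
}

seg_row <- function(sample_id = "T1", chrom = "chr1", start = 1L,
                    end = 1000000L, log2_value = 0, zscore = NA_real_) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             log2_value = log2_value, zscore = zscore,
             length_bp = end - start + 1L, stringsAsFactors = FALSE)
}

cluster_row <- function(patient_id = "P01", cluster_id = "C1",
                        n_variants = 2L, sample_id = "P01_s0",
                        prevalence = 0.5, contains_driver = FALSE) {
  data.frame(patient_id = patient_id, cluster_id = cluster_id,
             n_variants = n_variants, sample_id = sample_id,
             prevalence = prevalence, contains_driver = contains_driver,
             stringsAsFactors = FALSE)
}

# a deliberately tiny cohort configuration for pipeline-level tests
tiny_cohort_config <- function(seed = 1, ...) {
  cohort_config(
    n_patients = 6L, relapse_fraction = 0.5, n_controls = 4L,
    mutations_per_sample = list(mean = 80, dispersion = 5),
    cnv = list(n_chrom = 2L, chrom_length = 2e7, bin_size = 1e6,
               noise_sd = 0.1,
               n_aberrant = c(primary_no_relapse = 2, primary_with_relapse = 2,
                              relapsed = 6),
               mean_shift = c(primary_no_relapse = 0.5,
                              primary_with_relapse = 0.5, relapsed = 0.8),
               aberration_bins = c(2L, 5L)),
    tcr = list(zipf_exponent = c(primary_no_relapse = 1.0,
                                 primary_with_relapse = 1.0, relapsed = 1.3),
               n_clones = 200L, n_reads = 2000L,
               length_mode = c(primary_no_relapse = 15,
                               primary_with_relapse = 15, relapsed = 14),
               length_sd = 1.5, productive_rate = 0.9),
    seed = seed, ...
  )
}

expect_validation_error <- function(expr) {
  expect_error(expr, class = "relapsekit_validation_error")
}
expect_format_error <- function(expr) {
  expect_error(expr, class = "relapsekit_format_error")
}
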