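# Readers/writers for every table the pipeline touches.  All on-disk formats
# are plain TSV/CSV; coordinates in MAF-like and SEG tables are 1-based
# inclusive.  Readers are strict: a missing required column is a format
# error naming the column, an inconsistent row is a validation error naming
# the row.  Readers never silently drop rows.

.VARIANT_CLASSES <- c("missense", "nonsense", "splice", "silent",
                      "frameshift", "inframe", "other")
.TX_STRANDS <- c("transcribed", "untranscribed", "unknown")
.GROUPS <- c("primary_no_relapse", "primary_with_relapse", "relapsed", "control")

# MAF Variant_Classification -> internal enum
.MAF_CLASS_MAP <- c(
  Missense_Mutation = "missense", Nonsense_Mutation = "nonsense",
  Nonstop_Mutation = "nonsense", Splice_Site = "splice", Silent = "silent",
  Frame_Shift_Del = "frameshift", Frame_Shift_Ins = "frameshift",
  In_Frame_Del = "inframe", In_Frame_Ins = "inframe"
)
.MAF_CLASS_OUT <- c(
  missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
  splice = "Splice_Site", silent = "Silent", frameshift = "Frame_Shift_Ins",
  inframe = "In_Frame_Ins", other = "Other"
)

.read_tsv <- function(path, sep = "\t") {
  if (!file.exists(path)) rk_format_error("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = NULL)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    rk_format_error("%s: missing required column(s): %s", what,
                    paste(miss, collapse = ", "))
  }
}

.as_num <- function(x) suppressWarnings(as.numeric(x))
.as_int <- function(x) suppressWarnings(as.integer(x))
.as_flag <- function(x) {
  out <- rep(NA, length(x))
  out[toupper(x) %in% c("TRUE", "T", "YES", "1")] <- TRUE
  out[toupper(x) %in% c("FALSE", "F", "NO", "0")] <- FALSE
  out
}
.blank_to_na <- function(x) { x[!nzchar(x)] <- NA_character_; x }

.is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .BASES & alt %in% .BASES & ref != alt
}

#' Validate a mutation table
#'
#' Checks the invariants of the internal mutation representation: positive
#' positions, context 3-mers whose middle base equals the reference base for
#' SNVs, strand and class enums, and class/allele-length consistency.
#'
#' @param mut data.frame of mutations (internal column names).
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_mutations <- function(mut) {
  .require_cols(mut, c("sample_id", "patient_id", "timepoint_label", "chrom",
                       "pos", "ref_allele", "alt_allele", "variant_class",
                       "gene", "context3", "tx_strand"), "mutation table")
  if (nrow(mut) == 0) return(invisible(mut))
  if (any(is.na(mut$pos)) || any(mut$pos < 1)) {
    rk_validation_error("mutation table: pos must be an integer >= 1 (row %d)",
                        which(is.na(mut$pos) | mut$pos < 1)[1])
  }
  if (!all(mut$variant_class %in% .VARIANT_CLASSES)) {
    rk_validation_error("mutation table: unknown variant_class '%s'",
                        setdiff(mut$variant_class, .VARIANT_CLASSES)[1])
  }
  if (!all(mut$tx_strand %in% .TX_STRANDS)) {
    rk_validation_error("mutation table: unknown tx_strand '%s'",
                        setdiff(mut$tx_strand, .TX_STRANDS)[1])
  }
  snv <- .is_snv(mut$ref_allele, mut$alt_allele)
  has_ctx <- !is.na(mut$context3)
  bad_ctx <- snv & has_ctx &
    (nchar(mut$context3) != 3L | substr(mut$context3, 2, 2) != mut$ref_allele)
  if (any(bad_ctx)) {
    rk_validation_error("mutation table row %d: context3 '%s' inconsistent with ref '%s'",
                        which(bad_ctx)[1], mut$context3[which(bad_ctx)[1]],
                        mut$ref_allele[which(bad_ctx)[1]])
  }
  indel_class <- mut$variant_class %in% c("frameshift", "inframe")
  if (any(snv & indel_class)) {
    rk_validation_error("mutation table row %d: single-base alleles with indel variant_class",
                        which(snv & indel_class)[1])
  }
  point_class <- mut$variant_class %in% c("missense", "nonsense", "silent")
  if (any(!snv & point_class)) {
    rk_validation_error("mutation table row %d: indel alleles with point variant_class",
                        which(!snv & point_class)[1])
  }
  invisible(mut)
}

#' Read a MAF-like somatic mutation table
#'
#' @param path TSV file path.
#' @param dialect `"maf"` (default; MAF-style headers such as
#'   `Hugo_Symbol`, `Tumor_Sample_Barcode`) or `"internal"` (the package's
#'   own column names, as written by [write_mutations()] with
#'   `dialect = "internal"`).
#' @return data.frame with columns `sample_id`, `patient_id`,
#'   `timepoint_label`, `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `variant_class`, `gene`, `context3`, `tx_strand`, `cluster_id`,
#'   `is_neoantigenic`.  Row order is preserved.
#' @export
read_mutations <- function(path, dialect = c("maf", "internal")) {
  dialect <- match.arg(dialect)
  df <- .read_tsv(path)
  if (dialect == "maf") {
    req <- c("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
             "Tumor_Seq_Allele2", "Variant_Classification",
             "Tumor_Sample_Barcode", "context3", "tx_strand")
    .require_cols(df, req, "mutation table")
    cls <- df$Variant_Classification
    mapped <- unname(.MAF_CLASS_MAP[cls])
    mapped[is.na(mapped) & cls %in% .VARIANT_CLASSES] <-
      cls[is.na(mapped) & cls %in% .VARIANT_CLASSES]
    mapped[is.na(mapped)] <- "other"
    sid <- df$Tumor_Sample_Barcode
    out <- data.frame(
      sample_id = sid,
      patient_id = if ("Patient_ID" %in% names(df)) df$Patient_ID else sub("_[^_]*$", "", sid),
      timepoint_label = if ("Timepoint" %in% names(df)) df$Timepoint else sub("^.*_", "", sid),
      chrom = df$Chromosome,
      pos = .as_int(df$Start_Position),
      ref_allele = toupper(df$Reference_Allele),
      alt_allele = toupper(df$Tumor_Seq_Allele2),
      variant_class = mapped,
      gene = df$Hugo_Symbol,
      context3 = .blank_to_na(toupper(df$context3)),
      tx_strand = df$tx_strand,
      cluster_id = if ("Cluster_ID" %in% names(df)) .blank_to_na(df$Cluster_ID) else NA_character_,
      is_neoantigenic = if ("Is_Neoantigenic" %in% names(df)) .as_flag(df$Is_Neoantigenic) else NA,
      stringsAsFactors = FALSE
    )
  } else {
    req <- c("sample_id", "patient_id", "timepoint_label", "chrom", "pos",
             "ref_allele", "alt_allele", "variant_class", "gene", "context3",
             "tx_strand")
    .require_cols(df, req, "mutation table")
    out <- data.frame(
      sample_id = df$sample_id, patient_id = df$patient_id,
      timepoint_label = df$timepoint_label, chrom = df$chrom,
      pos = .as_int(df$pos), ref_allele = toupper(df$ref_allele),
      alt_allele = toupper(df$alt_allele), variant_class = df$variant_class,
      gene = df$gene, context3 = .blank_to_na(toupper(df$context3)),
      tx_strand = df$tx_strand,
      cluster_id = if ("cluster_id" %in% names(df)) .blank_to_na(df$cluster_id) else NA_character_,
      is_neoantigenic = if ("is_neoantigenic" %in% names(df)) .as_flag(df$is_neoantigenic) else NA,
      stringsAsFactors = FALSE
    )
  }
  # unparseable optional strand becomes unknown rather than an error
  out$tx_strand[!(out$tx_strand %in% .TX_STRANDS)] <- "unknown"
  validate_mutations(out)
  out
}

#' Write a mutation table
#' @param mut internal mutation data.frame.
#' @param path output TSV path.
#' @param dialect `"maf"` or `"internal"` (see [read_mutations()]).
#' @export
write_mutations <- function(mut, path, dialect = c("maf", "internal")) {
  dialect <- match.arg(dialect)
  validate_mutations(mut)
  if (dialect == "maf") {
    df <- data.frame(
      Hugo_Symbol = mut$gene, Chromosome = mut$chrom,
      Start_Position = mut$pos, Reference_Allele = mut$ref_allele,
      Tumor_Seq_Allele2 = mut$alt_allele,
      Variant_Classification = unname(.MAF_CLASS_OUT[mut$variant_class]),
      Tumor_Sample_Barcode = mut$sample_id, Patient_ID = mut$patient_id,
      Timepoint = mut$timepoint_label, context3 = mut$context3,
      tx_strand = mut$tx_strand, Cluster_ID = mut$cluster_id,
      Is_Neoantigenic = mut$is_neoantigenic, stringsAsFactors = FALSE
    )
  } else {
    df <- mut
  }
  .write_tsv(df, path)
}

.write_tsv <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Read a SEG-style copy-number segment table
#'
#' Expects the conventional SEG header (`ID`, `chrom`, `loc.start`,
#' `loc.end`, `seg.mean`), 1-based inclusive coordinates; an optional
#' `zscore` column carries a control-referenced Z-score.  `length_bp`
#' is derived as `end - start + 1`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `log2_value`, `zscore`, `length_bp`.
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("ID", "chrom", "loc.start", "loc.end", "seg.mean"),
                "segment table")
  out <- data.frame(
    sample_id = df$ID, chrom = df$chrom,
    start = .as_int(df$`loc.start`), end = .as_int(df$`loc.end`),
    log2_value = .as_num(df$`seg.mean`),
    zscore = if ("zscore" %in% names(df)) .as_num(df$zscore) else
      rep(NA_real_, nrow(df)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  if (length(bad)) {
    rk_validation_error("segment table row %d: start > end or non-integer bounds", bad[1])
  }
  out$length_bp <- out$end - out$start + 1L
  out
}

#' Write a SEG-style segment table
#' @param seg data.frame as returned by [read_segments()].
#' @param path output TSV path.
#' @export
write_segments <- function(seg, path) {
  df <- data.frame(ID = seg$sample_id, chrom = seg$chrom,
                   loc.start = seg$start, loc.end = seg$end,
                   seg.mean = seg$log2_value,
                   zscore = seg$zscore %||% NA_real_,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read an AIRR-style clonotype table
#'
#' Required columns: `repertoire_id` (sample), `junction_aa`,
#' `duplicate_count`, `productive`, `vj_in_frame`; optional `junction`
#' (nucleotide), `v_call`, `j_call`.
#'
#' @param path TSV path.
#' @return data.frame with columns `sample_id`, `cdr3_aa`, `cdr3_nt`,
#'   `v_gene`, `j_gene`, `read_count`, `productive`, `in_frame`.
#' @export
read_clonotypes <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("repertoire_id", "junction_aa", "duplicate_count",
                      "productive", "vj_in_frame"), "clonotype table")
  out <- data.frame(
    sample_id = df$repertoire_id, cdr3_aa = df$junction_aa,
    cdr3_nt = if ("junction" %in% names(df)) .blank_to_na(df$junction) else NA_character_,
    v_gene = if ("v_call" %in% names(df)) .blank_to_na(df$v_call) else NA_character_,
    j_gene = if ("j_call" %in% names(df)) .blank_to_na(df$j_call) else NA_character_,
    read_count = .as_int(df$duplicate_count),
    productive = .as_flag(df$productive),
    in_frame = .as_flag(df$vj_in_frame),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$read_count) | out$read_count < 1L)
  if (length(bad)) {
    rk_validation_error("clonotype table row %d: read_count must be >= 1", bad[1])
  }
  frame_bad <- which(!is.na(out$cdr3_nt) & out$in_frame %in% TRUE &
                       nchar(out$cdr3_nt) %% 3L != 0L)
  if (length(frame_bad)) {
    rk_validation_error("clonotype table row %d: in-frame junction length not divisible by 3",
                        frame_bad[1])
  }
  out
}

#' Write an AIRR-style clonotype table
#' @param clono data.frame as returned by [read_clonotypes()].
#' @param path output TSV path.
#' @export
write_clonotypes <- function(clono, path) {
  df <- data.frame(repertoire_id = clono$sample_id,
                   junction_aa = clono$cdr3_aa, junction = clono$cdr3_nt,
                   v_call = clono$v_gene, j_call = clono$j_gene,
                   duplicate_count = clono$read_count,
                   productive = clono$productive,
                   vj_in_frame = clono$in_frame, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a neoantigen candidate table
#'
#' @param path TSV with columns `sample_id`, `mutation_key`, `peptide`,
#'   `hla_allele`, `kd_mutant_nM`, `kd_wildtype_nM`, `expressed`.
#' @return validated data.frame (peptides 9-11 aa, K_D values positive).
#' @export
read_neoantigens <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "mutation_key", "peptide", "hla_allele",
                      "kd_mutant_nM", "kd_wildtype_nM", "expressed"),
                "neoantigen table")
  out <- data.frame(
    sample_id = df$sample_id, mutation_key = df$mutation_key,
    peptide = df$peptide, hla_allele = df$hla_allele,
    kd_mutant_nM = .as_num(df$kd_mutant_nM),
    kd_wildtype_nM = .as_num(df$kd_wildtype_nM),
    expressed = .as_flag(df$expressed), stringsAsFactors = FALSE
  )
  bad_len <- which(nchar(out$peptide) < 9L | nchar(out$peptide) > 11L)
  if (length(bad_len)) {
    rk_validation_error("neoantigen table row %d: peptide length outside 9-11 aa", bad_len[1])
  }
  bad_kd <- which(!is.na(out$kd_mutant_nM) & out$kd_mutant_nM <= 0 |
                    !is.na(out$kd_wildtype_nM) & out$kd_wildtype_nM <= 0)
  if (length(bad_kd)) {
    rk_validation_error("neoantigen table row %d: K_D values must be positive", bad_kd[1])
  }
  out
}

#' Write a neoantigen candidate table
#' @param neo data.frame as returned by [read_neoantigens()].
#' @param path output TSV path.
#' @export
write_neoantigens <- function(neo, path) .write_tsv(neo, path)

#' Read a sample metadata table
#' @param path TSV with columns `sample_id`, `patient_id`, `group`,
#'   `timepoint_order`.
#' @return validated data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "patient_id", "group", "timepoint_order"),
                "sample metadata")
  out <- data.frame(sample_id = df$sample_id, patient_id = df$patient_id,
                    group = df$group,
                    timepoint_order = .as_int(df$timepoint_order),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) {
    rk_validation_error("sample metadata: duplicated sample_id '%s'",
                        out$sample_id[duplicated(out$sample_id)][1])
  }
  if (!all(out$group %in% .GROUPS)) {
    rk_validation_error("sample metadata: unknown group '%s'",
                        setdiff(out$group, .GROUPS)[1])
  }
  out
}

#' Write a sample metadata table
#' @param meta data.frame as returned by [read_sample_meta()].
#' @param path output TSV path.
#' @export
write_sample_meta <- function(meta, path) .write_tsv(meta, path)

#' Read a signature catalog CSV
#'
#' Layout: 96 rows (one per channel, first column `channel` in the package
#' channel order) and one column per signature.  Every signature column must
#' sum to 1 within 1e-6.
#'
#' @param path CSV file path.
#' @return a `signature_catalog`: list with `names` (signatures) and `probs`
#'   (signatures x 96 matrix, rows summing to 1).
#' @export
read_signature_catalog <- function(path) {
  df <- .read_tsv(path, sep = ",")
  .require_cols(df, "channel", "signature catalog")
  if (nrow(df) != 96L) {
    rk_format_error("signature catalog: expected 96 channel rows, found %d", nrow(df))
  }
  if (!identical(df$channel, .CHANNELS)) {
    rk_validation_error("signature catalog: channel column does not match the fixed 96-channel order")
  }
  signames <- setdiff(names(df), "channel")
  if (!length(signames)) rk_format_error("signature catalog: no signature columns")
  probs <- t(vapply(df[signames], .as_num, numeric(96)))
  if (any(is.na(probs)) || any(probs < 0)) {
    rk_validation_error("signature catalog: entries must be nonnegative numbers")
  }
  sums <- rowSums(probs)
  off <- which(abs(sums - 1) > 1e-6)
  if (length(off)) {
    rk_validation_error("signature catalog: column '%s' sums to %.8f, not 1 within 1e-6",
                        signames[off[1]], sums[off[1]])
  }
  signature_catalog(signames, probs)
}

#' Construct a signature catalog object
#' @param names character vector of signature names.
#' @param probs numeric matrix, signatures x 96, rows summing to 1.
#' @return a `signature_catalog` object.
#' @export
signature_catalog <- function(names, probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 96L) rk_validation_error("catalog probs must have 96 columns")
  if (nrow(probs) != length(names)) rk_validation_error("catalog names/probs mismatch")
  if (any(probs < 0)) rk_validation_error("catalog probs must be nonnegative")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    rk_validation_error("catalog probability rows must sum to 1 within 1e-6")
  }
  rownames(probs) <- names
  colnames(probs) <- .CHANNELS
  structure(list(names = names, probs = probs), class = "signature_catalog")
}

#' Write a signature catalog CSV
#' @param catalog a `signature_catalog`.
#' @param path output CSV path.
#' @param digits decimal places written (default 8; column sums then stay
#'   within 1e-6 of 1).
#' @export
write_signature_catalog <- function(catalog, path, digits = 8) {
  df <- data.frame(channel = .CHANNELS, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (nm in catalog$names) {
    df[[nm]] <- formatC(catalog$probs[nm, ], format = "f", digits = digits)
  }
  .write_tsv(df, path, sep = ",")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("<signature_catalog: %d signatures x 96 channels>\n",
              length(x$names)))
  cat("signatures:", paste(utils::head(x$names, 10), collapse = ", "),
      if (length(x$names) > 10) "..." else "", "\n")
  invisible(x)
}

#' The packaged synthetic reference signature catalog
#'
#' Reads the catalog shipped in `inst/extdata/`.  The catalog is a
#' *synthetic stand-in* for a COSMIC-v2-style 30-signature reference: the
#' four signatures the pipeline's defaults rely on (1: 5-methylcytosine
#' deamination-like; 2 and 13: APOBEC-like; 22: aristolochic-acid-like) are
#' constructed to carry the field-standard channel peaks, and the remaining
#' 26 are smooth fillers.  It is not COSMIC data.
#'
#' @return a `signature_catalog` with 30 signatures.
#' @export
default_signature_catalog <- function() {
  path <- system.file("extdata", "signature_catalog_v2like_synthetic.csv",
                      package = "relapsekit", mustWork = TRUE)
  read_signature_catalog(path)
}
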