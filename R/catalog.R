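# Construction of the packaged synthetic signature catalog.  The real
# COSMIC v2 catalog cannot be redistributed here, so a 30-signature
# stand-in is built deterministically (pure arithmetic, no RNG):
#   "1"  - 5-methylcytosine deamination-like: C>T concentrated at NpCpG
#   "2"  - APOBEC-like C>T at tCw (T[C>T]A / T[C>T]T peaks)
#   "13" - APOBEC-like C>G at tCw (T[C>G]A / T[C>G]T peaks)
#   "22" - aristolochic-acid-like T>A, peaked at T[T>A]G (the TTG>TAG motif)
# All other signatures are smooth, mutually distinct fillers.  Peak channels
# follow the field-standard etiologies; absolute peak heights are the
# package's own choice (documented in the methods vignette).

# Peaks plus the remaining mass spread over `baseline_channels` only.
# Real substitution signatures are class-concentrated (near-zero outside
# their substitution classes); keeping the stand-ins equally concentrated
# is what makes a 10,000-draw empirical spectrum land within L1 0.05 of
# the generating vector.
.peaked_signature <- function(peaks, baseline_channels) {
  w <- numeric(96)
  names(w) <- .CHANNELS
  w[names(peaks)] <- peaks
  rest <- setdiff(baseline_channels, names(peaks))
  w[rest] <- w[rest] + (1 - sum(peaks)) / length(rest)
  w
}

.class_channels <- function(cls) {
  .CHANNELS[channel_class(1:96) %in% cls]
}

.filler_signature <- function(j) {
  i <- seq_len(96)
  w <- (1 + 0.95 * sin((0.37 + 0.11 * j) * i + 1.7 * j))^3
  w / sum(w)
}

#' Build the synthetic 30-signature reference catalog in code
#'
#' Deterministic (no RNG); [default_signature_catalog()] reads the same
#' catalog from the packaged CSV.  See the package vignette for what the
#' constructed signatures do and do not emulate.
#'
#' @return a `signature_catalog` with signatures named `"1"` to `"30"`.
#' @export
synthetic_signature_catalog <- function() {
  chan <- function(p5, cls, p3) paste0(p5, "[", cls, "]", p3)

  # CpG deamination: C>T with 3' G, all mass inside the C>T class
  sig1 <- .peaked_signature(stats::setNames(rep(0.19, 4),
                                            chan(.BASES, "C>T", "G")),
                            .class_channels("C>T"))

  sig2_peaks <- c(0.30, 0.35, 0.07, 0.07, 0.05, 0.05)
  names(sig2_peaks) <- c(chan("T", "C>T", "A"), chan("T", "C>T", "T"),
                         chan("T", "C>T", "C"), chan("T", "C>T", "G"),
                         chan("T", "C>G", "A"), chan("T", "C>G", "T"))
  sig2 <- .peaked_signature(sig2_peaks, .class_channels("C>T"))

  sig13_peaks <- c(0.30, 0.38, 0.06, 0.06, 0.05, 0.05)
  names(sig13_peaks) <- c(chan("T", "C>G", "A"), chan("T", "C>G", "T"),
                          chan("T", "C>G", "C"), chan("T", "C>G", "G"),
                          chan("T", "C>T", "A"), chan("T", "C>T", "T"))
  sig13 <- .peaked_signature(sig13_peaks, .class_channels("C>G"))

  # T>A transversions with the strongest peak at the TTG>TAG motif,
  # the remaining T>A channels carrying the residual mass
  sig22_peaks <- c(0.30, 0.15, 0.10, 0.10)
  names(sig22_peaks) <- c(chan("T", "T>A", "G"), chan("C", "T>A", "G"),
                          chan("A", "T>A", "G"), chan("G", "T>A", "G"))
  sig22 <- .peaked_signature(sig22_peaks, .class_channels("T>A"))

  probs <- matrix(0, nrow = 30, ncol = 96)
  nm <- as.character(1:30)
  for (j in 1:30) probs[j, ] <- .filler_signature(j)
  probs[1, ] <- sig1
  probs[2, ] <- sig2
  probs[13, ] <- sig13
  probs[22, ] <- sig22
  signature_catalog(nm, probs)
}
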