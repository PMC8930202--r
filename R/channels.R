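# The 96 single-base-substitution channels.  Fixed order: the six pyrimidine
# substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), within each class the
# 5' flanking base then the 3' flanking base, both alphabetical (A, C, G, T).
# This is the COSMIC-style ordering and is the contract for every spectrum,
# catalog and exposure matrix in the package.

.BASES <- c("A", "C", "G", "T")
.SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.make_channels <- function() {
  out <- character(96)
  i <- 1L
  for (cls in .SUB_CLASSES) {
    for (p5 in .BASES) {
      for (p3 in .BASES) {
        out[i] <- paste0(p5, "[", cls, "]", p3)
        i <- i + 1L
      }
    }
  }
  out
}

.CHANNELS <- .make_channels()

#' The 96 substitution channel labels, in package order
#'
#' Labels look like `"A[C>T]G"`: a C>T substitution with 5' flank A and 3'
#' flank G, always written with the mutated pyrimidine on the represented
#' strand.  Order is substitution class (C>A, C>G, C>T, T>A, T>C, T>G), then
#' 5' base, then 3' base, each alphabetical.
#'
#' @return character vector of length 96.
#' @export
mutation_channels <- function() .CHANNELS

#' Substitution class of each channel index
#' @param idx integer channel indices in 1..96.
#' @return character vector of classes like `"T>A"`.
#' @export
channel_class <- function(idx) {
  stopifnot(all(idx >= 1 & idx <= 96))
  .SUB_CLASSES[(as.integer(idx) - 1L) %/% 16L + 1L]
}

#' Reverse complement of DNA strings
#' @param x character vector of A/C/G/T strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGT", "TGCA", toupper(x))
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

.comp <- function(x) chartr("ACGT", "TGCA", x)

#' Map a substitution to its 96-channel index
#'
#' Purine-reference mutations (ref A or G) are reverse-complemented so every
#' channel is expressed with a central pyrimidine; a mutation and its reverse
#' complement therefore land on the same channel.
#'
#' @param ref single reference base per mutation.
#' @param alt single alternate base per mutation.
#' @param context3 3-mer centred on the reference base, plus strand.
#' @return integer vector of channel indices (1..96), named by channel label.
#' @export
channel_of <- function(ref, alt, context3) {
  ref <- toupper(ref); alt <- toupper(alt); ctx <- toupper(context3)
  n <- length(ref)
  if (length(alt) != n || length(ctx) != n) {
    rk_validation_error("ref, alt and context3 must have equal length")
  }
  if (!all(ref %in% .BASES) || !all(alt %in% .BASES)) {
    rk_validation_error("ref/alt must be unambiguous single bases (A/C/G/T)")
  }
  if (any(ref == alt)) rk_validation_error("ref and alt must differ")
  if (any(nchar(ctx) != 3L) || !all(strsplit(paste(ctx, collapse = ""), "")[[1]] %in% .BASES)) {
    rk_validation_error("context3 must be 3-mers over A/C/G/T")
  }
  if (any(substr(ctx, 2, 2) != ref)) {
    bad <- which(substr(ctx, 2, 2) != ref)[1]
    rk_validation_error("context3 middle base does not equal ref (first offence at element %d)", bad)
  }
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    ref[flip] <- .comp(ref[flip])
    alt[flip] <- .comp(alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
  }
  lab <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  idx <- match(lab, .CHANNELS)
  names(idx) <- lab
  idx
}

#' Decompose a channel label into its parts
#' @param idx integer channel indices.
#' @return data.frame with columns `ref`, `alt`, `p5`, `p3`, `context3`, `class`.
#' @export
channel_parts <- function(idx) {
  lab <- .CHANNELS[idx]
  data.frame(
    ref = substr(lab, 3, 3),
    alt = substr(lab, 5, 5),
    p5 = substr(lab, 1, 1),
    p3 = substr(lab, 7, 7),
    context3 = paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7)),
    class = channel_class(idx),
    stringsAsFactors = FALSE
  )
}
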