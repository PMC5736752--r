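#' @useDynLib platsig, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

BASES <- c("A", "C", "G", "T")

#' Single-base substitution classes
#'
#' The six pyrimidine-reference substitution classes, in the conventional
#' order used by published signature tables.
#'
#' @return Character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
sbs_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Channel labels for the 96-channel catalog
#'
#' Labels like `"A[C>A]A"`, ordered by substitution class
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3' flank, each over
#' A, C, G, T. This matches the ordering of published reference signature
#' tables, so signatures read from such tables align with catalogs built
#' here.
#'
#' @return Character vector of length 96.
#' @export
channel_labels <- function() {
  cls <- sbs_classes()
  out <- character(96)
  i <- 1L
  for (cl in cls) {
    ref <- substr(cl, 1, 1)
    alt <- substr(cl, 3, 3)
    for (f5 in BASES) {
      for (f3 in BASES) {
        out[i] <- paste0(f5, "[", ref, ">", alt, "]", f3)
        i <- i + 1L
      }
    }
  }
  out
}

#' Channel labels for the transcription-stranded 192-channel catalog
#'
#' Each 96-channel label is split into a coding-strand (`"|+"`) and a
#' noncoding-strand (`"|-"`) sub-channel, kept adjacent so that collapsing
#' consecutive pairs recovers the 96-channel ordering. "Coding" means the
#' pyrimidine-centered representation of the mutation lies on the coding
#' (untranscribed) strand of the overlapping gene.
#'
#' @return Character vector of length 192.
#' @export
channel_labels_192 <- function() {
  base <- channel_labels()
  out <- character(192)
  out[seq(1, 192, by = 2)] <- paste0(base, "|+")
  out[seq(2, 192, by = 2)] <- paste0(base, "|-")
  out
}

#' Pyrimidine-centered trinucleotide context labels
#'
#' The 32 trinucleotides with a C or T center, in the order induced by the
#' channel ordering: center C then T, 5' flank then 3' flank over A, C, G, T.
#' Purine-centered trinucleotides are recorded under their reverse
#' complement.
#'
#' @return Character vector of length 32.
#' @export
pyrimidine_contexts <- function() {
  out <- character(32)
  i <- 1L
  for (center in c("C", "T")) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        out[i] <- paste0(f5, center, f3)
        i <- i + 1L
      }
    }
  }
  out
}

#' Reverse complement of bases or base strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

.check_bases <- function(..., what = "base") {
  for (x in list(...)) {
    bad <- !(x %in% BASES)
    if (any(bad)) {
      stop("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "),
           " (must be one of A, C, G, T)")
    }
  }
  invisible(TRUE)
}

#' Collapse a mutation to its pyrimidine-reference channel
#'
#' Mutations with a purine reference base (A or G) are reverse-complemented
#' -- both alleles and both flanks, with the flanks swapped -- so every
#' mutation is expressed with a C or T reference, giving 96 channels.
#'
#' @param ref,alt Reference and alternate base (vectors recycled together).
#' @param flank5,flank3 Reference-strand bases immediately 5' and 3' of the
#'   mutated position.
#' @return A data.frame with columns `channel` (integer 1--96) and `label`.
#' @examples
#' collapse_to_pyrimidine("C", "A", "A", "A")  # A[C>A]A
#' collapse_to_pyrimidine("G", "T", "T", "T")  # also A[C>A]A
#' @export
collapse_to_pyrimidine <- function(ref, alt, flank5, flank3) {
  n <- max(length(ref), length(alt), length(flank5), length(flank3))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  flank5 <- rep_len(flank5, n); flank3 <- rep_len(flank3, n)
  .check_bases(ref, alt, flank5, flank3)
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  comp <- function(b) chartr("ACGT", "TGCA", b)
  r <- ifelse(flip, comp(ref), ref)
  a <- ifelse(flip, comp(alt), alt)
  f5 <- ifelse(flip, comp(flank3), flank5)
  f3 <- ifelse(flip, comp(flank5), flank3)
  cls_idx <- match(paste0(r, ">", a), sbs_classes()) - 1L
  ch <- cls_idx * 16L + (match(f5, BASES) - 1L) * 4L + match(f3, BASES)
  data.frame(channel = ch,
             label = paste0(f5, "[", r, ">", a, "]", f3),
             stringsAsFactors = FALSE)
}

#' Map 96-channel indices to their 32 pyrimidine-centered contexts
#'
#' @param channel Integer vector of channel indices (1--96).
#' @return Character vector of trinucleotide context labels (e.g. `"ACA"`).
#' @export
channel_context <- function(channel = seq_len(96)) {
  stopifnot(all(channel >= 1 & channel <= 96))
  lab <- channel_labels()[channel]
  paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
}

#' Stranded channel index for a pyrimidine channel and strand class
#'
#' @param channel Integer 96-channel index.
#' @param strand_class `"coding"` or `"noncoding"`.
#' @return Integer 192-channel index (coding and noncoding sub-channels of
#'   channel `i` are `2i - 1` and `2i`).
#' @export
stranded_channel <- function(channel, strand_class) {
  stopifnot(all(strand_class %in% c("coding", "noncoding")))
  2L * channel - ifelse(strand_class == "coding", 1L, 0L)
}

#' Collapse a 192-channel catalog or signature to 96 channels
#'
#' Sums each pair of coding/noncoding sub-channels.
#'
#' @param x Numeric matrix (192 x samples) or vector of length 192.
#' @return The 96-channel marginal, with channel labels.
#' @export
collapse_stranded <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  stopifnot(nrow(x) == 192)
  out <- x[seq(1, 192, by = 2), , drop = FALSE] +
    x[seq(2, 192, by = 2), , drop = FALSE]
  rownames(out) <- channel_labels()
  out
}
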