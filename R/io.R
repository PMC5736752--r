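#' Read a somatic mutation table
#'
#' Reads a tab-separated MAF-like table with required columns `sample`,
#' `chrom`, `pos` (1-based), `ref`, `alt`, and any of the optional columns
#' `ccf`, `subclone`, `strand`, `t_depth`, `t_alt_count`, `context5`,
#' `context3`, `patient`, `clonality`. Non-SNV rows (alleles not a single
#' A/C/G/T) are dropped and counted in the `"qc"` attribute.
#'
#' @param path Path to a tab-separated file with a header.
#' @return A data.frame of SNV records; attribute `"qc"` holds
#'   `n_input` and `n_non_snv`.
#' @export
read_mutations <- function(path) {
  mut <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  required <- c("sample", "chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(mut))
  if (length(missing) > 0) {
    stop("mutation table is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  mut$chrom <- as.character(mut$chrom)
  mut$ref <- toupper(as.character(mut$ref))
  mut$alt <- toupper(as.character(mut$alt))
  n_input <- nrow(mut)
  is_snv <- mut$ref %in% BASES & mut$alt %in% BASES & mut$ref != mut$alt
  mut <- mut[is_snv, , drop = FALSE]
  attr(mut, "qc") <- list(n_input = n_input, n_non_snv = n_input - nrow(mut))
  mut
}

#' Read mutation positions and alleles from a VCF
#'
#' Only positions and alleles are used; genotypes, filters and INFO are
#' ignored. Multi-allelic records are expanded, non-SNV alleles dropped.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample id to assign to all records.
#' @return A data.frame in the same shape as [read_mutations()].
#' @export
read_mutations_vcf <- function(path, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  mut <- data.frame(sample = sample_id,
                    chrom = fix$CHROM[idx],
                    pos = as.integer(fix$POS[idx]),
                    ref = toupper(fix$REF[idx]),
                    alt = toupper(unlist(alts)),
                    stringsAsFactors = FALSE)
  n_input <- nrow(mut)
  is_snv <- mut$ref %in% BASES & mut$alt %in% BASES & mut$ref != mut$alt
  mut <- mut[is_snv, , drop = FALSE]
  attr(mut, "qc") <- list(n_input = n_input, n_non_snv = n_input - nrow(mut))
  mut
}

#' Read a reference sequence from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Read territory intervals from a BED3 file
#'
#' BED coordinates are 0-based half-open; the returned ranges are 1-based
#' inclusive, the convention used everywhere else in this package.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A [GenomicRanges::GRanges] of the intervals.
#' @export
read_territory <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write / read a channels-by-samples catalog as TSV
#'
#' Channels are rows (first column `channel`), samples are columns.
#'
#' @param catalog Numeric matrix with channel rownames.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(channel = rownames(catalog), catalog,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @param path Path to a catalog TSV written by [write_catalog()] or in the
#'   same layout.
#' @return `read_catalog()` returns the catalog matrix.
#' @export
read_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a signature table as TSV
#'
#' Signatures are columns over labeled channel rows, the layout of published
#' 96-row reference signature panels, so external panels in this layout can
#' be read directly.
#'
#' @param W Channels-by-signatures matrix, columns summing to 1.
#' @param path File path.
#' @export
write_signatures <- function(W, path) {
  write_catalog(W, path)
}

#' @rdname write_signatures
#' @return `read_signatures()` returns the signature matrix, reordered to
#'   this package's channel ordering when the labels match the 96-channel
#'   convention.
#' @export
read_signatures <- function(path) {
  m <- read_catalog(path)
  if (nrow(m) == 96 && setequal(rownames(m), channel_labels())) {
    m <- m[channel_labels(), , drop = FALSE]
  }
  m
}
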