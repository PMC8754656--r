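#' Construct a genomic region
#'
#' A genomic region is the unit a tiling screen is designed against: a
#' chromosome name, a 0-based half-open coordinate interval, and the uppercase
#' DNA sequence of that interval. The screen described by this package was
#' developed on a 58 kb core region of the human CDKN2A/B locus, but any
#' region works.
#'
#' @param sequence DNA string (characters restricted to A, C, G, T, N);
#'   lowercase is accepted and upper-cased.
#' @param chrom Chromosome name, e.g. `"chr9"`.
#' @param start 0-based start of the region on `chrom` (BED convention).
#'
#' @return A list of class `genomic_region` with fields `chrom`, `start`,
#'   `end` and `sequence`; `end - start == nchar(sequence)`.
#' @examples
#' genomic_region("ACGTACGTAC", chrom = "chrX", start = 100)
#' @export
genomic_region <- function(sequence, chrom = "chr9", start = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    abort("region too short: empty sequence")
  }
  if (grepl("[^ACGTN]", sequence)) {
    abort("invalid sequence: characters outside {A,C,G,T,N}")
  }
  start <- as.integer(start)
  structure(
    list(
      chrom = chrom,
      start = start,
      end = start + nchar(sequence),
      sequence = sequence
    ),
    class = "genomic_region"
  )
}

#' Read a genomic region from a FASTA file
#'
#' Reads the first (or a named) record of a FASTA file as the region sequence.
#' The absolute offset is taken from `start` (the FASTA itself carries no
#' coordinates).
#'
#' @param path Path to a FASTA file.
#' @param chrom Chromosome label for downstream BED output.
#' @param start Absolute 0-based start coordinate of the sequence on `chrom`.
#' @param record Optional record name to select; default first record.
#' @return A [genomic_region()].
#' @export
read_region <- function(path, chrom = "chr9", start = 0L, record = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) abort(paste0("no FASTA records in ", path))
  if (!is.null(record)) {
    hit <- match(record, names(seqs))
    if (is.na(hit)) abort(paste0("FASTA record not found: ", record))
    seqs <- seqs[hit]
  }
  genomic_region(as.character(seqs[[1L]]), chrom = chrom, start = start)
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf(
    "<genomic_region> %s:%d-%d (%d bp)\n",
    x$chrom, x$start, x$end, x$end - x$start
  ))
  invisible(x)
}
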