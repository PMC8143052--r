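#' Read a reference genome from FASTA
#'
#' Loads a (multi-)FASTA file into a `genome` object: an ordered set of
#' named chromosome sequences. Sequences are uppercased and multi-line
#' records concatenated; record order is preserved. Coordinates throughout
#' the package are 1-based and inclusive.
#'
#' @param path Path to a FASTA file.
#' @return A `genome` object (named character vector of chromosome
#'   sequences with `lengths` and `total_size` accessors).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">")) stop("not a FASTA file (missing '>'): ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  # keep only the first word of each header, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome(seqs)
}

#' Construct a genome object
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return A `genome` object.
#' @export
genome <- function(seqs) {
  if (length(seqs) == 0L) stop("genome has no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name: ",
         names(seqs)[duplicated(names(seqs))][1L])
  seqs <- vapply(seqs, toupper, character(1L))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for ", names(seqs)[nchar(seqs) == 0L][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("illegal character in sequence of ", names(seqs)[bad][1L])
  structure(seqs, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "chromosome(s),",
      format(genome_size(x), big.mark = ","), "bp total\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %12s bp\n", nm,
                format(nchar(unclass(x)[[nm]]), big.mark = ",")))
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g A `genome` object.
#' @return Named integer vector of chromosome lengths in bp.
#' @export
chrom_lengths <- function(g) {
  stats::setNames(nchar(unclass(g)), names(g))
}

#' Total genome size in bp
#' @param g A `genome` object.
#' @return Total size in bp.
#' @export
genome_size <- function(g) sum(chrom_lengths(g))

#' Write a genome to FASTA
#'
#' @param g A `genome` object.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(g))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Extract a genomic subsequence
#'
#' @param g A `genome` object.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds (clipped to the chromosome).
#' @return Character scalar.
#' @export
genome_subseq <- function(g, chrom, start, end) {
  s <- unclass(g)[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  start <- max(1L, as.integer(start))
  end <- min(nchar(s), as.integer(end))
  if (end < start) return("")
  substr(s, start, end)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
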