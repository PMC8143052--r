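#' SAM flag bit constants
#' @keywords internal
#' @noRd
FLAG_PAIRED <- 1L
FLAG_PROPER <- 2L
FLAG_UNMAPPED <- 4L
FLAG_MATE_UNMAPPED <- 8L
FLAG_REVERSE <- 16L
FLAG_MATE_REVERSE <- 32L
FLAG_FIRST <- 64L
FLAG_SECOND <- 128L

#' Construct an alignment table
#'
#' The package-wide container for read alignments, mirroring the SAM
#' mandatory columns. `chrom = "*"` and flag bit 4 mark unmapped records;
#' soft clips appear only at CIGAR ends.
#'
#' @param qname,flag,chrom,pos,mapq,cigar,rnext,pnext,tlen,seq,qual SAM
#'   mandatory fields (vectors of equal length).
#' @return A data.frame of class `alignments`.
#' @export
alignments <- function(qname, flag, chrom, pos, mapq, cigar,
                       rnext = "*", pnext = 0L, tlen = 0L,
                       seq = "*", qual = "*") {
  structure(data.frame(qname = as.character(qname), flag = as.integer(flag),
                       chrom = as.character(chrom), pos = as.integer(pos),
                       mapq = as.integer(mapq), cigar = as.character(cigar),
                       rnext = rep_len(as.character(rnext), length(qname)),
                       pnext = rep_len(as.integer(pnext), length(qname)),
                       tlen = rep_len(as.integer(tlen), length(qname)),
                       seq = rep_len(as.character(seq), length(qname)),
                       qual = rep_len(as.character(qual), length(qname)),
                       stringsAsFactors = FALSE),
            class = c("alignments", "data.frame"))
}

#' Parse CIGAR strings into operation tables
#'
#' @param cigar Character vector of CIGAR strings.
#' @return List of data.frames with columns `op` and `len`.
#' @export
cigar_ops <- function(cigar) {
  lapply(cigar, function(cg) {
    if (cg == "*") return(data.frame(op = character(0), len = integer(0)))
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
    if (length(lens) != length(ops)) stop("malformed CIGAR: ", cg)
    data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
  })
}

#' Query length implied by a CIGAR string
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of query-consuming lengths.
#' @export
cigar_query_len <- function(cigar) {
  vapply(cigar_ops(cigar), function(d)
    sum(d$len[d$op %in% c("M", "I", "S", "=", "X")]), numeric(1L))
}

#' Reference span implied by a CIGAR string
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference-consuming lengths.
#' @export
cigar_ref_len <- function(cigar) {
  vapply(cigar_ops(cigar), function(d)
    sum(d$len[d$op %in% c("M", "D", "=", "X", "N")]), numeric(1L))
}

#' Write alignments to a plain-text SAM file
#'
#' @param aln An `alignments` table.
#' @param genome A `genome` object supplying the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
sam_write <- function(aln, genome, path) {
  lens <- chrom_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  body <- if (nrow(aln)) {
    paste(aln$qname, aln$flag, aln$chrom, aln$pos, aln$mapq, aln$cigar,
          aln$rnext, aln$pnext, aln$tlen, aln$seq, aln$qual, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a plain-text SAM file
#'
#' Parses the eleven mandatory SAM columns. Requires `@SQ` header lines;
#' rejects records whose CIGAR query length disagrees with the sequence
#' length.
#'
#' @param path Path to a SAM file.
#' @return An `alignments` table; the `@SQ` names and lengths are attached
#'   as attributes `sq_names` / `sq_lengths`.
#' @export
sam_read <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0L) stop("SAM file lacks @SQ header lines: ", path)
  sq_names <- sub("^.*\tSN:([^\t]+).*$", "\\1", sq)
  sq_lengths <- as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq))
  body <- ln[!startsWith(ln, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    out <- alignments(character(0), integer(0), character(0), integer(0),
                      integer(0), character(0))
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(f) < 11L)) stop("SAM record with fewer than 11 fields")
    col <- function(i) vapply(f, `[[`, character(1L), i)
    out <- alignments(qname = col(1L), flag = as.integer(col(2L)),
                      chrom = col(3L), pos = as.integer(col(4L)),
                      mapq = as.integer(col(5L)), cigar = col(6L),
                      rnext = col(7L), pnext = as.integer(col(8L)),
                      tlen = as.integer(col(9L)), seq = col(10L),
                      qual = col(11L))
    has_seq <- out$seq != "*" & out$cigar != "*"
    if (any(has_seq)) {
      ql <- cigar_query_len(out$cigar[has_seq])
      bad <- ql != nchar(out$seq[has_seq])
      if (any(bad)) {
        b <- which(has_seq)[bad][1L]
        stop("CIGAR query length disagrees with sequence length for read ",
             out$qname[b])
      }
    }
    mapped <- bitwAnd(out$flag, FLAG_UNMAPPED) == 0L
    if (any(mapped & !(out$chrom %in% sq_names)))
      stop("alignment to a chromosome absent from the @SQ header")
  }
  attr(out, "sq_names") <- sq_names
  attr(out, "sq_lengths") <- sq_lengths
  out
}
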