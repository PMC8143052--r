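#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features linked by `Parent` attributes into a
#' list of gene models, one per mRNA. Exons are stored in ascending
#' genomic order; CDS segments are stored in translation order (ascending
#' for plus-strand models, descending genomic order for minus-strand
#' models). Models whose total CDS length is not divisible by three are
#' flagged (`frame_ok = FALSE`) rather than rejected.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `genome` object used to validate that features
#'   lie within chromosome bounds.
#' @return A list of `gene_model` objects with fields `gene_id`,
#'   `mrna_id`, `chrom`, `strand`, `exons` (matrix start/end), `cds`
#'   (matrix start/end in translation order), `annotation`, `frame_ok`.
#' @export
read_gene_models <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_,
           character(1L))
  } else rep(NA_character_, length(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))

  lens <- if (!is.null(genome)) chrom_lengths(genome) else NULL

  is_mrna <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  is_cds <- type == "CDS"
  if (any((is_exon | is_cds) & is.na(parents)))
    stop("exon/CDS feature without Parent linkage in ", path)

  models <- vector("list", sum(is_mrna))
  mi <- 0L
  for (i in which(is_mrna)) {
    mid <- ids[i]
    if (is.na(mid)) stop("mRNA feature without ID in ", path)
    exi <- which(is_exon & parents == mid)
    cdi <- which(is_cds & parents == mid)
    ex <- if (length(exi)) {
      o <- order(starts[exi])
      cbind(start = starts[exi][o], end = ends[exi][o])
    } else cbind(start = starts[i], end = ends[i])
    cds <- NULL
    frame_ok <- NA
    if (length(cdi)) {
      o <- order(starts[cdi])
      cds <- cbind(start = starts[cdi][o], end = ends[cdi][o])
      if (strands[i] == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
      frame_ok <- sum(cds[, "end"] - cds[, "start"] + 1L) %% 3L == 0L
    }
    if (!is.null(lens)) {
      lim <- lens[[chroms[i]]]
      if (is.null(lim)) stop("unknown chromosome in GFF3: ", chroms[i])
      hi <- max(ends[c(i, exi, cdi)])
      if (hi > lim)
        stop("feature of ", mid, " extends beyond chromosome ", chroms[i],
             " (", hi, " > ", lim, ")")
    }
    ann <- ""
    if ("Note" %in% names(md)) {
      nt <- md$Note[[i]]
      if (length(nt)) ann <- paste(as.character(nt), collapse = "; ")
    }
    mi <- mi + 1L
    models[[mi]] <- structure(list(
      gene_id = if (!is.na(parents[i])) parents[i] else mid,
      mrna_id = mid,
      chrom = chroms[i],
      strand = strands[i],
      exons = ex,
      cds = cds,
      annotation = ann,
      frame_ok = frame_ok), class = "gene_model")
  }
  models[seq_len(mi)]
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene model %s (%s) %s:%d-%d [%s], %d exon(s), %s\n",
              x$mrna_id, x$gene_id, x$chrom, min(x$exons[, "start"]),
              max(x$exons[, "end"]), x$strand, nrow(x$exons),
              if (is.null(x$cds)) "non-coding" else
                sprintf("CDS %d bp%s", sum(x$cds[, "end"] - x$cds[, "start"] + 1L),
                        if (isFALSE(x$frame_ok)) " (frame violation)" else "")))
  invisible(x)
}

#' Spliced CDS sequence of a gene model
#'
#' Concatenates CDS segments in translation order; minus-strand models are
#' reverse-complemented so the result reads 5' to 3' on the coding strand.
#'
#' @param model A `gene_model`.
#' @param genome A `genome` object.
#' @return Character scalar coding sequence.
#' @export
cds_sequence <- function(model, genome) {
  if (is.null(model$cds)) stop("gene model ", model$mrna_id, " has no CDS")
  segs <- apply(model$cds, 1L, function(iv)
    genome_subseq(genome, model$chrom, iv[["start"]], iv[["end"]]))
  if (model$strand == "-") segs <- revcomp(segs)
  paste(segs, collapse = "")
}
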