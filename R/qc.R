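#' Read-depth distribution of a sample
#'
#' Computes the per-position read depth (count of reads whose reference
#' span covers the position) for every chromosome, summarised as a depth
#' histogram plus mean and median depth. The mean equals aligned bases
#' divided by genome size; the histogram always sums to the genome size.
#'
#' @param aln An `alignments` table.
#' @param genome The reference `genome`.
#' @return A list with `per_chrom` (named list of depth histograms as
#'   named integer vectors), `histogram` (genome-wide), `mean_depth`,
#'   `median_depth`.
#' @export
compute_rd_distribution <- function(aln, genome) {
  lens <- chrom_lengths(genome)
  keep <- bitwAnd(aln$flag, FLAG_UNMAPPED) == 0L
  sub <- aln[keep, , drop = FALSE]
  if (nrow(sub) && any(!sub$chrom %in% names(lens)))
    stop("alignment to a chromosome absent from the genome")
  span <- if ("matchL" %in% names(sub)) sub$matchL else
    as.integer(cigar_ref_len(sub$cigar))
  if (nrow(sub) && any(sub$pos + span - 1L > lens[sub$chrom]))
    stop("alignment extends beyond the chromosome end")
  per_chrom <- vector("list", length(lens))
  names(per_chrom) <- names(lens)
  all_counts <- integer(0)
  aligned_bases <- 0
  meds <- list()
  for (cn in names(lens)) {
    on_c <- sub$chrom == cn
    depth <- cov_from_ranges(sub$pos[on_c], (sub$pos + span - 1L)[on_c],
                             lens[[cn]])
    aligned_bases <- aligned_bases + sum(as.numeric(span[on_c]))
    h <- tabulate(depth + 1L)
    names(h) <- as.character(seq_along(h) - 1L)
    per_chrom[[cn]] <- h
    meds[[cn]] <- depth
  }
  maxd <- max(vapply(per_chrom, length, integer(1L)))
  total <- integer(maxd)
  for (h in per_chrom) total[seq_along(h)] <- total[seq_along(h)] + h
  names(total) <- as.character(seq_len(maxd) - 1L)
  list(per_chrom = per_chrom,
       histogram = total,
       mean_depth = aligned_bases / sum(lens),
       median_depth = stats::median(unlist(meds, use.names = FALSE)))
}
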