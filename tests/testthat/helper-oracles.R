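# Independent oracles, deliberately coded apart from the implementation.

# closed-form expected pooled allele frequencies (derived by conditional
# expectation over F2 genotype classes, not by gamete enumeration):
# mutant pool E[AF] = 1 - r; wild-type sibling pool E[AF] = (1 + r) / 3
oracle_af_mutant <- function(r) 1 - r
oracle_af_wt_sibling <- function(r) (1 + r) / 3

# brute-force triangular-weight smoothing of a per-chromosome profile
oracle_smooth <- function(vals, empty, weights = c(4, 3, 2, 1)) {
  n <- length(vals)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (empty[i] || is.na(vals[i])) next
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      d <- abs(j - i)
      if (d > length(weights) - 1L) next
      if (empty[j] || is.na(vals[j])) next
      num <- num + weights[d + 1L] * vals[j]
      den <- den + weights[d + 1L]
    }
    out[i] <- num / den
  }
  out
}

# exhaustive string-search alignment of an error-free read: every
# full-length placement on either strand with zero mismatches
oracle_exact_hits <- function(genome, read) {
  hits <- list()
  rc <- revcomp(read)
  for (cn in names(genome)) {
    s <- unclass(genome)[[cn]]
    for (q in unique(c(read, rc))) {
      p <- gregexpr(q, s, fixed = TRUE)[[1L]]
      if (p[1L] > 0L)
        hits[[length(hits) + 1L]] <- data.frame(chrom = cn, pos = as.integer(p),
                                                strand = if (q == read) 0L else 1L)
    }
  }
  if (!length(hits)) return(data.frame(chrom = character(0), pos = integer(0),
                                       strand = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

# per-position depth by naive counting over every alignment
oracle_depth <- function(starts, ends, len) {
  d <- integer(len)
  for (i in seq_along(starts)) {
    for (p in starts[i]:ends[i]) if (p >= 1 && p <= len) d[p] <- d[p] + 1L
  }
  d
}

# full-CDS translation comparison for effect prediction
oracle_effect_severity <- function(model, genome, variant) {
  mut <- unclass(genome)
  s <- mut[[variant$chrom]]
  substr(s, variant$pos, variant$pos) <- variant$alt
  mut[[variant$chrom]] <- s
  mut_genome <- genome(mut)
  wt <- cds_sequence(model, genome)
  mt <- cds_sequence(model, mut_genome)
  aa_wt <- as.character(Biostrings::translate(Biostrings::DNAString(wt),
                                              if.fuzzy.codon = "X",
                                              no.init.codon = TRUE))
  aa_mt <- as.character(Biostrings::translate(Biostrings::DNAString(mt),
                                              if.fuzzy.codon = "X",
                                              no.init.codon = TRUE))
  if (aa_wt == aa_mt) return("synonymous")
  d <- which(strsplit(aa_wt, "")[[1L]] != strsplit(aa_mt, "")[[1L]])[1L]
  mt_aa <- strsplit(aa_mt, "")[[1L]][d]
  if (mt_aa == "*") return("nonsense")
  if (d == 1L && substr(wt, 1L, 3L) == "ATG") return("start_loss")
  "missense"
}
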