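#' Build a k-mer seed index over a genome
#'
#' Indexes every k-mer of the reference (skipping those containing N) for
#' seed-and-extend alignment. The index holds its own copy of the
#' sequences, so reads can be aligned without passing the genome again.
#'
#' @param genome A `genome` object.
#' @param k Seed length (8..32).
#' @return An `align_index` object.
#' @export
build_index <- function(genome, k = 16L) {
  k <- as.integer(k)
  if (k < 8L || k > 32L) stop("k must be in 8..32")
  lens <- chrom_lengths(genome)
  if (k > min(lens))
    stop("k exceeds the shortest chromosome (", min(lens), " bp)")
  xp <- cpp_build_index(unname(unclass(genome)), names(genome), k)
  structure(list(ptr = xp, k = k, chroms = names(genome), lengths = lens),
            class = "align_index")
}

#' @export
print.align_index <- function(x, ...) {
  cat("seed index: k =", x$k, "over", length(x$chroms), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' Look up a k-mer in a seed index
#'
#' @param index An `align_index`.
#' @param kmer A nucleotide string of length `k`.
#' @return data.frame with columns `chrom` (name) and `pos` (1-based) of
#'   every exact occurrence; zero rows when absent or containing N.
#' @export
lookup_kmer <- function(index, kmer) {
  hit <- cpp_index_lookup(index$ptr, toupper(kmer))
  data.frame(chrom = index$chroms[hit$chrom], pos = hit$pos,
             stringsAsFactors = FALSE)
}

#' Align short reads to an indexed genome
#'
#' Seed-and-extend alignment with two modes. `end_to_end` reports a
#' full-length placement when at most `max_mismatches` mismatches remain
#' after seeding on both strands; `local` extends exact seeds with an
#' X-drop heuristic and soft-clips unextendable ends (CIGAR `xS yM zS`),
#' requiring a matched block of at least `min_block` nt. Ties are broken
#' deterministically by chromosome order, then position, then strand;
#' reads whose best score is shared by more than `max_hits` locations are
#' reported unmapped. In paired mode the proper-pair flag is set for
#' inward-facing mates within `insert_mean + 4 * insert_sd`.
#'
#' @param index An `align_index`.
#' @param reads A `read_set`, or a list of two `read_set`s (mates) when
#'   `paired = TRUE`.
#' @param mode `"end_to_end"` or `"local"`.
#' @param paired Logical; mate-aware flags and proper-pair calling.
#' @param max_mismatches Mismatch budget for end-to-end mode.
#' @param min_block Minimum matched block for local mode.
#' @param max_hits Multi-mapping cap; beyond it a read is unmapped.
#' @param xdrop X-drop threshold for local extension.
#' @param insert_mean,insert_sd Insert-size envelope for proper pairs.
#' @return An `alignments` table with extra columns `clipL`, `matchL`,
#'   `clipR`, `nmm`, `nhits`, `strand`; observed mismatches inside matched
#'   blocks are attached as attribute `mm` (data.frame `read`, `chrom`,
#'   `pos`, `base`).
#' @export
align_reads <- function(index, reads, mode = c("end_to_end", "local"),
                        paired = FALSE, max_mismatches = 3L, min_block = 20L,
                        max_hits = 4L, xdrop = 12L,
                        insert_mean = 300, insert_sd = 50) {
  mode <- match.arg(mode)
  if (paired) {
    if (!is.list(reads) || is.data.frame(reads) || length(reads) != 2L)
      stop("paired mode needs a list of two read sets")
    r1 <- reads[[1L]]; r2 <- reads[[2L]]
    if (nrow(r1) != nrow(r2)) stop("mate files differ in read count")
    all_reads <- rbind(r1, r2)
  } else {
    if (is.list(reads) && !is.data.frame(reads)) stop("single-end mode takes one read set")
    all_reads <- reads
  }
  res <- cpp_align(index$ptr, all_reads$seq,
                   if (mode == "end_to_end") 0L else 1L,
                   as.integer(max_mismatches), as.integer(min_block),
                   as.integer(max_hits), as.integer(xdrop))
  n <- nrow(all_reads)
  mapped <- res$mapped
  rev <- mapped & res$strand == 1L
  rev[is.na(rev)] <- FALSE
  flag <- FLAG_UNMAPPED * (!mapped) + FLAG_REVERSE * rev
  chrom <- rep("*", n)
  chrom[mapped] <- index$chroms[res$chrom[mapped]]
  pos <- integer(n)
  pos[mapped] <- res$pos[mapped]
  cigar <- cpp_make_cigars(res$clipL, res$matchL, res$clipR, mapped)
  mapq <- integer(n)
  mapq[mapped] <- res$mapq[mapped]
  if (paired) {
    np <- n %/% 2L
    i1 <- seq_len(np); i2 <- np + i1
    m1 <- mapped[i1]; m2 <- mapped[i2]
    flag[i1] <- flag[i1] + FLAG_PAIRED + FLAG_FIRST +
      FLAG_MATE_UNMAPPED * (!m2) + FLAG_MATE_REVERSE * rev[i2]
    flag[i2] <- flag[i2] + FLAG_PAIRED + FLAG_SECOND +
      FLAG_MATE_UNMAPPED * (!m1) + FLAG_MATE_REVERSE * rev[i1]
    end1 <- pos[i1] + res$matchL[i1] - 1L
    end2 <- pos[i2] + res$matchL[i2] - 1L
    span <- pmax(end1, end2, na.rm = FALSE) - pmin(pos[i1], pos[i2]) + 1L
    opp <- m1 & m2 & chrom[i1] == chrom[i2] & (rev[i1] != rev[i2])
    # inward-facing: the forward-strand mate lies left of the reverse mate
    fwd_left <- (!rev[i1] & pos[i1] <= pos[i2]) |
      (rev[i1] & pos[i2] <= pos[i1])
    proper <- opp & fwd_left & !is.na(span) &
      span <= insert_mean + 4 * insert_sd & span >= res$matchL[i1]
    proper[is.na(proper)] <- FALSE
    flag[i1] <- flag[i1] + FLAG_PROPER * proper
    flag[i2] <- flag[i2] + FLAG_PROPER * proper
    rnext <- rep("*", n); pnext <- integer(n); tlen <- integer(n)
    rnext[i1][m2] <- chrom[i2][m2]; rnext[i2][m1] <- chrom[i1][m1]
    pnext[i1][m2] <- pos[i2][m2]; pnext[i2][m1] <- pos[i1][m1]
    tl <- span * proper
    tl[is.na(tl)] <- 0L
    tlen[i1] <- tl * ifelse(rev[i1], -1L, 1L)
    tlen[i2] <- tl * ifelse(rev[i2], -1L, 1L)
  } else {
    rnext <- "*"; pnext <- 0L; tlen <- 0L
  }
  # SAM convention: reverse-strand records store the reference-oriented
  # (reverse-complemented) sequence and reversed qualities
  seqs <- all_reads$seq
  quals <- all_reads$qual
  if (any(rev)) {
    seqs[rev] <- revcomp(seqs[rev])
    quals[rev] <- vapply(strsplit(quals[rev], NULL),
                         function(q) paste(rev(q), collapse = ""),
                         character(1L))
  }
  out <- alignments(qname = all_reads$id, flag = as.integer(flag),
                    chrom = chrom, pos = pos, mapq = mapq,
                    cigar = cigar, rnext = rnext, pnext = pnext,
                    tlen = as.integer(tlen),
                    seq = seqs, qual = quals)
  out$clipL <- res$clipL; out$matchL <- res$matchL; out$clipR <- res$clipR
  out$nmm <- res$nmm; out$nhits <- res$nhits
  out$strand <- res$strand
  attr(out, "mm") <- data.frame(read = res$mm_read,
                                chrom = index$chroms[res$mm_chrom],
                                pos = res$mm_pos, base = res$mm_base,
                                stringsAsFactors = FALSE)
  out
}

#' Variant-calling stringency presets
#'
#' Two bundled filtering levels for polymorphic-site calling. The high
#' preset tightens every threshold and additionally requires alternative
#' support on both strands.
#'
#' @param level `"low"` or `"high"`, or a list with the preset fields to
#'   pass through unchanged.
#' @return A list with fields `level`, `min_dp`, `min_alt_reads`,
#'   `min_alt_frac`, `min_mapq`, `require_both_strands`.
#' @export
stringency_preset <- function(level = c("low", "high")) {
  if (is.list(level)) return(level)
  level <- match.arg(level)
  if (level == "low") {
    list(level = "low", min_dp = 4L, min_alt_reads = 2L, min_alt_frac = 0.15,
         min_mapq = 0L, require_both_strands = FALSE)
  } else {
    list(level = "high", min_dp = 8L, min_alt_reads = 3L, min_alt_frac = 0.25,
         min_mapq = 20L, require_both_strands = TRUE)
  }
}

cov_from_ranges <- function(start, end, len) {
  if (length(start) == 0L) return(integer(len))
  inc <- tabulate(start, nbins = len)
  dec <- tabulate(end + 1L, nbins = len + 1L)[seq_len(len)]
  cumsum(inc - dec)
}

# walk CIGARs of SAM-sourced records and collect observed mismatch triples
mm_from_sequences <- function(aln, genome) {
  out <- list()
  oi <- 0L
  ops <- cigar_ops(aln$cigar)
  for (i in seq_len(nrow(aln))) {
    d <- ops[[i]]
    q <- 1L; g <- aln$pos[i]
    rs <- aln$seq[i]
    gs <- unclass(genome)[[aln$chrom[i]]]
    for (j in seq_len(nrow(d))) {
      op <- d$op[j]; L <- d$len[j]
      if (op %in% c("M", "=", "X")) {
        rb <- utf8ToInt(substr(rs, q, q + L - 1L))
        gb <- utf8ToInt(substr(gs, g, g + L - 1L))
        diff <- which(rb != gb)
        if (length(diff)) {
          oi <- oi + 1L
          out[[oi]] <- data.frame(read = i, chrom = aln$chrom[i],
                                  pos = g + diff - 1L,
                                  base = substring(rs, q + diff - 1L, q + diff - 1L),
                                  stringsAsFactors = FALSE)
        }
        q <- q + L; g <- g + L
      } else if (op %in% c("S", "I")) {
        q <- q + L
      } else if (op %in% c("D", "N")) {
        g <- g + L
      }
    }
  }
  if (oi == 0L)
    data.frame(read = integer(0), chrom = character(0), pos = integer(0),
               base = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Build a pileup from alignments
#'
#' Per-position, per-strand base evidence. Soft-clipped bases contribute
#' nothing; records below `min_mapq` and unmapped records are skipped; N
#' bases are tallied but never count as reference or alternative
#' evidence. The pileup is stored as dense per-strand depth vectors plus a
#' sparse table of non-reference observations, which together give the
#' full per-base strand counts at any position.
#'
#' @param aln An `alignments` table (from [align_reads()] or [sam_read()]).
#' @param genome The reference `genome`.
#' @param min_mapq Minimum mapping quality.
#' @return A `pileup` object.
#' @export
pileup_from_alignments <- function(aln, genome, min_mapq = 0L) {
  lens <- chrom_lengths(genome)
  keep <- bitwAnd(aln$flag, FLAG_UNMAPPED) == 0L & aln$mapq >= min_mapq
  chromv <- aln$chrom[keep]
  posv <- aln$pos[keep]
  if (length(chromv) && any(!chromv %in% names(lens)))
    stop("alignment to a chromosome absent from the genome")
  ref_span <- if ("matchL" %in% names(aln)) aln$matchL[keep] else
    as.integer(cigar_ref_len(aln$cigar[keep]))
  if (length(chromv) && any(posv + ref_span - 1L > lens[chromv]))
    stop("alignment extends beyond the chromosome end")
  rev_flag <- bitwAnd(aln$flag[keep], FLAG_REVERSE) != 0L
  endv <- posv + ref_span - 1L
  cov_fwd <- cov_rev <- vector("list", length(lens))
  names(cov_fwd) <- names(cov_rev) <- names(lens)
  for (cn in names(lens)) {
    on_c <- chromv == cn
    cov_fwd[[cn]] <- cov_from_ranges(posv[on_c & !rev_flag],
                                     endv[on_c & !rev_flag], lens[[cn]])
    cov_rev[[cn]] <- cov_from_ranges(posv[on_c & rev_flag],
                                     endv[on_c & rev_flag], lens[[cn]])
  }
  mm <- attr(aln, "mm")
  if (is.null(mm)) {
    sub <- aln[which(keep), , drop = FALSE]
    mm <- mm_from_sequences(sub, genome)
    mm$rev <- rev_flag[mm$read]
  } else {
    mm <- mm[keep[mm$read], , drop = FALSE]
    mm$rev <- (bitwAnd(aln$flag[mm$read], FLAG_REVERSE) != 0L)
  }
  alt <- if (nrow(mm)) {
    key <- paste(mm$chrom, mm$pos, mm$base, sep = "\r")
    agg_f <- tapply(!mm$rev, key, sum)
    agg_r <- tapply(mm$rev, key, sum)
    parts <- strsplit(names(agg_f), "\r", fixed = TRUE)
    data.frame(chrom = vapply(parts, `[[`, character(1L), 1L),
               pos = as.integer(vapply(parts, `[[`, character(1L), 2L)),
               base = vapply(parts, `[[`, character(1L), 3L),
               nf = as.integer(agg_f), nr = as.integer(agg_r),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), pos = integer(0), base = character(0),
               nf = integer(0), nr = integer(0), stringsAsFactors = FALSE)
  }
  alt <- alt[order(match(alt$chrom, names(lens)), alt$pos, alt$base), ,
             drop = FALSE]
  rownames(alt) <- NULL
  structure(list(chroms = names(lens), lengths = lens,
                 cov_fwd = cov_fwd, cov_rev = cov_rev, alt = alt),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup over", length(x$chroms), "chromosome(s);",
      nrow(x$alt), "non-reference site/base observations\n")
  invisible(x)
}

#' Per-base strand counts at a position
#'
#' @param pile A `pileup`.
#' @param genome The reference `genome`.
#' @param chrom,pos Position to inspect.
#' @return A 2x5 matrix (rows fwd/rev, columns A,C,G,T,N) of base counts.
#' @export
pileup_counts <- function(pile, genome, chrom, pos) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(0L, 2L, 5L, dimnames = list(c("fwd", "rev"), bases))
  sel <- pile$alt$chrom == chrom & pile$alt$pos == pos
  for (i in which(sel)) {
    m["fwd", pile$alt$base[i]] <- pile$alt$nf[i]
    m["rev", pile$alt$base[i]] <- pile$alt$nr[i]
  }
  ref <- genome_subseq(genome, chrom, pos, pos)
  m["fwd", ref] <- pile$cov_fwd[[chrom]][pos] - sum(m["fwd", bases != ref])
  m["rev", ref] <- pile$cov_rev[[chrom]][pos] - sum(m["rev", bases != ref])
  m
}

#' Call polymorphic sites from a pileup
#'
#' Emits a variant record only where alternative-allele evidence passes
#' the stringency preset: depth at least `min_dp`, alternative reads at
#' least `min_alt_reads`, alternative fraction at least `min_alt_frac`,
#' and (high stringency) support on both strands. Monomorphic sites are
#' never reported; N observations never count as evidence. At multi-base
#' sites the strongest alternative allele is called (ties broken
#' alphabetically).
#'
#' @param pileup A `pileup` object.
#' @param genome The reference `genome`.
#' @param preset A [stringency_preset()] (its `min_mapq` applies at pileup
#'   construction).
#' @param sample Sample label for the emitted records.
#' @return A `variant_table` sorted by chromosome then position.
#' @export
call_variants <- function(pileup, genome, preset = stringency_preset("low"),
                          sample = "test") {
  preset <- stringency_preset(preset)
  alt <- pileup$alt
  if (nrow(alt) == 0L) return(variant_table(sample = sample))
  site <- paste(alt$chrom, alt$pos, sep = "\r")
  nonN <- alt$base != "N"
  tot <- alt$nf + alt$nr
  by_site <- split(seq_len(nrow(alt)), site)
  res <- list(); oi <- 0L
  for (others in by_site) {
    rows <- others[nonN[others]]
    if (!length(rows)) next
    best <- rows[order(-tot[rows], alt$base[rows])][1L]
    chrom <- alt$chrom[best]; pos <- alt$pos[best]
    ref <- genome_subseq(genome, chrom, pos, pos)
    if (alt$base[best] == ref) next
    adf_alt <- alt$nf[best]; adr_alt <- alt$nr[best]
    of <- sum(alt$nf[others]); orv <- sum(alt$nr[others])
    adf_ref <- pileup$cov_fwd[[chrom]][pos] - of
    adr_ref <- pileup$cov_rev[[chrom]][pos] - orv
    dp <- pileup$cov_fwd[[chrom]][pos] + pileup$cov_rev[[chrom]][pos]
    alt_n <- adf_alt + adr_alt
    denom <- alt_n + adf_ref + adr_ref
    if (dp < preset$min_dp) next
    if (alt_n < preset$min_alt_reads) next
    if (denom <= 0L || alt_n / denom < preset$min_alt_frac) next
    if (preset$require_both_strands && (adf_alt < 1L || adr_alt < 1L)) next
    oi <- oi + 1L
    res[[oi]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                            alt = alt$base[best], dp = dp,
                            adf_ref = adf_ref, adr_ref = adr_ref,
                            adf_alt = adf_alt, adr_alt = adr_alt,
                            stringsAsFactors = FALSE)
  }
  if (oi == 0L) return(variant_table(sample = sample))
  d <- do.call(rbind, res)
  o <- order(match(d$chrom, pileup$chroms), d$pos)
  d <- d[o, , drop = FALSE]
  variant_table(d$chrom, d$pos, d$ref, d$alt, d$adf_ref, d$adr_ref,
                d$adf_alt, d$adr_alt, dp = d$dp, sample = sample)
}
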