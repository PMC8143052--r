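test_that("the seed index returns every exact k-mer occurrence", {
  g <- genome(c(c1 = "ACGTACGT"))
  idx <- build_index(g, k = 8L)  # k floor is 8; index the whole sequence
  hit <- lookup_kmer(idx, "ACGTACGT")
  expect_identical(hit$pos, 1L)
  # a genome long enough for k below its length, with a repeated k-mer
  g2 <- genome(c(c1 = paste0("ACGTACGTTT", strrep("A", 20),
                             "ACGTACGT", strrep("C", 20))))
  idx2 <- build_index(g2, k = 8L)
  hit2 <- lookup_kmer(idx2, "ACGTACGT")
  expect_identical(hit2$pos, c(1L, 31L))
  expect_identical(nrow(lookup_kmer(idx2, "GGGGGGGG")), 0L)
  expect_identical(nrow(lookup_kmer(idx2, "ACGTACGN")), 0L)
  # every stored position yields an exact match
  for (i in seq_len(nrow(hit2)))
    expect_identical(genome_subseq(g2, hit2$chrom[i], hit2$pos[i],
                                   hit2$pos[i] + 7L), "ACGTACGT")
  expect_error(build_index(genome(c(c1 = "ACGT")), 8L), "shortest")
  expect_error(build_index(g, 4L), "8")
})

test_that("end-to-end alignment recovers exact and mismatched reads", {
  g <- random_genome(c(chr1 = 5000L, chr2 = 3000L), seed = 60)
  idx <- build_index(g, 16L)
  read <- genome_subseq(g, "chr1", 1001L, 1050L)
  aln <- align_reads(idx, read_set("r1", read, strrep("I", 50)))
  expect_identical(aln$chrom, "chr1")
  expect_identical(aln$pos, 1001L)
  expect_identical(aln$cigar, "50M")
  expect_identical(bitwAnd(aln$flag, 16L), 0L)

  # reverse-complemented read maps to the same locus, reverse flag set
  aln_rc <- align_reads(idx, read_set("r1", revcomp(read), strrep("I", 50)))
  expect_identical(aln_rc$pos, 1001L)
  expect_identical(bitwAnd(aln_rc$flag, 16L), 16L)

  # up to three mismatches are tolerated, four are not (75 nt leaves a
  # clean seed window wherever the three mismatches fall)
  read75 <- genome_subseq(g, "chr1", 2001L, 2075L)
  mut <- read75
  for (o in c(5L, 20L, 35L))
    substr(mut, o, o) <- chartr("ACGT", "TGCA", substr(mut, o, o))
  a3 <- align_reads(idx, read_set("m3", mut, strrep("I", 75)))
  expect_identical(a3$pos, 2001L)
  expect_identical(a3$nmm, 3L)
  substr(mut, 45L, 45L) <- chartr("ACGT", "TGCA", substr(mut, 45L, 45L))
  a4 <- align_reads(idx, read_set("m4", mut, strrep("I", 75)))
  expect_identical(bitwAnd(a4$flag, 4L), 4L)

  # a random 50-mer absent from the genome is unmapped
  set.seed(61)
  rnd <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  a_rnd <- align_reads(idx, read_set("rnd", rnd, strrep("I", 50)))
  expect_identical(bitwAnd(a_rnd$flag, 4L), 4L)

  # too-short reads are unmapped, not an error
  a_short <- align_reads(idx, read_set("s", "ACGTACGTAC", strrep("I", 10)))
  expect_identical(bitwAnd(a_short$flag, 4L), 4L)
})

test_that("aligner agrees with a brute-force search on error-free reads", {
  g <- random_genome(c(u = 40000L, v = 20000L), seed = 62)
  idx <- build_index(g, 16L)
  set.seed(63)
  lens <- chrom_lengths(g)
  reads <- character(60)
  truth <- vector("list", 60)
  for (i in 1:60) {
    cn <- sample(names(lens), 1L)
    p <- sample(lens[[cn]] - 74L, 1L)
    r <- genome_subseq(g, cn, p, p + 74L)
    if (i %% 2L == 0L) r <- revcomp(r)
    reads[i] <- r
    truth[[i]] <- oracle_exact_hits(g, r)
  }
  aln <- align_reads(idx, read_set(paste0("r", 1:60), reads, strrep("I", 75)))
  for (i in 1:60) {
    tr <- truth[[i]]
    expect_identical(aln$nmm[i], 0L)
    expect_true(any(tr$chrom == aln$chrom[i] & tr$pos == aln$pos[i]))
    # the reported best is the deterministic first of the oracle's hits
    expect_identical(aln$chrom[i], tr$chrom[1L])
    expect_identical(aln$pos[i], tr$pos[1L])
  }
})

test_that("local mode soft-clips chimeric reads at the junction", {
  g <- random_genome(c(chr1 = 8000L), seed = 64)
  idx <- build_index(g, 16L)
  genomic <- genome_subseq(g, "chr1", 2001L, 2025L)
  # a foreign tail differing from the genomic continuation at every base,
  # so local extension cannot creep past the junction
  foreign <- chartr("ACGT", "CATG",
                    genome_subseq(g, "chr1", 2026L, 2050L))
  chim <- paste0(genomic, foreign)
  aln <- align_reads(idx, read_set("c", chim, strrep("I", 50)),
                     mode = "local")
  expect_identical(aln$cigar, "25M25S")
  expect_identical(aln$pos, 2001L)
  # flipped order clips on the left (foreign differs base-by-base from
  # the leftward genomic continuation)
  foreign_l <- chartr("ACGT", "CATG",
                      genome_subseq(g, "chr1", 1976L, 2000L))
  aln2 <- align_reads(idx, read_set("c2", paste0(foreign_l, genomic),
                                    strrep("I", 50)), mode = "local")
  expect_identical(aln2$cigar, "25S25M")
  # a matched block below min_block is rejected
  aln3 <- align_reads(idx, read_set("c3", paste0(substr(genomic, 1, 18),
                                                 foreign),
                                    strrep("I", 43)), mode = "local",
                      min_block = 20L)
  expect_identical(bitwAnd(aln3$flag, 4L), 4L)
})

test_that("multi-mapping reads beyond max_hits are reported unmapped", {
  set.seed(655)
  seg <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  g <- genome(c(c1 = paste0(strrep("T", 30), paste(rep(seg, 6),
                                                   collapse = strrep("A", 40)))))
  idx <- build_index(g, 16L)
  rd <- substr(seg, 1L, 50L)
  a <- align_reads(idx, read_set("r", rd, strrep("I", 50)), max_hits = 4L)
  expect_identical(bitwAnd(a$flag, 4L), 4L)
  expect_gte(a$nhits, 5L)
  a2 <- align_reads(idx, read_set("r", rd, strrep("I", 50)), max_hits = 8L)
  expect_identical(bitwAnd(a2$flag, 4L), 0L)
  expect_lt(a2$mapq, 20L)  # ambiguous placements never look confident
})

test_that("paired alignment flags proper pairs by geometry", {
  g <- random_genome(c(chr1 = 10000L), seed = 66)
  idx <- build_index(g, 16L)
  frag <- genome_subseq(g, "chr1", 3001L, 3300L)
  r1 <- substr(frag, 1L, 75L)
  r2 <- revcomp(substring(frag, 300L - 74L))
  aln <- align_reads(idx, list(read_set("p", r1, strrep("I", 75)),
                               read_set("p", r2, strrep("I", 75))),
                     paired = TRUE, insert_mean = 300, insert_sd = 50)
  expect_identical(bitwAnd(aln$flag, 2L), c(2L, 2L))
  expect_identical(aln$tlen, c(300L, -300L))
  # a distant mate is not a proper pair
  far <- genome_subseq(g, "chr1", 8001L, 8075L)
  aln2 <- align_reads(idx, list(read_set("q", r1, strrep("I", 75)),
                                read_set("q", revcomp(far), strrep("I", 75))),
                      paired = TRUE, insert_mean = 300, insert_sd = 50)
  expect_identical(bitwAnd(aln2$flag, 2L), c(0L, 0L))
})

test_that("pileups count per-strand evidence and ignore soft clips", {
  g <- random_genome(c(chr1 = 2000L), seed = 67)
  idx <- build_index(g, 16L)
  base <- genome_subseq(g, "chr1", 501L, 550L)
  # two agreeing reads, one per strand
  rs <- read_set(c("a", "b"), c(base, revcomp(base)), strrep("I", 50))
  pile <- pileup_from_alignments(align_reads(idx, rs), g)
  cnt <- pileup_counts(pile, g, "chr1", 520L)
  ref <- genome_subseq(g, "chr1", 520L, 520L)
  expect_identical(unname(cnt["fwd", ref]), 1L)
  expect_identical(unname(cnt["rev", ref]), 1L)
  expect_identical(sum(cnt), 2L)

  # one read carrying a SNV at offset 10
  mut <- base
  alt <- setdiff(c("A", "C", "G", "T"), substr(base, 11L, 11L))[1L]
  substr(mut, 11L, 11L) <- alt
  pile2 <- pileup_from_alignments(align_reads(idx,
                                              read_set("m", mut,
                                                       strrep("I", 50))), g)
  expect_identical(pile2$alt$pos, 511L)
  expect_identical(pile2$alt$base, alt)

  # soft-clipped tails contribute nothing
  set.seed(68)
  foreign <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  chim <- paste0(base, foreign)
  pile3 <- pileup_from_alignments(align_reads(idx,
                                              read_set("c", chim,
                                                       strrep("I", 75)),
                                              mode = "local"), g)
  expect_identical(sum(pile3$cov_fwd$chr1), 50L)  # only the matched block
  expect_identical(pile3$cov_fwd$chr1[551L], 0L)

  # SAM-sourced alignments (no cached mismatches) give the same pileup
  f <- tmpfile(".sam")
  sam_write(align_reads(idx, read_set("m", mut, strrep("I", 50))), g, f)
  pile4 <- pileup_from_alignments(sam_read(f), g)
  expect_identical(pile4$alt[c("chrom", "pos", "base", "nf", "nr")],
                   pile2$alt[c("chrom", "pos", "base", "nf", "nr")])
})

test_that("variant calling applies the preset thresholds exactly", {
  g <- random_genome(c(chr1 = 300L), seed = 69)
  ref <- genome_subseq(g, "chr1", 100L, 100L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  mk_pile <- function(nf, nr, depth_f, depth_r) {
    lens <- chrom_lengths(g)
    cf <- integer(lens[[1]]); cf[100L] <- depth_f
    cr <- integer(lens[[1]]); cr[100L] <- depth_r
    structure(list(chroms = "chr1", lengths = lens,
                   cov_fwd = list(chr1 = cf), cov_rev = list(chr1 = cr),
                   alt = data.frame(chrom = "chr1", pos = 100L, base = alt,
                                    nf = nf, nr = nr,
                                    stringsAsFactors = FALSE)),
              class = "pileup")
  }
  # 10/10 alt, no ref: af 1, reported by both presets
  for (lvl in c("low", "high")) {
    v <- call_variants(mk_pile(10L, 10L, 10L, 10L), g,
                       stringency_preset(lvl))
    expect_identical(nrow(v), 1L)
    expect_equal(v$af, 1)
  }
  # monomorphic pileup: nothing reported
  empty <- mk_pile(0L, 0L, 15L, 15L)
  empty$alt <- empty$alt[0L, ]
  expect_identical(nrow(call_variants(empty, g)), 0L)
  # 2 alt of 30: below the low preset's 0.15 alt fraction
  expect_identical(nrow(call_variants(mk_pile(1L, 1L, 15L, 15L), g,
                                      stringency_preset("low"))), 0L)
  # single-strand alt support fails only the high preset
  one_strand <- mk_pile(6L, 0L, 10L, 10L)
  expect_identical(nrow(call_variants(one_strand, g,
                                      stringency_preset("low"))), 1L)
  expect_identical(nrow(call_variants(one_strand, g,
                                      stringency_preset("high"))), 0L)
  # depth below min_dp is suppressed
  expect_identical(nrow(call_variants(mk_pile(2L, 1L, 2L, 1L), g,
                                      stringency_preset("low"))), 0L)
  expect_identical(nrow(call_variants(mk_pile(2L, 1L, 2L, 1L), g,
                          list(level = "low", min_dp = 2L,
                               min_alt_reads = 2L, min_alt_frac = 0.15,
                               min_mapq = 0L,
                               require_both_strands = FALSE))), 1L)
})

test_that("high-stringency thresholds dominate the low preset", {
  lo <- stringency_preset("low"); hi <- stringency_preset("high")
  expect_gte(hi$min_dp, lo$min_dp)
  expect_gte(hi$min_alt_reads, lo$min_alt_reads)
  expect_gte(hi$min_alt_frac, lo$min_alt_frac)
  expect_gte(hi$min_mapq, lo$min_mapq)
})

test_that("planted homozygous SNVs are recovered perfectly at depth", {
  g <- random_genome(c(chr1 = 20000L), seed = 70)
  idx <- build_index(g, 16L)
  muts <- simulate_ems_mutations(g, 8, seed = 71)
  hp <- haplotype_pool(muts, matrix(TRUE, 1L, nrow(muts)))
  reads <- simulate_reads(g, read_sim_spec(depth = 30, read_length = 75,
                                           insert_mean = 250,
                                           insert_sd = 30),
                          pool = hp, seed = 72)
  aln <- align_reads(idx, reads, paired = TRUE)
  pile <- pileup_from_alignments(aln, g)
  for (lvl in c("low", "high")) {
    v <- call_variants(pile, g, stringency_preset(lvl))
    expect_identical(nrow(v), 8L)
    expect_identical(v$pos, muts$pos)
    expect_identical(v$alt, muts$alt)
    expect_true(all(v$af == 1))
  }
})

test_that("the fused fragment caller matches the modular route", {
  g <- random_genome(c(chr1 = 30000L), seed = 73)
  idx <- build_index(g, 16L)
  muts <- simulate_ems_mutations(g, 10, seed = 74)
  hp <- haplotype_pool(muts, matrix(c(TRUE, FALSE), 2L, nrow(muts)))
  lens <- chrom_lengths(g)
  set.seed(75)
  frag <- mapbyseq:::sample_fragments(lens, read_sim_spec(depth = 30,
                                                          read_length = 75))
  hap <- sample.int(2L, nrow(frag), replace = TRUE)
  edits <- mapbyseq:::pool_edit_list(hp, hap, frag$chrom, frag$start,
                                     frag$len, lens)
  # modular: materialise reads, align, pile, call
  r1 <- mapbyseq:::cpp_extract_reads(unname(unclass(g)), frag$chrom,
                                     frag$start, rep(75L, nrow(frag)),
                                     rep(FALSE, nrow(frag)))
  r2 <- mapbyseq:::cpp_extract_reads(unname(unclass(g)), frag$chrom,
                                     frag$start + frag$len - 75L,
                                     rep(75L, nrow(frag)),
                                     rep(TRUE, nrow(frag)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  off1 <- edits$pos - frag$start[edits$frag] + 1L
  off2 <- frag$start[edits$frag] + frag$len[edits$frag] - 1L - edits$pos + 1L
  in1 <- off1 <= 75L; in2 <- off2 <= 75L
  r1 <- mapbyseq:::apply_edits(r1, edits$frag[in1], off1[in1],
                               edits$base[in1])
  r2 <- mapbyseq:::apply_edits(r2, edits$frag[in2], off2[in2],
                               comp[edits$base[in2]])
  qual <- strrep("D", 75)
  aln <- align_reads(idx, list(read_set(seq_len(nrow(frag)), r1, qual),
                               read_set(seq_len(nrow(frag)), r2, qual)),
                     paired = TRUE)
  v_mod <- call_variants(pileup_from_alignments(aln, g), g)
  fused <- call_from_fragments(idx, g, frag, edits)
  v_fus <- fused$variants
  for (col in c("chrom", "pos", "ref", "alt", "dp", "adf_ref", "adr_ref",
                "adf_alt", "adr_alt", "af"))
    expect_identical(v_fus[[col]], v_mod[[col]])
  # coverage reductions agree as well
  expect_identical(fused$pileup$cov_fwd$chr1,
                   pileup_from_alignments(aln, g)$cov_fwd$chr1)
})
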