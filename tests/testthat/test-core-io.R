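test_that("FASTA parsing preserves order, uppercases and concatenates", {
  f <- write_lines_tmp(c(">chr1", "ACGT"), ".fa")
  g <- read_fasta(f)
  expect_s3_class(g, "genome")
  expect_identical(unclass(g)[["chr1"]], "ACGT")
  expect_identical(unname(chrom_lengths(g)), 4L)

  f2 <- write_lines_tmp(c(">c1", "ac", "gt", ">c2", "NN"), ".fa")
  g2 <- read_fasta(f2)
  expect_identical(names(g2), c("c1", "c2"))
  expect_identical(unname(chrom_lengths(g2)), c(4L, 2L))
  expect_identical(genome_size(g2), 6L)
  expect_identical(unclass(g2)[["c1"]], "ACGT")
})

test_that("FASTA rejects malformed input with a named cause", {
  expect_error(read_fasta(write_lines_tmp(character(0), ".fa")), "empty")
  expect_error(read_fasta(write_lines_tmp(c("ACGT"), ".fa")), "FASTA")
  expect_error(genome(c(c1 = "", c2 = "AA")), "empty sequence for c1")
  expect_error(genome(c(c1 = "AA", c1 = "TT")), "duplicate")
  expect_error(genome(c(c1 = "AXGT")), "illegal character")
})

test_that("genome write-then-read is the identity", {
  g <- random_genome(c(alpha = 211L, beta = 97L), seed = 7)
  f <- tmpfile(".fa")
  write_fasta(g, f)
  g2 <- read_fasta(f)
  expect_identical(names(g2), names(g))
  expect_identical(unclass(g2), unclass(g))
})

test_that("gene models load from GFF3 with Parent linkage and CDS frame check", {
  models <- read_gene_models(fixture_gff())
  expect_length(models, 2L)
  m1 <- models[[1L]]
  expect_identical(m1$gene_id, "g1")
  expect_identical(m1$exons[, "start"], c(101L, 281L))
  cds_len <- sum(m1$cds[, "end"] - m1$cds[, "start"] + 1L)
  expect_identical(cds_len, 220L)          # 120 + 100
  expect_false(m1$frame_ok)                # 220 not divisible by 3
  m2 <- models[[2L]]
  expect_identical(m2$strand, "-")
  expect_identical(unname(m2$exons), cbind(11L, 70L), ignore_attr = TRUE)
})

test_that("gene models beyond the chromosome end are rejected", {
  g <- random_genome(c(chr1 = 5000L), seed = 1)
  expect_silent(read_gene_models(fixture_gff(), genome = g))
  bad <- write_lines_tmp(c(
    "##gff-version 3",
    paste("chr1", "t", "mRNA", 9000, 9999, ".", "+", ".", "ID=m1", sep = "\t"),
    paste("chr1", "t", "CDS", 9000, 9999, ".", "+", "0",
          "ID=c;Parent=m1", sep = "\t")), ".gff3")
  expect_error(read_gene_models(bad, genome = g), "beyond")
})

test_that("FASTQ encoding detection follows the code-range rules", {
  rs33 <- read_set("r1", "ACGT", "#III")          # '#' = 35
  expect_identical(detect_fastq_encoding(rs33), "phred33")
  rs64 <- read_set("r1", "ACGT", "efgh")          # 101..104
  expect_identical(detect_fastq_encoding(rs64), "phred64")
  rsamb <- read_set("r1", "ACGT", "@ABI")         # 64..73
  expect_identical(detect_fastq_encoding(rsamb), "ambiguous")
  expect_error(detect_fastq_encoding(read_set("r", "A", " ")), "range")
})

test_that("encoding detector never reports phred64 when a code is below 64", {
  set.seed(99)
  for (i in 1:25) {
    codes <- sample(33:104, 30, replace = TRUE)
    q <- intToUtf8(codes)
    r <- read_set("x", strrep("A", nchar(q)), q)
    enc <- detect_fastq_encoding(r)
    if (any(codes < 64)) expect_false(enc == "phred64")
    if (any(codes < 59)) expect_identical(enc, "phred33")
  }
})

test_that("read-quality summary is deterministic and complete", {
  rs <- read_set(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"),
                 strrep("?", 10))                 # '?' = Q30
  s <- assess_read_quality(rs)
  expect_identical(s$n_reads, 2L)
  expect_true(all(s$mean_q_per_cycle == 30))

  rs_n <- read_set("c", paste0("NACGTACGTA"), strrep("I", 10))
  expect_equal(assess_read_quality(rs_n)$pct_n, 10)

  rs_mix <- read_set(c("a", "b"), c(strrep("A", 50), strrep("A", 75)),
                     c(strrep("I", 50), strrep("I", 75)))
  expect_identical(as.integer(assess_read_quality(rs_mix)$length_dist),
                   c(1L, 1L))

  expect_warning(assess_read_quality(read_set("l", "ACGT", "####")), "quality")
  expect_warning(s0 <- assess_read_quality(read_set(character(0),
                                                    character(0),
                                                    character(0))), "empty")
  expect_identical(s0$n_reads, 0L)
})

test_that("FASTQ write-then-read round-trips reads and qualities", {
  rs <- read_set(c("r1", "r2"), c("ACGTN", "TTTTT"), c("IIIII", "#####"))
  f <- tmpfile(".fastq")
  write_fastq(rs, f)
  back <- read_fastq(f)
  expect_identical(back$seq, rs$seq)
  expect_identical(back$qual, rs$qual)
})

test_that("read-depth distribution matches naive per-position counting", {
  g <- random_genome(c(chr1 = 100L), seed = 3)
  one <- alignments("r1", 0L, "chr1", 10L, 42L, "50M",
                    seq = strrep("A", 50), qual = strrep("I", 50))
  rd <- compute_rd_distribution(one, g)
  expect_equal(rd$mean_depth, 0.5)
  expect_identical(unname(rd$histogram[c("0", "1")]), c(50L, 50L))

  two <- alignments(c("r1", "r2"), c(0L, 0L), "chr1", c(10L, 10L), 42L, "50M",
                    seq = strrep("A", 50), qual = strrep("I", 50))
  rd2 <- compute_rd_distribution(two, g)
  expect_identical(unname(rd2$histogram[c("0", "2")]), c(50L, 50L))
  expect_false("1" %in% names(rd2$histogram)[rd2$histogram > 0])

  # 10 reads tiling a 1 kb genome at exactly 1x
  g3 <- random_genome(c(chr1 = 1000L), seed = 4)
  tiles <- alignments(paste0("t", 1:10), 0L, "chr1",
                      seq(1L, 901L, by = 100L), 42L, "100M",
                      seq = strrep("A", 100), qual = strrep("I", 100))
  rd3 <- compute_rd_distribution(tiles, g3)
  expect_identical(rd3$median_depth,
                   median(oracle_depth(seq(1L, 901L, 100L),
                                       seq(100L, 1000L, 100L), 1000L)))
  expect_equal(rd3$median_depth, 1L)
  # histogram always sums to genome size
  expect_equal(sum(rd$histogram), 100L, ignore_attr = TRUE)
  expect_equal(sum(rd2$histogram), 100L, ignore_attr = TRUE)
  expect_equal(sum(rd3$histogram), 1000L, ignore_attr = TRUE)
})

test_that("alignments beyond the chromosome end are rejected", {
  g <- random_genome(c(chr1 = 100L), seed = 3)
  off <- alignments("r", 0L, "chr1", 60L, 42L, "50M",
                    seq = strrep("A", 50), qual = strrep("I", 50))
  expect_error(compute_rd_distribution(off, g), "beyond")
})

test_that("VCF round-trip preserves sites and depths; AF is recomputed", {
  v <- variant_table(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(200L, 300L, 5L),
                     ref = c("G", "C", "A"), alt = c("A", "T", "G"),
                     adf_ref = c(0L, 3L, 5L), adr_ref = c(0L, 2L, 5L),
                     adf_alt = c(10L, 7L, 10L), adr_alt = c(10L, 8L, 10L))
  expect_equal(v$af, c(1, 0.75, 2 / 3))
  f <- tmpfile(".vcf")
  vcf_write(v, f)
  back <- vcf_read(f)
  for (col in c("chrom", "pos", "ref", "alt", "dp", "adf_ref", "adr_ref",
                "adf_alt", "adr_alt"))
    expect_identical(back[[col]], v[[col]])
  expect_equal(back$af, v$af)
  # file-level round trip is byte-identical
  f2 <- tmpfile(".vcf")
  vcf_write(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("multi-allelic VCF records split and identical alleles reject", {
  f <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"f\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"r\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S", sep = "\t"),
    paste("chr1", "100", ".", "G", "A,T", ".", "PASS", ".",
          "DP:ADF:ADR", "30:5,6,4:5,6,4", sep = "\t"),
    paste("chr1", "200", ".", "GA", "G", ".", "PASS", ".",
          "DP:ADF:ADR", "20:5,5:5,5", sep = "\t")), ".vcf")
  v <- vcf_read(f)
  expect_identical(nrow(v), 3L)
  expect_identical(v$alt[1:2], c("A", "T"))
  expect_identical(v$adf_alt[1:2], c(6L, 4L))
  expect_false(v$is_snv[3L])               # indel flagged non-SNV
  expect_error(variant_table("chr1", 1L, "A", "A", 0L, 0L, 1L, 1L), "identical")
})

test_that("SAM round-trip preserves mandatory fields and validates CIGAR", {
  g <- random_genome(c(chr1 = 500L), seed = 5)
  aln <- alignments(qname = c("a", "b", "c"),
                    flag = c(99L, 147L, 4L),
                    chrom = c("chr1", "chr1", "*"),
                    pos = c(10L, 200L, 0L),
                    mapq = c(42L, 42L, 0L),
                    cigar = c("50M", "25S25M", "*"),
                    rnext = c("chr1", "chr1", "*"),
                    pnext = c(200L, 10L, 0L),
                    tlen = c(240L, -240L, 0L),
                    seq = c(strrep("A", 50), strrep("C", 50), strrep("G", 50)),
                    qual = strrep("I", 50))
  f <- tmpfile(".sam")
  sam_write(aln, g, f)
  back <- sam_read(f)
  for (col in names(aln)) expect_identical(back[[col]], aln[[col]])
  expect_identical(attr(back, "sq_lengths"), 500L)

  # CIGAR query length must match the sequence
  bad <- aln
  bad$cigar[1L] <- "25M25S"
  bad$seq[1L] <- strrep("A", 49)
  f2 <- tmpfile(".sam")
  sam_write(bad, g, f2)
  expect_error(sam_read(f2), "CIGAR")

  # unmapped records never enter pileups
  pile <- pileup_from_alignments(back[3L, ], g)
  expect_identical(sum(pile$cov_fwd$chr1) + sum(pile$cov_rev$chr1), 0L)
})
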