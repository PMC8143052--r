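# Fixture builders used across test files; all content is generated in
# code so nothing binary ships with the package.

tmpfile <- function(ext) tempfile(fileext = ext)

write_lines_tmp <- function(lines, ext) {
  f <- tmpfile(ext)
  writeLines(lines, f)
  f
}

# a deterministic little genome with a known coding gene on each strand
fixture_gene_genome <- function() {
  set.seed(404)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  # plus-strand gene: ATG AAA TGG CCC TAA (15 nt CDS) at 101..115,
  # exon 91..130
  cds_plus <- "ATGAAATGGCCCTAA"
  # minus-strand gene: CDS on minus strand ATG GCA TGC TAA ->
  # genomic plus-strand revcomp at 201..212
  cds_minus_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGGCATGCTAA")))
  chr <- paste0(pad(90),                      # 1..90
                pad(10),                      # exon 91..100 (5' UTR)
                cds_plus,                     # 101..115
                pad(15),                      # 116..130 (3' UTR in exon)
                pad(70),                      # 131..200 intergenic
                cds_minus_rc,                 # 201..212 minus-strand CDS
                pad(88))                      # 213..300
  genome(c(chrA = chr))
}

fixture_gene_models <- function() {
  plus <- structure(list(
    gene_id = "geneP", mrna_id = "geneP.1", chrom = "chrA", strand = "+",
    exons = cbind(start = 91L, end = 130L),
    cds = cbind(start = 101L, end = 115L),
    annotation = "", frame_ok = TRUE), class = "gene_model")
  minus <- structure(list(
    gene_id = "geneM", mrna_id = "geneM.1", chrom = "chrA", strand = "-",
    exons = cbind(start = 195L, end = 218L),
    cds = cbind(start = 201L, end = 212L),
    annotation = "", frame_ok = TRUE), class = "gene_model")
  list(plus, minus)
}

# a GFF3 file matching a two-exon plus-strand gene
fixture_gff <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    "##sequence-region chr1 1 5000",
    paste("chr1", "test", "gene", 101, 400, ".", "+", ".", "ID=g1", sep = "\t"),
    paste("chr1", "test", "mRNA", 101, 400, ".", "+", ".",
          "ID=g1.1;Parent=g1", sep = "\t"),
    paste("chr1", "test", "exon", 101, 250, ".", "+", ".",
          "ID=e1;Parent=g1.1", sep = "\t"),
    paste("chr1", "test", "exon", 281, 400, ".", "+", ".",
          "ID=e2;Parent=g1.1", sep = "\t"),
    paste("chr1", "test", "CDS", 101, 220, ".", "+", "0",
          "ID=c1;Parent=g1.1", sep = "\t"),
    paste("chr1", "test", "CDS", 301, 400, ".", "+", "0",
          "ID=c2;Parent=g1.1", sep = "\t"),
    paste("chr1", "test", "gene", 11, 70, ".", "-", ".", "ID=g2", sep = "\t"),
    paste("chr1", "test", "mRNA", 11, 70, ".", "-", ".",
          "ID=g2.1;Parent=g2", sep = "\t"),
    paste("chr1", "test", "exon", 11, 70, ".", "-", ".",
          "ID=e3;Parent=g2.1", sep = "\t")), ".gff3")
}

# small variant table builder
vt <- function(chrom, pos, ref, alt, af = 1, dp = 20L, sample = "test") {
  n <- length(pos)
  alt_n <- as.integer(round(dp * af))
  ref_n <- dp - alt_n
  variant_table(chrom = rep_len(chrom, n), pos = pos,
                ref = rep_len(ref, n), alt = rep_len(alt, n),
                adf_ref = ref_n %/% 2L, adr_ref = ref_n - ref_n %/% 2L,
                adf_alt = alt_n %/% 2L, adr_alt = alt_n - alt_n %/% 2L,
                sample = sample)
}

# window profile builder for peak/smoothing tests
profile_fixture <- function(vals, chrom = "chr1", window_size = 10L,
                            step = 5L, orientation = "maximize_af") {
  n <- length(vals)
  out <- data.frame(chrom = chrom,
                    start = as.integer(seq(1L, by = step, length.out = n)),
                    end = as.integer(seq(1L, by = step, length.out = n) +
                                       window_size - 1L),
                    n_markers = ifelse(is.na(vals), 0L, 10L),
                    mean_af = vals, smoothed_af = NA_real_,
                    empty = is.na(vals))
  attr(out, "orientation") <- orientation
  class(out) <- c("window_profile", "data.frame")
  out
}
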