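#' Construct a variant table
#'
#' The package-wide container for called variants: one row per biallelic
#' record with per-strand allele depths (`adf_*` forward, `adr_*` reverse)
#' and the derived alternative-allele frequency
#' `af = alt / (ref + alt)`. `dp` may exceed the sum of the stored allele
#' depths when low-quality or N bases were discounted.
#'
#' @param chrom,pos,ref,alt Site and alleles (1-based positions).
#' @param adf_ref,adr_ref,adf_alt,adr_alt Per-strand allele depths.
#' @param dp Total depth; defaults to the sum of the allele depths.
#' @param sample `"test"` or `"control"`.
#' @return A data.frame of class `variant_table`.
#' @export
variant_table <- function(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          adf_ref = integer(0), adr_ref = integer(0),
                          adf_alt = integer(0), adr_alt = integer(0),
                          dp = NULL, sample = "test") {
  if (any(ref == alt)) stop("ref and alt allele identical at ",
                            paste0(chrom[ref == alt][1L], ":", pos[ref == alt][1L]))
  if (is.null(dp)) dp <- adf_ref + adr_ref + adf_alt + adr_alt
  if (any(dp + 1e-9 < adf_ref + adr_ref + adf_alt + adr_alt))
    stop("dp smaller than the sum of allele depths")
  alt_n <- adf_alt + adr_alt
  ref_n <- adf_ref + adr_ref
  af <- ifelse(alt_n + ref_n > 0, alt_n / (alt_n + ref_n), NA_real_)
  structure(data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                       ref = as.character(ref), alt = as.character(alt),
                       dp = as.integer(dp),
                       adf_ref = as.integer(adf_ref), adr_ref = as.integer(adr_ref),
                       adf_alt = as.integer(adf_alt), adr_alt = as.integer(adr_alt),
                       af = af,
                       is_snv = nchar(ref) == 1L & nchar(alt) == 1L,
                       sample = rep_len(as.character(sample), length(chrom)),
                       stringsAsFactors = FALSE),
            class = c("variant_table", "data.frame"))
}

#' Write variants to VCF
#'
#' Emits a VCFv4.2 file with one sample column carrying `DP`, `ADF` and
#' `ADR` FORMAT fields (allele depths split by strand, reference allele
#' first).
#'
#' @param variants A `variant_table`.
#' @param path Output path.
#' @param sample_name Name for the single sample column.
#' @return `path`, invisibly.
#' @export
vcf_write <- function(variants, path, sample_name = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Allele depths, forward strand\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Allele depths, reverse strand\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- if (nrow(variants)) {
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          ".", "PASS", paste0("DP=", variants$dp), "DP:ADF:ADR",
          paste0(variants$dp, ":",
                 variants$adf_ref, ",", variants$adf_alt, ":",
                 variants$adr_ref, ",", variants$adr_alt),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variants from VCF
#'
#' Reads a VCFv4.2 file whose FORMAT carries `DP`, `ADF` and `ADR`.
#' Multi-allelic records are split into biallelic records; indels are kept
#' but flagged `is_snv = FALSE`. Allele frequencies are recomputed from
#' the stored depths, never trusted from the file.
#'
#' @param path Path to an uncompressed VCF file.
#' @param sample Label stored in the `sample` column (`"test"` or
#'   `"control"`).
#' @return A `variant_table`.
#' @export
vcf_read <- function(path, sample = "test") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (nrow(fix) == 0L)
    return(variant_table(sample = sample))
  fmt <- strsplit(gt[, 1L], ":", fixed = TRUE)
  val <- strsplit(gt[, 2L], ":", fixed = TRUE)
  pick <- function(i, key) {
    j <- match(key, fmt[[i]])
    if (is.na(j)) stop("FORMAT field ", key, " missing in ", path)
    val[[i]][j]
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    dp <- as.integer(pick(i, "DP"))
    adf <- as.integer(strsplit(pick(i, "ADF"), ",", fixed = TRUE)[[1L]])
    adr <- as.integer(strsplit(pick(i, "ADR"), ",", fixed = TRUE)[[1L]])
    if (length(adf) != length(alts) + 1L || length(adr) != length(alts) + 1L)
      stop("ADF/ADR arity does not match allele count at ",
           fix[i, "CHROM"], ":", fix[i, "POS"])
    if (any(alts == ref)) stop("ALT equals REF at ", fix[i, "CHROM"], ":",
                               fix[i, "POS"])
    out[[i]] <- data.frame(chrom = fix[i, "CHROM"],
                           pos = as.integer(fix[i, "POS"]),
                           ref = ref, alt = alts, dp = dp,
                           adf_ref = adf[1L], adr_ref = adr[1L],
                           adf_alt = adf[-1L], adr_alt = adr[-1L],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  variant_table(d$chrom, d$pos, d$ref, d$alt, d$adf_ref, d$adr_ref,
                d$adf_alt, d$adr_alt, dp = d$dp, sample = sample)
}
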