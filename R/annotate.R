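#' Predict the functional effect of a point mutation
#'
#' Resolves the variant against the gene models on its chromosome:
#' `intergenic` (no model within `upstream_dist`), `upstream` (within
#' `upstream_dist` bp 5' of a model), `UTR` (exonic, outside the CDS),
#' `intron`, `splice_site` (first or last two intronic bases), or `CDS`.
#' For CDS variants the affected codon is recomputed on the coding
#' strand (minus-strand models complement the alleles) and the severity
#' is derived from the standard genetic code: `synonymous`, `missense`,
#' `nonsense` (stop gained), or `start_loss` (initiator ATG destroyed).
#'
#' @param variant One-row data.frame or list with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param gene_models List of `gene_model`s (see [read_gene_models()]).
#' @param genome The reference `genome`.
#' @param upstream_dist Upstream promoter window in bp.
#' @return A list of class `effect_annotation`: `region`, `gene_id`,
#'   `mrna_id`, `coding_change` (codon/aa from/to and aa position; CDS
#'   only), `severity`.
#' @export
predict_effect <- function(variant, gene_models, genome,
                           upstream_dist = 2000L) {
  chrom <- variant$chrom; pos <- as.integer(variant$pos)
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  gref <- genome_subseq(genome, chrom, pos, pos)
  if (gref != ref)
    stop("reference allele mismatch at ", chrom, ":", pos, " (genome has ",
         gref, ", variant says ", ref, ")")
  ann <- function(region, model = NULL, coding = NULL, severity = "none") {
    structure(list(region = region,
                   gene_id = if (is.null(model)) NA_character_ else model$gene_id,
                   mrna_id = if (is.null(model)) NA_character_ else model$mrna_id,
                   coding_change = coding, severity = severity),
              class = "effect_annotation")
  }
  on_chrom <- Filter(function(m) m$chrom == chrom, gene_models)
  # containing model first, then upstream proximity
  for (m in on_chrom) {
    span <- c(min(m$exons[, "start"]), max(m$exons[, "end"]))
    if (pos < span[1L] || pos > span[2L]) next
    in_cds <- !is.null(m$cds) &&
      any(pos >= m$cds[, "start"] & pos <= m$cds[, "end"])
    if (in_cds) return(cds_effect(m, genome, pos, ref, alt))
    in_exon <- any(pos >= m$exons[, "start"] & pos <= m$exons[, "end"])
    if (in_exon) return(ann("UTR", m))
    # intronic: splice site = first/last 2 intronic bases
    dist_to_exon <- min(abs(pos - m$exons[, "end"]),
                        abs(m$exons[, "start"] - pos))
    if (dist_to_exon <= 2L) return(ann("splice_site", m, severity = "splice"))
    return(ann("intron", m))
  }
  for (m in on_chrom) {
    span <- c(min(m$exons[, "start"]), max(m$exons[, "end"]))
    up <- if (m$strand == "-") pos > span[2L] && pos <= span[2L] + upstream_dist
    else pos < span[1L] && pos >= span[1L] - upstream_dist
    if (up) return(ann("upstream", m))
  }
  ann("intergenic")
}

cds_effect <- function(model, genome, pos, ref, alt) {
  cds <- model$cds
  minus <- model$strand == "-"
  seg_len <- cds[, "end"] - cds[, "start"] + 1L
  before <- 0L
  seg <- NA_integer_
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds[i, "start"] && pos <= cds[i, "end"]) { seg <- i; break }
    before <- before + seg_len[i]
  }
  off <- if (minus) unname(cds[seg, "end"]) - pos
  else pos - unname(cds[seg, "start"])
  cds_pos <- before + off + 1L
  cds_seq <- cds_sequence(model, genome)
  codon_i <- (cds_pos - 1L) %/% 3L + 1L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon_from <- substr(cds_seq, 3L * codon_i - 2L, 3L * codon_i)
  ref_c <- if (minus) revcomp(ref) else ref
  alt_c <- if (minus) revcomp(alt) else alt
  if (substr(codon_from, within, within) != ref_c)
    stop("coding-strand allele inconsistent with CDS sequence of ",
         model$mrna_id)
  codon_to <- codon_from
  substr(codon_to, within, within) <- alt_c
  code <- Biostrings::GENETIC_CODE
  aa_from <- unname(code[[codon_from]])
  aa_to <- unname(code[[codon_to]])
  severity <- if (aa_from == aa_to) "synonymous"
  else if (aa_to == "*") "nonsense"
  else if (codon_i == 1L && codon_from == "ATG") "start_loss"
  else "missense"
  structure(list(region = "CDS", gene_id = model$gene_id,
                 mrna_id = model$mrna_id,
                 coding_change = list(codon_from = codon_from,
                                      codon_to = codon_to,
                                      aa_from = aa_from, aa_to = aa_to,
                                      aa_pos = codon_i),
                 severity = severity),
            class = "effect_annotation")
}

#' @export
print.effect_annotation <- function(x, ...) {
  cat("effect:", x$region,
      if (!is.na(x$gene_id)) paste0("(", x$mrna_id, ")") else "",
      "-", x$severity, "\n")
  if (!is.null(x$coding_change))
    cat(sprintf("  %s>%s  %s%d%s\n", x$coding_change$codon_from,
                x$coding_change$codon_to, x$coding_change$aa_from,
                x$coding_change$aa_pos, x$coding_change$aa_to))
  invisible(x)
}

#' Sequences flanking a mutation
#'
#' @param variant List/row with `chrom`, `pos`, `ref`, `alt`.
#' @param genome The reference `genome`.
#' @param flank_len Flank length in bp (truncated at chromosome ends).
#' @return List with `upstream`, `downstream`, `ref`, `alt`.
#' @export
flanking_sequences <- function(variant, genome, flank_len = 200L) {
  if (flank_len < 1L) stop("flank_len must be at least 1")
  chrom <- variant$chrom; pos <- as.integer(variant$pos)
  list(upstream = genome_subseq(genome, chrom, pos - flank_len, pos - 1L),
       downstream = genome_subseq(genome, chrom, pos + 1L, pos + flank_len),
       ref = variant$ref, alt = variant$alt)
}

#' Wallace-rule melting temperature
#' @param x Primer sequence(s).
#' @return `2 (A+T) + 4 (G+C)` in degrees C.
#' @export
wallace_tm <- function(x) {
  at <- nchar(gsub("[^AT]", "", x))
  gc <- nchar(gsub("[^GC]", "", x))
  2 * at + 4 * gc
}

gc_frac <- function(x) nchar(gsub("[^GC]", "", x)) / nchar(x)

primer_ok <- function(p, gc_range, tm_range) {
  g <- gc_frac(p)
  t <- wallace_tm(p)
  g >= gc_range[1L] && g <= gc_range[2L] &&
    t >= tm_range[1L] && t <= tm_range[2L] &&
    !grepl("([ACGT])\\1{4}", p) && !grepl("N", p, fixed = TRUE)
}

#' Design genotyping primers around a mutation
#'
#' Minimal deterministic heuristic (not a nearest-neighbour
#' thermodynamic model): scan primer windows of 18-24 nt centred about
#' `offset` bp on each side of the variant, accepting the first window
#' with GC content in 40-60%, Wallace melting temperature in 55-65 C and
#' no homopolymer of 5+, while keeping the product at most `max_product`
#' bp. The product always spans the variant; both primers are exact
#' genome substrings (the reverse primer reverse-complemented).
#'
#' @param variant List/row with `chrom`, `pos`.
#' @param genome The reference `genome`.
#' @param offset Target distance of each primer from the variant (bp).
#' @param max_product Maximum product size (bp).
#' @return On success a list of class `primer_pair` with `forward`,
#'   `reverse`, `fwd_start`, `rev_end`, `tm_forward`, `tm_reverse`,
#'   `product_size`, `success = TRUE`; otherwise `success = FALSE` with a
#'   `reason`.
#' @export
design_genotyping_primers <- function(variant, genome, offset = 250L,
                                      max_product = 800L) {
  chrom <- variant$chrom; pos <- as.integer(variant$pos)
  len <- chrom_lengths(genome)[[chrom]]
  if (pos - max_product / 2 < 1L || pos + max_product / 2 > len)
    return(structure(list(success = FALSE,
                          reason = "variant too close to a chromosome end"),
                     class = "primer_pair"))
  gc_range <- c(0.40, 0.60); tm_range <- c(55, 65)
  scan_side <- function(side) {
    center <- if (side == "left") pos - offset else pos + offset
    for (delta in as.vector(rbind(0:100, -(0:100)))[-1L]) {
      for (L in 18:24) {
        s <- center + delta - L %/% 2L
        e <- s + L - 1L
        if (s < 1L || e > len) next
        if (side == "left" && e >= pos) next
        if (side == "right" && s <= pos) next
        p <- genome_subseq(genome, chrom, s, e)
        if (primer_ok(p, gc_range, tm_range)) return(list(s = s, e = e, p = p))
      }
    }
    NULL
  }
  left <- scan_side("left")
  if (is.null(left))
    return(structure(list(success = FALSE,
                          reason = "no acceptable forward-primer window"),
                     class = "primer_pair"))
  right <- scan_side("right")
  if (is.null(right))
    return(structure(list(success = FALSE,
                          reason = "no acceptable reverse-primer window"),
                     class = "primer_pair"))
  product <- right$e - left$s + 1L
  if (product > max_product)
    return(structure(list(success = FALSE,
                          reason = "product exceeds max_product"),
                     class = "primer_pair"))
  structure(list(success = TRUE, forward = left$p, reverse = revcomp(right$p),
                 fwd_start = left$s, rev_end = right$e,
                 tm_forward = wallace_tm(left$p),
                 tm_reverse = wallace_tm(right$p),
                 product_size = product),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  if (!isTRUE(x$success)) {
    cat("primer design failed:", x$reason, "\n")
  } else {
    cat(sprintf("F %s (Tm %.0f)\nR %s (Tm %.0f)\nproduct %d bp\n", x$forward,
                x$tm_forward, x$reverse, x$tm_reverse, x$product_size))
  }
  invisible(x)
}

#' Annotate candidate mutations
#'
#' Adds effect prediction, flanking sequences and genotyping primers to
#' a candidate table.
#'
#' @param candidates Candidate data.frame (from a `linkage_map`).
#' @param gene_models List of `gene_model`s.
#' @param genome The reference `genome`.
#' @param flank_len Flank length for reported sequences.
#' @return The candidate table with columns `region`, `gene`, `severity`,
#'   `aa_change`, `primer_f`, `primer_r`, `flank_up`, `flank_down`.
#' @export
annotate_candidates <- function(candidates, gene_models, genome,
                                flank_len = 50L) {
  n <- nrow(candidates)
  region <- gene <- severity <- aa <- pf <- pr <- fu <- fd <-
    rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- candidates[i, ]
    eff <- predict_effect(v, gene_models, genome)
    region[i] <- eff$region
    gene[i] <- eff$mrna_id
    severity[i] <- eff$severity
    if (!is.null(eff$coding_change))
      aa[i] <- sprintf("%s%d%s", eff$coding_change$aa_from,
                       eff$coding_change$aa_pos, eff$coding_change$aa_to)
    fl <- flanking_sequences(v, genome, flank_len)
    fu[i] <- fl$upstream; fd[i] <- fl$downstream
    pp <- design_genotyping_primers(v, genome)
    if (isTRUE(pp$success)) { pf[i] <- pp$forward; pr[i] <- pp$reverse }
  }
  cbind(candidates,
        data.frame(region = region, gene = gene, severity = severity,
                   aa_change = aa, primer_f = pf, primer_r = pr,
                   flank_up = fu, flank_down = fd, stringsAsFactors = FALSE))
}
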