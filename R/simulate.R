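#' @importFrom stats rbinom rnorm rpois runif setNames median
NULL

with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

#' Generate a random reference genome
#'
#' Uniform i.i.d. A/C/G/T sequence; a convenient stand-in reference for
#' simulation studies (synthetic, with none of the repeat or composition
#' structure of real genomes).
#'
#' @param lengths Named integer vector of chromosome lengths in bp.
#' @param seed Optional RNG seed.
#' @return A `genome` object.
#' @export
random_genome <- function(lengths, seed = NULL) {
  with_seed_if(seed, {
    if (is.null(names(lengths)))
      names(lengths) <- paste0("chr", seq_along(lengths))
    seqs <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1L))
    genome(seqs)
  })
}

global_to_chrom <- function(idx, lens) {
  cs <- cumsum(as.numeric(lens))
  ci <- findInterval(idx, cs, left.open = TRUE) + 1L
  pos <- idx - c(0, cs)[ci]
  data.frame(chrom = names(lens)[ci], pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

base_at <- function(genome, chrom, pos) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    out[sel] <- substring(unclass(genome)[[cn]], pos[sel], pos[sel])
  }
  out
}

#' Simulate EMS mutagenesis
#'
#' Draws `n_mutations` distinct point mutations. A share `ems_fraction` of
#' them are EMS-type alkylation products: G>A on the reference strand or
#' its complement C>T. The remainder are uniform substitutions at uniform
#' sites. Positions are unique; the same seed reproduces the same list.
#'
#' @param genome A `genome` object.
#' @param n_mutations Number of mutations to plant.
#' @param ems_fraction Expected share of EMS-type (G>A / C>T) changes.
#' @param seed Optional RNG seed.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ems_type`, sorted by genome order.
#' @export
simulate_ems_mutations <- function(genome, n_mutations, ems_fraction = 1,
                                   seed = NULL) {
  with_seed_if(seed, {
    lens <- chrom_lengths(genome)
    total <- sum(lens)
    if (n_mutations > total) stop("more mutations requested than sites")
    n_ems <- rbinom(1L, n_mutations, ems_fraction)
    if (n_ems > 0L && !any(grepl("[GC]", unclass(genome))))
      stop("no G/C sites available for EMS-type mutations")
    taken <- integer(0)
    draw_sites <- function(n_needed, want_gc) {
      out <- integer(0)
      tries <- 0L
      while (length(out) < n_needed) {
        tries <- tries + 1L
        if (tries > 1000L) stop("unable to find enough eligible sites")
        cand <- sample.int(total, min(total, max(2L * n_needed, 100L)),
                           replace = FALSE)
        cand <- setdiff(cand, c(taken, out))
        if (want_gc) {
          loc <- global_to_chrom(cand, lens)
          b <- base_at(genome, loc$chrom, loc$pos)
          cand <- cand[b %in% c("G", "C")]
        } else {
          loc <- global_to_chrom(cand, lens)
          b <- base_at(genome, loc$chrom, loc$pos)
          cand <- cand[b %in% c("A", "C", "G", "T")]
        }
        out <- c(out, utils::head(cand, n_needed - length(out)))
      }
      taken <<- c(taken, out)
      out
    }
    ems_idx <- if (n_ems > 0L) draw_sites(n_ems, TRUE) else integer(0)
    oth_idx <- if (n_mutations - n_ems > 0L)
      draw_sites(n_mutations - n_ems, FALSE) else integer(0)
    loc <- global_to_chrom(c(ems_idx, oth_idx), lens)
    ref <- base_at(genome, loc$chrom, loc$pos)
    alt <- character(nrow(loc))
    is_ems <- seq_len(nrow(loc)) <= length(ems_idx)
    alt[is_ems] <- ifelse(ref[is_ems] == "G", "A", "T")
    for (i in which(!is_ems)) {
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
    }
    d <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
                    ems_type = (ref == "G" & alt == "A") |
                      (ref == "C" & alt == "T"),
                    stringsAsFactors = FALSE)
    d <- d[order(match(d$chrom, names(lens)), d$pos), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

#' Recombination fraction between two loci (Haldane)
#'
#' Uniform genetic map: `cM_per_Mb` centimorgans per megabase per
#' chromosome, converted to a recombination fraction with the Haldane map
#' function `(1 - exp(-2 d)) / 2`. Loci on different chromosomes are
#' unlinked (recombination fraction 0.5).
#'
#' @param chrom1,pos1,chrom2,pos2 The two loci.
#' @param cM_per_Mb Recombination rate (default 4, a plant-like genome
#'   average).
#' @return Recombination fraction in `[0, 0.5]`.
#' @export
recomb_fraction <- function(chrom1, pos1, chrom2, pos2, cM_per_Mb = 4) {
  ifelse(chrom1 != chrom2, 0.5, {
    d <- abs(pos1 - pos2) / 1e6 * cM_per_Mb / 100  # Morgans
    (1 - exp(-2 * d)) / 2
  })
}

#' Expected pooled allele frequency at a marker
#'
#' Exact expectation of the mutant-parent allele frequency in a
#' phenotypically selected F2 pool, as a function of the recombination
#' fraction `r` between marker and causal locus. Computed by enumeration
#' of the sixteen F1 gamete combinations: gametes (M,m), (W,+) each with
#' probability (1-r)/2 and recombinant gametes (M,+), (W,m) each with
#' probability r/2, where M/W are the mutant/other parent marker alleles
#' and m/+ the causal alleles. The mutant pool conditions on genotype
#' m/m (recessive selection); the wild-type sibling pool conditions on
#' not-m/m.
#'
#' @param r Recombination fraction in `[0, 0.5]` (vectorised).
#' @param pool `"mutant"` or `"wild_type_sibling"`.
#' @return Expected mutant-parent allele frequency at the marker.
#' @export
expected_pool_af <- function(r, pool = c("mutant", "wild_type_sibling")) {
  pool <- match.arg(pool)
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]")
  vapply(r, function(rr) {
    # gamete rows: marker allele is mutant-parent (1/0), causal allele m (1/0)
    gam <- data.frame(M = c(1, 0, 1, 0), m = c(1, 0, 0, 1),
                      p = c((1 - rr) / 2, (1 - rr) / 2, rr / 2, rr / 2))
    num <- 0; den <- 0
    for (i in 1:4) for (j in 1:4) {
      p <- gam$p[i] * gam$p[j]
      mm <- gam$m[i] + gam$m[j] == 2
      keep <- if (pool == "mutant") mm else !mm
      if (keep) {
        num <- num + p * (gam$M[i] + gam$M[j]) / 2
        den <- den + p
      }
    }
    num / den
  }, numeric(1L))
}

#' Simulate genotypes of a selected F2 mapping pool
#'
#' Generates `n_individuals` F2 individuals as pairs of F1 gametes.
#' Gametes are founder-haplotype mosaics: per chromosome the crossover
#' count is Poisson with mean `length * cM_per_Mb / 100` Morgans,
#' breakpoints uniform, starting phase random. Phenotypic selection is
#' applied at the causal marker by rejection: the mutant pool keeps only
#' individuals homozygous for the mutant-parent haplotype at the causal
#' locus; the wild-type sibling pool keeps the rest.
#'
#' @param markers data.frame with columns `chrom`, `pos` (segregating
#'   sites, ordered per chromosome).
#' @param causal Row index of the causal marker in `markers`, or `NULL`
#'   for an unselected pool.
#' @param n_individuals Pool size.
#' @param selection `"mutant"`, `"wild_type_sibling"` or `"none"`.
#' @param chrom_lengths Named lengths of the chromosomes in bp.
#' @param cM_per_Mb Uniform recombination rate.
#' @param seed Optional RNG seed.
#' @return A list: `g1`, `g2` (n x m matrices of founder origin at each
#'   marker; 1 = mutant-parent haplotype, 0 = other), `genotypes`
#'   (`g1 + g2`), `af` (empirical mutant-parent allele frequency per
#'   marker).
#' @export
simulate_pool_genotypes <- function(markers, causal, n_individuals,
                                    selection = c("mutant",
                                                  "wild_type_sibling",
                                                  "none"),
                                    chrom_lengths, cM_per_Mb = 4,
                                    seed = NULL) {
  selection <- match.arg(selection)
  if (selection != "none" && (is.null(causal) || is.na(causal)))
    stop("selection requires a causal marker")
  with_seed_if(seed, {
    m <- nrow(markers)
    chroms <- names(chrom_lengths)
    marker_chrom <- match(markers$chrom, chroms)
    if (anyNA(marker_chrom)) stop("marker on unknown chromosome")
    one_gamete <- function() {
      origin <- integer(m)
      for (ci in seq_along(chroms)) {
        sel <- marker_chrom == ci
        if (!any(sel)) next
        len <- chrom_lengths[[ci]]
        nxo <- rpois(1L, len / 1e6 * cM_per_Mb / 100)
        phase <- sample(0:1, 1L)
        if (nxo > 0L) {
          bp <- sort(runif(nxo, 0, len))
          crossings <- findInterval(markers$pos[sel], bp)
          origin[sel] <- (phase + crossings) %% 2L
        } else {
          origin[sel] <- phase
        }
      }
      origin
    }
    g1 <- matrix(0L, n_individuals, m)
    g2 <- matrix(0L, n_individuals, m)
    accepted <- 0L
    guard <- 0L
    while (accepted < n_individuals) {
      guard <- guard + 1L
      if (guard > 1000L * n_individuals)
        stop("selection rejected too many individuals")
      a <- one_gamete(); b <- one_gamete()
      mm <- !is.null(causal) && !is.na(causal) &&
        (a[causal] + b[causal] == 2L)
      ok <- switch(selection, mutant = mm, wild_type_sibling = !mm,
                   none = TRUE)
      if (ok) {
        accepted <- accepted + 1L
        g1[accepted, ] <- a
        g2[accepted, ] <- b
      }
    }
    geno <- g1 + g2
    list(g1 = g1, g2 = g2, genotypes = geno, af = colMeans(geno) / 2)
  })
}

#' Read-simulation settings
#'
#' @param depth Target fold-coverage.
#' @param read_length Read length in bp.
#' @param paired Paired-end flag.
#' @param insert_mean,insert_sd Fragment-size distribution (paired mode);
#'   truncated below at `read_length`.
#' @param error_rate Per-base substitution probability.
#' @param base_quality Constant Phred quality written for every base.
#' @return A list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(depth = 25, read_length = 75, paired = TRUE,
                          insert_mean = 300, insert_sd = 50,
                          error_rate = 0, base_quality = 35L) {
  if (depth <= 0) stop("depth must be positive")
  if (paired && insert_mean < read_length)
    stop("insert_mean must be at least read_length")
  structure(list(depth = depth, read_length = as.integer(read_length),
                 paired = isTRUE(paired), insert_mean = insert_mean,
                 insert_sd = insert_sd, error_rate = error_rate,
                 base_quality = as.integer(base_quality)),
            class = "read_sim_spec")
}

#' Describe the haplotypes a read pool is drawn from
#'
#' @param variants data.frame with `chrom`, `pos`, `alt` columns.
#' @param hap_alt Logical matrix (haplotypes x variants): does haplotype h
#'   carry the alternative allele at variant v?
#' @return A list of class `haplotype_pool`.
#' @export
haplotype_pool <- function(variants, hap_alt) {
  if (!is.matrix(hap_alt) || ncol(hap_alt) != nrow(variants))
    stop("hap_alt must be a haplotypes x variants matrix")
  structure(list(variants = variants, hap_alt = hap_alt),
            class = "haplotype_pool")
}

# Genomic-coordinate edit list (fragment id, position, replacement base)
# for the haplotype alleles carried by each sampled fragment.
pool_edit_list <- function(pool, hap, ci, start, L, lens) {
  v <- pool$variants
  vc <- match(v$chrom, names(lens))
  frag_end <- start + L - 1L
  ord <- order(ci, start)
  by_chrom <- split(ord, ci[ord])        # fragment ids sorted by start
  st_by_chrom <- lapply(by_chrom, function(s) as.numeric(start[s]))
  maxL <- max(L)
  ef <- vector("list", nrow(v))
  for (j in seq_len(nrow(v))) {
    key <- as.character(vc[j])
    sel <- by_chrom[[key]]
    if (is.null(sel)) next
    st <- st_by_chrom[[key]]
    lo <- findInterval(v$pos[j] - maxL, st) + 1L
    hi <- findInterval(v$pos[j], st)
    if (hi < lo) next
    cand <- sel[lo:hi]
    cand <- cand[frag_end[cand] >= v$pos[j]]
    if (!is.null(hap)) cand <- cand[pool$hap_alt[hap[cand], j]]
    if (!length(cand)) next
    ef[[j]] <- data.frame(frag = cand, pos = v$pos[j], base = v$alt[j],
                          stringsAsFactors = FALSE)
  }
  ef <- ef[!vapply(ef, is.null, logical(1L))]
  if (!length(ef))
    return(data.frame(frag = integer(0), pos = integer(0),
                      base = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, ef)
  out[order(out$frag, out$pos), , drop = FALSE]
}

apply_edits <- function(seqs, idx, off, base) {
  while (length(idx)) {
    first <- !duplicated(idx)
    s <- seqs[idx[first]]
    substr(s, off[first], off[first]) <- base[first]
    seqs[idx[first]] <- s
    idx <- idx[!first]; off <- off[!first]; base <- base[!first]
  }
  seqs
}

#' Simulate short reads from a genome or haplotype pool
#'
#' Samples fragments uniformly (chromosomes weighted by length), emits
#' single reads or inward-facing mate pairs (mate 2 is the reverse
#' complement of the fragment's right end), substitutes the alternative
#' alleles carried by the fragment's haplotype, and injects i.i.d.
#' substitution errors at `error_rate`. Quality strings are constant.
#'
#' @param genome The reference `genome` fragments are drawn from.
#' @param spec A [read_sim_spec()].
#' @param pool Optional [haplotype_pool()]; each fragment is assigned a
#'   haplotype uniformly at random. `NULL` simulates the plain genome.
#' @param seed Optional RNG seed.
#' @param prefix Read-name prefix.
#' @param fastq Optional path(s) (two for paired mode) to also write
#'   FASTQ files.
#' @return For paired mode a list of two `read_set`s (`mate1`, `mate2`);
#'   otherwise a single `read_set`.
#' @export
simulate_reads <- function(genome, spec = read_sim_spec(), pool = NULL,
                           seed = NULL, prefix = "sim", fastq = NULL) {
  with_seed_if(seed, {
    lens <- chrom_lengths(genome)
    rl <- spec$read_length
    if (rl > min(lens)) stop("read_length exceeds a chromosome length")
    per_frag <- if (spec$paired) 2L * rl else rl
    n_frag <- max(1L, round(spec$depth * sum(lens) / per_frag))
    ci <- sample.int(length(lens), n_frag, replace = TRUE,
                     prob = lens / sum(lens))
    if (spec$paired) {
      L <- pmax(rl, round(rnorm(n_frag, spec$insert_mean, spec$insert_sd)))
    } else {
      L <- rep(rl, n_frag)
    }
    L <- pmin(L, lens[ci])
    start <- 1L + floor(runif(n_frag) * (lens[ci] - L + 1))
    start <- as.integer(start)
    L <- as.integer(L)
    hap <- NULL
    if (!is.null(pool)) hap <- sample.int(nrow(pool$hap_alt), n_frag,
                                          replace = TRUE)
    seqs <- unname(unclass(genome))
    if (spec$paired) {
      r1 <- cpp_extract_reads(seqs, ci, start, rep(rl, n_frag),
                              rep(FALSE, n_frag))
      r2 <- cpp_extract_reads(seqs, ci, start + L - rl, rep(rl, n_frag),
                              rep(TRUE, n_frag))
      strand1 <- rep(FALSE, n_frag)
    } else {
      strand1 <- sample(c(FALSE, TRUE), n_frag, replace = TRUE)
      r1 <- cpp_extract_reads(seqs, ci, start, rep(rl, n_frag), strand1)
      r2 <- NULL
    }
    # haplotype alleles
    if (!is.null(pool) && nrow(pool$variants)) {
      ed <- pool_edit_list(pool, hap, ci, start, L, lens)
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      frag_end <- start + L - 1L
      off_l <- ed$pos - start[ed$frag] + 1L
      off_r <- frag_end[ed$frag] - ed$pos + 1L
      if (spec$paired) {
        in1 <- off_l <= rl
        r1 <- apply_edits(r1, ed$frag[in1], off_l[in1], ed$base[in1])
        in2 <- off_r <= rl
        r2 <- apply_edits(r2, ed$frag[in2], off_r[in2],
                          comp[ed$base[in2]])
      } else {
        fw <- !strand1[ed$frag]
        r1 <- apply_edits(r1, ed$frag[fw], off_l[fw], ed$base[fw])
        r1 <- apply_edits(r1, ed$frag[!fw], off_r[!fw], comp[ed$base[!fw]])
      }
    }
    # sequencing errors
    inject <- function(rs) {
      nb <- length(rs) * rl
      ne <- rbinom(1L, nb, spec$error_rate)
      if (ne == 0L) return(rs)
      at <- sample.int(nb, ne)
      idx <- (at - 1L) %/% rl + 1L
      off <- (at - 1L) %% rl + 1L
      old <- substring(rs[idx], off, off)
      alt3 <- matrix(c("C", "G", "T",  "A", "G", "T",
                       "A", "C", "T",  "A", "C", "G"), nrow = 3L,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
      oi <- match(old, colnames(alt3))
      oi[is.na(oi)] <- 1L  # N bases mutate as if A
      new <- alt3[cbind(sample.int(3L, ne, replace = TRUE), oi)]
      apply_edits(rs, idx, off, new)
    }
    if (spec$error_rate > 0) {
      r1 <- inject(r1)
      if (spec$paired) r2 <- inject(r2)
    }
    qual <- strrep(intToUtf8(spec$base_quality + 33L), rl)
    ids <- cpp_make_ids(prefix, n_frag)
    if (spec$paired) {
      out <- list(mate1 = read_set(ids, r1, qual),
                  mate2 = read_set(ids, r2, qual))
      if (!is.null(fastq)) {
        stopifnot(length(fastq) == 2L)
        write_fastq(out$mate1, fastq[[1L]])
        write_fastq(out$mate2, fastq[[2L]])
      }
      out
    } else {
      out <- read_set(ids, r1, qual)
      if (!is.null(fastq)) write_fastq(out, fastq[[1L]])
      out
    }
  })
}

#' Insert foreign sequence into a genome
#'
#' Places each insert immediately before original position `pos`, so the
#' last untouched base on the left is `pos - 1` and the first displaced
#' original base is `pos` (at `pos = 1` the insert precedes the whole
#' chromosome). The reported junction coordinate of an insertion is `pos`
#' in original coordinates. Multiple inserts are applied right-to-left so
#' all `pos` values refer to the original genome.
#'
#' @param genome A `genome` object.
#' @param insert_seq Insert sequence(s), recycled across sites.
#' @param chrom,pos Insertion sites in original coordinates
#'   (`1 <= pos <= length + 1`; `length + 1` appends).
#' @return A list: `genome` (mutant genome) and `truth` (data.frame with
#'   `chrom`, `pos`, `insert_length`, `left_flank_end`,
#'   `right_flank_start` in original coordinates).
#' @export
insert_fragment <- function(genome, insert_seq, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  insert_seq <- rep_len(toupper(insert_seq), n)
  lens <- chrom_lengths(genome)
  if (any(!chrom %in% names(lens))) stop("unknown chromosome")
  if (any(pos < 1L | pos > lens[chrom] + 1L)) stop("pos out of range")
  seqs <- unclass(genome)
  ord <- order(match(chrom, names(lens)), -pos)
  for (i in ord) {
    s <- seqs[[chrom[i]]]
    seqs[[chrom[i]]] <- paste0(substr(s, 1L, pos[i] - 1L), insert_seq[i],
                               substr(s, pos[i], nchar(s)))
  }
  truth <- data.frame(chrom = chrom, pos = pos,
                      insert_length = nchar(insert_seq),
                      left_flank_end = pos - 1L,
                      right_flank_start = pos,
                      stringsAsFactors = FALSE)
  o <- order(match(truth$chrom, names(lens)), truth$pos)
  list(genome = genome(seqs), truth = truth[o, , drop = FALSE])
}

#' Simulate a complete bulked-segregant mapping experiment
#'
#' End-to-end generator for the linkage-mapping workflow: EMS mutagenesis
#' of a founder, an F2 mapping population from a backcross or outcross
#' with recessive phenotypic selection, and paired-end reads for the test
#' pool and the design's control sample. The returned truth set anchors
#' recovery tests.
#'
#' @param genome Reference `genome`.
#' @param design Experimental design `"A"`, `"B"`, `"C"` or `"D"`:
#'   A backcross/reference background/parental-line control;
#'   B outcross/reference background/polymorphic-parent control;
#'   C backcross/non-reference background/wild-type-sibling control;
#'   D outcross/non-reference background/mutagenized-parent control.
#' @param n_mutations EMS mutations planted in the mutant founder.
#' @param causal Index (into the EMS mutation list) of the causal
#'   mutation, or `NULL` to draw one uniformly.
#' @param n_individuals F2 pool size.
#' @param spec A [read_sim_spec()] shared by test and control samples.
#' @param cM_per_Mb Uniform recombination rate.
#' @param poly_density Natural-polymorphism density (per bp) of the
#'   genetically distant parent in outcross designs.
#' @param ems_fraction Share of EMS-type changes among planted mutations.
#' @param seed Optional RNG seed.
#' @return A list with `mutations` (incl. `causal` flag), `causal`
#'   (row), `natural` (outcross polymorphisms, possibly empty),
#'   `pool` (genotype simulation), `expected_af`, `test` and `control`
#'   read pairs.
#' @export
simulate_mapping_experiment <- function(genome, design = "A",
                                        n_mutations = 400, causal = NULL,
                                        n_individuals = 50,
                                        spec = read_sim_spec(),
                                        cM_per_Mb = 4,
                                        poly_density = 1 / 2000,
                                        ems_fraction = 1,
                                        seed = NULL) {
  design <- match.arg(design, c("A", "B", "C", "D"))
  with_seed_if(seed, {
    lens <- chrom_lengths(genome)
    muts <- simulate_ems_mutations(genome, n_mutations, ems_fraction)
    if (is.null(causal)) causal <- sample.int(nrow(muts), 1L)
    muts$causal <- seq_len(nrow(muts)) == causal

    outcross <- design %in% c("B", "D")
    natural <- NULL
    if (outcross) {
      n_poly <- max(1L, round(sum(lens) * poly_density))
      natural <- simulate_ems_mutations(genome, n_poly, ems_fraction = 0)
      natural <- natural[!paste(natural$chrom, natural$pos) %in%
                           paste(muts$chrom, muts$pos), , drop = FALSE]
      natural$ems_type <- NULL
    }

    # segregating variants: founder1 (mutant line) carries the EMS alts,
    # founder2 carries the natural polymorphisms of the distant parent
    seg <- rbind(
      data.frame(muts[c("chrom", "pos", "ref", "alt")], f1 = TRUE, f2 = FALSE),
      if (outcross)
        data.frame(natural[c("chrom", "pos", "ref", "alt")], f1 = FALSE,
                   f2 = TRUE))
    o <- order(match(seg$chrom, names(lens)), seg$pos)
    seg <- seg[o, , drop = FALSE]
    rownames(seg) <- NULL
    causal_row <- which(seg$f1 & paste(seg$chrom, seg$pos) ==
                          paste(muts$chrom[causal], muts$pos[causal]))

    pool <- simulate_pool_genotypes(seg[c("chrom", "pos")], causal_row,
                                    n_individuals, "mutant", lens, cM_per_Mb)
    # haplotype allele matrix for the test pool: 2n gamete rows
    origin <- rbind(pool$g1, pool$g2)  # 1 = founder1 haplotype
    hap_alt <- matrix(FALSE, nrow(origin), nrow(seg))
    for (j in seq_len(nrow(seg))) {
      hap_alt[, j] <- ifelse(origin[, j] == 1L, seg$f1[j], seg$f2[j])
    }
    test_pool <- haplotype_pool(seg, hap_alt)
    test <- simulate_reads(genome, spec, pool = test_pool, prefix = "test")

    control_pool <- switch(design,
      A = NULL,  # parental line: reference itself
      B = haplotype_pool(seg, matrix(rep(seg$f2, each = 2L), 2L,
                                     byrow = FALSE)),  # polymorphic parent
      C = {      # phenotypically wild-type F2 siblings
        sib <- simulate_pool_genotypes(seg[c("chrom", "pos")], causal_row,
                                       n_individuals, "wild_type_sibling",
                                       lens, cM_per_Mb)
        sorg <- rbind(sib$g1, sib$g2)
        salt <- matrix(FALSE, nrow(sorg), nrow(seg))
        for (j in seq_len(nrow(seg)))
          salt[, j] <- ifelse(sorg[, j] == 1L, seg$f1[j], seg$f2[j])
        haplotype_pool(seg, salt)
      },
      D = haplotype_pool(seg, matrix(rep(seg$f1, each = 2L), 2L,
                                     byrow = FALSE)))  # mutagenized parent
    control <- simulate_reads(genome, spec, pool = control_pool,
                              prefix = "ctrl")

    r <- recomb_fraction(seg$chrom, seg$pos, seg$chrom[causal_row],
                         seg$pos[causal_row], cM_per_Mb)
    expected_af <- expected_pool_af(r, "mutant")  # of the founder1 allele

    list(design = design, mutations = muts, causal = causal,
         natural = natural, segregating = seg, causal_row = causal_row,
         pool = pool, expected_af = expected_af,
         test = test, control = control)
  })
}

#' Simulate an insertion-mutant sequencing experiment
#'
#' Builds a mutant genome carrying the given insert at each requested
#' position and simulates reads from it. Pooled lines are supported by
#' passing several positions: each mutant contributes `spec$depth`
#' coverage of its own genome, emulating pooling single-insert mutants.
#'
#' @param genome Reference `genome`.
#' @param insert_seq Insert sequence (known tag, e.g. a T-DNA).
#' @param chrom,pos Insertion sites (original coordinates). With
#'   `pooled = TRUE` each site defines a separate single-insert mutant;
#'   otherwise one mutant carries all the inserts.
#' @param spec A [read_sim_spec()]; depth applies per mutant.
#' @param pooled Pool independent single-insert mutants?
#' @param seed Optional RNG seed.
#' @return A list with `truth` (junction table) and `reads` (a read pair
#'   list, or a single `read_set` for single-end specs).
#' @export
simulate_insertion_experiment <- function(genome, insert_seq, chrom, pos,
                                          spec = read_sim_spec(depth = 10),
                                          pooled = FALSE, seed = NULL) {
  with_seed_if(seed, {
    n <- max(length(chrom), length(pos))
    chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
    if (pooled && n > 1L) {
      parts <- lapply(seq_len(n), function(i) {
        mut <- insert_fragment(genome, insert_seq, chrom[i], pos[i])
        list(truth = mut$truth,
             reads = simulate_reads(mut$genome, spec,
                                    prefix = paste0("mut", i)))
      })
      truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
      if (spec$paired) {
        reads <- list(
          mate1 = do.call(rbind, lapply(parts, function(p) p$reads$mate1)),
          mate2 = do.call(rbind, lapply(parts, function(p) p$reads$mate2)))
        class(reads$mate1) <- class(reads$mate2) <- c("read_set", "data.frame")
      } else {
        reads <- do.call(rbind, lapply(parts, `[[`, "reads"))
        class(reads) <- c("read_set", "data.frame")
      }
      list(truth = truth, reads = reads)
    } else {
      mut <- insert_fragment(genome, insert_seq, chrom, pos)
      list(truth = mut$truth,
           reads = simulate_reads(mut$genome, spec, prefix = "mut"))
    }
  })
}
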