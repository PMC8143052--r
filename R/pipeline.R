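#' Call variants directly from simulated fragments
#'
#' Deep-coverage fast path fusing read construction, end-to-end
#' alignment and pileup reduction in one pass: paired reads are built
#' from fragment coordinates and a genomic edit list, aligned with the
#' same seed-and-extend core as [align_reads()], and reduced on the fly
#' to per-strand coverage and mismatch tallies, from which
#' [call_variants()] emits polymorphic sites. Equivalent to the modular
#' [simulate_reads()] / [align_reads()] / [pileup_from_alignments()]
#' route, without materialising millions of read strings.
#'
#' @param index An [build_index()] of the reference genome.
#' @param genome The reference `genome`.
#' @param frag data.frame with `chrom` (index into the genome), `start`,
#'   `len` of each fragment.
#' @param edits data.frame with `frag`, `pos`, `base` (sorted by `frag`):
#'   replacement bases planted on the fragments.
#' @param read_len Read length (both mates).
#' @param preset A [stringency_preset()].
#' @param sample Sample label for emitted records.
#' @param max_mismatches Aligner mismatch budget.
#' @return A list: `variants` (a `variant_table`), `pileup`, and
#'   `stats` (mapped reads, aligned bases, mean depth).
#' @export
call_from_fragments <- function(index, genome, frag, edits = NULL,
                                read_len = 75L,
                                preset = stringency_preset("low"),
                                sample = "test", max_mismatches = 3L) {
  preset <- stringency_preset(preset)
  if (is.null(edits) || nrow(edits) == 0L) {
    edits <- data.frame(frag = integer(0), pos = integer(0),
                        base = character(0))
  } else {
    edits <- edits[order(edits$frag, edits$pos), , drop = FALSE]
  }
  res <- cpp_align_fragments(index$ptr, as.integer(frag$chrom),
                             as.integer(frag$start), as.integer(frag$len),
                             as.integer(read_len),
                             as.integer(edits$frag), as.integer(edits$pos),
                             as.character(edits$base),
                             as.integer(max_mismatches), 4L,
                             as.integer(preset$min_mapq))
  lens <- chrom_lengths(genome)
  cov_fwd <- stats::setNames(res$cov_fwd, names(lens))
  cov_rev <- stats::setNames(res$cov_rev, names(lens))
  alt <- data.frame(chrom = names(lens)[res$mm_chrom], pos = res$mm_pos,
                    base = res$mm_base,
                    nf = ifelse(res$mm_strand == 0L, res$mm_count, 0L),
                    nr = ifelse(res$mm_strand == 1L, res$mm_count, 0L),
                    stringsAsFactors = FALSE)
  if (nrow(alt)) {
    key <- paste(alt$chrom, alt$pos, alt$base, sep = "\r")
    if (anyDuplicated(key)) {
      nf <- tapply(alt$nf, key, sum)
      nr <- tapply(alt$nr, key, sum)
      first <- !duplicated(key)
      alt <- alt[first, , drop = FALSE]
      k2 <- key[first]
      alt$nf <- as.integer(nf[k2])
      alt$nr <- as.integer(nr[k2])
    }
    alt <- alt[order(match(alt$chrom, names(lens)), alt$pos, alt$base), ,
               drop = FALSE]
    rownames(alt) <- NULL
  }
  pile <- structure(list(chroms = names(lens), lengths = lens,
                         cov_fwd = cov_fwd, cov_rev = cov_rev, alt = alt),
                    class = "pileup")
  list(variants = call_variants(pile, genome, preset, sample = sample),
       pileup = pile,
       stats = list(mapped_reads = res$mapped_reads,
                    aligned_bases = res$aligned_bases,
                    mean_depth = res$aligned_bases / sum(lens)))
}

# sample paired-fragment coordinates, shared by the fused caller
sample_fragments <- function(lens, spec) {
  rl <- spec$read_length
  per_frag <- 2L * rl
  n_frag <- max(1L, round(spec$depth * sum(lens) / per_frag))
  ci <- sample.int(length(lens), n_frag, replace = TRUE,
                   prob = lens / sum(lens))
  L <- pmax(rl, round(rnorm(n_frag, spec$insert_mean, spec$insert_sd)))
  L <- pmin(L, lens[ci])
  start <- 1L + floor(runif(n_frag) * (lens[ci] - L + 1))
  data.frame(chrom = ci, start = as.integer(start), len = as.integer(L))
}

#' Simulate a sequencing sample and call its variants in one pass
#'
#' Samples paired fragments from the genome (optionally through a
#' [haplotype_pool()]), plants haplotype alleles and fragment-level
#' substitution errors, and runs the fused alignment/calling path of
#' [call_from_fragments()]. This is the deep-coverage engine behind the
#' simulated linkage experiments; sequencing errors are planted on the
#' fragment, so overlapping mates share them (akin to pre-sequencing
#' template damage).
#'
#' @param genome Reference `genome`.
#' @param index An [build_index()] of the same genome.
#' @param spec A [read_sim_spec()] (paired mode).
#' @param pool Optional [haplotype_pool()].
#' @param preset A [stringency_preset()].
#' @param sample Sample label.
#' @param seed Optional RNG seed.
#' @return As [call_from_fragments()].
#' @export
simulate_and_call <- function(genome, index, spec = read_sim_spec(),
                              pool = NULL,
                              preset = stringency_preset("low"),
                              sample = "test", seed = NULL) {
  if (!spec$paired) stop("the fused caller supports paired fragments only")
  with_seed_if(seed, {
    lens <- chrom_lengths(genome)
    frag <- sample_fragments(lens, spec)
    hap <- NULL
    if (!is.null(pool))
      hap <- sample.int(nrow(pool$hap_alt), nrow(frag), replace = TRUE)
    edits <- if (!is.null(pool) && nrow(pool$variants)) {
      pool_edit_list(pool, hap, frag$chrom, frag$start, frag$len, lens)
    } else {
      data.frame(frag = integer(0), pos = integer(0), base = character(0))
    }
    if (spec$error_rate > 0) {
      rl <- spec$read_length
      nb <- nrow(frag) * 2L * rl
      ne <- rbinom(1L, nb, spec$error_rate)
      if (ne > 0L) {
        at <- sample.int(nb, ne)
        f <- (at - 1L) %/% (2L * rl) + 1L
        r <- (at - 1L) %% (2L * rl)
        mate2 <- r >= rl
        off <- r %% rl
        gpos <- ifelse(mate2,
                       frag$start[f] + frag$len[f] - 1L - off,
                       frag$start[f] + off)
        old <- base_at(genome, names(lens)[frag$chrom[f]], gpos)
        alt3 <- matrix(c("C", "G", "T",  "A", "G", "T",
                         "A", "C", "T",  "A", "C", "G"), nrow = 3L,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
        oi <- match(old, colnames(alt3))
        oi[is.na(oi)] <- 1L
        err <- data.frame(frag = f, pos = as.integer(gpos),
                          base = alt3[cbind(sample.int(3L, ne, TRUE), oi)],
                          stringsAsFactors = FALSE)
        edits <- rbind(edits, err)
      }
    }
    call_from_fragments(index, genome, frag, edits,
                        read_len = spec$read_length, preset = preset,
                        sample = sample)
  })
}

#' Run a complete simulated linkage-mapping experiment
#'
#' Convenience end-to-end driver used by recovery studies: simulates the
#' mapping experiment at the genotype level, sequences test and control
#' pools through the fused caller, and maps the causal mutation.
#'
#' @param genome Reference `genome`.
#' @param index Prebuilt [build_index()] (rebuilt when `NULL`).
#' @param design Experimental design id (see [design_spec()]).
#' @param n_mutations,n_individuals,cM_per_Mb,poly_density Simulation
#'   settings (see [simulate_mapping_experiment()]).
#' @param spec A [read_sim_spec()].
#' @param stringency Variant-calling stringency level.
#' @param seed RNG seed.
#' @param ... Passed to [map_point_mutation()] (window geometry,
#'   interval override, ...).
#' @return A list: `truth` (mutations, causal row, expected AFs),
#'   `result` (the `linkage_map`), `recovered` (causal inside the
#'   interval) and `causal_in_candidates`.
#' @export
run_linkage_simulation <- function(genome, index = NULL, design = "A",
                                   n_mutations = 400, n_individuals = 50,
                                   cM_per_Mb = 4, poly_density = 1 / 2000,
                                   spec = read_sim_spec(),
                                   stringency = "low", seed = NULL, ...) {
  if (is.null(index)) index <- build_index(genome)
  preset <- stringency_preset(stringency)
  with_seed_if(seed, {
    lens <- chrom_lengths(genome)
    muts <- simulate_ems_mutations(genome, n_mutations)
    causal <- sample.int(nrow(muts), 1L)
    muts$causal <- seq_len(nrow(muts)) == causal
    outcross <- design %in% c("B", "D")
    natural <- NULL
    if (outcross) {
      n_poly <- max(1L, round(sum(lens) * poly_density))
      natural <- simulate_ems_mutations(genome, n_poly, ems_fraction = 0)
      natural <- natural[!paste(natural$chrom, natural$pos) %in%
                           paste(muts$chrom, muts$pos), , drop = FALSE]
    }
    seg <- rbind(
      data.frame(muts[c("chrom", "pos", "ref", "alt")], f1 = TRUE,
                 f2 = FALSE),
      if (outcross)
        data.frame(natural[c("chrom", "pos", "ref", "alt")], f1 = FALSE,
                   f2 = TRUE))
    seg <- seg[order(match(seg$chrom, names(lens)), seg$pos), , drop = FALSE]
    rownames(seg) <- NULL
    causal_row <- which(seg$f1 & paste(seg$chrom, seg$pos) ==
                          paste(muts$chrom[causal], muts$pos[causal]))
    pool <- simulate_pool_genotypes(seg[c("chrom", "pos")], causal_row,
                                    n_individuals, "mutant", lens, cM_per_Mb)
    origin <- rbind(pool$g1, pool$g2)
    hap_alt <- matrix(FALSE, nrow(origin), nrow(seg))
    for (j in seq_len(nrow(seg)))
      hap_alt[, j] <- ifelse(origin[, j] == 1L, seg$f1[j], seg$f2[j])
    test <- simulate_and_call(genome, index, spec,
                              pool = haplotype_pool(seg, hap_alt),
                              preset = preset, sample = "test")
    control_pool <- switch(design,
      A = NULL,
      B = haplotype_pool(seg, matrix(rep(seg$f2, each = 2L), 2L)),
      C = {
        sib <- simulate_pool_genotypes(seg[c("chrom", "pos")], causal_row,
                                       n_individuals, "wild_type_sibling",
                                       lens, cM_per_Mb)
        sorg <- rbind(sib$g1, sib$g2)
        salt <- matrix(FALSE, nrow(sorg), nrow(seg))
        for (j in seq_len(nrow(seg)))
          salt[, j] <- ifelse(sorg[, j] == 1L, seg$f1[j], seg$f2[j])
        haplotype_pool(seg, salt)
      },
      D = haplotype_pool(seg, matrix(rep(seg$f1, each = 2L), 2L)))
    control <- simulate_and_call(genome, index, spec, pool = control_pool,
                                 preset = preset, sample = "control")
    result <- map_point_mutation(test$variants, control$variants, genome,
                                 design = design, stringency = preset,
                                 index = index, spec = spec, ...)
    cpos <- muts$pos[causal]; cchrom <- muts$chrom[causal]
    list(truth = list(mutations = muts, causal = causal,
                      segregating = seg, causal_row = causal_row,
                      pool_af = pool$af),
         test_variants = test$variants, control_variants = control$variants,
         result = result,
         recovered = cchrom == result$interval$chrom &&
           cpos >= result$interval$start && cpos <= result$interval$end,
         causal_in_candidates = any(result$candidates$chrom == cchrom &
                                      result$candidates$pos == cpos))
  })
}
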