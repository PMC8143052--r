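insert_index <- function(insert_seq, k) {
  build_index(genome(c(insert = toupper(insert_seq))), k = k)
}

evidence_frame <- function() {
  data.frame(read = character(0), kind = character(0), side = character(0),
             probe = character(0), junction_offset = integer(0),
             stringsAsFactors = FALSE)
}

#' Select reads spanning insert-genome junctions
#'
#' Locally aligns reads against the insert sequence and keeps those whose
#' alignment reaches an insert terminus while leaving a soft-clipped end
#' of at least `min_clip` nt: such reads straddle a junction, and the
#' clipped part is genomic. Side `left` means the clipped genomic
#' sequence precedes the insert 5' end (in insert orientation), `right`
#' that it follows the 3' end; the clipped substring becomes the genomic
#' probe.
#'
#' @param reads A `read_set`, or a list of two mates (both are scanned).
#' @param insert_seq The known insert sequence.
#' @param min_clip Minimum clipped length to qualify as a probe.
#' @param k Seed length for the insert index.
#' @param terminus_tol Tolerance (bp) for "reaches the terminus".
#' @param min_block Minimum matched block inside the insert.
#' @param insert_idx Optional prebuilt index of the insert sequence.
#' @return data.frame of junction evidence: `read`, `kind`, `side`,
#'   `probe`, `junction_offset` (offset of the junction in the oriented
#'   read).
#' @export
select_junction_reads <- function(reads, insert_seq, min_clip = 15L,
                                  k = 16L, terminus_tol = 3L,
                                  min_block = 20L, insert_idx = NULL) {
  insert_seq <- toupper(insert_seq)
  if (nchar(insert_seq) < min_clip) stop("insert shorter than min_clip")
  if (is.list(reads) && !is.data.frame(reads))
    reads <- {
      r <- do.call(rbind, reads)
      class(r) <- c("read_set", "data.frame")
      r
    }
  idx <- if (is.null(insert_idx)) insert_index(insert_seq, k) else insert_idx
  aln <- align_reads(idx, reads, mode = "local", min_block = min_block)
  ilen <- nchar(insert_seq)
  mapped <- bitwAnd(aln$flag, FLAG_UNMAPPED) == 0L
  out <- list(); oi <- 0L
  for (i in which(mapped)) {
    # stored SEQ is reference-oriented, matching clipL/matchL/clipR
    oriented <- aln$seq[i]
    at_start <- aln$pos[i] <= 1L + terminus_tol
    at_end <- aln$pos[i] + aln$matchL[i] - 1L >= ilen - terminus_tol
    if (at_start && aln$clipL[i] >= min_clip) {
      oi <- oi + 1L
      out[[oi]] <- data.frame(read = aln$qname[i], kind = "junction",
                              side = "left",
                              probe = substr(oriented, 1L, aln$clipL[i]),
                              junction_offset = aln$clipL[i],
                              stringsAsFactors = FALSE)
    }
    if (at_end && aln$clipR[i] >= min_clip) {
      oi <- oi + 1L
      out[[oi]] <- data.frame(read = aln$qname[i], kind = "junction",
                              side = "right",
                              probe = substr(oriented,
                                             aln$clipL[i] + aln$matchL[i] + 1L,
                                             nchar(oriented)),
                              junction_offset = aln$clipL[i] + aln$matchL[i],
                              stringsAsFactors = FALSE)
    }
  }
  if (oi == 0L) return(evidence_frame())
  do.call(rbind, out)
}

#' Select discordant mates bracketing an insertion
#'
#' For each pair in which exactly one mate aligns end-to-end within the
#' insert, the other mate is genomic and becomes a probe. The side is
#' inferred from the insert-aligned mate's strand (minus strand: the
#' genomic mate lies on the left of the insertion; plus strand: on the
#' right), consistent with inward-facing mate geometry.
#'
#' @param pairs List of two `read_set`s (mates). Single-end input yields
#'   an empty result with a message.
#' @param insert_seq The known insert sequence.
#' @param k Seed length for the insert index.
#' @param max_mismatches End-to-end mismatch budget against the insert.
#' @param insert_idx Optional prebuilt index of the insert sequence.
#' @return data.frame of discordant evidence (`kind = "discordant"`).
#' @export
select_discordant_mates <- function(pairs, insert_seq, k = 16L,
                                    max_mismatches = 3L, insert_idx = NULL) {
  if (!is.list(pairs) || is.data.frame(pairs) || length(pairs) != 2L) {
    message("paired-read analysis unavailable for single-end input")
    return(evidence_frame())
  }
  insert_seq <- toupper(insert_seq)
  idx <- if (is.null(insert_idx)) insert_index(insert_seq, k) else insert_idx
  a1 <- align_reads(idx, pairs[[1L]], mode = "end_to_end",
                    max_mismatches = max_mismatches)
  a2 <- align_reads(idx, pairs[[2L]], mode = "end_to_end",
                    max_mismatches = max_mismatches)
  m1 <- bitwAnd(a1$flag, FLAG_UNMAPPED) == 0L
  m2 <- bitwAnd(a2$flag, FLAG_UNMAPPED) == 0L
  pick1 <- m2 & !m1   # mate2 in insert, mate1 is the probe
  pick2 <- m1 & !m2
  res <- list()
  if (any(pick1))
    res[[1L]] <- data.frame(read = a1$qname[pick1], kind = "discordant",
                            side = ifelse(a2$strand[pick1] == 1L, "left",
                                          "right"),
                            probe = a1$seq[pick1],
                            junction_offset = NA_integer_,
                            stringsAsFactors = FALSE)
  if (any(pick2))
    res[[length(res) + 1L]] <- data.frame(
      read = a2$qname[pick2], kind = "discordant",
      side = ifelse(a1$strand[pick2] == 1L, "left", "right"),
      probe = a2$seq[pick2], junction_offset = NA_integer_,
      stringsAsFactors = FALSE)
  if (!length(res)) return(evidence_frame())
  do.call(rbind, res)
}

#' Map genomic probes back to the reference
#'
#' Aligns each probe end-to-end against the genome. Junction probes
#' anchor an exact junction coordinate (the genomic base adjacent to the
#' clipped/matched boundary); discordant probes delimit an interval of
#' plausible junction positions (`anchor .. anchor + envelope` on the
#' left side, mirrored on the right). Probes that fail to map or map to
#' more than `max_hits` locations are dropped and counted in the
#' diagnostics. A junction probe mapping to the reverse strand flips its
#' genome-side (its orientation is tied to the insert's); discordant
#' probes keep theirs (`genome_side`).
#'
#' @param evidence Evidence from [select_junction_reads()] /
#'   [select_discordant_mates()].
#' @param genome_index An [build_index()] of the reference genome.
#' @param envelope Insert-size envelope (bp) for discordant intervals.
#' @param max_mismatches Probe mismatch budget.
#' @param max_hits Multi-mapping cap.
#' @return The evidence with columns `chrom`, `gs`, `ge`, `genome_side`,
#'   `anchor`, `junction` (junction kind only, else NA); attribute
#'   `diagnostics` counts dropped probes.
#' @export
map_probes_to_genome <- function(evidence, genome_index, envelope = 500L,
                                 max_mismatches = 2L, max_hits = 4L) {
  if (nrow(evidence) == 0L) {
    out <- cbind(evidence, data.frame(chrom = character(0), gs = integer(0),
                                      ge = integer(0),
                                      genome_side = character(0),
                                      anchor = integer(0),
                                      junction = integer(0)))
    attr(out, "diagnostics") <- c(unmapped = 0L, multimapped = 0L)
    return(out)
  }
  probes <- read_set(paste0("probe_", seq_len(nrow(evidence))),
                     evidence$probe, strrep("I", nchar(evidence$probe)))
  aln <- align_reads(genome_index, probes, mode = "end_to_end",
                     max_mismatches = max_mismatches, max_hits = max_hits)
  mapped <- bitwAnd(aln$flag, FLAG_UNMAPPED) == 0L
  multi <- !mapped & aln$nhits > max_hits
  diagnostics <- c(unmapped = sum(!mapped & !multi), multimapped = sum(multi))
  ev <- evidence[mapped, , drop = FALSE]
  sub <- aln[mapped, , drop = FALSE]
  ev$chrom <- sub$chrom
  ev$gs <- sub$pos
  ev$ge <- sub$pos + sub$matchL - 1L
  # Junction probes carry insert orientation: a reverse-strand hit means
  # the clipped flank lies on the other side of the junction in genome
  # coordinates. Discordant probes are sequenced mates whose orientation
  # already alternates with library geometry, so their side stands.
  rev <- sub$strand == 1L
  ev$genome_side <- ifelse(ev$kind == "junction" & rev,
                           ifelse(ev$side == "left", "right", "left"),
                           ev$side)
  # anchor: genomic base adjacent to the junction on the flank's own side
  ev$anchor <- ifelse(ev$genome_side == "left", ev$ge, ev$gs)
  ev$junction <- ifelse(ev$kind == "junction",
                        ifelse(ev$genome_side == "left", ev$ge + 1L, ev$gs),
                        NA_integer_)
  ev$envelope <- envelope
  rownames(ev) <- NULL
  attr(ev, "diagnostics") <- diagnostics
  ev
}

#' Cluster insertion evidence into putative sites
#'
#' Single-linkage clustering of mapped evidence along each chromosome:
#' consecutive anchors at most `max_gap` bp apart join a cluster.
#' Clusters with fewer than `min_support` pieces of evidence are
#' discarded. The junction estimate is the median of junction-read
#' coordinates when available, otherwise the midpoint between the
#' innermost left and right discordant anchors. A per-position probe
#' read-depth histogram over the cluster span is attached.
#'
#' @param mapped_evidence Output of [map_probes_to_genome()].
#' @param max_gap Maximum anchor gap within a cluster (bp).
#' @param min_support Minimum total evidence per cluster.
#' @return A list of `insertion_cluster` objects.
#' @export
cluster_insertion_sites <- function(mapped_evidence, max_gap = 500L,
                                    min_support = 4L) {
  ev <- mapped_evidence
  if (nrow(ev) == 0L) return(list())
  ev <- ev[order(ev$chrom, ev$anchor, ev$gs, ev$kind, ev$read), , drop = FALSE]
  newc <- c(TRUE, ev$chrom[-1L] != ev$chrom[-nrow(ev)] |
              diff(ev$anchor) > max_gap)
  cid <- cumsum(newc)
  out <- list()
  for (g in split(seq_len(nrow(ev)), cid)) {
    sub <- ev[g, , drop = FALSE]
    if (nrow(sub) < min_support) next
    jx <- sub$junction[sub$kind == "junction"]
    est <- if (length(jx)) {
      as.integer(round(median(jx)))
    } else {
      la <- sub$anchor[sub$genome_side == "left"]
      ra <- sub$anchor[sub$genome_side == "right"]
      if (length(la) && length(ra)) as.integer(round((max(la) + min(ra)) / 2))
      else if (length(la)) max(la) + 1L
      else min(ra)
    }
    span <- c(min(sub$gs), max(sub$ge))
    depth <- cov_from_ranges(sub$gs - span[1L] + 1L, sub$ge - span[1L] + 1L,
                             span[2L] - span[1L] + 1L)
    support <- table(factor(paste(sub$kind, sub$genome_side, sep = "_"),
                            levels = c("junction_left", "junction_right",
                                       "discordant_left",
                                       "discordant_right")))
    out[[length(out) + 1L]] <- structure(
      list(chrom = sub$chrom[1L], junction_estimate = est,
           span = span, support = c(support),
           support_total = nrow(sub),
           rd_histogram = data.frame(pos = span[1L]:span[2L], depth = depth),
           evidence = sub, verdict = NA_character_),
      class = "insertion_cluster")
  }
  out
}

#' Classify a cluster as genuine or false positive
#'
#' A cluster is called genuine when it has enough accumulated evidence
#' (`support_total >= min_support_genuine`), evidence on both sides of
#' the junction (for single-end data: junction reads on both sides), and
#' a compact span (`<= max_span`); disorganized or weakly supported
#' clusters are labelled `false_positive` but retained for visual
#' inspection.
#'
#' @param cluster An `insertion_cluster`.
#' @param min_support_genuine Evidence threshold.
#' @param max_span Maximum organized-cluster span (bp).
#' @param single_end Restrict the both-sides rule to junction evidence?
#' @return The cluster with `verdict` filled in.
#' @export
classify_cluster <- function(cluster, min_support_genuine = 6L,
                             max_span = 2000L, single_end = FALSE) {
  s <- cluster$support
  both <- if (single_end) {
    s[["junction_left"]] >= 1L && s[["junction_right"]] >= 1L
  } else {
    (s[["junction_left"]] + s[["discordant_left"]] >= 1L) &&
      (s[["junction_right"]] + s[["discordant_right"]] >= 1L)
  }
  width <- cluster$span[2L] - cluster$span[1L] + 1L
  cluster$verdict <- if (cluster$support_total >= min_support_genuine &&
                           both && width <= max_span)
    "genuine" else "false_positive"
  cluster
}

#' @export
print.insertion_cluster <- function(x, ...) {
  cat(sprintf("insertion cluster %s:%s (span %s-%s), support %d [%s]%s\n",
              x$chrom, format(x$junction_estimate, big.mark = ","),
              format(x$span[1L], big.mark = ","),
              format(x$span[2L], big.mark = ","), x$support_total,
              paste(names(x$support), x$support, sep = "=", collapse = ", "),
              if (is.na(x$verdict)) "" else paste0(" -> ", x$verdict)))
  invisible(x)
}

#' Map large insertions of known sequence
#'
#' Full Workflow-2 pipeline: find reads overlapping the insert's
#' junctions (local alignment) and, for paired data, mates bracketing the
#' insertion; re-align the genomic probes to the reference; cluster the
#' hits; and classify each cluster as a genuine insertion or a false
#' positive. Single-end input runs the junction analysis only.
#'
#' @param reads A `read_set` (single-end) or list of two mates (paired).
#' @param insert_seq Known insert sequence (FASTA path or string).
#' @param genome Reference `genome`.
#' @param min_clip,k,terminus_tol Junction-read selection parameters.
#' @param envelope Insert-size envelope for discordant intervals (bp).
#' @param max_gap,min_support Clustering parameters.
#' @param min_support_genuine,max_span Classification thresholds; the
#'   default evidence threshold is 6 for paired and 4 for single-end
#'   data.
#' @param index Optional prebuilt genome [build_index()].
#' @return An object of class `insertion_map`: `clusters` (list),
#'   `table` (one row per cluster), `evidence`, `diagnostics`, `params`.
#' @export
map_insertions <- function(reads, insert_seq, genome, min_clip = 15L,
                           k = 16L, terminus_tol = 3L, envelope = 500L,
                           max_gap = 500L, min_support = 4L,
                           min_support_genuine = NULL, max_span = 2000L,
                           index = NULL) {
  if (is.character(insert_seq) && file.exists(insert_seq))
    insert_seq <- unclass(read_fasta(insert_seq))[[1L]]
  paired <- is.list(reads) && !is.data.frame(reads)
  if (is.null(min_support_genuine))
    min_support_genuine <- if (paired) 6L else 4L
  if (is.null(index)) index <- build_index(genome, k = k)
  iidx <- insert_index(insert_seq, k)
  jr <- select_junction_reads(reads, insert_seq, min_clip = min_clip, k = k,
                              terminus_tol = terminus_tol, insert_idx = iidx)
  dm <- if (paired) select_discordant_mates(reads, insert_seq, k = k,
                                            insert_idx = iidx)
  else evidence_frame()
  ev <- rbind(jr, dm)
  mapped <- map_probes_to_genome(ev, index, envelope = envelope)
  clusters <- cluster_insertion_sites(mapped, max_gap = max_gap,
                                      min_support = min_support)
  clusters <- lapply(clusters, classify_cluster,
                     min_support_genuine = min_support_genuine,
                     max_span = max_span, single_end = !paired)
  tab <- if (length(clusters)) {
    do.call(rbind, lapply(clusters, function(cl)
      data.frame(chrom = cl$chrom, junction = cl$junction_estimate,
                 span_start = cl$span[1L], span_end = cl$span[2L],
                 support = cl$support_total,
                 junction_left = cl$support[["junction_left"]],
                 junction_right = cl$support[["junction_right"]],
                 discordant_left = cl$support[["discordant_left"]],
                 discordant_right = cl$support[["discordant_right"]],
                 verdict = cl$verdict, stringsAsFactors = FALSE)))
  } else {
    data.frame(chrom = character(0), junction = integer(0),
               span_start = integer(0), span_end = integer(0),
               support = integer(0), junction_left = integer(0),
               junction_right = integer(0), discordant_left = integer(0),
               discordant_right = integer(0), verdict = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(clusters = clusters, table = tab, evidence = mapped,
                 diagnostics = attr(mapped, "diagnostics"),
                 params = list(min_clip = min_clip, k = k,
                               terminus_tol = terminus_tol,
                               envelope = envelope, max_gap = max_gap,
                               min_support = min_support,
                               min_support_genuine = min_support_genuine,
                               max_span = max_span, paired = paired)),
            class = "insertion_map")
}

#' @export
print.insertion_map <- function(x, ...) {
  cat("tagged-sequence insertion mapping:", length(x$clusters),
      "cluster(s),", sum(x$table$verdict == "genuine"), "genuine\n")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot an insertion-mapping overview
#'
#' Genome overview with cluster positions and one read-depth histogram
#' per cluster.
#'
#' @param x An `insertion_map`.
#' @param genome Optional `genome` for chromosome extents.
#' @param ... Unused.
#' @export
plot.insertion_map <- function(x, genome = NULL, ...) {
  n <- length(x$clusters)
  if (n == 0L) {
    graphics::plot.new()
    graphics::title("no insertion clusters")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(n, 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cl in x$clusters) {
    graphics::plot(cl$rd_histogram$pos, cl$rd_histogram$depth, type = "h",
                   col = if (cl$verdict == "genuine") "steelblue" else "grey",
                   xlab = paste0(cl$chrom, " (bp)"), ylab = "probe depth",
                   main = sprintf("%s:%d [%s]", cl$chrom,
                                  cl$junction_estimate, cl$verdict))
    graphics::abline(v = cl$junction_estimate, col = "red3", lty = 2)
  }
  invisible(x)
}
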