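#' Experimental-design specification for linkage mapping
#'
#' The four supported bulked-segregant designs. The id fixes the cross
#' type, the mutant background relative to the reference sequence, the
#' control sample and how marker allele frequencies are oriented for peak
#' calling:
#'
#' * `A` - backcross, reference background, control = parental line;
#'   markers are the EMS-induced test-only variants; the causal region
#'   maximises AF.
#' * `B` - outcross, reference background, control = polymorphic parent;
#'   markers are the natural polymorphisms shared by both samples; the
#'   causal region drives the outcross-parent allele towards 0 (minimise).
#' * `C` - backcross, non-reference background, control = phenotypically
#'   wild-type F2 siblings; markers are shared variants scored in both
#'   samples; the causal region maximises `af_test - af_control`.
#' * `D` - outcross, non-reference background, control = mutagenized
#'   parent; markers are the shared background polymorphisms (maximise);
#'   test-only variants are kept separately as EMS candidates.
#'
#' @param id One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(id = c("A", "B", "C", "D")) {
  id <- match.arg(id)
  spec <- switch(id,
    A = list(cross = "backcross", background = "reference",
             control_kind = "parental_line", marker_rule = "test_minus_control",
             orientation = "maximize_af"),
    B = list(cross = "outcross", background = "reference",
             control_kind = "polymorphic_parent", marker_rule = "intersection",
             orientation = "minimize_af"),
    C = list(cross = "backcross", background = "non-reference",
             control_kind = "wt_siblings", marker_rule = "intersection_scored",
             orientation = "maximize_delta"),
    D = list(cross = "outcross", background = "non-reference",
             control_kind = "mutagenized_parent", marker_rule = "intersection",
             orientation = "maximize_af"))
  structure(c(list(id = id), spec), class = "design_spec")
}

variant_key <- function(v) paste(v$chrom, v$pos, sep = ":")

#' Contrast test and control variant lists into mapping markers
#'
#' Applies the design's set rule to produce the biallelic markers whose
#' pooled allele frequencies carry the linkage signal. The oriented value
#' used for window averaging is stored in column `value` (`af_test` for
#' designs A/B/D, `af_test - af_control` for design C). For design D the
#' test-only variants (EMS candidates) are attached as attribute
#' `ems_pool`.
#'
#' @param test_variants,control_variants `variant_table`s called against
#'   the same reference.
#' @param design A [design_spec()] or its id.
#' @return A data.frame of class `marker_set` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `af_test`, `af_control`, `source`, `value`;
#'   attributes `design` and `orientation`.
#' @export
select_informative_markers <- function(test_variants, control_variants,
                                       design = "A") {
  if (!inherits(design, "design_spec")) design <- design_spec(design)
  tv <- test_variants[test_variants$is_snv, , drop = FALSE]
  cv <- control_variants[control_variants$is_snv, , drop = FALSE]
  tk <- variant_key(tv); ck <- variant_key(cv)
  if (design$marker_rule == "test_minus_control") {
    keep <- !(tk %in% ck)
    m <- tv[keep, , drop = FALSE]
    out <- data.frame(chrom = m$chrom, pos = m$pos, ref = m$ref, alt = m$alt,
                      af_test = m$af, af_control = rep(NA_real_, nrow(m)),
                      source = rep_len("ems_induced", nrow(m)),
                      value = m$af, stringsAsFactors = FALSE)
  } else {
    shared <- tk %in% ck
    m <- tv[shared, , drop = FALSE]
    mc <- cv[match(tk[shared], ck), , drop = FALSE]
    src <- if (design$id == "B") "cross_polymorphism" else
      if (design$id == "D") "cross_polymorphism" else "ems_induced"
    val <- if (design$orientation == "maximize_delta") m$af - mc$af else m$af
    out <- data.frame(chrom = m$chrom, pos = m$pos, ref = m$ref, alt = m$alt,
                      af_test = m$af, af_control = mc$af,
                      source = rep_len(src, nrow(m)), value = val,
                      stringsAsFactors = FALSE)
  }
  if (nrow(out) == 0L)
    stop("no informative markers: check that the design matches the ",
         "control sample (design ", design$id, ", control ",
         design$control_kind, ")")
  if (anyDuplicated(paste(out$chrom, out$pos)))
    out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- design
  attr(out, "orientation") <- design$orientation
  class(out) <- c("marker_set", "data.frame")
  if (design$id == "D") {
    attr(out, "ems_pool") <- tv[!(tk %in% ck), , drop = FALSE]
  }
  out
}

#' Average marker allele frequencies in overlapping sliding windows
#'
#' Windows of `window_size` bp advance by `step` bp along each
#' chromosome; the final window is truncated at the chromosome end when
#' needed to cover the tail. A window's `mean_af` is the arithmetic mean
#' of the oriented marker values inside it; windows holding fewer than
#' `min_markers_per_window` markers are flagged empty and excluded from
#' peak calling. A chromosome shorter than the window yields one
#' whole-chromosome window.
#'
#' @param markers A `marker_set` (or data.frame with `chrom`, `pos`,
#'   `value`).
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param window_size,step Window geometry in bp (`step <= window_size`).
#' @param min_markers_per_window Occupancy threshold.
#' @return A data.frame of class `window_profile` with columns `chrom`,
#'   `start`, `end`, `n_markers`, `mean_af`, `smoothed_af`, `empty`.
#' @export
compute_window_profile <- function(markers, chrom_lengths,
                                   window_size = 4e6, step = window_size / 2,
                                   min_markers_per_window = 5L) {
  if (step > window_size) stop("step must not exceed window_size")
  rows <- list(); ri <- 0L
  for (cn in names(chrom_lengths)) {
    len <- chrom_lengths[[cn]]
    starts <- integer(0)
    if (window_size >= len) {
      starts <- 1L
    } else {
      s <- 1
      covered <- 0
      while (s <= len && covered < len) {
        starts <- c(starts, as.integer(s))
        covered <- min(len, s + window_size - 1)
        s <- s + step
      }
    }
    mk <- markers[markers$chrom == cn, , drop = FALSE]
    for (s in starts) {
      e <- as.integer(min(len, s + window_size - 1))
      inside <- mk$pos >= s & mk$pos <= e
      n <- sum(inside)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(chrom = cn, start = as.integer(s), end = e,
                               n_markers = n,
                               mean_af = if (n >= min_markers_per_window)
                                 mean(mk$value[inside]) else NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$smoothed_af <- NA_real_
  out$empty <- out$n_markers < min_markers_per_window
  rownames(out) <- NULL
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  attr(out, "min_markers_per_window") <- min_markers_per_window
  attr(out, "orientation") <- attr(markers, "orientation")
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Smooth a window profile by weighted neighbour averaging
#'
#' Corrects each window's mean by a triangular weighted average over up
#' to six adjacent windows (three on each side) on the same chromosome:
#' weight `4 - d` at window distance `d`, renormalised over the
#' non-empty windows actually present. Constant profiles are fixed
#' points; empty windows stay unscored.
#'
#' @param profile A `window_profile`.
#' @param weights Weight vector for distances 0..3 (pluggable).
#' @return The profile with `smoothed_af` filled in.
#' @export
smooth_profile <- function(profile, weights = c(4, 3, 2, 1)) {
  span <- length(weights) - 1L
  for (cn in unique(profile$chrom)) {
    idx <- which(profile$chrom == cn)
    vals <- profile$mean_af[idx]
    ok <- !profile$empty[idx] & !is.na(vals)
    for (i in seq_along(idx)) {
      if (!ok[i]) next
      j <- max(1L, i - span):min(length(idx), i + span)
      j <- j[ok[j]]
      w <- weights[abs(j - i) + 1L]
      profile$smoothed_af[idx[i]] <- sum(w * vals[j]) / sum(w)
    }
  }
  profile
}

#' Locate the mapping region
#'
#' Selects the window most likely to contain the causal mutation: the
#' argmax of the smoothed profile after the orientation transform
#' (`minimize_af` scores `1 - af`; `maximize_delta` scores the stored
#' delta). Ties break to the earliest chromosome, then lowest start. The
#' window midpoint becomes the center of the mapping region.
#'
#' @param profile A smoothed `window_profile`.
#' @param orientation Orientation override; defaults to the profile's.
#' @return A list with `chrom`, `center`, `window` (row of the profile),
#'   `score`.
#' @export
locate_mapping_region <- function(profile, orientation = NULL) {
  if (is.null(orientation)) orientation <- attr(profile, "orientation")
  if (is.null(orientation)) orientation <- "maximize_af"
  score <- profile$smoothed_af
  if (all(is.na(score))) score <- profile$mean_af
  if (identical(orientation, "minimize_af")) score <- 1 - score
  usable <- which(!profile$empty & !is.na(score))
  if (!length(usable)) stop("all windows are empty; nothing to map")
  best <- usable[order(-score[usable], usable)][1L]
  w <- profile[best, , drop = FALSE]
  list(chrom = w$chrom,
       center = as.integer((w$start + w$end) %/% 2),
       window = w,
       score = score[best])
}

#' Define the candidate interval around the mapping-region center
#'
#' Interval size defaults by genome size: 4 Mb below 200 Mb, 10 Mb up to
#' 1 Gb, 20 Mb beyond, and may be overridden (toy genomes). The interval
#' `[center - size/2 + 1, center + size/2]` is shifted to stay inside the
#' chromosome, and truncated if the chromosome is shorter than the size.
#'
#' @param chrom,center Mapping-region center (from
#'   [locate_mapping_region()]).
#' @param genome The reference `genome`, or a named vector of chromosome
#'   lengths in bp.
#' @param size Optional interval-size override in bp.
#' @return A list of class `candidate_interval` with `chrom`, `center`,
#'   `start`, `end`, `size`.
#' @export
define_candidate_interval <- function(chrom, center, genome, size = NULL) {
  lens <- if (is.numeric(genome)) genome else chrom_lengths(genome)
  if (!chrom %in% names(lens)) stop("unknown chromosome: ", chrom)
  if (is.null(size)) {
    g <- sum(lens)
    size <- if (g < 200e6) 4e6 else if (g <= 1e9) 10e6 else 20e6
  }
  size <- as.numeric(size)
  len <- lens[[chrom]]
  start <- center - size / 2 + 1
  end <- center + size / 2
  if (start < 1) { end <- end + (1 - start); start <- 1 }
  if (end > len) { start <- start - (end - len); end <- len }
  start <- max(1, start)
  structure(list(chrom = chrom, center = as.integer(center),
                 start = as.integer(start), end = as.integer(end),
                 size = as.integer(min(size, len))),
            class = "candidate_interval")
}

#' @export
print.candidate_interval <- function(x, ...) {
  cat(sprintf("candidate interval %s:%s-%s (%.2f Mb) centered at %s\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), x$size / 1e6,
              format(x$center, big.mark = ",")))
  invisible(x)
}

#' Is an EMS-type change?
#' @param ref,alt Alleles.
#' @return Logical: G>A or C>T.
#' @export
is_ems_type <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Select candidate mutations within the interval
#'
#' Candidates are the test variants inside the candidate interval with
#' `af >= min_candidate_af`, restricted to EMS-type (G>A / C>T) changes
#' when `ems_only`. The genome-wide report lists every test variant with
#' its EMS flag and interval membership, so non-EMS changes remain
#' inspectable.
#'
#' @param test_variants A `variant_table`.
#' @param interval A `candidate_interval`.
#' @param min_candidate_af Minimum allele frequency for candidacy.
#' @param ems_only Restrict candidates to EMS-type changes?
#' @return A list: `candidates` and `all_variants` (both data.frames with
#'   `ems_type` and `in_interval` flags); `candidates` is always a subset
#'   of `all_variants`.
#' @export
select_candidate_mutations <- function(test_variants, interval,
                                       min_candidate_af = 0.75,
                                       ems_only = TRUE) {
  av <- as.data.frame(test_variants)
  av$ems_type <- is_ems_type(av$ref, av$alt)
  av$in_interval <- av$chrom == interval$chrom &
    av$pos >= interval$start & av$pos <= interval$end
  keep <- av$in_interval & !is.na(av$af) & av$af >= min_candidate_af &
    av$is_snv
  if (ems_only) keep <- keep & av$ems_type
  list(candidates = av[keep, , drop = FALSE], all_variants = av)
}

resolve_variants <- function(x, genome, index, preset, sample, spec,
                             mode = "end_to_end") {
  if (inherits(x, "variant_table")) return(x)
  if (is.character(x) && length(x) %in% c(1L, 2L) && all(file.exists(x))) {
    if (length(x) == 1L && grepl("\\.vcf$", x, ignore.case = TRUE))
      return(vcf_read(x, sample = sample))
    if (length(x) == 1L && grepl("\\.sam$", x, ignore.case = TRUE)) {
      aln <- sam_read(x)
      pile <- pileup_from_alignments(aln, genome, min_mapq = preset$min_mapq)
      return(call_variants(pile, genome, preset, sample = sample))
    }
    x <- if (length(x) == 2L) list(read_fastq(x[[1L]]), read_fastq(x[[2L]]))
    else read_fastq(x)
  }
  paired <- is.list(x) && !is.data.frame(x)
  if (is.null(index)) stop("an align_index is required to process reads")
  aln <- align_reads(index, x, mode = mode, paired = paired,
                     insert_mean = spec$insert_mean,
                     insert_sd = spec$insert_sd)
  pile <- pileup_from_alignments(aln, genome, min_mapq = preset$min_mapq)
  call_variants(pile, genome, preset, sample = sample)
}

#' Map a point mutation by bulked-segregant linkage analysis
#'
#' Full Workflow-1 pipeline: obtain test/control variant lists (from
#' variant tables, VCF/SAM files, or raw reads via the internal aligner
#' and caller), contrast them into design-specific markers, average the
#' oriented allele frequencies in overlapping windows, smooth, locate the
#' peak, set the candidate interval, and collect candidate EMS mutations.
#'
#' @param test,control Test and control inputs: `variant_table`, path to
#'   a `.vcf`/`.sam` file, a `read_set`, or a list of two `read_set`s
#'   (paired).
#' @param genome The reference `genome`.
#' @param design Design id (`"A"`..`"D"`) or a [design_spec()].
#' @param stringency `"low"` or `"high"` ([stringency_preset()]).
#' @param interval_size Candidate-interval override in bp (`NULL`: by
#'   genome size).
#' @param window_size,step Window geometry; default `interval_size / 8`
#'   and half-window step.
#' @param min_markers_per_window Window occupancy threshold.
#' @param min_candidate_af Candidate allele-frequency floor.
#' @param ems_only Restrict candidates to EMS-type changes?
#' @param index Optional prebuilt [build_index()] (required when inputs
#'   are reads).
#' @param spec A [read_sim_spec()] supplying the insert-size envelope for
#'   paired alignment.
#' @return An object of class `linkage_map`.
#' @export
map_point_mutation <- function(test, control, genome, design = "A",
                               stringency = "low", interval_size = NULL,
                               window_size = NULL, step = NULL,
                               min_markers_per_window = 5L,
                               min_candidate_af = 0.75, ems_only = TRUE,
                               index = NULL, spec = read_sim_spec()) {
  if (!inherits(design, "design_spec")) design <- design_spec(design)
  preset <- stringency_preset(stringency)
  tv <- resolve_variants(test, genome, index, preset, "test", spec)
  cv <- resolve_variants(control, genome, index, preset, "control", spec)
  markers <- select_informative_markers(tv, cv, design)
  lens <- chrom_lengths(genome)
  if (is.null(interval_size)) {
    g <- sum(lens)
    interval_size <- if (g < 200e6) 4e6 else if (g <= 1e9) 10e6 else 20e6
  }
  if (is.null(window_size)) window_size <- interval_size / 8
  if (is.null(step)) step <- window_size / 2
  profile <- compute_window_profile(markers, lens, window_size, step,
                                    min_markers_per_window)
  profile <- smooth_profile(profile)
  peak <- locate_mapping_region(profile)
  interval <- define_candidate_interval(peak$chrom, peak$center, genome,
                                        size = interval_size)
  cand_source <- if (design$id %in% c("A", "B", "D")) {
    tv[!(variant_key(tv) %in% variant_key(cv)), , drop = FALSE]
  } else tv
  cands <- select_candidate_mutations(cand_source, interval,
                                      min_candidate_af, ems_only)
  all_report <- select_candidate_mutations(tv, interval, min_candidate_af,
                                           ems_only)$all_variants
  structure(list(design = design, test_variants = tv, control_variants = cv,
                 markers = markers, profile = profile, peak = peak,
                 interval = interval, candidates = cands$candidates,
                 all_variants = all_report,
                 params = list(stringency = preset$level,
                               interval_size = interval_size,
                               window_size = window_size, step = step,
                               min_markers_per_window = min_markers_per_window,
                               min_candidate_af = min_candidate_af,
                               ems_only = ems_only)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("bulked-segregant linkage mapping (design", x$design$id, ")\n")
  cat(sprintf("  markers: %d (%s)\n", nrow(x$markers),
              x$design$orientation))
  cat(sprintf("  peak window: %s:%s-%s\n", x$peak$window$chrom,
              format(x$peak$window$start, big.mark = ","),
              format(x$peak$window$end, big.mark = ",")))
  print(x$interval)
  cat(sprintf("  candidate mutations: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates)) {
    utils::head(x$candidates[c("chrom", "pos", "ref", "alt", "af")], 10L)
  }
  invisible(x)
}

#' @export
summary.linkage_map <- function(object, ...) {
  print(object)
  cat(sprintf("  windows scored: %d of %d\n",
              sum(!object$profile$empty), nrow(object$profile)))
  cat(sprintf("  genome-wide variants reported: %d (EMS-type %d)\n",
              nrow(object$all_variants), sum(object$all_variants$ems_type)))
  invisible(object)
}

#' Plot allele frequency versus position
#'
#' One panel per chromosome holding markers: raw marker values, the
#' smoothed window profile, and the candidate interval highlighted.
#'
#' @param x A `linkage_map`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.linkage_map <- function(x, ...) {
  chroms <- unique(x$markers$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1L),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cn in chroms) {
    mk <- x$markers[x$markers$chrom == cn, ]
    pr <- x$profile[x$profile$chrom == cn & !x$profile$empty, ]
    graphics::plot(mk$pos / 1e6, mk$value, pch = 16, cex = 0.4,
                   col = "grey50", xlab = paste(cn, "(Mb)"),
                   ylab = "allele frequency", ylim = c(0, 1),
                   main = paste("design", x$design$id), ...)
    if (identical(cn, x$interval$chrom))
      graphics::rect(x$interval$start / 1e6, 0, x$interval$end / 1e6, 1,
                     col = grDevices::adjustcolor("pink", 0.4), border = NA)
    if (nrow(pr))
      graphics::lines((pr$start + pr$end) / 2e6, pr$smoothed_af,
                      col = "red3", lwd = 2)
    if (nrow(x$candidates) && any(x$candidates$chrom == cn))
      graphics::points(x$candidates$pos[x$candidates$chrom == cn] / 1e6,
                       x$candidates$af[x$candidates$chrom == cn],
                       pch = 17, col = "blue")
  }
  invisible(x)
}
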