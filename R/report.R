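write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a mapping report bundle
#'
#' Writes tabular and graphical output for one or more completed
#' workflow results: marker/window/candidate tables and per-chromosome
#' allele-frequency plots with the candidate region highlighted for
#' linkage runs; cluster tables, per-cluster read-depth histograms and a
#' genome overview for insertion runs; and a run log listing every
#' effective parameter. The report is a pure function of its inputs, so
#' repeated runs produce identical tables.
#'
#' @param run_results A `linkage_map`, an `insertion_map`, or a list
#'   containing either/both (named or not).
#' @param out_dir Output directory (created if needed).
#' @param gene_models Optional gene models for candidate annotation.
#' @param genome Optional `genome` (required for candidate annotation).
#' @param plots Emit PNG figures as well as tables?
#' @return Character vector of the files written, invisibly.
#' @export
generate_report <- function(run_results, out_dir, gene_models = NULL,
                            genome = NULL, plots = TRUE) {
  if (inherits(run_results, c("linkage_map", "insertion_map")))
    run_results <- list(run_results)
  if (!length(run_results)) stop("no completed workflow results to report")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  log <- character(0)
  for (res in run_results) {
    if (inherits(res, "linkage_map")) {
      cand <- res$candidates
      if (!is.null(gene_models) && !is.null(genome) && nrow(cand))
        cand <- annotate_candidates(cand, gene_models, genome)
      files <- c(files,
                 write_tsv(res$markers, file.path(out_dir, "markers.tsv")),
                 write_tsv(res$profile, file.path(out_dir,
                                                  "window_profile.tsv")),
                 write_tsv(cand, file.path(out_dir, "candidates.tsv")),
                 write_tsv(res$all_variants,
                           file.path(out_dir, "all_variants.tsv")))
      if (plots) {
        f <- file.path(out_dir, "af_vs_position.png")
        grDevices::png(f, width = 900,
                       height = 300 * length(unique(res$markers$chrom)))
        plot(res)
        grDevices::dev.off()
        files <- c(files, f)
      }
      log <- c(log, "[linkage]",
               sprintf("design=%s", res$design$id),
               sprintf("interval=%s:%d-%d", res$interval$chrom,
                       res$interval$start, res$interval$end),
               sprintf("%s=%s", names(res$params),
                       vapply(res$params, function(p)
                         paste(format(p), collapse = ","), character(1L))))
      if (!is.null(gene_models) && !is.null(genome) && nrow(cand) && plots) {
        hit <- unique(stats::na.omit(cand$gene))
        for (gid in hit) {
          m <- Filter(function(g) g$mrna_id == gid, gene_models)[[1L]]
          f <- file.path(out_dir, paste0("gene_", gsub("\\W", "_", gid),
                                         ".png"))
          grDevices::png(f, width = 700, height = 200)
          plot_gene_model(m, cand[which(cand$gene == gid), , drop = FALSE])
          grDevices::dev.off()
          files <- c(files, f)
        }
      }
    } else if (inherits(res, "insertion_map")) {
      files <- c(files,
                 write_tsv(res$table, file.path(out_dir, "clusters.tsv")))
      for (i in seq_along(res$clusters)) {
        files <- c(files,
                   write_tsv(res$clusters[[i]]$rd_histogram,
                             file.path(out_dir,
                                       sprintf("cluster_%02d_rd.tsv", i))))
      }
      if (plots && length(res$clusters)) {
        f <- file.path(out_dir, "insertion_overview.png")
        grDevices::png(f, width = 900,
                       height = 250 * max(1L, length(res$clusters)))
        plot(res)
        grDevices::dev.off()
        files <- c(files, f)
      }
      log <- c(log, "[insertion]",
               sprintf("clusters=%d genuine=%d", nrow(res$table),
                       sum(res$table$verdict == "genuine")),
               sprintf("%s=%s", names(res$params),
                       vapply(res$params, function(p)
                         paste(format(p), collapse = ","), character(1L))))
    } else {
      stop("unsupported result object of class ", class(res)[1L])
    }
  }
  lf <- file.path(out_dir, "run_log.txt")
  writeLines(log, lf)
  invisible(c(files, lf))
}

# simple exon/CDS diagram with the mutation position marked
plot_gene_model <- function(model, variants = NULL) {
  span <- c(min(model$exons[, "start"]), max(model$exons[, "end"]))
  graphics::plot(NA, xlim = span, ylim = c(0, 2), yaxt = "n",
                 xlab = paste0(model$chrom, " (bp)"), ylab = "",
                 main = sprintf("%s [%s]", model$mrna_id, model$strand))
  graphics::segments(span[1L], 1, span[2L], 1)
  for (i in seq_len(nrow(model$exons)))
    graphics::rect(model$exons[i, "start"], 0.8, model$exons[i, "end"], 1.2,
                   col = "grey80")
  if (!is.null(model$cds))
    for (i in seq_len(nrow(model$cds)))
      graphics::rect(model$cds[i, "start"], 0.75, model$cds[i, "end"], 1.25,
                     col = "steelblue")
  if (!is.null(variants) && nrow(variants)) {
    graphics::points(variants$pos, rep(1.6, nrow(variants)), pch = 25,
                     bg = "red3")
    graphics::text(variants$pos, 1.85,
                   paste0(variants$ref, ">", variants$alt), cex = 0.8)
  }
  invisible(model)
}
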