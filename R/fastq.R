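#' Read a FASTQ file
#'
#' Minimal four-line-record FASTQ reader. Returns a `read_set`: a
#' data.frame with columns `id`, `seq` and `qual`. Quality strings are
#' kept verbatim so that encoding detection can inspect them.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @param n_max Maximum number of records to read (`Inf` for all).
#' @return A data.frame of class `read_set` with columns `id`, `seq`,
#'   `qual`.
#' @export
read_fastq <- function(path, n_max = Inf) {
  ln <- if (is.finite(n_max)) readLines(path, n = 4L * n_max) else readLines(path)
  if (length(ln) %% 4L != 0L)
    stop("truncated FASTQ file (line count not a multiple of 4): ", path)
  n <- length(ln) %/% 4L
  if (n == 0L) return(read_set(character(0), character(0), character(0)))
  id <- ln[seq(1L, by = 4L, length.out = n)]
  if (any(!startsWith(id, "@"))) stop("malformed FASTQ header in ", path)
  seq <- toupper(ln[seq(2L, by = 4L, length.out = n)])
  qual <- ln[seq(4L, by = 4L, length.out = n)]
  read_set(sub("^@", "", sub("\\s.*$", "", id)), seq, qual)
}

#' Construct a read set
#'
#' @param id Read identifiers.
#' @param seq Nucleotide sequences.
#' @param qual Per-base quality strings (same lengths as `seq`).
#' @return A data.frame of class `read_set`.
#' @export
read_set <- function(id, seq, qual) {
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence and quality lengths differ")
  structure(data.frame(id = as.character(id), seq = as.character(seq),
                       qual = as.character(qual), stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Write a read set to FASTQ
#'
#' @param reads A `read_set` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con,
             sep = "\n")
  invisible(path)
}

#' Detect the FASTQ quality-score encoding
#'
#' Inspects quality characters of up to `max_records` reads. Any code
#' below 59 forces `phred33`; codes all at or above 75 with none below 64
#' force `phred64`; anything else is `ambiguous`, in which case downstream
#' code defaults to `phred33` (modern data dominate) with a warning.
#'
#' @param reads A `read_set` or a character vector of quality strings.
#' @param max_records Number of reads to inspect.
#' @return One of `"phred33"`, `"phred64"`, `"ambiguous"`.
#' @export
detect_fastq_encoding <- function(reads, max_records = 10000L) {
  qual <- if (is.data.frame(reads)) reads$qual else as.character(reads)
  if (length(qual) == 0L) stop("at least one read is required")
  qual <- utils::head(qual, max_records)
  codes <- utf8ToInt(paste(qual, collapse = ""))
  if (any(codes < 33L | codes > 126L))
    stop("quality character outside the printable range 33..126")
  if (any(codes < 59L)) return("phred33")
  if (all(codes >= 75L)) return("phred64")
  "ambiguous"
}

#' Summarise read quality
#'
#' Deterministic per-sample quality-control summary: read count, read
#' length distribution, mean quality per cycle and percentage of N calls.
#' Emits a warning when the overall mean quality falls below `min_mean_q`.
#'
#' @param reads A `read_set`.
#' @param encoding Quality encoding, `"phred33"` or `"phred64"`.
#' @param min_mean_q Quality floor below which a warning is raised.
#' @return A list with elements `n_reads`, `length_dist` (named table),
#'   `mean_q_per_cycle`, `mean_q`, `pct_n`.
#' @export
assess_read_quality <- function(reads, encoding = "phred33",
                                min_mean_q = 20) {
  offset <- if (identical(encoding, "phred64")) 64L else 33L
  if (nrow(reads) == 0L) {
    warning("empty read set")
    return(list(n_reads = 0L, length_dist = table(integer(0)),
                mean_q_per_cycle = numeric(0), mean_q = 0, pct_n = 0))
  }
  lens <- nchar(reads$seq)
  max_len <- max(lens)
  qsum <- numeric(max_len)
  qcnt <- numeric(max_len)
  for (i in seq_len(nrow(reads))) {
    q <- utf8ToInt(reads$qual[[i]]) - offset
    idx <- seq_along(q)
    qsum[idx] <- qsum[idx] + q
    qcnt[idx] <- qcnt[idx] + 1
  }
  n_n <- sum(vapply(gregexpr("N", reads$seq, fixed = TRUE),
                    function(m) sum(m > 0L), numeric(1)))
  mean_q_per_cycle <- qsum / qcnt
  mean_q <- sum(qsum) / sum(qcnt)
  if (mean_q < min_mean_q)
    warning(sprintf("mean base quality %.1f below Q%d floor", mean_q,
                    as.integer(min_mean_q)))
  list(n_reads = nrow(reads),
       length_dist = table(lens),
       mean_q_per_cycle = mean_q_per_cycle,
       mean_q = mean_q,
       pct_n = 100 * n_n / sum(lens))
}
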