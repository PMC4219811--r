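#' Trim raw reads by N content, base quality and length
#'
#' Applies three removal rules, in a fixed order so every read is counted
#' once under its first failing rule: (1) fraction of unknown base calls
#' (N) strictly above 5%; (2) fraction of low-quality bases (Q < 5)
#' strictly above 50%; (3) length strictly below 20 bases. All thresholds
#' are strict, so a 100-base read with exactly 5 Ns passes. Surviving reads
#' are emitted unmodified.
#'
#' @param fastq_in Path to a Phred+33 FASTQ file, or the list returned by
#'   [simulate_reads()].
#' @param fastq_out Optional path for the retained reads (FASTQ).
#' @param max_n_fraction,max_lowq_fraction,min_length The three thresholds;
#'   defaults 0.05, 0.50 and 20.
#' @return List with `sequences`, `qualities` (retained reads) and
#'   `report`, a one-row data frame: `input_count`, `removed_n_fraction`,
#'   `removed_low_quality`, `removed_short`, `retained`.
#' @export
trim_reads <- function(fastq_in, fastq_out = NULL, max_n_fraction = 0.05,
                       max_lowq_fraction = 0.50, min_length = 20L) {
  if (is.character(fastq_in)) {
    parsed <- read_fastq(fastq_in)
  } else if (is.list(fastq_in) && all(c("sequences", "qualities") %in%
                                      names(fastq_in))) {
    parsed <- fastq_in[c("sequences", "qualities")]
  } else {
    stop("fastq_in must be a FASTQ path or a sequences/qualities list")
  }
  seqs <- parsed$sequences
  quals <- parsed$qualities
  len <- nchar(seqs)
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  n_frac <- ifelse(len > 0, n_count / len, 1)
  lowq_frac <- vapply(quals, function(q) {
    ph <- utf8ToInt(q) - 33L
    if (length(ph) == 0) return(1)
    mean(ph < 5L)
  }, numeric(1), USE.NAMES = FALSE)
  fail_n <- n_frac > max_n_fraction
  fail_q <- !fail_n & lowq_frac > max_lowq_fraction
  fail_len <- !fail_n & !fail_q & len < min_length
  keep <- !(fail_n | fail_q | fail_len)
  report <- data.frame(input_count = length(seqs),
                       removed_n_fraction = sum(fail_n),
                       removed_low_quality = sum(fail_q),
                       removed_short = sum(fail_len),
                       retained = sum(keep))
  out <- list(sequences = seqs[keep], qualities = quals[keep],
              report = report)
  if (!is.null(fastq_out)) write_fastq(out$sequences, out$qualities, fastq_out)
  out
}

## FASTQ reader with structural validation that names the offending record
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count ", length(lines),
         " is not a multiple of 4 (truncated record ",
         length(lines) %/% 4L + 1L, ")")
  }
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  hdr <- lines[idx * 4L - 3L]
  seqs <- lines[idx * 4L - 2L]
  plus <- lines[idx * 4L - 1L]
  quals <- lines[idx * 4L]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ record ", bad_hdr[1], ": header does not start with @")
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ record ", bad_plus[1], ": separator line missing +")
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len)) {
    stop("malformed FASTQ record ", bad_len[1],
         ": sequence and quality lengths differ")
  }
  names(seqs) <- sub("^@", "", sub("\\s.*$", "", hdr))
  list(sequences = seqs, qualities = quals)
}
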