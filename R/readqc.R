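#' Read-cleaning parameters
#'
#' Thresholds for the three-stage cleaning rule applied to short reads:
#' reads with more than `max_missing` missing calls, or with a mean quality
#' below `head_min_mean_q` over the first `head_len` bases, are removed; the
#' 3' end is then trimmed while any trailing region of up to `tail_window`
#' bases has mean quality below `tail_min_mean_q`; reads shorter than
#' `min_len` after trimming are dropped.
#'
#' The trailing-window realisation of "3' regions with mean quality lower
#' than 20" is a design choice; the window size is configurable.
#'
#' @param max_missing Maximum tolerated `N` calls per read (default 2).
#' @param head_len Length of the head segment tested (default 10 bp).
#' @param head_min_mean_q Minimum mean Phred quality of the head (default 15).
#' @param tail_min_mean_q Minimum mean Phred quality of the trailing window
#'   (default 20).
#' @param tail_window Trailing window length in bp (default 10).
#' @param min_len Minimum read length after trimming (default 30 bp).
#' @return A list of class `clean_params`.
#' @export
clean_params <- function(max_missing = 2L, head_len = 10L, head_min_mean_q = 15,
                         tail_min_mean_q = 20, tail_window = 10L, min_len = 30L) {
  stopifnot(max_missing >= 0, head_len >= 0, head_min_mean_q >= 0,
            tail_min_mean_q >= 0, tail_window >= 1, min_len >= 0)
  structure(list(max_missing = as.integer(max_missing),
                 head_len = as.integer(head_len),
                 head_min_mean_q = head_min_mean_q,
                 tail_min_mean_q = tail_min_mean_q,
                 tail_window = as.integer(tail_window),
                 min_len = as.integer(min_len)),
            class = "clean_params")
}

#' Keep/discard decision for a single read
#'
#' A read is discarded when it has more than `max_missing` missing (`N`)
#' calls, or when the mean quality of its first `head_len` bases (the whole
#' read, if shorter) is below `head_min_mean_q`. Empty reads are discarded as
#' short.
#'
#' @param bases Character scalar of base calls.
#' @param quals Integer vector of Phred qualities, one per base.
#' @param params A [clean_params()].
#' @return A list with `keep` (logical) and `reason` (`NA`, `"missing"`,
#'   `"head_quality"` or `"short"`).
#' @export
assess_read <- function(bases, quals, params = clean_params()) {
  stopifnot(nchar(bases) == length(quals))
  if (length(quals) == 0L) return(list(keep = FALSE, reason = "short"))
  n_miss <- nchar(bases) - nchar(gsub("N", "", bases, fixed = TRUE))
  if (n_miss > params$max_missing) return(list(keep = FALSE, reason = "missing"))
  if (mean(quals[seq_len(min(params$head_len, length(quals)))]) < params$head_min_mean_q)
    return(list(keep = FALSE, reason = "head_quality"))
  list(keep = TRUE, reason = NA_character_)
}

#' Trim the low-quality 3' end of a read
#'
#' Repeatedly removes the last base while any trailing region of up to
#' `tail_window` bases has a mean quality below `tail_min_mean_q`; the kept
#' read therefore ends with no low-quality 3' region of any length up to the
#' window. May return an empty read.
#'
#' @inheritParams assess_read
#' @return A list with trimmed `bases` and `quals`.
#' @export
trim_three_prime <- function(bases, quals, params = clean_params()) {
  len <- trim_length(quals, params$tail_window, params$tail_min_mean_q)
  list(bases = substr(bases, 1L, len), quals = quals[seq_len(len)])
}

# Final length after 3' trimming (workhorse; operates on one read): the last
# base is removed while any trailing region of up to `window` bases has a
# mean quality below `min_mean`, so no low-quality 3' region of any length up
# to the window survives.
trim_length <- function(quals, window, min_mean) {
  len <- length(quals)
  while (len > 0L) {
    w <- min(window, len)
    tailq <- quals[(len - w + 1L):len]
    # running means of the suffixes of length 1..w
    suffix_means <- cumsum(rev(tailq)) / seq_len(w)
    if (all(suffix_means >= min_mean)) break
    len <- len - 1L
  }
  len
}

#' Clean a FASTQ read set
#'
#' Applies, in order: the missing-call and head-quality read filters
#' ([assess_read()]), 3' quality trimming ([trim_three_prime()]), and the
#' minimum-length filter. Reports the attrition at each stage.
#'
#' @param input FASTQ path (Sanger Phred+33) or a `data.table` with columns
#'   `id`, `seq`, `qual`.
#' @param output Optional path for the cleaned FASTQ.
#' @param params A [clean_params()].
#' @param report Optional path for a TSV attrition report.
#' @return A list with `reads` (cleaned read table) and `report`, a one-row
#'   `data.table` with `reads_in`, `reads_out`, `bases_in`, `bases_out`,
#'   `mean_len_out`, `discarded_missing`, `discarded_head_quality`,
#'   `discarded_short`. The counts satisfy
#'   `reads_out + discarded_missing + discarded_head_quality + discarded_short == reads_in`.
#' @export
clean_fastq <- function(input, output = NULL, params = clean_params(),
                        report = NULL) {
  reads <- if (is.character(input)) read_fastq(input) else as.data.table(input)
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  n_in <- nrow(reads)
  bases_in <- sum(nchar(reads$seq))
  if (n_in > 0L && any(nchar(reads$seq) != nchar(reads$qual)))
    stop("malformed reads: sequence and quality lengths differ")

  if (n_in == 0L) {
    keep <- logical(0); reason <- character(0)
    out <- reads
  } else {
    quals <- phred_decode(reads$qual)
    lens <- nchar(reads$seq)
    n_miss <- lens - nchar(gsub("N", "", reads$seq, fixed = TRUE))
    head_mean <- vapply(quals, function(q) {
      if (!length(q)) return(NA_real_)
      mean(q[seq_len(min(params$head_len, length(q)))])
    }, numeric(1))
    reason <- rep(NA_character_, n_in)
    reason[lens == 0L] <- "short"
    reason[is.na(reason) & n_miss > params$max_missing] <- "missing"
    reason[is.na(reason) & head_mean < params$head_min_mean_q] <- "head_quality"
    surv <- which(is.na(reason))
    newlen <- lens
    newlen[surv] <- vapply(quals[surv], trim_length, integer(1),
                           window = params$tail_window,
                           min_mean = params$tail_min_mean_q)
    short <- surv[newlen[surv] < params$min_len]
    reason[short] <- "short"
    keep <- is.na(reason)
    out <- reads[keep]
    kl <- newlen[keep]
    out[, seq := substr(seq, 1L, kl)]
    out[, qual := substr(qual, 1L, kl)]
  }

  rep_dt <- data.table(
    reads_in = n_in, reads_out = nrow(out),
    bases_in = bases_in, bases_out = sum(nchar(out$seq)),
    mean_len_out = if (nrow(out)) mean(nchar(out$seq)) else 0,
    discarded_missing = sum(reason == "missing", na.rm = TRUE),
    discarded_head_quality = sum(reason == "head_quality", na.rm = TRUE),
    discarded_short = sum(reason == "short", na.rm = TRUE))

  if (!is.null(output)) write_fastq(out, output)
  if (!is.null(report)) fwrite(rep_dt, report, sep = "\t")
  list(reads = out[], report = rep_dt)
}

#' Read a FASTQ file into a read table
#'
#' Parsing is done with [Biostrings::readDNAStringSet()]; a light structural
#' pre-check reports the index of the first malformed record.
#'
#' @param path FASTQ path (Sanger Phred+33).
#' @return `data.table` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  validate_fastq(path)
  if (file.size(path) == 0L)
    return(data.table(id = character(), seq = character(), qual = character()))
  dss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table(id = sub("\\s.*$", "", names(dss)),
             seq = as.character(dss),
             qual = as.character(S4Vectors::mcols(dss)$qualities))
}

validate_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ record %d in %s: truncated record",
                 length(lines) %/% 4L + 1L, path))
  if (!length(lines)) return(invisible(TRUE))
  idx <- seq(1L, length(lines), by = 4L)
  bad_hdr <- which(!startsWith(lines[idx], "@") | !startsWith(lines[idx + 2L], "+"))
  if (length(bad_hdr))
    stop(sprintf("malformed FASTQ record %d in %s: bad header/separator",
                 bad_hdr[1], path))
  bad_len <- which(nchar(lines[idx + 1L]) != nchar(lines[idx + 3L]))
  if (length(bad_len))
    stop(sprintf("malformed FASTQ record %d in %s: sequence/quality length mismatch",
                 bad_len[1], path))
  invisible(TRUE)
}

#' Write a read table as FASTQ
#' @param reads `data.table` with `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  if (!nrow(reads)) {
    file.create(path)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
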