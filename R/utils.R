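#' @import data.table
#' @importFrom stats rpois runif rnorm setNames
#' @importFrom utils head tail
#' @importFrom methods is
NULL

# Decode Phred+33 quality strings to integer vectors (one element per read).
phred_decode <- function(x) {
  lapply(x, function(s) utf8ToInt(s) - 33L)
}

# Encode integer quality vectors as Phred+33 strings.
phred_encode <- function(q) {
  vapply(q, function(v) if (length(v)) intToUtf8(v + 33L) else "", character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

pool_names <- function(n) paste0("pool", seq_len(n))

is_indel_allele <- function(allele) {
  startsWith(allele, "+") | startsWith(allele, "-")
}

# Load a reference as a named character vector of scaffold sequences.
# Accepts a FASTA path, a Biostrings::DNAStringSet, a named character vector,
# or a simulation object produced by make_genome().
load_reference <- function(x) {
  if (inherits(x, "pool_sim")) return(x$seqs)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    dss <- Biostrings::readDNAStringSet(x)
    return(setNames(as.character(dss), sub("\\s.*$", "", names(dss))))
  }
  if (methods::is(x, "DNAStringSet")) {
    return(setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("cannot interpret 'reference'; give a FASTA path, DNAStringSet or named character vector")
}

#' Percentage of a count over a total
#'
#' Small reporting helper used throughout the per-pool and filter summaries:
#' `100 * count / total`, rounded to `digits` decimal places.
#'
#' @param count Numerator count.
#' @param total Denominator count; must be positive.
#' @param digits Decimal places to round to (default 1).
#' @return Numeric percentage.
#' @export
proportion_pct <- function(count, total, digits = 1) {
  stopifnot(total > 0)
  round(100 * count / total, digits)
}
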