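# Fixture builders and independent oracles used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an alignment table from a compact read spec. `qual` may be a scalar
# Phred value (applied to every base) or an integer vector per read.
make_reads <- function(..., default_mapq = 60L) {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    len <- nchar(s$seq)
    q <- s$qual %||% 30L
    if (length(q) == 1L) q <- rep(q, len)
    stopifnot(length(q) == len)
    data.table::data.table(
      qname = s$qname %||% sprintf("r%03d", i),
      flag = s$flag %||% 0L,
      rname = s$rname %||% "chr1",
      pos = s$pos,
      mapq = s$mapq %||% default_mapq,
      cigar = s$cigar %||% sprintf("%dM", len),
      seq = s$seq,
      qual = intToUtf8(q + 33L))
  })
  out <- data.table::rbindlist(rows)
  out[order(match(rname, unique(rname)), pos)]
}

write_sam_fixture <- function(reads, seqlengths, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths))
  body <- if (nrow(reads)) {
    paste(reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
          reads$cigar, "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  path
}

# Random reference of length n as a named character vector.
random_ref <- function(n, name = "chr1", seed = 1) {
  withr::with_seed(seed,
    stats::setNames(paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
                    name))
}

# ---------------------------------------------------------------------------
# Independent brute-force caller: literal, loop-based application of the
# coverage / allele-support / summed-quality rules, sharing no code with the
# package implementation. Handles plain M-cigar reads only.
brute_force_calls <- function(reads, ref, params) {
  obs <- list()  # key "pos" -> named list allele -> c(depth, qsum)
  for (i in seq_len(nrow(reads))) {
    if (reads$mapq[i] < params$min_mapq) next
    fl <- reads$flag[i]
    if (bitwAnd(fl, 4L) || bitwAnd(fl, 256L) || bitwAnd(fl, 1024L) ||
        bitwAnd(fl, 2048L)) next
    bases <- strsplit(reads$seq[i], "")[[1]]
    quals <- utf8ToInt(reads$qual[i]) - 33L
    for (k in seq_along(bases)) {
      if (bases[k] == "N" || quals[k] == 0L) next
      p <- as.character(reads$pos[i] + k - 1L)
      if (is.null(obs[[p]])) obs[[p]] <- list()
      a <- bases[k]
      if (is.null(obs[[p]][[a]])) obs[[p]][[a]] <- c(0L, 0)
      obs[[p]][[a]] <- obs[[p]][[a]] + c(1L, quals[k])
    }
  }
  out <- list()
  for (p in names(obs)) {
    al <- obs[[p]]
    total <- sum(vapply(al, `[`, numeric(1), 1))
    if (total < params$min_coverage) next
    sup <- names(al)[vapply(al, `[`, numeric(1), 1) >= params$min_allele_reads]
    if (!length(sup)) next
    depths <- vapply(al[sup], `[`, numeric(1), 1)
    qsums <- vapply(al[sup], `[`, numeric(1), 2)
    ord <- order(-depths, sup)  # majority first, lexicographic ties
    sup <- sup[ord]; depths <- depths[ord]; qsums <- qsums[ord]
    if (length(sup) == 1L) {
      status <- "monomorphic"; alleles <- sup; maf <- 1
    } else {
      minq <- min(qsums[-1L])
      if (minq >= params$min_quality) {
        status <- "polymorphic"; alleles <- paste(sup, collapse = ",")
        maf <- depths[1L] / sum(depths)
      } else {
        status <- "monomorphic"; alleles <- sup[1L]; maf <- 1
      }
    }
    out[[p]] <- data.table::data.table(
      pos = as.integer(p), status = status, alleles = alleles, maf = maf)
  }
  if (!length(out))
    return(data.table::data.table(pos = integer(), status = character(),
                                  alleles = character(), maf = numeric()))
  res <- data.table::rbindlist(out)
  res[order(pos)]
}

# Random tiny pileup fixture: short reads over a small reference with planted
# alternates, low-quality bases, Ns and a few flagged/low-mapq reads.
random_fixture <- function(seed, ref_len = 120L, n_reads = 40L, read_len = 12L) {
  withr::with_seed(seed, {
    ref <- random_ref(ref_len, seed = seed + 999)
    refv <- strsplit(ref[[1]], "")[[1]]
    rows <- lapply(seq_len(n_reads), function(i) {
      pos <- sample.int(ref_len - read_len + 1L, 1L)
      bases <- refv[pos:(pos + read_len - 1L)]
      # plant alternates at ~2 hot positions to create real polymorphism
      hot <- c(25L, 70L)
      for (h in hot) {
        k <- h - pos + 1L
        if (k >= 1L && k <= read_len && runif(1) < 0.45) bases[k] <- "G"
      }
      # sprinkle errors, Ns
      err <- runif(read_len) < 0.05
      bases[err] <- sample(c("A", "C", "G", "T"), sum(err), TRUE)
      bases[runif(read_len) < 0.04] <- "N"
      quals <- sample(c(0L, 5L, 12L, 25L, 35L, 40L), read_len, TRUE,
                      prob = c(.05, .1, .15, .2, .3, .2))
      list(pos = pos, seq = paste(bases, collapse = ""), qual = quals,
           mapq = sample(c(0L, 60L), 1L, prob = c(.08, .92)),
           flag = sample(c(0L, 1024L), 1L, prob = c(.93, .07)),
           rname = names(ref))
    })
    list(reads = do.call(make_reads, rows), ref = ref)
  })
}

# Minimal hand-built multi-pool variant table for the diversity/marker tests.
# `spec` rows: scaffold, pos, ref, alleles, kind, global_maf and per-pool
# status/allele/maf triples supplied as lists.
make_variants_table <- function(df, pools) {
  dt <- data.table::as.data.table(df)
  data.table::setattr(dt, "pools", pools)
  dt
}
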