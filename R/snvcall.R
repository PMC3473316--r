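#' SNV-calling parameters
#'
#' Thresholds of the pooled pileup caller: only positions with at least
#' `min_coverage` reads are mined; an allele is *supported* when at least
#' `min_allele_reads` reads carry it; a polymorphic call additionally requires
#' a call quality -- the minimum summed Phred quality over supported
#' non-majority alleles -- of at least `min_quality`. Alignments below
#' `min_mapq` mapping quality are ignored.
#'
#' @param min_coverage Minimum fold-coverage per position (default 6).
#' @param min_allele_reads Minimum reads per supported allele (default 3).
#' @param min_quality Minimum summed Phred quality of every supported minority
#'   allele (default 70).
#' @param min_mapq Minimum mapping quality (default 1).
#' @return A list of class `call_params`.
#' @export
call_params <- function(min_coverage = 6L, min_allele_reads = 3L,
                        min_quality = 70, min_mapq = 1L) {
  stopifnot(min_coverage >= 1, min_allele_reads >= 1, min_quality >= 0,
            min_mapq >= 0)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_allele_reads = as.integer(min_allele_reads),
                 min_quality = min_quality, min_mapq = as.integer(min_mapq)),
            class = "call_params")
}

# Read alignments from a SAM/BAM path (via Rsamtools) or accept an in-memory
# alignment table as produced by simulate_pool_reads().
read_alignments <- function(alignments) {
  if (is.data.frame(alignments)) {
    aln <- as.data.table(alignments)
    stopifnot(all(c("flag", "rname", "pos", "mapq", "cigar", "seq", "qual") %in%
                    names(aln)))
    return(aln)
  }
  path <- alignments
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "mapq", "cigar", "seq", "qual")))[[1]]
  data.table(flag = res$flag, rname = as.character(res$rname), pos = res$pos,
             mapq = res$mapq, cigar = res$cigar,
             seq = as.character(res$seq), qual = as.character(res$qual))
}

#' Build pileup columns for one pool
#'
#' Converts coordinate-sorted alignments into per-position, per-allele
#' observations: read depth and summed base quality. Only primary, mapped,
#' non-duplicate alignments with mapping quality `>= min_mapq` contribute.
#' Missing calls (`N`) and quality-0 bases are excluded entirely (they do not
#' count toward depth). Insertions are recorded as `+SEQ` alleles and
#' deletions as `-L` alleles, both anchored at the base preceding the event;
#' the anchor base's match observation is replaced by the indel observation
#' for that read.
#'
#' @param alignments SAM/BAM path or an alignment `data.table`
#'   (`flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`, `qual`).
#' @param reference FASTA path, `DNAStringSet`, named character vector or
#'   `pool_sim` object; used to validate scaffold names.
#' @param params A [call_params()].
#' @return A `data.table` of class `pileup`: `scaffold`, `pos`, `allele`,
#'   `depth`, `qual_sum`, one row per observed allele per covered position.
#' @export
pileup_columns <- function(alignments, reference, params = call_params()) {
  aln <- read_alignments(alignments)
  seqs <- load_reference(reference)
  empty <- data.table(scaffold = character(), pos = integer(),
                      allele = character(), depth = integer(),
                      qual_sum = numeric())
  if (!nrow(aln)) return(structure(empty, class = c("pileup", class(empty))))

  bad <- setdiff(unique(aln$rname), names(seqs))
  if (length(bad))
    stop("reference/alignment name mismatch: ", paste(bad, collapse = ", "))
  # coordinate-sortedness: positions non-decreasing within contiguous
  # scaffold blocks, each scaffold appearing in a single block
  rl <- rle(aln$rname)
  if (anyDuplicated(rl$values))
    stop("unsorted input: alignments for a scaffold are not contiguous")
  if (any(vapply(split(aln$pos, factor(aln$rname, levels = rl$values)),
                 is.unsorted, logical(1))))
    stop("unsorted input: alignment positions are not sorted")

  keep <- !bitwAnd(aln$flag, 0x4) & !bitwAnd(aln$flag, 0x100) &
    !bitwAnd(aln$flag, 0x800) & !bitwAnd(aln$flag, 0x400) &
    aln$mapq >= params$min_mapq
  aln <- aln[keep]
  if (!nrow(aln)) return(structure(empty, class = c("pileup", class(empty))))

  lens <- nchar(aln$seq)
  simple <- aln$cigar == sprintf("%dM", lens)
  obs <- vector("list", 2L)

  if (any(simple)) {
    a <- aln[simple]
    ql <- nchar(a$seq)
    idx <- sequence(ql)
    obs[[1L]] <- data.table(
      scaffold = rep(a$rname, ql),
      pos = rep(a$pos, ql) + idx - 1L,
      allele = unlist(strsplit(a$seq, "", fixed = TRUE), use.names = FALSE),
      q = unlist(phred_decode(a$qual), use.names = FALSE))
  }
  if (any(!simple)) {
    a <- aln[!simple]
    ops <- GenomicAlignments::explodeCigarOps(a$cigar)
    opl <- GenomicAlignments::explodeCigarOpLengths(a$cigar)
    rows <- vector("list", nrow(a))
    for (i in seq_len(nrow(a))) {
      qv <- utf8ToInt(a$qual[i]) - 33L
      bv <- strsplit(a$seq[i], "", fixed = TRUE)[[1]]
      rpos <- a$pos[i]; qpos <- 1L
      pos_v <- integer(0); al_v <- character(0); q_v <- numeric(0)
      for (k in seq_along(ops[[i]])) {
        op <- ops[[i]][k]; ln <- opl[[i]][k]
        if (op %in% c("M", "=", "X")) {
          pos_v <- c(pos_v, rpos + seq_len(ln) - 1L)
          al_v <- c(al_v, bv[qpos + seq_len(ln) - 1L])
          q_v <- c(q_v, qv[qpos + seq_len(ln) - 1L])
          rpos <- rpos + ln; qpos <- qpos + ln
        } else if (op == "I") {
          ins <- paste(bv[qpos + seq_len(ln) - 1L], collapse = "")
          anchor <- rpos - 1L
          drop <- which(pos_v == anchor)
          if (length(drop)) {
            pos_v <- pos_v[-drop]; al_v <- al_v[-drop]; q_v <- q_v[-drop]
          }
          pos_v <- c(pos_v, anchor)
          al_v <- c(al_v, paste0("+", ins))
          q_v <- c(q_v, sum(qv[qpos + seq_len(ln) - 1L]))
          qpos <- qpos + ln
        } else if (op == "D") {
          anchor <- rpos - 1L
          aq <- q_v[match(anchor, pos_v)]
          drop <- which(pos_v == anchor)
          if (length(drop)) {
            pos_v <- pos_v[-drop]; al_v <- al_v[-drop]; q_v <- q_v[-drop]
          }
          pos_v <- c(pos_v, anchor)
          al_v <- c(al_v, paste0("-", ln))
          q_v <- c(q_v, if (is.na(aq)) 0 else aq)
          rpos <- rpos + ln
        } else if (op %in% c("S", "H")) {
          if (op == "S") qpos <- qpos + ln
        } else if (op == "N") {
          rpos <- rpos + ln
        }
      }
      rows[[i]] <- data.table(scaffold = a$rname[i], pos = pos_v,
                              allele = al_v, q = q_v)
    }
    obs[[2L]] <- rbindlist(rows)
  }
  dt <- rbindlist(obs[!vapply(obs, is.null, logical(1))])
  dt <- dt[allele != "N" & q > 0]
  cols <- dt[, .(depth = .N, qual_sum = sum(q)), by = .(scaffold, pos, allele)]
  setorder(cols, scaffold, pos, allele)
  structure(cols, class = c("pileup", class(cols)))
}

#' Covered length at the calling depth floor
#'
#' Number of reference positions whose total depth reaches `min_coverage` --
#' the denominator used for per-pool SNP densities.
#'
#' @param columns A [pileup_columns()] table for one pool.
#' @param params A [call_params()].
#' @return Integer count of positions (bp).
#' @export
covered_length <- function(columns, params = call_params()) {
  if (!nrow(columns)) return(0L)
  tot <- columns[, .(depth = sum(depth)), by = .(scaffold, pos)]
  sum(tot$depth >= params$min_coverage)
}

#' Call variants in one pool from pileup columns
#'
#' Positions below `min_coverage` total depth are skipped. At a covered
#' position, alleles with at least `min_allele_reads` reads are *supported*.
#' With two or more supported alleles, the call quality is the minimum
#' `qual_sum` over the supported non-majority alleles: the position yields a
#' polymorphic call when that quality reaches `min_quality`, otherwise it is
#' retained as a monomorphic call on the majority allele. Positions with
#' exactly one supported allele are retained as monomorphic calls without any
#' quality test (needed for fixed-difference comparisons between pools).
#' Majority ties are broken lexicographically.
#'
#' @param columns A [pileup_columns()] table for one pool.
#' @param reference Reference (for the reference allele at each call).
#' @param params A [call_params()].
#' @return A `data.table` with one row per called position: `scaffold`,
#'   `pos`, `ref`, `status` (`"polymorphic"`/`"monomorphic"`), `kind`
#'   (`"SNP"`/`"INDEL"`), `alleles` (comma-joined supported alleles),
#'   `major_allele`, `depth` (supported-allele depth), `maf`, `quality`
#'   and `counts` (e.g. `"A:12,G:5"`).
#' @export
call_pool_variants <- function(columns, reference, params = call_params()) {
  seqs <- load_reference(reference)
  empty <- data.table(scaffold = character(), pos = integer(), ref = character(),
                      status = character(), kind = character(), alleles = character(),
                      major_allele = character(), depth = integer(), maf = numeric(),
                      quality = numeric(), counts = character())
  if (!nrow(columns)) return(empty)
  tot <- columns[, .(total_depth = sum(depth)), by = .(scaffold, pos)]
  covered <- tot[total_depth >= params$min_coverage]
  if (!nrow(covered)) return(empty)
  sup <- columns[covered, on = .(scaffold, pos)][depth >= params$min_allele_reads]
  if (!nrow(sup)) return(empty)
  setorder(sup, scaffold, pos, -depth, allele)  # majority first, ties lexicographic
  calls <- sup[, {
    n_sup <- .N
    if (n_sup == 1L) {
      list(status = "monomorphic", alleles = allele[1L],
           major_allele = allele[1L], depth = depth[1L], maf = 1,
           quality = NA_real_, counts = sprintf("%s:%d", allele[1L], depth[1L]))
    } else {
      qual <- min(qual_sum[-1L])
      if (qual >= params$min_quality) {
        list(status = "polymorphic", alleles = paste(allele, collapse = ","),
             major_allele = allele[1L], depth = sum(depth),
             maf = depth[1L] / sum(depth), quality = qual,
             counts = paste(sprintf("%s:%d", allele, depth), collapse = ","))
      } else {
        list(status = "monomorphic", alleles = allele[1L],
             major_allele = allele[1L], depth = depth[1L], maf = 1,
             quality = qual, counts = sprintf("%s:%d", allele[1L], depth[1L]))
      }
    }
  }, by = .(scaffold, pos)]
  calls[, ref := substring(seqs[[.BY$scaffold]], pos, pos), by = scaffold]
  calls[, kind := ifelse(vapply(strsplit(alleles, ",", fixed = TRUE),
                                function(a) any(is_indel_allele(a)), logical(1)),
                         "INDEL", "SNP")]
  setcolorder(calls, c("scaffold", "pos", "ref", "status", "kind", "alleles",
                       "major_allele", "depth", "maf", "quality", "counts"))
  calls[]
}

#' Variant kind of a call
#'
#' `"INDEL"` when any supported allele is an insertion (`+SEQ`) or deletion
#' (`-L`) descriptor, otherwise `"SNP"`.
#'
#' @param alleles Character vector of allele descriptors (or a comma-joined
#'   scalar as stored in call tables).
#' @return `"SNP"` or `"INDEL"`.
#' @export
classify_kind <- function(alleles) {
  if (length(alleles) == 1L && grepl(",", alleles, fixed = TRUE))
    alleles <- strsplit(alleles, ",", fixed = TRUE)[[1]]
  if (any(is_indel_allele(alleles))) "INDEL" else "SNP"
}

#' Per-pool calling profile
#'
#' Bundles one pool's pileup, its covered length at the calling floor and its
#' variant calls -- the row unit of the per-pool diversity summary.
#'
#' @param pool_id Pool identifier (integer or name).
#' @param alignments SAM/BAM path or alignment table for this pool.
#' @param reference Reference genome.
#' @param params A [call_params()].
#' @return A list of class `pool_profile`: `pool_id`, `covered_length`,
#'   `calls`, `columns`.
#' @export
pool_profile <- function(pool_id, alignments, reference, params = call_params()) {
  cols <- pileup_columns(alignments, reference, params)
  structure(list(pool_id = pool_id,
                 covered_length = covered_length(cols, params),
                 calls = call_pool_variants(cols, reference, params),
                 columns = cols, params = params),
            class = "pool_profile")
}

#' @export
print.pool_profile <- function(x, ...) {
  cat(sprintf("pool_profile %s: %s bp covered >= %dX, %d calls (%d polymorphic)\n",
              x$pool_id, format(x$covered_length, big.mark = ","),
              x$params$min_coverage, nrow(x$calls),
              sum(x$calls$status == "polymorphic")))
  invisible(x)
}

#' Merge per-pool calls into a multi-pool variant table
#'
#' One record per position where at least two distinct alleles are supported
#' across pools combined, or where a non-reference allele is fixed in at
#' least one pool. Each record carries per-pool status
#' (`polymorphic` / `fixed_ref` / `fixed_alt` / `no_call` / `no_coverage`),
#' per-pool supported-allele depths and MAF (where the pool reaches
#' `min_coverage`), and the global MAF from depths summed over covered pools.
#'
#' @param profiles List of [pool_profile()] objects (distinct `pool_id`s).
#' @param reference Reference genome.
#' @param params A [call_params()].
#' @return A `data.table` of class `pool_variants`, one row per variant:
#'   `scaffold`, `pos`, `ref`, `alleles`, `kind`, `global_maf`,
#'   `n_pools_covered`, and per pool `<pool>_status`, `<pool>_allele` (the
#'   single supported allele when fixed, the majority when polymorphic),
#'   `<pool>_depth`, `<pool>_maf`, `<pool>_counts`. The pool identifiers are
#'   stored in `attr(, "pools")`.
#' @export
merge_pool_calls <- function(profiles, reference, params = call_params()) {
  ids <- vapply(profiles, function(p) as.character(p$pool_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate pool ids: ", ids[duplicated(ids)][1])
  seqs <- load_reference(reference)
  pools <- if (all(grepl("^[0-9]+$", ids))) paste0("pool", ids) else ids

  # candidate positions: polymorphic anywhere, or fixed non-reference anywhere
  cand <- rbindlist(lapply(profiles, function(p) {
    cl <- p$calls
    cl[status == "polymorphic" | (status == "monomorphic" & major_allele != ref),
       .(scaffold, pos)]
  }))
  out_cols <- c("scaffold", "pos", "ref", "alleles", "kind", "global_maf",
                "n_pools_covered",
                unlist(lapply(pools, function(pn)
                  paste0(pn, c("_status", "_allele", "_depth", "_maf", "_counts")))))
  if (!nrow(cand)) {
    empty <- setNames(data.table(matrix(nrow = 0, ncol = length(out_cols))), out_cols)
    setattr(empty, "pools", pools)
    return(empty)
  }
  cand <- unique(cand)
  setorder(cand, scaffold, pos)

  glob <- new.env(); glob$depth <- list()
  per_pool <- vector("list", length(profiles))
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    tot <- p$columns[, .(total_depth = sum(depth)), by = .(scaffold, pos)]
    cv <- tot[cand, on = .(scaffold, pos)]
    cv[is.na(total_depth), total_depth := 0L]
    calls <- p$calls[cand, on = .(scaffold, pos)]
    st <- ifelse(cv$total_depth < params$min_coverage, "no_coverage",
          ifelse(is.na(calls$status), "no_call",
          ifelse(calls$status == "polymorphic", "polymorphic",
          ifelse(calls$major_allele == calls$ref, "fixed_ref", "fixed_alt"))))
    per_pool[[k]] <- data.table(
      scaffold = cand$scaffold, pos = cand$pos, status = st,
      allele = calls$major_allele, depth = calls$depth, maf = calls$maf,
      counts = calls$counts, alleles = calls$alleles)
    per_pool[[k]][status %in% c("no_coverage", "no_call"),
                  `:=`(allele = NA_character_, depth = NA_integer_,
                       maf = NA_real_, counts = NA_character_,
                       alleles = NA_character_)]
  }

  # global allele depths from supported alleles of covered pools
  allele_rows <- rbindlist(lapply(seq_along(profiles), function(k) {
    pp <- per_pool[[k]][!is.na(counts)]
    if (!nrow(pp)) return(NULL)
    spl <- strsplit(pp$counts, ",", fixed = TRUE)
    nn <- lengths(spl)
    flat <- unlist(spl, use.names = FALSE)
    mm <- regmatches(flat, regexpr(":[0-9]+$", flat))
    data.table(scaffold = rep(pp$scaffold, nn), pos = rep(pp$pos, nn),
               allele = substr(flat, 1L, nchar(flat) - nchar(mm)),
               depth = as.integer(sub(":", "", mm)))
  }))
  gsum <- allele_rows[, .(depth = sum(depth)), by = .(scaffold, pos, allele)]
  setorder(gsum, scaffold, pos, -depth, allele)
  gstat <- gsum[, .(alleles = paste(allele, collapse = ","),
                    global_maf = depth[1L] / sum(depth),
                    n_alleles = .N), by = .(scaffold, pos)]

  res <- gstat[cand, on = .(scaffold, pos)]
  res[, ref := substring(seqs[[.BY$scaffold]], pos, pos), by = scaffold]
  res[, kind := vapply(strsplit(alleles, ",", fixed = TRUE),
                       function(a) if (any(is_indel_allele(a))) "INDEL" else "SNP",
                       character(1))]
  covered_mat <- vapply(per_pool, function(pp)
    !pp$status %in% c("no_coverage"), logical(nrow(cand)))
  if (is.null(dim(covered_mat))) covered_mat <- matrix(covered_mat, nrow = nrow(cand))
  res[, n_pools_covered := rowSums(covered_mat)]
  for (k in seq_along(pools)) {
    pn <- pools[k]
    res[, paste0(pn, "_status") := per_pool[[k]]$status]
    res[, paste0(pn, "_allele") := per_pool[[k]]$allele]
    res[, paste0(pn, "_depth") := per_pool[[k]]$depth]
    res[, paste0(pn, "_maf") := per_pool[[k]]$maf]
    res[, paste0(pn, "_counts") := per_pool[[k]]$counts]
  }
  # record filter: >=2 distinct supported alleles overall, or fixed non-ref
  fa_mat <- vapply(per_pool, function(pp) pp$status == "fixed_alt",
                   logical(nrow(cand)))
  if (is.null(dim(fa_mat))) fa_mat <- matrix(fa_mat, nrow = nrow(cand))
  fixed_nonref <- rowSums(fa_mat) > 0
  res <- res[n_alleles >= 2L | fixed_nonref]
  res[, n_alleles := NULL]
  setcolorder(res, out_cols)
  setattr(res, "pools", pools)
  res[]
}
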