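#' Simulation configuration for pooled transcriptome resequencing
#'
#' Builds the configuration object driving the synthetic-data generator: a toy
#' genome with multi-exon gene models, pool-structured truth variants, and
#' per-pool exon-confined short reads with per-base Phred qualities,
#' substitution errors and occasional missing calls.
#'
#' The defaults define the simulated study conditions: 8 pools of 49-bp reads
#' at a mean 30-fold coverage, a 1% mean substitution rate and 0.5% missing
#' calls, with a small fraction of exons expressed so lowly that their
#' coverage falls below the 6X calling floor.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_scaffolds,scaffold_len Number and length (bp) of genome scaffolds.
#' @param genes_per_scaffold Genes laid out per scaffold.
#' @param exons_per_gene,exon_len,intron_len,utr_len Gene structure in bp.
#'   Each gene is UTR5--CDS--UTR3 across `exons_per_gene` exons separated by
#'   introns; the UTRs occupy the outer `utr_len` bp of the terminal exons.
#' @param n_pools Number of sequenced pools (default 8).
#' @param read_len Read length in bp (default 49).
#' @param per_pool_depth Mean fold-coverage per pool over exons.
#' @param error_rate Mean per-base substitution probability. Errors are
#'   quality-aware: each base's substitution probability is proportional to
#'   `10^(-Q/10)` for its drawn quality Q, rescaled so the mean equals
#'   `error_rate`. `0` disables substitution errors.
#' @param missing_rate Per-base probability of a missing call (an `N` with
#'   quality 0), the base-space proxy for colorspace missing calls.
#' @param low_coverage_exon_frac Fraction of exons assigned a low expression
#'   level (coverage multiplied by `low_coverage_factor`), the same exons in
#'   every pool; no truth variants are planted in them.
#' @param low_coverage_factor Depth multiplier for low-coverage exons.
#' @param n_variants_per_class Named integer vector of planted variant counts
#'   per class. Recognised classes: `shared_all` (0 < freq < 1 in every pool),
#'   `pool_specific` (polymorphic in exactly one pool), `fixed_differential`
#'   (fixed 1.0/0.0 between `fixed_diff_pools`), `background` (arbitrary
#'   pool pattern), `near_intron` (within 60 bp of an intron boundary),
#'   `clustered` (pairs closer than 61 bp to each other) and `indel`
#'   (short insertions/deletions). `clustered` counts pairs.
#' @param fixed_diff_pools Length-2 integer vector: the pool fixed for the
#'   alternate allele and the pool fixed for the reference allele.
#' @param min_flank Minimum distance (bp) of planted variants from intron
#'   boundaries and from each other, except for the dedicated classes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 2L,
                       scaffold_len = 32000L,
                       genes_per_scaffold = 16L,
                       exons_per_gene = 3L,
                       exon_len = 400L,
                       intron_len = 200L,
                       utr_len = 100L,
                       n_pools = 8L,
                       read_len = 49L,
                       per_pool_depth = 30,
                       error_rate = 0.01,
                       missing_rate = 0.005,
                       low_coverage_exon_frac = 0.08,
                       low_coverage_factor = 0.1,
                       n_variants_per_class = c(shared_all = 50L,
                                                pool_specific = 30L,
                                                fixed_differential = 20L,
                                                background = 80L,
                                                near_intron = 20L,
                                                clustered = 12L,
                                                indel = 8L),
                       fixed_diff_pools = c(1L, 8L),
                       min_flank = 61L) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_len = as.integer(scaffold_len),
              genes_per_scaffold = as.integer(genes_per_scaffold),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
              utr_len = as.integer(utr_len), n_pools = as.integer(n_pools),
              read_len = as.integer(read_len), per_pool_depth = per_pool_depth,
              error_rate = error_rate, missing_rate = missing_rate,
              low_coverage_exon_frac = low_coverage_exon_frac,
              low_coverage_factor = low_coverage_factor,
              n_variants_per_class = n_variants_per_class,
              fixed_diff_pools = as.integer(fixed_diff_pools),
              min_flank = as.integer(min_flank))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$per_pool_depth < 0) stop("per_pool_depth must be >= 0")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.1)
    stop("error_rate must be in [0, 0.1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 0.1)
    stop("missing_rate must be in [0, 0.1)")
  if (cfg$read_len > cfg$exon_len)
    stop("read_len must not exceed exon_len")
  if (cfg$utr_len >= cfg$exon_len)
    stop("utr_len must be smaller than exon_len")
  if (any(cfg$n_variants_per_class < 0)) stop("variant counts must be >= 0")
  if (length(cfg$fixed_diff_pools) != 2L ||
      any(cfg$fixed_diff_pools < 1L | cfg$fixed_diff_pools > cfg$n_pools) ||
      cfg$fixed_diff_pools[1] == cfg$fixed_diff_pools[2])
    stop("fixed_diff_pools must name two distinct pools")
  span <- gene_span(cfg)
  if (cfg$genes_per_scaffold > 0 &&
      cfg$genes_per_scaffold * span + (cfg$genes_per_scaffold + 1L) * 50L > cfg$scaffold_len)
    stop("configuration error: gene models (exon/intron lengths) exceed scaffold length")
  invisible(cfg)
}

gene_span <- function(cfg) {
  cfg$exons_per_gene * cfg$exon_len + (cfg$exons_per_gene - 1L) * cfg$intron_len
}

#' Generate a toy genome and gene models
#'
#' Draws random scaffold sequences and lays out multi-exon genes with
#' UTR5--CDS--UTR3 structure on alternating strands, evenly spaced along each
#' scaffold. A fixed fraction of exons is marked low-coverage (emulating lowly
#' expressed genes, shared across pools since the pools derive from the same
#' normalised cDNA protocol). Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `pool_sim`: list with `genome`
#'   (a [Biostrings::DNAStringSet]), `seqs` (named character), `features`
#'   (GFF3-writable feature table), `exons` (per-exon table with the
#'   low-coverage flag) and `config`.
#' @export
make_genome <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_scaffolds), function(i) {
      paste(sample(DNA_BASES, config$scaffold_len, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("scaffold%02d", seq_len(config$n_scaffolds))

    feats <- list(); exons <- list()
    span <- gene_span(config)
    E <- config$exons_per_gene
    for (sc in names(seqs)) {
      ng <- config$genes_per_scaffold
      if (ng == 0L) next
      gap <- (config$scaffold_len - ng * span) %/% (ng + 1L)
      for (g in seq_len(ng)) {
        gid <- sprintf("gene_%s_%02d", sub("scaffold", "s", sc), g)
        gstart <- gap * g + span * (g - 1L) + 1L
        gend <- gstart + span - 1L
        strand <- if (g %% 2L == 1L) "+" else "-"
        ex_start <- gstart + (seq_len(E) - 1L) * (config$exon_len + config$intron_len)
        ex_end <- ex_start + config$exon_len - 1L
        mid <- paste0(gid, ".t1")
        rows <- list(
          data.table(gene_id = gid, scaffold = sc, strand = strand,
                     type = "gene", start = gstart, end = gend,
                     ID = gid, Parent = NA_character_),
          data.table(gene_id = gid, scaffold = sc, strand = strand,
                     type = "mRNA", start = gstart, end = gend,
                     ID = mid, Parent = gid),
          data.table(gene_id = gid, scaffold = sc, strand = strand,
                     type = "exon", start = ex_start, end = ex_end,
                     ID = sprintf("%s.exon%d", mid, seq_len(E)), Parent = mid)
        )
        u <- config$utr_len
        if (strand == "+") {
          utr5 <- c(ex_start[1L], ex_start[1L] + u - 1L)
          utr3 <- c(ex_end[E] - u + 1L, ex_end[E])
        } else {
          utr3 <- c(ex_start[1L], ex_start[1L] + u - 1L)
          utr5 <- c(ex_end[E] - u + 1L, ex_end[E])
        }
        cds_start <- ex_start; cds_end <- ex_end
        # trim the UTR off the terminal exons
        cds_start[1L] <- ex_start[1L] + u
        cds_end[E] <- ex_end[E] - u
        rows <- c(rows, list(
          data.table(gene_id = gid, scaffold = sc, strand = strand,
                     type = "five_prime_UTR", start = utr5[1], end = utr5[2],
                     ID = paste0(mid, ".utr5"), Parent = mid),
          data.table(gene_id = gid, scaffold = sc, strand = strand,
                     type = "three_prime_UTR", start = utr3[1], end = utr3[2],
                     ID = paste0(mid, ".utr3"), Parent = mid),
          data.table(gene_id = gid, scaffold = sc, strand = strand,
                     type = "CDS", start = cds_start, end = cds_end,
                     ID = paste0(mid, ".cds"), Parent = mid)
        ))
        feats[[length(feats) + 1L]] <- rbindlist(rows)
        exons[[length(exons) + 1L]] <- data.table(
          exon_id = sprintf("%s.exon%d", mid, seq_len(E)), gene_id = gid,
          scaffold = sc, start = ex_start, end = ex_end, rank = seq_len(E),
          left_intron = seq_len(E) > 1L, right_intron = seq_len(E) < E)
      }
    }
    features <- if (length(feats)) rbindlist(feats) else
      data.table(gene_id = character(), scaffold = character(), strand = character(),
                 type = character(), start = integer(), end = integer(),
                 ID = character(), Parent = character())
    exons <- if (length(exons)) rbindlist(exons) else
      data.table(exon_id = character(), gene_id = character(), scaffold = character(),
                 start = integer(), end = integer(), rank = integer(),
                 left_intron = logical(), right_intron = logical())
    exons[, low_coverage := if (.N) runif(.N) < config$low_coverage_exon_frac else logical(0)]

    out <- list(genome = Biostrings::DNAStringSet(seqs), seqs = seqs,
                features = features, exons = exons, config = config)
    class(out) <- "pool_sim"
    out
  })
}

#' @export
print.pool_sim <- function(x, ...) {
  cat(sprintf("pool_sim: %d scaffold(s) of %s bp, %d genes, %d exons (%d low-coverage)\n",
              length(x$seqs), format(x$config$scaffold_len, big.mark = ","),
              sum(x$features$type == "gene"), nrow(x$exons),
              sum(x$exons$low_coverage)))
  invisible(x)
}

#' Write the simulated genome as FASTA
#' @param sim A `pool_sim` object.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(sim, path) {
  Biostrings::writeXStringSet(sim$genome, path)
  invisible(path)
}

#' Write the simulated gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features with
#' 1-based inclusive coordinates.
#'
#' @param sim A `pool_sim` object.
#' @param path Output GFF3 path.
#' @export
write_gene_gff3 <- function(sim, path) {
  f <- sim$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$scaffold, ranges = IRanges::IRanges(f$start, f$end),
    strand = f$strand)
  GenomeInfoDb::seqlengths(gr) <- nchar(sim$seqs)[GenomeInfoDb::seqlevels(gr)]
  gr$type <- f$type
  gr$ID <- f$ID
  # CDS phase in translation order within each gene
  phase <- rep(NA_integer_, nrow(f))
  for (g in unique(f$gene_id)) {
    ci <- which(f$gene_id == g & f$type == "CDS")
    if (!length(ci)) next
    ord <- if (f$strand[ci[1]] == "+") order(f$start[ci]) else order(-f$start[ci])
    lens <- (f$end - f$start + 1L)[ci][ord]
    cum <- c(0L, cumsum(lens))[seq_along(lens)]
    phase[ci[ord]] <- (3L - cum %% 3L) %% 3L
  }
  gr$phase <- phase
  gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
    lapply(f$Parent, function(p) if (is.na(p)) character(0) else p)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Sample one planting position from candidate intervals, rejecting positions
# closer than `gap` bp to anything already placed on the same scaffold.
sample_position <- function(cand, placed, gap, tries = 2000L) {
  wts <- cand$end - cand$start + 1L
  keep <- wts > 0L
  cand <- cand[keep]; wts <- wts[keep]
  if (!nrow(cand)) stop("generation error: insufficient exonic space for planting")
  for (i in seq_len(tries)) {
    j <- sample.int(nrow(cand), 1L, prob = wts)
    pos <- cand$start[j] + sample.int(wts[j], 1L) - 1L
    sc <- cand$scaffold[j]
    if (!length(placed[[sc]]) || all(abs(placed[[sc]] - pos) >= gap))
      return(list(scaffold = sc, pos = pos, exon = cand$exon_id[j]))
  }
  stop("generation error: insufficient exonic space for planting")
}

#' Plant pool-structured truth variants
#'
#' Places variants of the requested classes at exonic positions of the
#' simulated genome, at least `min_flank` bp from any intron boundary and from
#' each other -- except the dedicated `near_intron` class (placed 48--59 bp from
#' a junction) and the `clustered` class (pairs 10--60 bp apart). Variants are
#' planted only in normally covered exons. Per-pool alternate-allele
#' frequencies follow the class definitions (see [sim_config()]).
#'
#' @param sim A `pool_sim` object.
#' @param config Configuration; defaults to the one stored in `sim`.
#' @return A `data.table` with one row per truth variant: `id`, `scaffold`,
#'   `pos`, `ref`, `alt`, `class`, `kind` and `freq_pool1..freq_poolN`.
#' @export
plant_variants <- function(sim, config = sim$config) {
  counts <- config$n_variants_per_class
  P <- config$n_pools
  fcols <- paste0("freq_", pool_names(P))
  empty <- data.table(id = character(), scaffold = character(), pos = integer(),
                      ref = character(), alt = character(), class = character(),
                      kind = character())
  for (fc in fcols) empty[, (fc) := numeric(0)]
  if (!length(counts) || sum(counts) == 0L) return(empty[])

  ex <- sim$exons[low_coverage == FALSE]
  if (!nrow(ex) && sum(counts) > 0L)
    stop("generation error: no usable exons to plant variants in")
  m <- config$min_flank - 1L  # distance kept from junctions (>= 61 bp rule)
  interior <- ex[, .(exon_id, scaffold,
                     start = start + m, end = end - m)]
  # near-intron candidates: 48-59 bp from a junction, still on the full-coverage
  # plateau of the exon (reads are exon-confined, so coverage ramps at edges)
  ni <- rbind(
    ex[left_intron == TRUE, .(exon_id, scaffold, start = start + 47L, end = start + 58L)],
    ex[right_intron == TRUE, .(exon_id, scaffold, start = end - 58L, end = end - 47L)])

  withr::with_seed(config$seed + 2L, {
    placed <- setNames(vector("list", length(sim$seqs)), names(sim$seqs))
    recs <- list()
    add_rec <- function(sc, pos, class, alt = NULL) {
      ref <- substr(sim$seqs[[sc]], pos, pos)
      if (is.null(alt)) alt <- sample(setdiff(DNA_BASES, ref), 1L)
      placed[[sc]] <<- c(placed[[sc]], pos)
      recs[[length(recs) + 1L]] <<- data.table(
        scaffold = sc, pos = as.integer(pos), ref = ref, alt = alt,
        class = class)
    }
    for (cls in c("shared_all", "pool_specific", "fixed_differential",
                  "background", "indel", "near_intron", "clustered")) {
      n <- as.integer(counts[cls] %||% 0L)
      if (is.na(n) || n == 0L) next
      if (cls == "clustered") {
        for (i in seq_len(n)) {
          # anchor needs room for a partner up to 60 bp downstream
          anc_cand <- copy(interior)[, end := end - 60L]
          p1 <- sample_position(anc_cand, placed, config$min_flank)
          d <- sample(10:60, 1L)
          p2 <- p1$pos + d
          tries <- 0L
          while (length(placed[[p1$scaffold]]) &&
                 any(abs(placed[[p1$scaffold]] - p2) < config$min_flank)) {
            p1 <- sample_position(anc_cand, placed, config$min_flank)
            d <- sample(10:60, 1L)
            p2 <- p1$pos + d
            tries <- tries + 1L
            if (tries > 2000L) stop("generation error: cannot place clustered pair")
          }
          add_rec(p1$scaffold, p1$pos, "clustered")
          add_rec(p1$scaffold, p2, "clustered")
        }
      } else if (cls == "near_intron") {
        for (i in seq_len(n)) {
          p <- sample_position(ni, placed, config$min_flank)
          add_rec(p$scaffold, p$pos, "near_intron")
        }
      } else if (cls == "indel") {
        for (i in seq_len(n)) {
          p <- sample_position(interior, placed, config$min_flank)
          if (i %% 2L == 1L) {
            ins <- paste(sample(DNA_BASES, sample(1:2, 1L), replace = TRUE),
                         collapse = "")
            add_rec(p$scaffold, p$pos, "indel", alt = paste0("+", ins))
          } else {
            add_rec(p$scaffold, p$pos, "indel", alt = paste0("-", sample(1:2, 1L)))
          }
        }
      } else {
        for (i in seq_len(n)) {
          p <- sample_position(interior, placed, config$min_flank)
          add_rec(p$scaffold, p$pos, cls)
        }
      }
    }
    truth <- rbindlist(recs)
    truth[, kind := ifelse(is_indel_allele(alt), "INDEL", "SNP")]

    # per-pool alternate-allele frequencies, by class
    fq <- matrix(0, nrow = nrow(truth), ncol = P)
    for (cls in unique(truth$class)) {
      idx <- which(truth$class == cls)
      fq[idx, ] <- switch(cls,
        shared_all = , near_intron = , indel =
          matrix(runif(length(idx) * P, 0.3, 0.7), ncol = P),
        clustered = {
          # anchors look like shared_all; partners (the flanking variants)
          # carry one uniform alternate frequency in (0.05, 0.5) so their
          # global MAFs spread over (0.5, 0.95) and the neighbour-MAF
          # threshold of the flanking filter has gradations to act on
          mm <- matrix(runif(length(idx) * P, 0.3, 0.7), ncol = P)
          partners <- seq_along(idx) %% 2L == 0L
          mm[partners, ] <- runif(sum(partners), 0.05, 0.5)
          mm
        },
        pool_specific = {
          mm <- matrix(0, length(idx), P)
          tgt <- rep(seq_len(P), length.out = length(idx))
          mm[cbind(seq_along(idx), tgt)] <- runif(length(idx), 0.3, 0.7)
          mm
        },
        fixed_differential = {
          mm <- matrix(0, length(idx), P)
          mm[, config$fixed_diff_pools[1]] <- 1
          mm[, config$fixed_diff_pools[2]] <- 0
          mm
        },
        background = {
          mm <- matrix(runif(length(idx) * P, 0.2, 0.8), ncol = P)
          mm[matrix(runif(length(idx) * P) < 0.5, ncol = P)] <- 0
          mm
        })
    }
    for (j in seq_len(P)) truth[, (fcols[j]) := fq[, j]]
    setorder(truth, scaffold, pos)
    truth[, id := sprintf("tv%04d", .I)]
    setcolorder(truth, c("id", "scaffold", "pos", "ref", "alt", "class", "kind"))
    truth[]
  })
}

#' Per-pool truth frequency matrix
#' @param truth Truth table from [plant_variants()].
#' @return Numeric matrix, one row per variant, one column per pool.
#' @export
truth_freq_matrix <- function(truth) {
  fcols <- grep("^freq_pool", names(truth), value = TRUE)
  mm <- as.matrix(truth[, fcols, with = FALSE])
  colnames(mm) <- sub("^freq_", "", fcols)
  rownames(mm) <- truth$id
  mm
}

#' Write the truth table as TSV
#' @param truth Truth table.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' Write the truth table as VCF
#'
#' Indel descriptors (`+SEQ` insertions, `-L` deletions) are converted to
#' anchored REF/ALT representation. Per-pool alternate frequencies go in the
#' INFO column, together with the variant class.
#'
#' @param truth Truth table.
#' @param sim The `pool_sim` the truth was planted in (for reference bases).
#' @param path Output VCF path.
#' @export
write_truth_vcf <- function(truth, sim, path) {
  seqs <- sim$seqs
  P <- sim$config$n_pools
  fcols <- paste0("freq_", pool_names(P))
  anch <- vcf_anchor_alleles(truth$scaffold, truth$pos, truth$ref,
                             lapply(truth$alt, identity), seqs)
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(seqs), nchar(seqs)),
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Planted variant class\">",
    sprintf("##INFO=<ID=AF%d,Number=1,Type=Float,Description=\"Planted alternate frequency in pool %d\">",
            seq_len(P), seq_len(P)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(truth)), function(i) {
    paste0("CLASS=", truth$class[i], ";",
           paste(sprintf("AF%d=%s", seq_len(P),
                         format(unlist(truth[i, fcols, with = FALSE]), digits = 4)),
                 collapse = ";"))
  }, character(1))
  body <- paste(truth$scaffold, anch$pos, truth$id, anch$ref,
                vapply(anch$alt, paste, character(1), collapse = ","),
                ".", "PASS", info, sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

# Convert internal allele descriptors to anchored VCF REF/ALT.
# alleles: list of character vectors (may mix SNP bases and +SEQ/-L descriptors).
vcf_anchor_alleles <- function(scaffold, pos, ref, alleles, seqs) {
  n <- length(pos)
  out_ref <- character(n); out_alt <- vector("list", n); out_pos <- as.integer(pos)
  for (i in seq_len(n)) {
    al <- setdiff(alleles[[i]], ref[i])
    dels <- al[startsWith(al, "-")]
    maxdel <- if (length(dels)) max(as.integer(sub("^-", "", dels))) else 0L
    sc <- seqs[[scaffold[i]]]
    anchor_ref <- substr(sc, pos[i], pos[i] + maxdel)
    out_ref[i] <- anchor_ref
    out_alt[[i]] <- vapply(al, function(a) {
      if (startsWith(a, "+")) {
        paste0(ref[i], sub("^\\+", "", a), substr(sc, pos[i] + 1L, pos[i] + maxdel))
      } else if (startsWith(a, "-")) {
        L <- as.integer(sub("^-", "", a))
        paste0(ref[i], substr(sc, pos[i] + L + 1L, pos[i] + maxdel))
      } else {
        paste0(a, substr(sc, pos[i] + 1L, pos[i] + maxdel))
      }
    }, character(1), USE.NAMES = FALSE)
  }
  list(pos = out_pos, ref = out_ref, alt = out_alt)
}

#' Simulate aligned reads for one pool
#'
#' Samples exon-confined `read_len`-bp reads (no junction-spanning reads,
#' emulating unspliced cDNA-to-genome mapping). At each truth position a read
#' carries the alternate allele with the pool's planted frequency. Base
#' qualities follow a two-level model (high-quality body, decaying 3' tail);
#' substitution errors are quality-aware with mean `error_rate`; missing calls
#' are `N` with quality 0. Deterministic per `(seed, pool)`.
#'
#' @param sim A `pool_sim` object.
#' @param truth Truth table from [plant_variants()] (may be empty).
#' @param pool_id Pool index in `1..n_pools`.
#' @param config Configuration; defaults to the one stored in `sim`.
#' @param sam,fastq Optional output paths. The SAM is coordinate-sorted with a
#'   proper header; the FASTQ (Sanger Phred+33) holds the same reads.
#' @return Invisibly, a `data.table` of alignments: `qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`, `seq`, `qual`.
#' @export
simulate_pool_reads <- function(sim, truth, pool_id, config = sim$config,
                                sam = NULL, fastq = NULL) {
  if (!is.numeric(pool_id) || pool_id < 1L || pool_id > config$n_pools)
    stop("pool_id must be in 1..n_pools")
  pool_id <- as.integer(pool_id)
  L <- config$read_len
  fcol <- paste0("freq_", pool_names(config$n_pools)[pool_id])
  pool_seed <- (config$seed * 131L + pool_id * 7L) %% .Machine$integer.max

  withr::with_seed(pool_seed, {
    starts <- integer(0); rname <- character(0); seqv <- character(0)
    cigar <- character(0); ends <- integer(0)
    snp_sub <- list()  # deferred SNP substitutions: (read index, offset, alt)
    for (e in seq_len(nrow(sim$exons))) {
      ex <- sim$exons[e]
      depth_e <- config$per_pool_depth *
        (if (ex$low_coverage) config$low_coverage_factor else 1)
      n <- rpois(1L, depth_e * (ex$end - ex$start + 1L) / L)
      if (n == 0L) next
      st <- ex$start + sample.int(ex$end - ex$start - L + 2L, n, replace = TRUE) - 1L
      en <- st + L - 1L
      sq <- substring(sim$seqs[[ex$scaffold]], st, en)
      cg <- rep(sprintf("%dM", L), n)
      off0 <- length(starts)
      if (!is.null(truth) && nrow(truth)) {
        tv <- truth[scaffold == ex$scaffold & pos >= ex$start & pos <= ex$end]
        for (k in seq_len(nrow(tv))) {
          f <- tv[[fcol]][k]
          if (f <= 0) next
          cov <- which(st <= tv$pos[k] & en >= tv$pos[k])
          if (!length(cov)) next
          carriers <- cov[runif(length(cov)) < f]
          if (!length(carriers)) next
          off <- tv$pos[k] - st[carriers] + 1L
          alt <- tv$alt[k]
          if (!is_indel_allele(alt)) {
            snp_sub[[length(snp_sub) + 1L]] <-
              data.table(idx = off0 + carriers, off = off, alt = alt)
          } else if (startsWith(alt, "+")) {
            ins <- sub("^\\+", "", alt); m <- nchar(ins)
            for (jj in seq_along(carriers)) {
              o <- off[jj]
              if (o + m > L - 1L) next  # insertion would fall off the read end
              ci <- carriers[jj]
              sq[ci] <- paste0(substr(sq[ci], 1L, o), ins,
                               substr(sq[ci], o + 1L, L - m))
              cg[ci] <- sprintf("%dM%dI%dM", o, m, L - o - m)
              en[ci] <- en[ci] - m
            }
          } else {
            dl <- as.integer(sub("^-", "", alt))
            scseq <- sim$seqs[[ex$scaffold]]
            for (jj in seq_along(carriers)) {
              o <- off[jj]
              if (o >= L) next
              ci <- carriers[jj]
              p <- tv$pos[k]
              sq[ci] <- paste0(substr(scseq, st[ci], p),
                               substr(scseq, p + dl + 1L, st[ci] + L + dl - 1L))
              cg[ci] <- sprintf("%dM%dD%dM", o, dl, L - o)
              en[ci] <- en[ci] + dl
            }
          }
        }
      }
      starts <- c(starts, st); ends <- c(ends, en)
      rname <- c(rname, rep(ex$scaffold, n))
      seqv <- c(seqv, sq); cigar <- c(cigar, cg)
    }

    n_reads <- length(starts)
    if (n_reads > 0L) {
      # base matrix: positions x reads
      bm <- matrix(unlist(strsplit(seqv, "", fixed = TRUE), use.names = FALSE),
                   nrow = L)
      if (length(snp_sub)) {
        ss <- rbindlist(snp_sub)
        bm[cbind(ss$off, ss$idx)] <- ss$alt
      }
      # quality model: ~15% low-quality bases in the body, decaying 3' tail
      N <- L * n_reads
      q <- integer(N)
      low <- runif(N) < 0.15
      q[low] <- sample(10:14, sum(low), replace = TRUE)
      q[!low] <- sample(30:40, sum(!low), replace = TRUE)
      dim(q) <- c(L, n_reads)
      tail_len <- 6L
      ramp <- seq_len(tail_len) * 3L
      q[(L - tail_len + 1L):L, ] <- pmax(q[(L - tail_len + 1L):L, ] - ramp, 8L)
      # quality-aware substitution errors, mean rate calibrated to error_rate
      if (config$error_rate > 0) {
        eraw <- 10^(-q / 10)
        perr <- pmin(1, config$error_rate * eraw / mean(eraw))
        errm <- which(runif(N) < perr)
        if (length(errm)) {
          cur <- bm[errm]
          newb <- sample(DNA_BASES, length(errm), replace = TRUE)
          same <- which(newb == cur)
          while (length(same)) {
            newb[same] <- sample(DNA_BASES, length(same), replace = TRUE)
            same <- same[newb[same] == cur[same]]
          }
          bm[errm] <- newb
        }
      }
      if (config$missing_rate > 0) {
        miss <- which(runif(N) < config$missing_rate)
        if (length(miss)) {
          bm[miss] <- "N"
          q[miss] <- 0L
        }
      }
      seqv <- do.call(paste0, lapply(seq_len(L), function(i) bm[i, ]))
      qm <- matrix(intToUtf8(q + 33L, multiple = TRUE), nrow = L)
      qualv <- do.call(paste0, lapply(seq_len(L), function(i) qm[i, ]))
    } else {
      qualv <- character(0)
    }

    reads <- data.table(qname = sprintf("pool%d_r%06d", pool_id, seq_len(n_reads)),
                        flag = 0L, rname = rname, pos = starts, mapq = 60L,
                        cigar = cigar, seq = seqv, qual = qualv)
    setorder(reads, rname, pos)
    if (!is.null(sam)) write_sam(reads, nchar(sim$seqs), sam)
    if (!is.null(fastq)) {
      if (n_reads > 0L) {
        dna <- Biostrings::DNAStringSet(reads$seq)
        names(dna) <- reads$qname
        Biostrings::writeXStringSet(dna, fastq, format = "fastq",
                                    qualities = Biostrings::BStringSet(reads$qual))
      } else {
        file.create(fastq)
      }
    }
    invisible(reads)
  })
}

# Write a coordinate-sorted SAM file (header + alignment lines).
write_sam <- function(reads, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths))
  reads <- reads[order(match(rname, names(seqlengths)), pos)]
  body <- if (nrow(reads)) {
    paste(reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
          reads$cigar, "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a full pooled experiment to disk
#'
#' Convenience wrapper: writes the genome FASTA, gene-model GFF3, truth TSV
#' and VCF, and one coordinate-sorted SAM plus FASTQ per pool.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the `sim` object, the `truth` table and the
#'   vector of per-pool SAM paths.
#' @export
simulate_experiment <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_genome(config)
  truth <- plant_variants(sim, config)
  write_genome_fasta(sim, file.path(outdir, "genome.fa"))
  write_gene_gff3(sim, file.path(outdir, "genes.gff3"))
  write_truth_tsv(truth, file.path(outdir, "truth.tsv"))
  write_truth_vcf(truth, sim, file.path(outdir, "truth.vcf"))
  sams <- character(config$n_pools)
  for (p in seq_len(config$n_pools)) {
    sams[p] <- file.path(outdir, sprintf("pool%d.sam", p))
    simulate_pool_reads(sim, truth, p, config,
                        sam = sams[p],
                        fastq = file.path(outdir, sprintf("pool%d.fastq", p)))
  }
  invisible(list(sim = sim, truth = truth, sam_paths = sams))
}
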