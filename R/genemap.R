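#' Load gene models from GFF3
#'
#' Reads gene/mRNA/exon/CDS/UTR features (1-based inclusive), resolves the
#' Parent chain, merges 5' and 3' UTRs into a single "UTR" stratum for
#' reporting, and derives introns as the inter-exon gaps of each gene. Genes
#' whose CDS segments fall outside their exons are rejected with a warning.
#' Overlapping genes are allowed.
#'
#' @param gff3 Path to a GFF3 file, or a `pool_sim` object (whose feature
#'   table is used directly).
#' @return An object of class `gene_models`: list with `genes` (a
#'   `data.table`) and `GRanges` components `exons`, `cds`, `utr`, `introns`,
#'   each carrying a `gene_id` metadata column.
#' @export
load_gene_models <- function(gff3) {
  if (inherits(gff3, "pool_sim")) {
    f <- gff3$features
    feat <- data.table(scaffold = f$scaffold, start = f$start, end = f$end,
                       strand = f$strand, type = f$type, ID = f$ID,
                       parent = f$Parent)
  } else {
    gr <- rtracklayer::import(gff3, format = "gff3")
    feat <- data.table(scaffold = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr),
                       end = GenomicRanges::end(gr),
                       strand = as.character(GenomicRanges::strand(gr)),
                       type = as.character(gr$type),
                       ID = if (is.null(gr$ID)) NA_character_ else gr$ID,
                       parent = vapply(
                         if (is.null(gr$Parent)) replicate(length(gr), character(0), simplify = FALSE)
                         else as.list(gr$Parent),
                         function(p) if (length(p)) p[[1]] else NA_character_,
                         character(1)))
  }
  empty_models <- function() {
    eg <- GenomicRanges::GRanges()
    eg$gene_id <- character(0)
    structure(list(genes = data.table(gene_id = character(), scaffold = character(),
                                      strand = character(), start = integer(),
                                      end = integer(), n_introns = integer()),
                   exons = eg, cds = eg, utr = eg, introns = eg),
              class = "gene_models")
  }
  genes <- feat[type == "gene"]
  if (!nrow(genes)) return(empty_models())

  # map every feature to its gene through the mRNA level
  mrna <- feat[type == "mRNA"]
  tx2gene <- setNames(mrna$parent, mrna$ID)
  feat[, gene_id := ifelse(type == "gene", ID,
                    ifelse(type == "mRNA", parent,
                    unname(tx2gene[parent])))]
  feat <- feat[!is.na(gene_id)]

  keep_genes <- genes$ID
  for (g in genes$ID) {
    cds <- feat[gene_id == g & type == "CDS"]
    ex <- feat[gene_id == g & type == "exon"]
    if (nrow(cds) && nrow(ex)) {
      inside <- vapply(seq_len(nrow(cds)), function(i)
        any(ex$start <= cds$start[i] & ex$end >= cds$end[i]), logical(1))
      if (!all(inside)) {
        warning("gene model rejected (CDS outside exon): ", g)
        keep_genes <- setdiff(keep_genes, g)
      }
    }
  }
  feat <- feat[gene_id %in% keep_genes]
  genes <- genes[ID %in% keep_genes]
  if (!nrow(genes)) return(empty_models())

  as_gr <- function(dt) {
    if (!nrow(dt)) {
      gr <- GenomicRanges::GRanges(); gr$gene_id <- character(0); return(gr)
    }
    gr <- GenomicRanges::GRanges(dt$scaffold, IRanges::IRanges(dt$start, dt$end),
                                 strand = dt$strand)
    gr$gene_id <- dt$gene_id
    gr
  }
  exons <- as_gr(feat[type == "exon"])
  cds <- as_gr(feat[type == "CDS"])
  utr <- as_gr(feat[type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")])

  # introns: the gene span minus its exons
  intron_dt <- feat[type == "exon", {
    gs <- genes[ID == .BY$gene_id]
    ir <- IRanges::setdiff(IRanges::IRanges(gs$start, gs$end),
                           IRanges::IRanges(start, end))
    if (length(ir)) list(scaffold = scaffold[1L], strand = strand[1L],
                         start = IRanges::start(ir), end = IRanges::end(ir))
    else list(scaffold = character(0), strand = character(0),
              start = integer(0), end = integer(0))
  }, by = .(gene_id)]
  introns <- as_gr(intron_dt)

  n_intr <- table(intron_dt$gene_id)
  gene_dt <- data.table(gene_id = genes$ID, scaffold = genes$scaffold,
                        strand = genes$strand, start = genes$start,
                        end = genes$end)
  gene_dt[, n_introns := as.integer(ifelse(is.na(n_intr[gene_id]), 0L,
                                           n_intr[gene_id]))]
  structure(list(genes = gene_dt, exons = exons, cds = cds, utr = utr,
                 introns = introns),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons, %d introns\n",
              nrow(x$genes), length(x$exons), length(x$introns)))
  invisible(x)
}

#' Assign variants to gene features
#'
#' Each variant is tested, per overlapping gene, against CDS, then UTR, then
#' intron intervals; variants overlapping no gene are `intergenic`. For each
#' in-gene assignment the distance to the nearest exon--intron junction of
#' that gene is reported (`NA` for intron-free genes): the number of bases
#' between the variant and the closest intron base (0 inside an intron).
#'
#' @param variants `data.table` with at least `scaffold` and `pos` columns.
#' @param models A [load_gene_models()] object.
#' @return A `data.table` with one row per (variant, overlapping gene), plus
#'   one `intergenic` row for variants in no gene: `scaffold`, `pos`,
#'   `gene_id`, `feature`, `dist_to_intron`.
#' @export
assign_feature <- function(variants, models) {
  v <- as.data.table(variants)[, .(scaffold, pos)]
  out_empty <- data.table(scaffold = character(), pos = integer(),
                          gene_id = character(), feature = character(),
                          dist_to_intron = integer())
  if (!nrow(v)) return(out_empty)
  vgr <- GenomicRanges::GRanges(v$scaffold, IRanges::IRanges(v$pos, v$pos))

  gg <- models$genes
  res <- list()
  if (nrow(gg)) {
    ggr <- GenomicRanges::GRanges(gg$scaffold, IRanges::IRanges(gg$start, gg$end))
    hits <- GenomicRanges::findOverlaps(vgr, ggr, ignore.strand = TRUE)
    if (length(hits)) {
      vi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
      in_feat <- function(gr) {
        if (!length(gr)) return(rep(FALSE, length(vi)))
        ft <- GenomicRanges::findOverlaps(vgr[vi], gr, ignore.strand = TRUE)
        ok <- gr$gene_id[S4Vectors::subjectHits(ft)] ==
          gg$gene_id[gi][S4Vectors::queryHits(ft)]
        tapply_ok <- rep(FALSE, length(vi))
        tapply_ok[unique(S4Vectors::queryHits(ft)[ok])] <- TRUE
        tapply_ok
      }
      is_cds <- in_feat(models$cds)
      is_utr <- !is_cds & in_feat(models$utr)
      is_intron <- !is_cds & !is_utr & in_feat(models$introns)
      feature <- ifelse(is_cds, "CDS", ifelse(is_utr, "UTR",
                 ifelse(is_intron, "intron", "intergenic")))
      # distance to the nearest intron base of the assigned gene
      idt <- as.data.table(models$introns)[, .(scaffold = as.character(seqnames),
                                               start, end, gene_id)]
      dist <- rep(NA_integer_, length(vi))
      for (j in seq_along(vi)) {
        gid <- gg$gene_id[gi[j]]
        ii <- idt[gene_id == gid]
        if (!nrow(ii)) next
        p <- v$pos[vi[j]]
        dist[j] <- min(pmax(pmax(ii$start - p, p - ii$end), 0L))
      }
      res[[1L]] <- data.table(scaffold = v$scaffold[vi], pos = v$pos[vi],
                              gene_id = gg$gene_id[gi], feature = feature,
                              dist_to_intron = dist)
      genic <- unique(vi)
    } else genic <- integer(0)
  } else genic <- integer(0)
  inter <- setdiff(seq_len(nrow(v)), genic)
  if (length(inter))
    res[[length(res) + 1L]] <- data.table(scaffold = v$scaffold[inter],
                                          pos = v$pos[inter],
                                          gene_id = NA_character_,
                                          feature = "intergenic",
                                          dist_to_intron = NA_integer_)
  out <- rbindlist(res)
  setorder(out, scaffold, pos)
  out[]
}

#' Variant density per kilobase
#'
#' `count / length * 1000`. Summary tables report it to one decimal.
#'
#' @param count Number of variants.
#' @param length Covered length in bp; must be positive.
#' @return Density in variants/kb (unrounded).
#' @export
density_per_kb <- function(count, length) {
  if (any(length <= 0)) stop("length must be positive")
  count / length * 1000
}

#' Positions covered at the calling floor in at least one pool
#'
#' The global coverage mask used as the denominator source for
#' feature-stratified densities: a position is in the mask when any pool
#' reaches `min_coverage` there (the space in which variants are
#' discoverable).
#'
#' @param profiles List of [pool_profile()] objects.
#' @param params A [call_params()].
#' @return A `data.table` of mask positions: `scaffold`, `pos`.
#' @export
coverage_mask <- function(profiles, params = call_params()) {
  mask <- rbindlist(lapply(profiles, function(p) {
    tot <- p$columns[, .(depth = sum(depth)), by = .(scaffold, pos)]
    tot[depth >= params$min_coverage, .(scaffold, pos)]
  }))
  if (!nrow(mask)) return(data.table(scaffold = character(), pos = integer()))
  unique(mask)
}

#' Feature-stratified densities and per-gene summary
#'
#' Counts in-gene variants (once per overlapping gene for per-gene statistics,
#' once overall for the genome-wide total), computes CDS and UTR variant
#' densities over the feature-specific covered lengths (the global coverage
#' mask intersected with the feature intervals), the number of genes carrying
#' variants and the mean variants per such gene.
#'
#' @param variants `data.table` with `scaffold`, `pos` (typically a
#'   `pool_variants` table).
#' @param models A [load_gene_models()] object.
#' @param mask Optional coverage mask from [coverage_mask()]; when `NULL` the
#'   full feature lengths are used as denominators.
#' @return A list of class `feature_density_report`: `feature_stats`
#'   (`data.table` with `feature`, `n_variants`, `covered_bp`, `per_kb`),
#'   `n_in_gene`, `genes_with_variants`, `mean_variants_per_gene`,
#'   `pct_cds_of_in_gene`, and `assignments`.
#' @export
gene_summary <- function(variants, models, mask = NULL) {
  asg <- assign_feature(variants, models)
  genic <- asg[feature %in% c("CDS", "UTR", "intron")]
  # genome-wide counts: one per variant position
  dedup <- unique(genic, by = c("scaffold", "pos", "feature"))
  pos_feat <- unique(genic, by = c("scaffold", "pos"))

  feat_len <- function(gr) {
    if (!length(gr)) return(0L)
    red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    if (is.null(mask)) return(sum(GenomicRanges::width(red)))
    mgr <- GenomicRanges::GRanges(mask$scaffold, IRanges::IRanges(mask$pos, mask$pos))
    sum(GenomicRanges::width(GenomicRanges::intersect(red, mgr, ignore.strand = TRUE)))
  }
  n_cds <- length(unique(dedup[feature == "CDS", paste(scaffold, pos)]))
  n_utr <- length(unique(dedup[feature == "UTR", paste(scaffold, pos)]))
  cds_bp <- feat_len(models$cds)
  utr_bp <- feat_len(models$utr)
  feature_stats <- data.table(
    feature = c("CDS", "UTR"),
    n_variants = c(n_cds, n_utr),
    covered_bp = c(cds_bp, utr_bp),
    per_kb = c(if (cds_bp > 0) round(density_per_kb(n_cds, cds_bp), 1) else NA_real_,
               if (utr_bp > 0) round(density_per_kb(n_utr, utr_bp), 1) else NA_real_))

  per_gene <- genic[, .(n = uniqueN(paste(scaffold, pos))), by = gene_id]
  gwv <- nrow(per_gene)
  n_in_gene <- nrow(pos_feat)
  total_gene_hits <- sum(per_gene$n)
  structure(list(
    feature_stats = feature_stats,
    n_in_gene = n_in_gene,
    genes_with_variants = gwv,
    mean_variants_per_gene = if (gwv > 0) total_gene_hits / gwv else 0,
    mean_defined = gwv > 0,
    pct_cds_of_in_gene = if (n_cds + n_utr > 0)
      proportion_pct(n_cds, n_cds + n_utr) else NA_real_,
    assignments = asg), class = "feature_density_report")
}

#' @export
print.feature_density_report <- function(x, ...) {
  cat(sprintf("feature_density_report: %d in-gene variants in %d genes (mean %.1f/gene)\n",
              x$n_in_gene, x$genes_with_variants, x$mean_variants_per_gene))
  print(x$feature_stats)
  invisible(x)
}
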