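#' Write the merged variant table as VCF
#'
#' Emits one merged VCF with per-pool supported-allele depths (AD-style,
#' ordered REF then ALTs), per-pool depth, MAF and status as FORMAT fields,
#' and the global MAF, variant kind and number of covered pools as INFO
#' fields. Internal indel descriptors are converted to anchored REF/ALT.
#'
#' @param variants A `pool_variants` table from [merge_pool_calls()].
#' @param reference Reference genome (for anchor bases).
#' @param path Output VCF path.
#' @export
write_variant_vcf <- function(variants, reference, path) {
  seqs <- load_reference(reference)
  pools <- attr(variants, "pools")
  n <- nrow(variants)
  allele_list <- strsplit(variants$alleles, ",", fixed = TRUE)
  anch <- vcf_anchor_alleles(variants$scaffold, variants$pos, variants$ref,
                             allele_list, seqs)

  rr <- GenomicRanges::GRanges(
    variants$scaffold,
    IRanges::IRanges(anch$pos, width = nchar(anch$ref)))
  GenomeInfoDb::seqlengths(rr) <- nchar(seqs)[GenomeInfoDb::seqlevels(rr)]
  names(rr) <- sprintf("%s:%d", variants$scaffold, variants$pos)

  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(anch$ref),
    ALT = Biostrings::DNAStringSetList(anch$alt),
    QUAL = rep(NA_real_, n),
    FILTER = rep(".", n))
  info <- S4Vectors::DataFrame(
    MAF = round(variants$global_maf, 4),
    KIND = variants$kind,
    NP = as.integer(variants$n_pools_covered))

  ad <- matrix(vector("list", n * length(pools)), nrow = n,
               dimnames = list(names(rr), pools))
  dp <- matrix(NA_integer_, n, length(pools), dimnames = dimnames(ad))
  mf <- matrix(NA_real_, n, length(pools), dimnames = dimnames(ad))
  st <- matrix(".", n, length(pools), dimnames = dimnames(ad))
  for (k in seq_along(pools)) {
    pn <- pools[k]
    counts <- variants[[paste0(pn, "_counts")]]
    for (i in seq_len(n)) {
      order_al <- c(variants$ref[i], setdiff(allele_list[[i]], variants$ref[i]))
      if (is.na(counts[i])) {
        ad[i, k][[1]] <- rep(NA_integer_, length(order_al))
      } else {
        cc <- strsplit(strsplit(counts[i], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
        dmap <- setNames(as.integer(vapply(cc, `[`, character(1), 2L)),
                         vapply(cc, `[`, character(1), 1L))
        ad[i, k][[1]] <- unname(ifelse(is.na(dmap[order_al]), 0L, dmap[order_al]))
      }
    }
    dp[, k] <- variants[[paste0(pn, "_depth")]]
    mf[, k] <- round(variants[[paste0(pn, "_maf")]], 4)
    stv <- variants[[paste0(pn, "_status")]]
    st[, k] <- ifelse(is.na(stv), ".", stv)
  }

  hdr <- VariantAnnotation::VCFHeader(
    samples = pools,
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                        row.names = "fileformat"),
      INFO = S4Vectors::DataFrame(
        Number = c("1", "1", "1"), Type = c("Float", "String", "Integer"),
        Description = c("Global major allele frequency from summed supported depths",
                        "Variant kind (SNP or INDEL)",
                        "Number of pools covered at the calling depth floor"),
        row.names = c("MAF", "KIND", "NP")),
      FORMAT = S4Vectors::DataFrame(
        Number = c(".", "1", "1", "1"),
        Type = c("Integer", "Integer", "Float", "String"),
        Description = c("Supported-allele depths (REF first, then ALTs)",
                        "Total supported-allele depth",
                        "Pool major allele frequency",
                        "Pool status at this site"),
        row.names = c("AD", "DP", "MF", "ST"))))

  vcf <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_along(pools), row.names = pools),
    exptData = list(header = hdr),
    fixed = fixed, info = info,
    geno = S4Vectors::SimpleList(AD = ad, DP = dp, MF = mf, ST = st))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Write the merged variant table as TSV
#'
#' Long-format mirror of the multi-pool variant collection: position,
#' alleles, kind, global MAF and the per-pool status/depth/MAF/count columns.
#'
#' @param variants A `pool_variants` table.
#' @param path Output path.
#' @export
write_variant_tsv <- function(variants, path) {
  fwrite(variants, path, sep = "\t")
  invisible(path)
}
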