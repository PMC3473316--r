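#' Major allele frequency from pooled allele depths
#'
#' Depth of the most frequent allele over the total depth. With two alleles
#' tied for the majority this equals 0.5.
#'
#' @param depths Numeric vector of per-allele read depths (optionally named).
#' @return Frequency in (0, 1].
#' @export
pool_maf <- function(depths) {
  if (!length(depths) || sum(depths) <= 0) stop("undefined MAF: zero depth")
  max(depths) / sum(depths)
}

# Column helpers over a pool_variants table
pool_status_col <- function(variants, pool) variants[[paste0(pool, "_status")]]
pool_maf_col <- function(variants, pool) variants[[paste0(pool, "_maf")]]

check_pool <- function(variants, pool) {
  pools <- attr(variants, "pools")
  if (!pool %in% pools)
    stop("unknown pool '", pool, "'; available: ", paste(pools, collapse = ", "))
  invisible(pool)
}

#' Per-pool MAF histogram
#'
#' Bins the pool MAFs of the pool's polymorphic SNPs into right-closed bins
#' of width `bin_width` over [0.5, 1]; the lowest bin includes 0.5. Counts
#' sum to the pool's polymorphic SNP count.
#'
#' @param variants A `pool_variants` table.
#' @param pool Pool name (e.g. `"pool1"`).
#' @param bin_width Bin width (default 0.05).
#' @return A `data.table` with `bin_lo`, `bin_hi`, `count`.
#' @export
maf_histogram <- function(variants, pool, bin_width = 0.05) {
  check_pool(variants, pool)
  breaks <- seq(0.5, 1, by = bin_width)
  mafs <- pool_maf_col(variants, pool)[
    pool_status_col(variants, pool) == "polymorphic" & variants$kind == "SNP"]
  mafs <- mafs[!is.na(mafs)]
  ct <- if (length(mafs))
    table(cut(mafs, breaks, include.lowest = TRUE, right = TRUE))
  else setNames(rep(0L, length(breaks) - 1L), seq_len(length(breaks) - 1L))
  data.table(bin_lo = head(breaks, -1L), bin_hi = tail(breaks, -1L),
             count = as.integer(ct))
}

#' Highly variable SNP fraction of a pool
#'
#' Count and percentage of the pool's polymorphic SNPs whose pool MAF is
#' below `threshold` (default 0.7) -- lower MAF means higher within-pool
#' variability.
#'
#' @inheritParams maf_histogram
#' @param threshold MAF ceiling (default 0.7).
#' @return List with `count`, `n_snps`, `pct` (one decimal).
#' @export
high_variability_fraction <- function(variants, pool, threshold = 0.7) {
  check_pool(variants, pool)
  poly <- pool_status_col(variants, pool) == "polymorphic" & variants$kind == "SNP"
  mafs <- pool_maf_col(variants, pool)[poly]
  n <- sum(poly)
  cnt <- sum(mafs < threshold, na.rm = TRUE)
  list(count = cnt, n_snps = n,
       pct = if (n > 0) proportion_pct(cnt, n) else NA_real_)
}

#' Per-pool diversity summary
#'
#' The per-pool table of the analysis: covered length at the calling floor,
#' polymorphic SNP count, SNPs/kb (one decimal) and the count and percentage
#' of SNPs with pool MAF below `maf_threshold`.
#'
#' @param variants A `pool_variants` table.
#' @param profiles List of [pool_profile()] objects in the same pool order.
#' @param maf_threshold MAF ceiling for the high-variability column.
#' @return A `data.table`, one row per pool.
#' @export
diversity_summary <- function(variants, profiles, maf_threshold = 0.7) {
  pools <- attr(variants, "pools")
  stopifnot(length(profiles) == length(pools))
  rbindlist(lapply(seq_along(pools), function(k) {
    hv <- high_variability_fraction(variants, pools[k], maf_threshold)
    cl <- profiles[[k]]$covered_length
    data.table(pool = pools[k],
               covered_length_bp = cl,
               n_snps = hv$n_snps,
               snps_per_kb = if (cl > 0) round(density_per_kb(hv$n_snps, cl), 1)
                             else NA_real_,
               n_maf_below = hv$count,
               pct_maf_below = hv$pct)
  }))
}

#' SNPs shared (polymorphic) between two pools
#'
#' Number of positions polymorphic within both pools, with the percentage of
#' each pool's polymorphic SNP total.
#'
#' @param variants A `pool_variants` table.
#' @param pool_a,pool_b Distinct pool names.
#' @return List with `count`, `pct_a`, `pct_b`.
#' @export
pairwise_shared <- function(variants, pool_a, pool_b) {
  if (identical(pool_a, pool_b)) stop("pool_a and pool_b must differ")
  check_pool(variants, pool_a); check_pool(variants, pool_b)
  snp <- variants$kind == "SNP"
  pa <- pool_status_col(variants, pool_a) == "polymorphic" & snp
  pb <- pool_status_col(variants, pool_b) == "polymorphic" & snp
  cnt <- sum(pa & pb)
  list(count = cnt,
       pct_a = if (sum(pa) > 0) proportion_pct(cnt, sum(pa)) else NA_real_,
       pct_b = if (sum(pb) > 0) proportion_pct(cnt, sum(pb)) else NA_real_)
}

#' Fixed-differential positions between two pools
#'
#' Number of positions where each pool has exactly one supported allele
#' (is fixed), the two alleles differ, and both pools reach the calling depth
#' floor. Pools without coverage at a position are excluded, as are positions
#' polymorphic in either pool.
#'
#' @inheritParams pairwise_shared
#' @return Integer count.
#' @export
pairwise_fixed_differential <- function(variants, pool_a, pool_b) {
  if (identical(pool_a, pool_b)) stop("pool_a and pool_b must differ")
  check_pool(variants, pool_a); check_pool(variants, pool_b)
  snp <- variants$kind == "SNP"
  sa <- pool_status_col(variants, pool_a); sb <- pool_status_col(variants, pool_b)
  fa <- sa %in% c("fixed_ref", "fixed_alt"); fb <- sb %in% c("fixed_ref", "fixed_alt")
  aa <- variants[[paste0(pool_a, "_allele")]]
  ab <- variants[[paste0(pool_b, "_allele")]]
  sum(snp & fa & fb & aa != ab, na.rm = TRUE)
}

#' SNPs polymorphic in every pool
#'
#' The intersection of the per-pool polymorphic SNP sets, with its percentage
#' over the SNP total and over the full SNV total (both denominators are
#' reported since either may be quoted).
#'
#' @param variants A `pool_variants` table.
#' @param pools Pool names (default: all pools; at least 2).
#' @return List with `count`, `pct_of_snps`, `pct_of_snvs`.
#' @export
shared_across_all <- function(variants, pools = attr(variants, "pools")) {
  stopifnot(length(pools) >= 2L)
  for (p in pools) check_pool(variants, p)
  snp <- variants$kind == "SNP"
  poly_all <- Reduce(`&`, lapply(pools, function(p)
    pool_status_col(variants, p) == "polymorphic"))
  cnt <- sum(snp & poly_all)
  n_snp <- sum(snp); n_snv <- nrow(variants)
  list(count = cnt,
       pct_of_snps = if (n_snp > 0) proportion_pct(cnt, n_snp) else NA_real_,
       pct_of_snvs = if (n_snv > 0) proportion_pct(cnt, n_snv) else NA_real_)
}

#' Pairwise pool comparison matrix
#'
#' Square matrix over the pools with shared-polymorphism counts above the
#' diagonal and fixed-differential counts below it.
#'
#' @param variants A `pool_variants` table.
#' @return An integer matrix with pool names as dimnames.
#' @export
pairwise_matrix <- function(variants) {
  pools <- attr(variants, "pools")
  m <- matrix(NA_integer_, length(pools), length(pools),
              dimnames = list(pools, pools))
  for (i in seq_along(pools)) for (j in seq_along(pools)) {
    if (i < j) m[i, j] <- pairwise_shared(variants, pools[i], pools[j])$count
    if (i > j) m[i, j] <- pairwise_fixed_differential(variants, pools[i], pools[j])
  }
  m
}
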