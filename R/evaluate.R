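#' Benchmark called variants against planted truth
#'
#' Site-level and pool-level comparison of a merged variant table with the
#' generator's truth:
#'
#' * **recall / precision** are computed at the (site, pool) level for SNPs:
#'   a truth SNP with planted frequency in `freq_range` in a covered pool
#'   should be called polymorphic there (recall); a pool-polymorphic SNP call
#'   should sit at a planted position with nonzero planted frequency in that
#'   pool (precision).
#' * **MAF accuracy**: fraction of covered (site, pool) truth entries whose
#'   estimated pool MAF lies within 3 binomial standard deviations
#'   (at the pool's observed depth) of the planted major-allele frequency.
#' * **class recovery**: planted-truth expectations versus recovered counts
#'   for shared-in-all-pools, pool-specific and fixed-differential sites.
#'
#' @param variants A `pool_variants` table.
#' @param truth Truth table from [plant_variants()].
#' @param config The [sim_config()] used.
#' @param freq_range Planted-frequency band over which recall is assessed
#'   (default `c(0.2, 0.8)`).
#' @return A list with `recall`, `precision`, `maf_within_3sd`,
#'   `class_recovery` (a `data.table` with truth-derived and recovered
#'   counts) and the underlying per-(site, pool) table `site_pool`.
#' @export
evaluate_calls <- function(variants, truth, config, freq_range = c(0.2, 0.8)) {
  pools <- pool_names(config$n_pools)
  fq <- truth_freq_matrix(truth)
  key_v <- paste(variants$scaffold, variants$pos)
  key_t <- paste(truth$scaffold, truth$pos)
  vrow <- match(key_t, key_v)

  sp <- rbindlist(lapply(seq_along(pools), function(k) {
    pn <- pools[k]
    st <- if (all(is.na(vrow))) rep(NA_character_, nrow(truth))
          else pool_status_col(variants, pn)[vrow]
    mafhat <- if (all(is.na(vrow))) rep(NA_real_, nrow(truth))
              else pool_maf_col(variants, pn)[vrow]
    dep <- if (all(is.na(vrow))) rep(NA_integer_, nrow(truth))
           else variants[[paste0(pn, "_depth")]][vrow]
    data.table(id = truth$id, kind = truth$kind, pool = pn,
               freq = fq[, k], status = st, maf_hat = mafhat, depth = dep)
  }))
  sp[, maf_true := pmax(freq, 1 - freq)]

  # recall over covered truth SNP (site, pool) entries in the frequency band
  band <- sp[kind == "SNP" & freq >= freq_range[1] & freq <= freq_range[2] &
               !is.na(status) & status != "no_coverage"]
  recall <- if (nrow(band)) mean(band$status == "polymorphic") else NA_real_

  # precision over pool-polymorphic SNP calls
  calls <- rbindlist(lapply(pools, function(pn) {
    idx <- which(pool_status_col(variants, pn) == "polymorphic" &
                   variants$kind == "SNP")
    data.table(site = key_v[idx], pool = pn)
  }))
  truth_poly <- rbindlist(lapply(seq_along(pools), function(k)
    data.table(site = key_t[fq[, k] > 0], pool = pools[k])))
  precision <- if (nrow(calls))
    mean(paste(calls$site, calls$pool) %in%
           paste(truth_poly$site, truth_poly$pool)) else NA_real_

  # MAF accuracy: 3 binomial SDs at observed depth
  mafchk <- sp[kind == "SNP" & !is.na(maf_hat) & !is.na(depth) & depth > 0 &
                 freq > 0 & freq < 1]
  mafchk[, sd3 := 3 * sqrt(maf_true * (1 - maf_true) / depth)]
  maf_within <- if (nrow(mafchk))
    mean(abs(mafchk$maf_hat - mafchk$maf_true) <= mafchk$sd3) else NA_real_

  # class recovery: each planted record scored against its class signature
  poly_mat <- vapply(pools, function(pn)
    pool_status_col(variants, pn)[vrow] == "polymorphic", logical(nrow(truth)))
  if (is.null(dim(poly_mat))) poly_mat <- matrix(poly_mat, nrow = nrow(truth))
  poly_mat[is.na(poly_mat)] <- FALSE
  fixed_mat <- vapply(pools, function(pn)
    pool_status_col(variants, pn)[vrow] %in% c("fixed_ref", "fixed_alt"),
    logical(nrow(truth)))
  if (is.null(dim(fixed_mat))) fixed_mat <- matrix(fixed_mat, nrow = nrow(truth))
  fd <- config$fixed_diff_pools
  al_a <- variants[[paste0(pools[fd[1]], "_allele")]][vrow]
  al_b <- variants[[paste0(pools[fd[2]], "_allele")]][vrow]
  sig_ok <- function(i) {
    switch(truth$class[i],
      shared_all = all(poly_mat[i, ]),
      pool_specific = sum(poly_mat[i, ]) == 1L &&
        poly_mat[i, which(fq[i, ] > 0 & fq[i, ] < 1)],
      fixed_differential = fixed_mat[i, fd[1]] && fixed_mat[i, fd[2]] &&
        !is.na(al_a[i]) && !is.na(al_b[i]) && al_a[i] != al_b[i],
      NA)
    }
  classes <- c("shared_all", "pool_specific", "fixed_differential")
  class_recovery <- rbindlist(lapply(classes, function(cl) {
    idx <- which(truth$class == cl)
    data.table(class = cl, expected = length(idx),
               recovered = sum(vapply(idx, sig_ok, logical(1))))
  }))
  class_recovery[, rel_err := ifelse(expected > 0,
                                     abs(recovered - expected) / expected,
                                     NA_real_)]

  list(recall = recall, precision = precision, maf_within_3sd = maf_within,
       class_recovery = class_recovery[], site_pool = sp[])
}
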