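#' Flag INDEL-kind variants (VKS filter)
#'
#' INDELs are a major source of false positives on short-read platforms and
#' are removed from the SNP collection; this flag marks them.
#'
#' @param variants A `pool_variants` table.
#' @return Logical vector, `TRUE` for INDEL records.
#' @export
flag_vks <- function(variants) {
  variants$kind == "INDEL"
}

#' Flag variants close to an intron boundary (IS60 filter)
#'
#' A variant is flagged when it lies in a gene with introns and its distance
#' to the nearest exon--intron junction of an overlapping gene is strictly
#' less than `window` bp ("closer than 60 bp" is read as strict: a variant
#' exactly `window` bp away passes). Intergenic variants and variants in
#' intron-free genes are never flagged.
#'
#' @param variants A `pool_variants` table (needs `scaffold`, `pos`).
#' @param models A [load_gene_models()] object.
#' @param window Distance threshold in bp (default 60).
#' @return Logical vector along `variants` rows.
#' @export
flag_is60 <- function(variants, models, window = 60L) {
  asg <- assign_feature(variants, models)
  near <- asg[!is.na(dist_to_intron) & dist_to_intron < window,
              unique(paste(scaffold, pos))]
  paste(variants$scaffold, variants$pos) %in% near
}

#' Flag variants with close flanking polymorphisms (CS60 / CS60_MAF filter)
#'
#' A variant is flagged when any *other* SNV on the same scaffold lies within
#' `window` bp and has a global MAF below `maf_threshold` -- i.e. only
#' sufficiently rare flanking variants (high-MAF neighbours) are tolerated
#' near a candidate marker. With `maf_threshold = 1` every neighbour flags
#' (the plain flanking-polymorphism filter): any variant, however rare,
#' disturbs primer design. All SNVs, including INDELs, act as flagging
#' neighbours.
#'
#' @param variants A `pool_variants` table.
#' @param window Flanking window in bp (default 60).
#' @param maf_threshold Neighbour MAF threshold `t`; neighbours with global
#'   MAF `>= t` are tolerated (default 1: none tolerated).
#' @return Logical vector along `variants` rows.
#' @export
flag_cs60_maf <- function(variants, window = 60L, maf_threshold = 1) {
  n <- nrow(variants)
  flag <- logical(n)
  if (n < 2L) return(flag)
  v <- data.table(i = seq_len(n), scaffold = variants$scaffold,
                  pos = variants$pos, maf = variants$global_maf)
  setorder(v, scaffold, pos)
  for (sc in unique(v$scaffold)) {
    vs <- v[scaffold == sc]
    if (nrow(vs) < 2L) next
    blocks <- vs$maf < maf_threshold | maf_threshold >= 1
    for (j in seq_len(nrow(vs))) {
      nb <- which(abs(vs$pos - vs$pos[j]) <= window & seq_len(nrow(vs)) != j)
      if (any(blocks[nb])) flag[vs$i[j]] <- TRUE
    }
  }
  flag
}

#' Filter-combination counts
#'
#' For a grid of neighbour-MAF thresholds `t`, counts the SNPs (INDELs are
#' excluded throughout by the VKS rule) passing the flanking-polymorphism
#' filter alone, passing it together with the intron-distance filter, and
#' additionally polymorphic in every pool. Percentages are of the SNP total.
#'
#' @param variants A `pool_variants` table.
#' @param models A [load_gene_models()] object.
#' @param t_values Neighbour-MAF thresholds (default
#'   `c(1, 0.99, 0.98, 0.97, 0.96, 0.95, 0.7)`).
#' @param window Flanking/intron window in bp (default 60).
#' @return A `data.table` with one row per `t`: `t`, `n_no_cs60`,
#'   `n_no_cs60_no_is60`, `pct_no_cs60_no_is60`, `n_variable_all_pools`.
#' @export
filter_table <- function(variants, models,
                         t_values = c(1, 0.99, 0.98, 0.97, 0.96, 0.95, 0.7),
                         window = 60L) {
  snp <- !flag_vks(variants)
  n_snp <- sum(snp)
  is60 <- flag_is60(variants, models, window)
  pools <- attr(variants, "pools")
  poly_all <- Reduce(`&`, lapply(pools, function(p)
    pool_status_col(variants, p) == "polymorphic"))
  rbindlist(lapply(t_values, function(t) {
    cs <- flag_cs60_maf(variants, window, t)
    no_cs <- snp & !cs
    both <- no_cs & !is60
    data.table(t = t,
               n_no_cs60 = sum(no_cs),
               n_no_cs60_no_is60 = sum(both),
               pct_no_cs60_no_is60 = if (n_snp > 0)
                 proportion_pct(sum(both), n_snp, 2) else NA_real_,
               n_variable_all_pools = sum(both & poly_all))
  }))
}

#' Panel-selection criteria
#'
#' @param monomorphic_within Pool names that must be fixed (a single
#'   supported allele) at a selected marker.
#' @param polymorphic_between List of pool-name pairs that must be
#'   fixed-differential at a selected marker.
#' @param maf_max Optional global-MAF ceiling (strict) for selected markers.
#' @param n_select Number of markers to draw.
#' @param seed Integer seed for the random draw.
#' @param cs60_maf Neighbour-MAF threshold used for the flanking filter.
#' @param window Flanking/intron window in bp.
#' @return A list of class `panel_criteria`.
#' @export
panel_criteria <- function(monomorphic_within = character(),
                           polymorphic_between = list(),
                           maf_max = NULL, n_select = 10L, seed = 1L,
                           cs60_maf = 1, window = 60L) {
  structure(list(monomorphic_within = monomorphic_within,
                 polymorphic_between = polymorphic_between,
                 maf_max = maf_max, n_select = as.integer(n_select),
                 seed = as.integer(seed), cs60_maf = cs60_maf,
                 window = as.integer(window)),
            class = "panel_criteria")
}

#' Select a genotyping panel
#'
#' Candidate markers are SNPs passing the intron-distance and
#' flanking-polymorphism filters that are fixed within every pool in
#' `monomorphic_within`, fixed-differential between every pair in
#' `polymorphic_between`, and (optionally) below the global-MAF ceiling.
#' `n_select` markers are drawn uniformly without replacement with the
#' criteria seed; if fewer candidates exist, all are returned with a warning.
#'
#' @param variants A `pool_variants` table.
#' @param models A [load_gene_models()] object.
#' @param criteria A [panel_criteria()].
#' @return A `data.table` of selected variant rows, with an added
#'   `candidate_pool_size` attribute (number of candidates drawn from).
#' @export
select_panel <- function(variants, models, criteria) {
  ok <- !flag_vks(variants) &
    !flag_is60(variants, models, criteria$window) &
    !flag_cs60_maf(variants, criteria$window, criteria$cs60_maf)
  for (p in criteria$monomorphic_within) {
    check_pool(variants, p)
    ok <- ok & pool_status_col(variants, p) %in% c("fixed_ref", "fixed_alt")
  }
  for (pr in criteria$polymorphic_between) {
    stopifnot(length(pr) == 2L)
    check_pool(variants, pr[1]); check_pool(variants, pr[2])
    sa <- pool_status_col(variants, pr[1]); sb <- pool_status_col(variants, pr[2])
    aa <- variants[[paste0(pr[1], "_allele")]]
    ab <- variants[[paste0(pr[2], "_allele")]]
    fd <- sa %in% c("fixed_ref", "fixed_alt") &
      sb %in% c("fixed_ref", "fixed_alt") & !is.na(aa) & !is.na(ab) & aa != ab
    ok <- ok & fd
  }
  if (!is.null(criteria$maf_max))
    ok <- ok & variants$global_maf < criteria$maf_max
  cand <- which(ok)
  if (criteria$n_select > length(cand)) {
    warning(sprintf("only %d candidates for n_select = %d; returning all",
                    length(cand), criteria$n_select))
    sel <- cand
  } else {
    sel <- withr::with_seed(criteria$seed,
                            sort(sample(cand, criteria$n_select)))
  }
  out <- variants[sel]
  setattr(out, "pools", attr(variants, "pools"))
  setattr(out, "candidate_pool_size", length(cand))
  out
}

#' Polymorphism information content
#'
#' PIC of a marker with allele frequencies `p`:
#' `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. A monomorphic marker has
#' PIC 0; a biallelic marker with p = q = 0.5 has PIC 0.375. PIC never
#' exceeds the expected heterozygosity `1 - sum(p_i^2)`.
#'
#' @param p Numeric vector of allele frequencies summing to 1.
#' @return PIC value in [0, 1).
#' @export
pic <- function(p) {
  if (any(p < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Validation-rate arithmetic for a genotyping assay
#'
#' Fraction of assayed markers that proved polymorphic: markers monomorphic
#' across all genotyped accessions count as failures.
#'
#' @param n_assayed Markers assayed.
#' @param n_monomorphic Markers monomorphic in all accessions.
#' @param digits Decimal places for the percentage.
#' @return Percentage validated.
#' @export
validation_ratio <- function(n_assayed, n_monomorphic, digits = 0) {
  stopifnot(n_assayed > 0, n_monomorphic >= 0, n_monomorphic <= n_assayed)
  round(100 * (n_assayed - n_monomorphic) / n_assayed, digits)
}
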