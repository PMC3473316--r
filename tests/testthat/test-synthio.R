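small_cfg <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_scaffolds = 1L, genes_per_scaffold = 4L,
               per_pool_depth = 20,
               n_variants_per_class = c(shared_all = 6L, pool_specific = 4L,
                                        fixed_differential = 4L, background = 6L,
                                        near_intron = 3L, clustered = 2L,
                                        indel = 2L))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("generator outputs are byte-identical for a fixed seed and differ across seeds", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  for (f in c("genome.fa", "genes.gff3", "truth.tsv", "pool1.sam", "pool1.fastq"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  sim <- make_genome(cfg)
  truth <- plant_variants(sim, cfg)
  r1 <- simulate_pool_reads(sim, truth, 1L, cfg)
  cfg2 <- small_cfg(seed = 12L)
  sim2 <- make_genome(cfg2)
  r2 <- simulate_pool_reads(sim2, plant_variants(sim2, cfg2), 1L, cfg2)
  expect_false(identical(r1$pos, r2$pos))
})

test_that("gene layout follows the configuration and survives a GFF3 round trip", {
  cfg <- sim_config(seed = 2L, n_scaffolds = 2L, genes_per_scaffold = 3L,
                    n_variants_per_class = c(shared_all = 0L))
  sim <- make_genome(cfg)
  expect_equal(sum(sim$features$type == "gene"), 6L)
  gff <- tempfile(fileext = ".gff3")
  suppressWarnings(write_gene_gff3(sim, gff))
  models <- load_gene_models(gff)
  expect_equal(nrow(models$genes), 6L)
  expect_equal(length(models$introns), 6L * (cfg$exons_per_gene - 1L))
  # empty gene set still yields a genome
  cfg0 <- sim_config(seed = 2L, genes_per_scaffold = 0L,
                     n_variants_per_class = c(shared_all = 0L))
  sim0 <- make_genome(cfg0)
  expect_equal(sum(sim0$features$type == "gene"), 0L)
  expect_equal(length(sim0$genome), cfg0$n_scaffolds)
  expect_gt(sum(nchar(sim0$seqs)), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(missing_rate = 0.5), "missing_rate")
  expect_error(sim_config(read_len = 500L), "read_len")
  expect_error(sim_config(scaffold_len = 2000L), "configuration error")
  expect_error(sim_config(fixed_diff_pools = c(1L, 1L)), "distinct")
})

test_that("planted truth matches the requested class structure", {
  cfg <- small_cfg()
  sim <- make_genome(cfg)
  truth <- plant_variants(sim, cfg)
  expect_equal(as.list(table(truth$class)),
               list(background = 6L, clustered = 4L, fixed_differential = 4L,
                    indel = 2L, near_intron = 3L, pool_specific = 4L,
                    shared_all = 6L))
  fq <- truth_freq_matrix(truth)
  expect_true(all(fq >= 0 & fq <= 1))
  expect_true(all(truth$ref != truth$alt))
  expect_true(all(truth$pos >= 1 & truth$pos <= cfg$scaffold_len))

  sa <- fq[truth$class == "shared_all", , drop = FALSE]
  expect_true(all(sa > 0 & sa < 1))
  ps <- fq[truth$class == "pool_specific", , drop = FALSE]
  expect_true(all(rowSums(ps > 0 & ps < 1) == 1L))
  expect_true(all(ps[ps != 0] > 0 & ps[ps != 0] < 1))
  fd <- fq[truth$class == "fixed_differential", , drop = FALSE]
  expect_true(all(fd[, cfg$fixed_diff_pools[1]] == 1))
  expect_true(all(fd[, cfg$fixed_diff_pools[2]] == 0))
  expect_true(all(fd %in% c(0, 1)))
  expect_equal(unname(table(truth$kind)["INDEL"]), 2L, ignore_attr = TRUE)

  # all-zero request gives an empty truth table
  cfg0 <- sim_config(seed = 5L, n_variants_per_class = c(shared_all = 0L))
  expect_equal(nrow(plant_variants(make_genome(cfg0), cfg0)), 0L)
})

test_that("clustered pairs sit within 60 bp of each other; everything else is isolated", {
  cfg <- small_cfg(seed = 21L)
  sim <- make_genome(cfg)
  truth <- plant_variants(sim, cfg)
  cl <- truth[class == "clustered"][order(pos)]
  expect_equal(nrow(cl), 4L)  # 2 requested pairs
  gaps <- diff(cl$pos)
  expect_true(all(gaps[c(1, 3)] >= 10 & gaps[c(1, 3)] <= 60))
  # non-clustered variants are pairwise >= 61 bp apart
  ncl <- truth[class != "clustered"][order(scaffold, pos)]
  expect_true(all(diff(ncl$pos) >= 61 | diff(as.integer(factor(ncl$scaffold))) != 0))
  # distance of planted variants to intron boundaries
  models <- load_gene_models(sim)
  asg <- assign_feature(truth, models)
  d <- asg[!is.na(dist_to_intron)]
  near <- merge(d, truth[, .(scaffold, pos, class)], by = c("scaffold", "pos"))
  expect_true(all(near[class == "near_intron"]$dist_to_intron < 60))
  expect_true(all(near[!class %in% "near_intron"]$dist_to_intron >= 61))
})

test_that("simulated reads honour planted frequencies, depth and error settings", {
  cfg <- small_cfg(seed = 31L, per_pool_depth = 100, error_rate = 0,
                   missing_rate = 0)
  sim <- make_genome(cfg)
  truth <- plant_variants(sim, cfg)
  reads <- simulate_pool_reads(sim, truth, 1L, cfg)

  # forced site: fixed_differential has freq 1.0 in pool 1
  site <- truth[class == "fixed_differential"][1]
  cov <- reads[rname == site$scaffold & pos <= site$pos & pos + 48L >= site$pos]
  base_at <- substr(cov$seq, site$pos - cov$pos + 1L, site$pos - cov$pos + 1L)
  expect_true(all(base_at == site$alt))

  # binomial site: pick a shared_all site, compare alt fraction to its freq
  sh <- truth[class == "shared_all"][1]
  f <- truth_freq_matrix(truth)[sh$id, 1]
  cov <- reads[rname == sh$scaffold & pos <= sh$pos & pos + 48L >= sh$pos]
  base_at <- substr(cov$seq, sh$pos - cov$pos + 1L, sh$pos - cov$pos + 1L)
  phat <- mean(base_at == sh$alt)
  expect_lt(abs(phat - f), 3 * sqrt(f * (1 - f) / length(base_at)))

  # mean realized coverage over exons within 15% of per_pool_depth
  total_exon_bp <- sim$exons[, sum(end - start + 1L)]
  frac_low <- sim$exons[, sum((end - start + 1L) * low_coverage)] / total_exon_bp
  expected <- cfg$per_pool_depth *
    (1 - frac_low * (1 - cfg$low_coverage_factor))
  realized <- sum(nchar(reads$seq)) / total_exon_bp
  expect_lt(abs(realized - expected) / expected, 0.15)
})

test_that("depth 0 yields an empty SAM body under a valid header", {
  cfg <- small_cfg(seed = 41L, per_pool_depth = 0)
  sim <- make_genome(cfg)
  truth <- plant_variants(sim, cfg)
  sam <- tempfile(fileext = ".sam")
  reads <- simulate_pool_reads(sim, truth, 1L, cfg, sam = sam)
  expect_equal(nrow(reads), 0L)
  lines <- readLines(sam)
  expect_true(all(startsWith(lines, "@")))
  expect_equal(sum(startsWith(lines, "@SQ")), cfg$n_scaffolds)
  expect_error(simulate_pool_reads(sim, truth, 99L, cfg), "pool_id")
})

test_that("error and missing-call rates are realized near their settings", {
  cfg <- small_cfg(seed = 51L, per_pool_depth = 40,
                   n_variants_per_class = c(shared_all = 0L))
  sim <- make_genome(cfg)
  truth <- plant_variants(sim, cfg)
  reads <- simulate_pool_reads(sim, truth, 2L, cfg)
  bases <- unlist(strsplit(reads$seq, ""), use.names = FALSE)
  n_miss <- mean(bases == "N")
  expect_lt(abs(n_miss - cfg$missing_rate), cfg$missing_rate)
  # mismatch rate against the reference approximates error_rate
  refv <- strsplit(sim$seqs[[1]], "")[[1]]
  ref_bases <- unlist(lapply(seq_len(nrow(reads)), function(i)
    refv[reads$pos[i]:(reads$pos[i] + 48L)]), use.names = FALSE)
  mm <- mean(bases != ref_bases & bases != "N")
  expect_lt(abs(mm - cfg$error_rate) / cfg$error_rate, 0.35)
})
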