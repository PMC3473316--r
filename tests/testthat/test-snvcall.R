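ref20 <- stats::setNames(strrep("A", 100), "chr1")

test_that("pileup columns aggregate depth and summed quality per allele", {
  # 7 reads matching the reference at position 10
  reads <- do.call(make_reads, replicate(7, list(pos = 10L, seq = "AAAAA"),
                                         simplify = FALSE))
  pc <- pileup_columns(reads, ref20)
  col10 <- pc[pos == 10L]
  expect_equal(nrow(col10), 1L)
  expect_equal(col10$depth, 7L)
  expect_equal(col10$qual_sum, 7 * 30)

  # 4 reference + 3 alternate reads
  reads <- do.call(make_reads, c(
    replicate(4, list(pos = 10L, seq = "AAAAA"), simplify = FALSE),
    replicate(3, list(pos = 10L, seq = "AAGAA", qual = 25L), simplify = FALSE)))
  col12 <- pileup_columns(reads, ref20)[pos == 12L][order(allele)]
  expect_equal(col12$allele, c("A", "G"))
  expect_equal(col12$depth, c(4L, 3L))
  expect_equal(col12$qual_sum, c(120, 75))

  # empty input
  expect_equal(nrow(pileup_columns(make_reads(list(pos = 1L, seq = "A"))[0],
                                   ref20)), 0L)
})

test_that("N bases, zero-quality bases and excluded alignments do not contribute", {
  reads <- make_reads(
    list(pos = 1L, seq = "ANAAA", qual = c(30L, 30L, 0L, 30L, 30L)),
    list(pos = 1L, seq = "AAAAA", mapq = 0L),            # below min_mapq
    list(pos = 1L, seq = "AAAAA", flag = 4L),            # unmapped
    list(pos = 1L, seq = "AAAAA", flag = 256L),          # secondary
    list(pos = 1L, seq = "AAAAA", flag = 1024L),         # duplicate
    list(pos = 1L, seq = "AAAAA"))
  pc <- pileup_columns(reads, ref20)
  expect_equal(pc[pos == 1L]$depth, 2L)  # reads 1 and 6
  expect_equal(nrow(pc[pos == 2L]), 1L)  # the N excluded
  expect_equal(pc[pos == 2L]$depth, 1L)
  expect_equal(pc[pos == 3L]$depth, 1L)  # the quality-0 base excluded
})

test_that("unsorted or mismatching alignments are rejected", {
  reads <- make_reads(list(pos = 30L, seq = "AAAA"), list(pos = 10L, seq = "AAAA"))
  reads <- reads[c(2, 1)][order(-pos)]  # deliberately out of order
  expect_error(pileup_columns(reads, ref20), "unsorted")
  reads <- make_reads(list(pos = 1L, seq = "AAAA", rname = "chrX"))
  expect_error(pileup_columns(reads, ref20), "mismatch")
})

test_that("SAM files round-trip through the Rsamtools path", {
  reads <- do.call(make_reads, c(
    replicate(4, list(pos = 10L, seq = "AAAAA"), simplify = FALSE),
    replicate(3, list(pos = 10L, seq = "AAGAA"), simplify = FALSE)))
  sam <- write_sam_fixture(reads, c(chr1 = 100L))
  pc_file <- pileup_columns(sam, ref20)
  pc_mem <- pileup_columns(reads, ref20)
  expect_equal(as.data.frame(pc_file), as.data.frame(pc_mem))
})

test_that("insertions and deletions appear as anchored indel alleles", {
  # read with a 2-bp insertion after position 12 and one with a 1-bp deletion
  reads <- make_reads(
    list(pos = 10L, seq = "AAATTAA", cigar = "3M2I2M"),
    list(pos = 10L, seq = "AAAA", cigar = "2M1D2M"))
  pc <- pileup_columns(reads, ref20)
  expect_equal(pc[allele == "+TT"]$pos, 12L)
  expect_equal(pc[allele == "-1"]$pos, 11L)
  # the anchor base observation is replaced by the indel observation, and the
  # deleted base is not observed by the deletion-carrying read
  expect_equal(pc[pos == 12L]$allele, "+TT")
  expect_equal(pc[pos == 11L][order(allele)]$allele, c("-1", "A"))
  expect_equal(classify_kind(c("A", "+TG")), "INDEL")
  expect_equal(classify_kind(c("A", "G")), "SNP")
  expect_equal(classify_kind(c("A", "G", "-1")), "INDEL")
})

test_that("covered length counts positions at the depth floor", {
  cols <- data.table::data.table(
    scaffold = "chr1", pos = c(1L, 1L, 2L, 3L, 4L),
    allele = c("A", "G", "A", "A", "A"),
    depth = c(3L, 3L, 6L, 7L, 5L), qual_sum = 100)
  expect_equal(covered_length(cols), 3L)
  cols5 <- data.table::data.table(scaffold = "chr1", pos = 1:4, allele = "A",
                                  depth = 5L, qual_sum = 100)
  expect_equal(covered_length(cols5), 0L)
})

test_that("calling applies the coverage, support and quality thresholds", {
  p <- call_params()
  mk <- function(n_ref, n_alt, q_ref = 30L, q_alt = 30L) {
    do.call(make_reads, c(
      replicate(n_ref, list(pos = 10L, seq = "A", qual = q_ref), simplify = FALSE),
      if (n_alt > 0)
        replicate(n_alt, list(pos = 10L, seq = "G", qual = q_alt),
                  simplify = FALSE)))
  }
  # depth 5: below the 6X floor, no call
  calls <- call_pool_variants(pileup_columns(mk(3, 2), ref20), ref20, p)
  expect_equal(nrow(calls), 0L)
  # 4 ref @Q30 + 3 alt @Q30: alt qual_sum 90 >= 70, polymorphic SNP
  calls <- call_pool_variants(pileup_columns(mk(4, 3), ref20), ref20, p)
  expect_equal(calls$status, "polymorphic")
  expect_equal(calls$alleles, "A,G")
  expect_equal(calls$kind, "SNP")
  expect_equal(calls$maf, 4 / 7)
  expect_equal(calls$quality, 90)
  # 4 ref @Q30 + 3 alt @Q20: qual_sum 60 < 70, monomorphic on the majority
  calls <- call_pool_variants(pileup_columns(mk(4, 3, q_alt = 20L), ref20, p),
                              ref20, p)
  expect_equal(calls$status, "monomorphic")
  expect_equal(calls$alleles, "A")
  # 2 alt reads never reach support even at depth 6
  calls <- call_pool_variants(pileup_columns(mk(4, 2), ref20), ref20, p)
  expect_equal(calls$status, "monomorphic")
  # majority tie broken lexicographically
  calls <- call_pool_variants(pileup_columns(mk(3, 3), ref20), ref20, p)
  expect_equal(calls$major_allele, "A")
  expect_equal(calls$maf, 0.5)
})

test_that("merging pools keeps polymorphic and fixed-difference records only", {
  p <- call_params()
  fixed_reads <- function(base) do.call(make_reads, replicate(
    8, list(pos = 10L, seq = base), simplify = FALSE))
  prof_a <- pool_profile(1L, fixed_reads("A"), ref20, p)  # fixed reference
  prof_g <- pool_profile(8L, fixed_reads("G"), ref20, p)  # fixed alternate

  # a single pool monomorphic for the reference everywhere: no records
  v <- merge_pool_calls(list(prof_a), ref20, p)
  expect_equal(nrow(v), 0L)

  # pool 1 fixed A, pool 8 fixed G: one record with two alleles, MAF 1 each
  v <- merge_pool_calls(list(prof_a, prof_g), ref20, p)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 10L)
  expect_equal(sort(strsplit(v$alleles, ",")[[1]]), c("A", "G"))
  expect_equal(v$pool1_maf, 1)
  expect_equal(v$pool8_maf, 1)
  expect_equal(v$pool1_status, "fixed_ref")
  expect_equal(v$pool8_status, "fixed_alt")
  expect_equal(v$global_maf, 0.5)

  expect_error(merge_pool_calls(list(prof_a, prof_a), ref20, p), "duplicate")
})

test_that("calls match a brute-force evaluation of the rules on random fixtures", {
  p <- call_params()
  for (seed in c(101, 202, 303, 404, 505)) {
    fx <- random_fixture(seed)
    pkg <- call_pool_variants(pileup_columns(fx$reads, fx$ref), fx$ref, p)
    bf <- brute_force_calls(fx$reads, fx$ref, p)
    expect_equal(pkg$pos, bf$pos, label = sprintf("positions (seed %d)", seed))
    expect_equal(pkg$status, bf$status, label = sprintf("status (seed %d)", seed))
    expect_equal(pkg$alleles, bf$alleles, label = sprintf("alleles (seed %d)", seed))
    expect_equal(pkg$maf, bf$maf, tolerance = 1e-12,
                 label = sprintf("maf (seed %d)", seed))
  }
})
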