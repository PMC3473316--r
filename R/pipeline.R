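#' Run the full pooled SNV pipeline on synthetic data
#'
#' Executes simulate -> clean -> pileup/call -> merge -> annotate ->
#' diversity -> filter/panel on a synthetic experiment, entirely in memory
#' (file outputs optional). Deterministic for a fixed configuration seed.
#'
#' @param config A [sim_config()].
#' @param call_params A [call_params()].
#' @param clean_params A [clean_params()].
#' @param outdir Optional directory; when given, the genome FASTA, gene GFF3,
#'   truth TSV/VCF, per-pool SAM/FASTQ, cleaned FASTQ, merged VCF and the
#'   summary TSVs are written there.
#' @param panel A [panel_criteria()] or `NULL` to skip panel selection.
#' @param quiet Suppress progress messages.
#' @return A list with `sim`, `truth`, `qc` (per-pool attrition reports),
#'   `profiles`, `variants`, `models`, `summary` (per-pool diversity),
#'   `pairwise` (shared/fixed-differential matrix), `shared_all`,
#'   `features` (gene/feature report), `filters` (filter-combination table)
#'   and `panel`.
#' @export
run_pool_pipeline <- function(config = sim_config(),
                              call_params = poolsnv::call_params(),
                              clean_params = poolsnv::clean_params(),
                              outdir = NULL, panel = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  write_out <- !is.null(outdir)
  if (write_out) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  say("simulating genome and %d pools", config$n_pools)
  sim <- make_genome(config)
  truth <- plant_variants(sim, config)
  if (write_out) {
    write_genome_fasta(sim, file.path(outdir, "genome.fa"))
    write_gene_gff3(sim, file.path(outdir, "genes.gff3"))
    write_truth_tsv(truth, file.path(outdir, "truth.tsv"))
    write_truth_vcf(truth, sim, file.path(outdir, "truth.vcf"))
  }

  qc <- vector("list", config$n_pools)
  profiles <- vector("list", config$n_pools)
  for (p in seq_len(config$n_pools)) {
    sam <- if (write_out) file.path(outdir, sprintf("pool%d.sam", p)) else NULL
    fastq <- if (write_out) file.path(outdir, sprintf("pool%d.fastq", p)) else NULL
    reads <- simulate_pool_reads(sim, truth, p, config, sam = sam, fastq = fastq)
    say("pool %d: %d reads", p, nrow(reads))
    raw <- data.table(id = reads$qname, seq = reads$seq, qual = reads$qual)
    cleaned <- clean_fastq(raw, params = clean_params,
                           output = if (write_out)
                             file.path(outdir, sprintf("pool%d.clean.fastq", p))
                           else NULL)
    qc[[p]] <- cleaned$report
    profiles[[p]] <- pool_profile(p, reads, sim, call_params)
    say("pool %d: %s bp covered, %d calls", p,
        format(profiles[[p]]$covered_length, big.mark = ","),
        nrow(profiles[[p]]$calls))
  }
  qc <- rbindlist(qc)[, pool := pool_names(config$n_pools)]
  setcolorder(qc, "pool")

  say("merging calls across pools")
  variants <- merge_pool_calls(profiles, sim, call_params)
  models <- load_gene_models(sim)
  mask <- coverage_mask(profiles, call_params)
  features <- gene_summary(variants, models, mask)
  summary <- diversity_summary(variants, profiles)
  pairwise <- pairwise_matrix(variants)
  shared_all <- shared_across_all(variants)
  filters <- filter_table(variants, models)
  panel_sel <- if (!is.null(panel)) select_panel(variants, models, panel) else NULL

  if (write_out) {
    write_variant_vcf(variants, sim, file.path(outdir, "variants.vcf"))
    write_variant_tsv(variants, file.path(outdir, "variants.tsv"))
    fwrite(qc, file.path(outdir, "qc_report.tsv"), sep = "\t")
    fwrite(summary, file.path(outdir, "diversity_summary.tsv"), sep = "\t")
    fwrite(as.data.table(pairwise, keep.rownames = "pool"),
           file.path(outdir, "pairwise_matrix.tsv"), sep = "\t")
    fwrite(filters, file.path(outdir, "filter_table.tsv"), sep = "\t")
    if (!is.null(panel_sel))
      fwrite(panel_sel, file.path(outdir, "panel.tsv"), sep = "\t")
  }
  list(sim = sim, truth = truth, qc = qc, profiles = profiles,
       variants = variants, models = models, summary = summary,
       pairwise = pairwise, shared_all = shared_all, features = features,
       filters = filters, panel = panel_sel)
}
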