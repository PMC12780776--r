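# End-to-end pipeline over the synthetic fixtures: generate, reconcile,
# profile methylation, filter variants, classify effects, summarise
# diversity/LD/heterozygosity, QC, and write a report bundle of TSVs.

#' Build a validated pipeline configuration
#'
#' All thresholds default to the study parameter set implemented across the
#' package (weak = at least one modified read, high = at least 20% of
#' reads; QUAL >= 40, mean depth in [5, 500], at most 20% missing
#' genotypes, indels removed; micro-introns below 4 bp joined; 10 kb
#' diversity windows and 100 kb methylation windows; top 5% windows at
#' adjusted p < 0.01; telomere motif AACCT). Unknown keys are rejected.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed master seed driving every stage.
#' @param ... overrides of top-level sections (`genome`, `defects`,
#'   `methylation`, `variants`, `thresholds`, `stages`), each a named list
#'   whose keys must already exist in the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("gnomekit_run_"), seed = 1, ...) {
  defaults <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    genome = list(n_contigs = 3, length_range = c(60000, 80000), gc = 0.35,
                  telomere_prob = 1, genes_per_contig = 6, spare_per_contig = 1,
                  gene_spacing = 2000),
    defects = defect_config(),
    methylation = list(depth = 30),
    variants = list(theta = c(exon = 0.0006, intron = 0.0017, intergenic = 0.0012),
                    n_samples = 10,
                    effect_counts = c(synonymous = 10, missense = 5, nonsense = 1,
                                      splice_site = 2),
                    artifacts = c(low_qual = 4, bad_depth = 2, high_missing = 2,
                                  indel = 3, multiallelic = 1),
                    ld_block = 0, depth = 19),
    thresholds = list(weak_min_modified = 1, high_fraction = 0.20,
                      min_qual = 40, mean_depth_range = c(5, 500),
                      max_missing_frac = 0.20, min_intron = 4,
                      flank = 5000, splice_window = 2,
                      diversity_window = 10000, methylation_window = 100000,
                      top_frac = 0.05, alpha = 0.01,
                      telomere_motif = "AACCT", telomere_min_copies = 25,
                      telomere_end_window = 10000, telomere_max_divergence = 0.1,
                      ld_max_dist = 100000),
    stages = list(synth = TRUE, reconcile = TRUE, methprofile = TRUE,
                  popgen = TRUE, qc = TRUE)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]])) {
      bad <- setdiff(names(overrides[[k]]), names(defaults[[k]]))
      if (length(bad)) {
        stop("unknown config key(s) in '", k, "': ", paste(bad, collapse = ", "))
      }
      defaults[[k]] <- utils::modifyList(defaults[[k]], overrides[[k]])
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full synthetic-data pipeline
#'
#' Stages run in dependency order: fixture synthesis, annotation
#' reconciliation, methylation profiling, variant filtering and effect
#' classification, diversity/LD/heterozygosity/enrichment summaries, and
#' assembly QC. Every stage logs parameter and record counts to
#' `run.log`; outputs are TSV (plus FASTA/GFF3/bedMethyl/VCF fixtures)
#' under `config$out_dir`. Rerunning with an identical configuration and
#' seed reproduces every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a named list of result objects and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  th <- config$thresholds
  res <- list()
  path <- function(...) file.path(config$out_dir, ...)

  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      .log_line(con, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    .log_line(con, sprintf("stage %s done in %.2fs", name,
                           as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  # ---- synthesize ----
  gp <- config$genome
  syn <- run_stage("synth", function() {
    g <- generate_genome(n_contigs = gp$n_contigs, length_range = gp$length_range,
                         gc = gp$gc, telomere_prob = gp$telomere_prob,
                         genes_per_contig = gp$genes_per_contig,
                         spare_per_contig = gp$spare_per_contig,
                         gene_spacing = gp$gene_spacing, seed = config$seed)
    gs <- generate_gene_sets(g, config$defects, seed = config$seed)
    mp <- generate_methylation_pileup(g, depth = config$methylation$depth,
                                      seed = config$seed)
    vv <- generate_variants(g, theta = config$variants$theta,
                            n_samples = config$variants$n_samples,
                            effect_counts = config$variants$effect_counts,
                            artifacts = config$variants$artifacts,
                            ld_block = config$variants$ld_block,
                            depth = config$variants$depth, seed = config$seed)
    write_fasta(g$contigs, path("genome.fa"))
    write_gff3(gs$evidence, path("evidence.gff3"))
    write_gff3(gs$orthology, path("orthology.gff3"))
    write_bedmethyl(mp, path("pileup.bedmethyl.tsv"))
    write_vcf(vv$variants, path("variants.vcf"))
    write_ledger(rbind(gs$ledger[c("kind", "detail")],
                       vv$ledger[c("kind", "detail")]), path("truth_ledger.tsv"))
    .log_line(con, "synth: ", length(g$contigs), " contigs, ",
              n_transcripts(gs$evidence), "+", n_transcripts(gs$orthology),
              " transcripts, ", nrow(mp), " pileup records, ",
              n_sites(vv$variants), " variant sites")
    list(genome = g, gene_sets = gs, pileup = mp, variants = vv)
  })
  res$synthesis <- syn

  # ---- reconcile ----
  if (isTRUE(config$stages$reconcile)) {
    res$reconcile <- run_stage("reconcile", function() {
      r <- reconcile_pipeline(syn$gene_sets$evidence, syn$gene_sets$orthology,
                              syn$genome$contigs, min_intron = th$min_intron)
      write_gff3(r$set, path("merged.gff3"))
      write_reconcile_report(r, path("reconcile_report.tsv"))
      .log_line(con, "reconcile: ", n_genes(r$set), " genes, ",
                n_transcripts(r$set), " transcripts after merge")
      r
    })
  }

  # ---- methylation profile ----
  if (isTRUE(config$stages$methprofile)) {
    res$methylation <- run_stage("methprofile", function() {
      cl <- classify_sites(syn$pileup, weak_min_modified = th$weak_min_modified,
                           high_fraction = th$high_fraction)
      counts <- count_by_feature(cl, syn$genome$features)
      tab <- methylation_table(counts)
      win <- window_aggregate(cl, syn$genome$features,
                              window = th$methylation_window)
      write_methylation_table(tab, path("methylation_by_feature.tsv"))
      utils::write.table(win, path("methylation_windows.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      .log_line(con, "methprofile: ", nrow(tab), " feature rows, ",
                nrow(win), " window rows")
      list(classified = cl, table = tab, windows = win)
    })
  }

  # ---- popgen ----
  if (isTRUE(config$stages$popgen)) {
    res$popgen <- run_stage("popgen", function() {
      flt <- filter_variants(syn$variants$variants, min_qual = th$min_qual,
                             mean_depth_range = th$mean_depth_range,
                             max_missing_frac = th$max_missing_frac)
      write_vcf(flt$variants, path("variants.filtered.vcf"))
      utils::write.table(flt$report, path("filter_report.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      snv <- flt$variants
      keep <- !.is_indel(snv$sites)
      snv <- variant_table(snv$sites[keep, , drop = FALSE],
                           snv$gt[keep, , drop = FALSE],
                           snv$dp[keep, , drop = FALSE],
                           snv$samples, snv$contig_lengths)
      genes <- if (!is.null(res$reconcile)) res$reconcile$set else syn$gene_sets$evidence
      eff <- classify_effects(snv, genes, syn$genome$contigs,
                              flank = th$flank, splice_window = th$splice_window)
      utils::write.table(eff, path("effects.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      win <- windowed_diversity(flt$variants, window = th$diversity_window)
      utils::write.table(win, path("diversity_windows.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fd <- feature_diversity(flt$variants, syn$genome$features,
                              window = th$diversity_window)
      utils::write.table(fd$tests, path("feature_diversity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      enr <- chromosome_enrichment(win, top_frac = th$top_frac, alpha = th$alpha)
      utils::write.table(enr, path("chromosome_enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ld <- ld_decay(flt$variants, max_dist = th$ld_max_dist)
      utils::write.table(ld, path("ld_curve.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      het <- inbreeding_F(flt$variants)
      utils::write.table(het, path("sample_het.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      summ <- variant_summary(eff, flt$variants,
                              sum(flt$variants$contig_lengths))
      utils::write.table(summ$totals, path("variant_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      .log_line(con, "popgen: ", n_sites(flt$variants), " filtered sites, ",
                nrow(win), " diversity windows")
      list(filtered = flt, effects = eff, windows = win, feature = fd,
           enrichment = enr, ld = ld, het = het, summary = summ)
    })
  }

  # ---- qc ----
  if (isTRUE(config$stages$qc)) {
    res$qc <- run_stage("qc", function() {
      st <- assembly_stats(syn$genome$contigs)
      tel <- find_telomeres(syn$genome$contigs, motif = th$telomere_motif,
                            min_copies = th$telomere_min_copies,
                            end_window = th$telomere_end_window,
                            max_divergence = th$telomere_max_divergence)
      qc_df <- data.frame(
        metric = c("n_contigs", "total_length", "mean_length", "gc",
                   "N50", "N70", "N90", "longest", "n_telomeres"),
        value = c(st$n_contigs, st$total_length, st$mean_length, st$gc,
                  st$N50["length"], st$N70["length"], st$N90["length"],
                  st$longest, nrow(tel)))
      utils::write.table(qc_df, path("assembly_qc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(tel, path("telomeres.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      .log_line(con, "qc: ", nrow(tel), " telomere call(s)")
      list(stats = st, telomeres = tel)
    })
  }

  .log_line(con, "pipeline complete: ", config$out_dir)
  invisible(res)
}
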