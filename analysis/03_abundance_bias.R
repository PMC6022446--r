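#!/usr/bin/env Rscript

# Step 3: map the simulated viromes from step 1 against the community
# contigs, compute RPKM profiles, fold changes against the unamplified
# virome, the highly-biased contig fraction, read GC histograms and the
# GC/fold-change regression.
#
# Reads:  results/contigs.fasta, results/reads_<style>.fastq
# Writes: results/rpkm.tsv, results/fold_changes.tsv,
#         results/gc_histograms.tsv, results/alignments_<style>.sam

suppressPackageStartupMessages(library(virobias))

out_dir <- "results"
genomes <- read_fasta_contigs(file.path(out_dir, "contigs.fasta"))
primer <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
styles <- c("unamplified", "mda", "sispa")

alignments <- list()
gc_hist <- list()
for (st in styles) {
  reads <- read_fastq_reads(file.path(out_dir,
                                      sprintf("reads_%s.fastq", st)),
                            sample = st)
  gc_hist[[st]] <- cbind(style = st, read_gc_histogram(reads))
  if (st == "sispa") reads <- trim_primer(reads, primer)$reads
  al <- map_reads(reads, genomes)
  write_sam(al, genomes, reads, file.path(out_dir,
                                          sprintf("alignments_%s.sam", st)))
  alignments[[st]] <- al
  cat(sprintf("%s: %d/%d reads mapped (strict identity > 0.96)\n",
              st, nrow(al), nrow(reads)))
}

ab <- compute_rpkm(alignments, genomes, library_sizes = 50000)
write_rpkm_table(ab$rpkm, file.path(out_dir, "rpkm.tsv"))

fc <- fold_changes(ab, "unamplified")
write.table(fc, file.path(out_dir, "fold_changes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nbias classes per amplified virome:\n")
print(table(fc$sample, fc$bias_class))
for (st in c("mda", "sispa")) {
  cat(sprintf("%s: %.1f%% of contigs biased beyond 10x\n", st,
              classify_biased_fraction(fc[fc$sample == st, ])))
}

gcr <- gc_fold_regression(fc[fc$sample == "mda", ], genomes)
cat(sprintf("\nGC response (MDA): log10 fold change = %.4f x GC%% + %.2f over %d linear contigs\n",
            gcr$slope, gcr$intercept, gcr$n_contigs))

write.table(do.call(rbind, gc_hist), file.path(out_dir, "gc_histograms.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
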