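#!/usr/bin/env Rscript

# Step 1: build the synthetic mock community and the virome read sets used
# by the downstream analyses. One unamplified (neutral) virome, one
# MDA-style virome (circular over-amplification + GC response), and one
# SISPA-style virome (coverage hotspots + primer-dimer reads).
#
# Writes: results/contigs.fasta, results/reads_<style>.fastq,
#         results/read_truth_<style>.tsv

suppressPackageStartupMessages(library(virobias))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 20251102
n_reads <- 50000

# A 10-genome community: 3 small circular genomes (the templates that MDA
# over-amplifies) and 7 linear genomes spanning a 30-55% GC gradient.
gcs <- seq(0.30, 0.55, length.out = 7)
genomes <- rbind(
  do.call(rbind, lapply(1:3, function(i)
    synthesize_genome(3000, 0.45, seed = seed + i,
                      id = sprintf("circ_%d", i), topology = "circular"))),
  do.call(rbind, lapply(1:7, function(i)
    synthesize_genome(6000, gcs[i], seed = seed + 10 + i,
                      id = sprintf("lin_gc%02.0f", 100 * gcs[i])))))
write_fasta_contigs(genomes, file.path(out_dir, "contigs.fasta"))

gc_tbl <- data.frame(gc_pct = c(0, 30, 45, 55, 60, 100),
                     mult = c(0.5, 0.8, 1.2, 1.2, 0.6, 0.2))
peaks <- data.frame(contig_id = genomes$id[4:10],
                    position = as.integer(genomes$length_nt[4:10] / 2),
                    fold = 25, width_nt = 100)
styles <- list(
  unamplified = neutral_bias(),
  mda = bias_params(circular_factor = 5, gc_response = gc_tbl),
  sispa = bias_params(peak_sites = peaks, primer_dimer_rate = 0.25))

for (st in names(styles)) {
  spec <- community_spec(genomes, read_length_nt = 150, sample = st,
                         seed = seed + match(st, names(styles)))
  sim <- simulate_reads(spec, styles[[st]], n_reads)
  write_fastq_reads(sim$reads, file.path(out_dir,
                                         sprintf("reads_%s.fastq", st)))
  write.table(sim$truth,
              file.path(out_dir, sprintf("read_truth_%s.tsv", st)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d reads, classes: %s\n", st, nrow(sim$reads),
              paste(names(table(sim$truth$weight_class)),
                    table(sim$truth$weight_class),
                    sep = "=", collapse = " ")))
}
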