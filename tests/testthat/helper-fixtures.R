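# Small deterministic fixtures shared across the test files.

fixture_contigs <- function() {
  contig_set(
    id = c("ctgA", "ctgB"),
    seq = c(
      paste(rep("ACGT", 250), collapse = ""),          # 1000 nt, 50% GC
      paste(rep("AACCGGTTAT", 80), collapse = "")),    # 800 nt
    topology = c("linear", "circular"))
}

# Perfect reads drawn from known positions of a contig (0-based starts).
fixture_reads_from <- function(contig, starts, read_length = 100,
                               prefix = "r") {
  seqs <- substring(contig$seq, starts + 1, starts + read_length)
  read_set(sprintf("%s%03d", prefix, seq_along(starts)), seqs)
}

fixture_qpcr <- function(seed = 7) {
  generate_qpcr_fixture(
    true_copies = c(vacc = 2e6, lambda = 5e5, m13 = 8e4),
    seed = seed)
}

random_genome <- function(n, seed, gc = 0.5, id = "g", topology = "linear") {
  synthesize_genome(n, gc, seed = seed, id = id, topology = topology)
}
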