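test_that("synthesize_genome hits length, GC target and inserts", {
  g <- synthesize_genome(10000, 0.4, seed = 2, id = "g1")
  expect_equal(nchar(g$seq), 10000L)
  expect_equal(gc_content(g$seq), 0.4, tolerance = 0.05)
  ins <- data.frame(position = 2000, length = 120, motif = "AT")
  g2 <- synthesize_genome(10000, 0.5, low_complexity_inserts = ins, seed = 2)
  expect_equal(substring(g2$seq, 2000, 2119), strrep("AT", 60))
  overlapping <- data.frame(position = c(100, 150), length = 100,
                            motif = c("A", "C"))
  expect_error(synthesize_genome(1000, 0.5,
                                 low_complexity_inserts = overlapping,
                                 seed = 1))
})

test_that("mock community members match the benchmarked genome panel", {
  m <- mock_community_members()
  expect_equal(nrow(m), 7L)
  expect_equal(sum(m$topology == "circular"), 2L)
  expect_equal(m$length_nt[m$id == "vaccinia_WR"], 194700L)
  expect_equal(m$length_nt[m$id == "PCV2a"], 1800L)
  expect_equal(unique(m$theoretical_pct), 100 / 7)
})

test_that("simulated reads are exact substrings at their truth positions", {
  g <- random_genome(5000, seed = 9, id = "lin")
  sim <- simulate_reads(community_spec(g, read_length_nt = 100, seed = 4),
                        neutral_bias(), 500)
  expect_equal(nrow(sim$reads), 500L)
  ok <- vapply(seq_len(500), function(i) {
    tr <- sim$truth[i, ]
    frag <- substring(g$seq, tr$start + 1, tr$start + 100)
    read <- sim$reads$seq[match(tr$read_id, sim$reads$id)]
    read == frag || read == revcomp(frag)
  }, TRUE)
  expect_true(all(ok))
})

test_that("circular genomes are sampled across the junction", {
  g <- synthesize_genome(2000, 0.5, seed = 10, id = "circ",
                         topology = "circular")
  sim <- simulate_reads(community_spec(g, read_length_nt = 300, seed = 5),
                        neutral_bias(), 2000)
  junction <- sim$truth$start > 2000 - 300
  expect_gt(sum(junction), 0)
  doubled <- paste0(g$seq, g$seq)
  i <- which(junction)[1]
  tr <- sim$truth[i, ]
  read <- sim$reads$seq[match(tr$read_id, sim$reads$id)]
  frag <- substring(doubled, tr$start + 1, tr$start + 300)
  expect_true(read == frag || read == revcomp(frag))
})

test_that("neutral sampling recovers relative abundances", {
  genomes <- rbind(random_genome(8000, seed = 1, id = "big"),
                   random_genome(2000, seed = 2, id = "small"))
  spec <- community_spec(genomes, abundance = c(3, 1), seed = 6)
  sim <- simulate_reads(spec, neutral_bias(), 40000)
  share <- mean(sim$truth$contig_id == "big")
  expect_equal(share, 0.75, tolerance = 0.02)
})

test_that("circular_factor skews sampling toward circular genomes", {
  genomes <- rbind(
    synthesize_genome(4000, 0.5, seed = 3, id = "c", topology = "circular"),
    synthesize_genome(4000, 0.5, seed = 4, id = "l", topology = "linear"))
  sim <- simulate_reads(community_spec(genomes, seed = 7),
                        bias_params(circular_factor = 5), 30000)
  ratio <- sum(sim$truth$contig_id == "c") / sum(sim$truth$contig_id == "l")
  expect_equal(ratio, 5, tolerance = 0.1)
})

test_that("peak sites concentrate read starts and are labelled", {
  g <- random_genome(10000, seed = 8, id = "g")
  sites <- data.frame(contig_id = "g", position = 5000, fold = 50,
                      width_nt = 100)
  sim <- simulate_reads(community_spec(g, read_length_nt = 150, seed = 8),
                        bias_params(peak_sites = sites), 20000)
  peak <- sim$truth$weight_class == "peak"
  expect_true(all(sim$truth$start[peak] >= 5000 - 150 &
                    sim$truth$start[peak] <= 5000 + 99))
  # enriched region is ~249/10000 of the genome at 50x weight
  expect_gt(mean(peak), 0.4)
})

test_that("primer-dimer reads carry a removable >35 nt prefix", {
  g <- random_genome(6000, seed = 12, id = "g")
  primer <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
  sim <- simulate_reads(community_spec(g, read_length_nt = 150, seed = 9),
                        bias_params(primer_dimer_rate = 0.5), 2000)
  dimer_ids <- sim$truth$read_id[sim$truth$weight_class == "primer_dimer"]
  expect_gt(length(dimer_ids), 800)
  tr <- trim_primer(sim$reads, primer)
  expect_true(all(tr$bases_removed[dimer_ids] > 35))
  clean_ids <- setdiff(sim$reads$id, dimer_ids)
  expect_true(all(tr$bases_removed[clean_ids] <= 35))
  # trimmed dimer reads still satisfy the strict mapping contract
  al <- map_reads(tr$reads, g)
  expect_gt(mean(dimer_ids %in% al$read_id), 0.95)
})

test_that("substitution error rate is honoured", {
  g <- random_genome(4000, seed = 13, id = "g")
  sim <- simulate_reads(community_spec(g, read_length_nt = 100, seed = 10),
                        bias_params(error_rate = 0.02), 2000)
  mm <- vapply(seq_len(2000), function(i) {
    tr <- sim$truth[i, ]
    frag <- substring(g$seq, tr$start + 1, tr$start + 100)
    read <- sim$reads$seq[match(tr$read_id, sim$reads$id)]
    if (tr$strand == "-") read <- revcomp(read)
    sum(utf8ToInt(read) != utf8ToInt(frag))
  }, 0L)
  expect_equal(mean(mm) / 100, 0.02, tolerance = 0.15)
})

test_that("simulation is reproducible for a fixed seed", {
  g <- random_genome(3000, seed = 14, id = "g")
  spec <- community_spec(g, seed = 11)
  a <- simulate_reads(spec, neutral_bias(), 200)
  b <- simulate_reads(spec, neutral_bias(), 200)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})
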