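test_that("homopolymer window complexity matches the closed form", {
  cx <- linguistic_complexity(strrep("A", 10), window_nt = 10, step_nt = 10)
  # V_k = 1 for all k; denominators min(4^k, W-k+1) = 4,9,8,7,6,5,4
  expect_equal(cx$complexity, 1 / (4 * 9 * 8 * 7 * 6 * 5 * 4),
               tolerance = 1e-14)
})

test_that("complexity agrees with Biostrings k-mer enumeration", {
  g <- random_genome(500, seed = 61)
  cx <- linguistic_complexity(g, window_nt = 50, step_nt = 20)
  brute <- vapply(seq_len(nrow(cx)), function(i) {
    w <- Biostrings::DNAString(substring(g$seq, cx$start[i] + 1, cx$end[i]))
    prod(vapply(1:7, function(k) {
      vk <- sum(Biostrings::oligonucleotideFrequency(w, k) > 0)
      vk / min(4^k, 50 - k + 1)
    }, 0))
  }, 0)
  expect_equal(cx$complexity, brute, tolerance = 1e-12)
})

test_that("low-complexity inserts depress windowed complexity", {
  ins <- data.frame(position = 300, length = 150, motif = "AT")
  g <- synthesize_genome(1000, 0.5, low_complexity_inserts = ins, seed = 62)
  cx <- linguistic_complexity(g)
  inside <- cx$start >= 300 & cx$end <= 450
  expect_lt(max(cx$complexity[inside]), min(cx$complexity[!inside]))
})

test_that("primer_spec derives constant part, scan words and trim words", {
  p <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
  expect_equal(p$constant, "GACCATCTAGCGACCTCCAC")
  expect_equal(length(p$scan_words), 8L)
  expect_true(all(nchar(p$scan_words) == 8))
  # the 8 words are the overlapping 8-mers of the constant part's last 15 nt
  last15 <- substring(p$constant, 6, 20)
  expect_equal(p$scan_words, substring(last15, 1:8, 8:15))
  expect_equal(length(p$trim_words), 3L)
  expect_true(all(nchar(p$trim_words) == 15))
  expect_error(primer_spec("short", "ACGTNNNN"))
})

test_that("scan_primer_sites reports 0-based hits on both strands", {
  p <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
  word <- p$scan_words[1]
  seq <- paste0(strrep("T", 100), word, strrep("T", 100), revcomp(word),
                strrep("T", 100))
  hits <- scan_primer_sites(seq, p)
  fwd <- hits[hits$strand == "+" & hits$word == word, ]
  rev <- hits[hits$strand == "-" & hits$word == word, ]
  expect_true(100 %in% fwd$position)
  expect_true(208 %in% rev$position)
})

test_that("trim_primer removes through the rightmost in-window match", {
  p <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
  genomic <- substring(random_genome(300, seed = 63)$seq, 1, 120)
  # single full primer instance (constant + realised tail) then genome
  single <- paste0(p$constant, "ACGTACGT", genomic)
  reads <- read_set("r1", single)
  tr <- trim_primer(reads, p)
  expect_equal(unname(tr$bases_removed["r1"]), 20L)
  expect_equal(tr$reads$seq[1], paste0("ACGTACGT", genomic))
  # a read with no primer is untouched
  tr2 <- trim_primer(read_set("r2", genomic), p)
  expect_equal(unname(tr2$bases_removed["r2"]), 0L)
  expect_equal(tr2$reads$seq[1], genomic)
})

test_that("trim_primer tolerates one mismatch but not two", {
  p <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
  genomic <- substring(random_genome(300, seed = 64)$seq, 1, 100)
  one_mm <- paste0("GACCATCTAGCGACCTCCAG", genomic)   # last base changed
  two_mm <- paste0("GACCATCTATCTACCTCCAC", genomic)  # mm at 10 and 12,
  # inside all three 15-mer trim windows (1-15, 3-17, 6-20)
  tr <- trim_primer(read_set(c("a", "b"), c(one_mm, two_mm)), p)
  expect_equal(unname(tr$bases_removed["a"]), 20L)
  expect_equal(unname(tr$bases_removed["b"]), 0L)
})

test_that("primer-dimer windows report the share of >35 nt trims", {
  ctg <- contig_set("c", strrep("ACGT", 50))  # 200 nt
  al <- data.frame(read_id = c("d1", "d2", "n1", "n2"),
                   contig_id = "c",
                   start = c(0L, 10L, 0L, 150L), end = c(60L, 70L, 60L, 200L))
  removed <- c(d1 = 48L, d2 = 40L, n1 = 0L, n2 = 48L)
  win <- primer_dimer_windows(al, removed, ctg)
  first <- win[win$start == 0, ]
  # reads overlapping [0,50): d1, d2, n1 -> 2/3 dimers
  expect_equal(first$pct_dimer_reads, 100 * 2 / 3)
  empty <- win[win$start == 80, ]
  expect_true(is.na(empty$pct_dimer_reads))
})

test_that("circularity is detected on circles and rejected on lines", {
  circ <- synthesize_genome(3000, 0.5, seed = 65, id = "circ",
                            topology = "circular")
  lin <- synthesize_genome(3000, 0.5, seed = 66, id = "lin")
  doubled <- paste0(circ$seq, circ$seq)
  junction <- read_set(sprintf("j%d", 1:5),
                       substring(doubled, 2851 + 0:4 * 7, 3150 + 0:4 * 7))
  call <- detect_circularity(circ, junction, min_support = 1)
  expect_true(call$is_circular)
  expect_equal(call$supporting_reads, 5L)
  lin_reads <- fixture_reads_from(lin, c(0, 500, 2700), read_length = 300)
  call2 <- detect_circularity(lin, lin_reads)
  expect_false(call2$is_circular)
  expect_equal(call2$supporting_reads, 0L)
})

test_that("junction arms respect the 60 nt / 3 mismatch / 2 indel bounds", {
  circ <- synthesize_genome(2400, 0.5, seed = 67, id = "c",
                            topology = "circular")
  doubled <- paste0(circ$seq, circ$seq)
  # read splits 50 | 250: first arm far below the minimum overlap
  # (too short to rescue with the 2-indel allowance)
  short_arm <- substring(doubled, 2351, 2650)
  expect_false(detect_circularity(
    circ, read_set("s", short_arm))$is_circular)
  # balanced split with 3 scattered mismatches is accepted...
  ok <- substring(doubled, 2251, 2550)
  mutate_at <- function(s, pos) {
    for (p in pos) substring(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                                 substring(s, p, p))[1]
    s
  }
  expect_true(detect_circularity(
    circ, read_set("m3", mutate_at(ok, c(20, 80, 140))))$is_circular)
  # ...four mismatches on one arm are not
  expect_false(detect_circularity(
    circ, read_set("m4", mutate_at(ok, c(20, 50, 80, 140))))$is_circular)
})

test_that("reverse-complement junction reads also support circularity", {
  circ <- synthesize_genome(2400, 0.5, seed = 68, id = "c",
                            topology = "circular")
  doubled <- paste0(circ$seq, circ$seq)
  rc <- revcomp(substring(doubled, 2251, 2550))
  expect_true(detect_circularity(circ, read_set("rc", rc))$is_circular)
})

test_that("peak annotation distinguishes primer and low-complexity causes", {
  p <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
  peaks <- data.frame(start = c(100L, 1000L), end = c(300L, 1200L),
                      peak_mean = c(50, 40), fold = c(10, 8))
  complexity <- data.frame(start = seq(0, 1950, 50),
                           end = seq(50, 2000, 50),
                           complexity = 0.9)
  complexity$complexity[complexity$start >= 1000 &
                          complexity$end <= 1200] <- 0.001
  hits <- data.frame(position = 150L, strand = "+", word = p$scan_words[1])
  ann <- associate_peaks_with_signals(peaks, complexity, list(K8N = hits))
  expect_equal(ann$annotations$category, c("primer_specific",
                                           "low_complexity"))
  expect_equal(unname(ann$counts[c("primer_specific", "low_complexity")]),
               c(1L, 1L))
})
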