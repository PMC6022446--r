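test_that("map_reads recovers exact origins, strands and identities", {
  g <- random_genome(5000, seed = 31, id = "ref")
  starts <- c(0L, 123L, 2500L, 4900L)
  reads <- fixture_reads_from(g, starts)
  reads$seq[2] <- revcomp(reads$seq[2])
  al <- map_reads(reads, g)
  al <- al[order(al$read_id), ]
  expect_equal(al$start, starts)
  expect_equal(al$end, starts + 100L)
  expect_equal(al$strand, c("+", "-", "+", "+"))
  expect_equal(al$mismatches, rep(0L, 4))
  expect_equal(al$identity, rep(1, 4))
})

test_that("mapping identity threshold is strict at 0.96", {
  g <- random_genome(3000, seed = 32, id = "ref")
  base <- substring(g$seq, 1001, 1100)
  mutate_at <- function(s, pos) {
    for (p in pos) {
      old <- substring(s, p, p)
      new <- setdiff(c("A", "C", "G", "T"), old)[1]
      substring(s, p, p) <- new
    }
    s
  }
  reads <- read_set(c("mm3", "mm4"),
                    c(mutate_at(base, c(10, 40, 70)),
                      mutate_at(base, c(10, 40, 70, 90))))
  al <- map_reads(reads, g)
  expect_equal(al$read_id, "mm3")        # 0.97 passes, 0.96 does not
  expect_equal(al$mismatches, 3L)
})

test_that("ambiguous placements resolve by the deterministic tie-break", {
  # identical duplicated segment: fewest mismatches tie -> lexicographic
  # contig id -> smallest start -> plus strand
  seg <- synthesize_genome(400, 0.5, seed = 33)$seq
  ctg <- contig_set(c("b_ctg", "a_ctg"),
                    c(paste0(seg, strrep("A", 50)),
                      paste0(strrep("C", 50), seg)))
  reads <- read_set("r1", substring(seg, 101, 200))
  al <- map_reads(reads, ctg)
  expect_equal(nrow(al), 1L)
  expect_equal(al$contig_id, "a_ctg")
  expect_equal(al$start, 150L)
})

test_that("RPKM matches the hand formula", {
  ctg <- contig_set(c("k1", "k2"), c(strrep("ACGT", 500), strrep("ACGT", 125)))
  al <- data.frame(read_id = sprintf("r%d", 1:30),
                   contig_id = rep(c("k1", "k2"), c(20, 10)))
  ab <- compute_rpkm(list(s1 = al), ctg, library_sizes = c(s1 = 50000))
  # k1: 20 / (2 kb * 0.05 M) = 200 ; k2: 10 / (0.5 * 0.05) = 400
  expect_equal(ab$rpkm["k1", "s1"], 200)
  expect_equal(ab$rpkm["k2", "s1"], 400)
  expect_equal(ab$counts["k1", "s1"], 20L)
})

test_that("fold changes and bias classes use strict thresholds", {
  rpkm <- cbind(ref = c(a = 10, b = 10, c = 10, d = 10, e = 0, f = 10),
                amp = c(a = 501, b = 101, c = 10, d = 0.5, e = 5, f = 0.1))
  fc <- fold_changes(rpkm, "ref")
  got <- setNames(fc$bias_class, fc$contig_id)
  expect_equal(got[["a"]], "over50")     # 50.1 > 50
  expect_equal(got[["b"]], "over10")     # 10.1
  expect_equal(got[["c"]], "neutral")    # exactly 1
  expect_equal(got[["d"]], "under01")    # 0.05
  expect_equal(got[["e"]], "undefined")  # zero reference
  expect_equal(got[["f"]], "under002")   # 0.01
})

test_that("bias class boundaries are strict", {
  expect_equal(virobias:::bias_class(c(50, 50.0001, 10, 0.1, 0.02, 0.019)),
               c("over10", "over50", "neutral", "neutral", "under01",
                 "under002"))
})

test_that("biased fraction counts only defined fold changes", {
  fc <- data.frame(contig_id = letters[1:5],
                   fold_change = c(11, 0.05, 1, NA, 2))
  expect_equal(classify_biased_fraction(fc, threshold = 10), 50)
  expect_equal(classify_biased_fraction(fc, threshold = 10,
                                        subset = c("a", "c", "e")),
               100 / 3)
})

test_that("GC histogram is a distribution with right-open bins", {
  reads <- read_set(sprintf("r%d", 1:4),
                    c("AAAA", "GGGG", "ACGC", "ACGT"))  # 0, 100, 75, 50 %GC
  h <- read_gc_histogram(reads, bin_width_pct = 50)
  expect_equal(sum(h$relative_abundance), 1)
  # [0,50) holds 0%; [50,100] holds 50, 75, 100
  expect_equal(h$relative_abundance, c(0.25, 0.75))
})

test_that("GC regression recovers a linear GC to log-fold trend", {
  gcs <- seq(32, 53, length.out = 12)
  ctg <- do.call(rbind, lapply(seq_along(gcs), function(i)
    synthesize_genome(3000, gcs[i] / 100, seed = 40 + i,
                      id = sprintf("c%02d", i))))
  true_slope <- -0.04
  fc <- data.frame(contig_id = ctg$id, sample = "amp",
                   fold_change = 10^(true_slope * gc_content(ctg$seq,
                                                             as_pct = TRUE)))
  fit <- gc_fold_regression(fc, ctg)
  expect_equal(fit$slope, true_slope, tolerance = 1e-9)
  expect_equal(fit$n_contigs, 12L)
})

test_that("RPKM table TSV round trip preserves the matrix", {
  m <- matrix(c(1.5, 0, 2.25, 10), 2,
              dimnames = list(c("c1", "c2"), c("s1", "s2")))
  path <- tempfile(fileext = ".tsv")
  write_rpkm_table(m, path)
  back <- read_rpkm_table(path)
  expect_equal(back, m)
  unlink(path)
})
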