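test_that("Bray-Curtis matches the hand formula and its edge cases", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  # sum|x-y| = 6+0+2 = 8 ; sum(x+y) = 10+4+6 = 20? no: (2+8)+(2+2)+(4+2)
  x <- c(2, 2, 4); y <- c(8, 2, 2)
  expect_equal(bray_curtis(x, y), (6 + 0 + 2) / 20)
  expect_true(is.na(bray_curtis(c(0, 0), c(0, 0))))
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)))
  expect_error(bray_curtis(c(-1, 2), c(1, 2)))
})

test_that("Sorensen uses presence sets with a strict threshold", {
  # A = {1,2,3}, B = {2,3,4}: shared 2 -> 1 - 4/6
  expect_equal(sorensen(c(5, 1, 1, 0), c(0, 2, 9, 3)), 1 - 4 / 6)
  expect_equal(sorensen(c(1, 1), c(1, 1)), 0)
  expect_equal(sorensen(c(1, 0), c(0, 1)), 1)
  # threshold is strict: abundance exactly at threshold is absent
  expect_equal(sorensen(c(0.5, 1), c(0.5, 1), presence_threshold = 0.5),
               0)
  expect_true(is.na(sorensen(c(0, 0), c(0, 0))))
})

test_that("dissimilarity_matrix agrees with the pairwise primitives", {
  rpkm <- matrix(c(10, 0, 5, 8, 2, 5, 0, 0, 7), 3,
                 dimnames = list(c("c1", "c2", "c3"), c("s1", "s2", "s3")))
  bc <- dissimilarity_matrix(rpkm, "bray_curtis")
  so <- dissimilarity_matrix(rpkm, "sorensen")
  for (i in 1:3) for (j in 1:3) {
    expect_equal(bc[i, j], bray_curtis(rpkm[, i], rpkm[, j]))
    expect_equal(so[i, j], sorensen(rpkm[, i], rpkm[, j]))
  }
  expect_equal(diag(bc), c(s1 = 0, s2 = 0, s3 = 0))
})

test_that("pearson_profile_matrix is cor() with zero-variance guards", {
  rpkm <- matrix(c(1, 2, 3, 2, 4, 6, 5, 5, 5), 3,
                 dimnames = list(c("c1", "c2", "c3"), c("s1", "s2", "flat")))
  pm <- pearson_profile_matrix(rpkm)
  expect_equal(pm["s1", "s2"], 1)
  expect_true(is.na(pm["s1", "flat"]))
  expect_equal(pm["s1", "s1"], 1)
})

test_that("NMDS embeds a perfect 1-D gradient with near-zero stress", {
  pts <- c(0, 1, 2, 3, 4, 5)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:6], letters[1:6])
  ord <- suppressWarnings(nmds_ordination(d, dims = 2, seed = 5))
  expect_lt(ord$stress, 0.01)
  emb <- dist(ord$coordinates)
  expect_gt(cor(as.vector(emb), as.vector(dist(pts))), 0.99)
})

test_that("NMDS is deterministic for a fixed seed", {
  set.seed(99)
  m <- matrix(runif(60), 10)
  d <- as.matrix(vegan::vegdist(t(m)))
  a <- suppressWarnings(nmds_ordination(d, seed = 42))
  b <- suppressWarnings(nmds_ordination(d, seed = 42))
  expect_identical(a$coordinates, b$coordinates)
  expect_identical(a$stress, b$stress)
})

test_that("homologous sharing separates same-source from unrelated reads", {
  g1 <- random_genome(4000, seed = 71, id = "g1")
  g2 <- random_genome(4000, seed = 72, id = "g2")
  mk <- function(g, s, pre) {
    sim <- simulate_reads(community_spec(g, read_length_nt = 200, seed = s),
                          neutral_bias(), 300)
    sim$reads$id <- paste0(pre, sim$reads$id)
    sim$reads
  }
  a1 <- mk(g1, 1, "a")
  a2 <- mk(g1, 2, "b")
  b1 <- mk(g2, 3, "c")
  intra <- homologous_read_sharing(a1, a2, subsample_size = 100,
                                   n_iterations = 20, seed = 4)
  inter <- homologous_read_sharing(a1, b1, subsample_size = 100,
                                   n_iterations = 20, seed = 4)
  expect_gt(intra$mean, 50)
  expect_equal(inter$mean, 0)
  expect_equal(length(intra$counts), 20L)
})

test_that("self-comparison excludes a read's hit to itself", {
  g <- random_genome(10000, seed = 73, id = "g")
  # widely spaced reads share no 100 nt homology with each other
  reads <- fixture_reads_from(g, seq(0, 9000, by = 500), read_length = 150)
  sh <- homologous_read_sharing(reads, reads, subsample_size = nrow(reads),
                                n_iterations = 2, seed = 1)
  expect_equal(sh$mean, 0)
})

test_that("the exact rule requires identical sequences either strand", {
  base <- random_genome(2000, seed = 74, id = "g")
  reads_a <- fixture_reads_from(base, c(0, 200, 400), prefix = "a")
  reads_b <- read_set(c("b1", "b2", "b3"),
                      c(reads_a$seq[1], revcomp(reads_a$seq[2]),
                        substring(base$seq, 1001, 1100)))
  sh <- homologous_read_sharing(reads_a, reads_b, subsample_size = 3,
                                n_iterations = 1, rule = "exact", seed = 2)
  expect_equal(sh$counts, 2L)
})

test_that("compare_sharing reproduces exact and approximate Mann-Whitney", {
  # disjoint supports, n = 5 each, no ties: exact p = 2/choose(10,5)
  res <- compare_sharing(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 2 / choose(10, 5))
  big <- compare_sharing(rnorm(50), rnorm(50) + 5)
  expect_lt(big$p_value, 1e-10)
})
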