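#' Simulation studies reproducing the benchmark's study conditions
#'
#' These functions bundle the fixed synthetic designs used to validate the
#' pipeline end to end: community composition, bias-recovery, coverage
#' evenness, circularity calling, peak/dimer association and beta-diversity
#' clustering. Their defaults *are* the study conditions (genome sizes,
#' depths, bias strengths); tests and the reproduction script call them
#' unchanged apart from the seed.
#'
#' @name virobias-studies
NULL

# Derive a reproducible sub-seed without integer overflow for any valid
# set.seed() input (exact in double arithmetic: |seed| * 69069 < 2^53).
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 69069 + salt) %% 2147483647)
}

# A bank of equal-abundance genomes, part circular, part linear.
study_genomes <- function(n_circular, n_linear, length_nt = 5000, gc = 0.5,
                          seed = 100) {
  mk <- function(i, topo) synthesize_genome(
    length_nt, gc, seed = derive_seed(seed, i),
    id = sprintf("%s_%03d", ifelse(topo == "circular", "circ", "lin"), i),
    topology = topo)
  rbind(
    do.call(rbind, lapply(seq_len(n_circular), mk, topo = "circular")),
    do.call(rbind, lapply(n_circular + seq_len(n_linear), mk, topo = "linear")))
}

#' Recovery of the circular over-amplification factor through the pipeline
#'
#' Simulates one neutral and one biased virome per factor from a community
#' of 3 circular and 3 linear 5 kb genomes, maps the reads under the strict
#' identity contract, normalises to RPKM, and estimates the factor as the
#' ratio of median circular to median linear fold change (biased vs
#' neutral).
#'
#' @param factors circular over-amplification factors to simulate.
#' @param n_reads reads per virome.
#' @param seed integer seed.
#' @return data frame `factor`, `estimate`, `rel_error`.
#' @export
study_circular_recovery <- function(factors = c(2, 5, 10), n_reads = 1e5,
                                    seed = 1) {
  genomes <- study_genomes(3, 3, seed = derive_seed(seed, 5))
  spec <- community_spec(genomes, read_length_nt = 150, sample = "sim",
                         seed = seed)
  neutral <- simulate_reads(spec, neutral_bias(), n_reads)
  a_neutral <- map_reads(neutral$reads, genomes)
  circs <- genomes$id[genomes$topology == "circular"]
  out <- lapply(seq_along(factors), function(i) {
    f <- factors[i]
    spec_b <- spec
    spec_b$seed <- derive_seed(seed, 1000 + i)
    biased <- simulate_reads(spec_b, bias_params(circular_factor = f), n_reads)
    a_biased <- map_reads(biased$reads, genomes)
    ab <- compute_rpkm(list(neutral = a_neutral, amplified = a_biased),
                       genomes, n_reads)
    fc <- fold_changes(ab, "neutral")
    est <- median(fc$fold_change[fc$contig_id %in% circs]) /
      median(fc$fold_change[!fc$contig_id %in% circs])
    data.frame(factor = f, estimate = est, rel_error = abs(est - f) / f)
  })
  do.call(rbind, out)
}

# GC response emulating hexamer-primed isothermal amplification:
# under-representation above ~60% GC and mild suppression at the extremes.
mda_gc_response <- function() {
  tbl <- data.frame(gc_pct = c(0, 30, 45, 55, 60, 70, 100),
                    mult = c(0.5, 0.8, 1.2, 1.2, 0.6, 0.2, 0.2))
  function(gc_pct) stats::approx(tbl$gc_pct, tbl$mult, xout = gc_pct,
                                 rule = 2)$y
}

# Peak sites for SISPA-style hotspots: `per_contig` sites per contig at
# fixed relative positions.
sispa_peak_sites <- function(genomes, per_contig = 2, fold = 25,
                             width_nt = 100) {
  rel <- seq(0.25, 0.75, length.out = per_contig)
  do.call(rbind, lapply(seq_len(nrow(genomes)), function(g)
    data.frame(contig_id = genomes$id[g],
               position = pmax(1L, as.integer(rel * genomes$length_nt[g])),
               fold = fold, width_nt = width_nt)))
}

#' Coverage-evenness ordering across amplification styles
#'
#' Simulates the same 20-contig community as an unamplified virome, an
#' MDA-style virome (GC response) and a SISPA-style virome (coverage
#' hotspots plus primer-dimer reads, trimmed before mapping), at roughly
#' 40x mean depth, and summarises per-contig trimmed coefficients of
#' coverage variation and Gini indexes.
#'
#' @param n_contigs community size.
#' @param contig_length_nt genome length.
#' @param depth target mean coverage depth.
#' @param seed integer seed.
#' @return list: `stats` (contig, style, cv, gini), `p_sispa_vs_mda`,
#'   `p_sispa_vs_neutral`, `p_mda_vs_neutral` (one-sided Mann-Whitney,
#'   greater CV).
#' @export
study_evenness_ordering <- function(n_contigs = 20, contig_length_nt = 4000,
                                    depth = 40, seed = 1) {
  genomes <- study_genomes(0, n_contigs, length_nt = contig_length_nt,
                           gc = 0.5, seed = derive_seed(seed, 3))
  rl <- 150L
  n_reads <- as.integer(n_contigs * contig_length_nt * depth / rl)
  primer <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
  styles <- list(
    neutral = neutral_bias(),
    mda = bias_params(gc_response = mda_gc_response()),
    sispa = bias_params(peak_sites = sispa_peak_sites(genomes),
                        primer_dimer_rate = 0.25))
  stats_l <- lapply(names(styles), function(st) {
    spec <- community_spec(genomes, read_length_nt = rl, sample = st,
                           seed = derive_seed(seed, 2000 + match(st, names(styles))))
    sim <- simulate_reads(spec, styles[[st]], n_reads)
    reads <- if (st == "sispa") trim_primer(sim$reads, primer)$reads else
      sim$reads
    al <- map_reads(reads, genomes)
    do.call(rbind, lapply(seq_len(nrow(genomes)), function(g) {
      cov <- build_coverage(al, genomes[g, ])
      data.frame(contig_id = genomes$id[g], style = st,
                 cv = coverage_cv(cov), gini = lorenz_curve(cov)$gini,
                 stringsAsFactors = FALSE)
    }))
  })
  stats <- do.call(rbind, stats_l)
  cvs <- split(stats$cv, stats$style)
  ginis <- split(stats$gini, stats$style)
  p_gt <- function(a, b) suppressWarnings(
    wilcox.test(a, b, alternative = "greater")$p.value)
  list(stats = stats,
       p_sispa_vs_mda = p_gt(cvs$sispa, cvs$mda),
       p_sispa_vs_neutral = p_gt(cvs$sispa, cvs$neutral),
       p_mda_vs_neutral = p_gt(cvs$mda, cvs$neutral),
       p_gini_sispa_vs_mda = p_gt(ginis$sispa, ginis$mda),
       p_gini_sispa_vs_neutral = p_gt(ginis$sispa, ginis$neutral),
       mean_cv = vapply(cvs, mean, 0), mean_gini = vapply(ginis, mean, 0))
}

#' Sensitivity and specificity of junction-read circularity calling
#'
#' Simulates `n_circular` circular and `n_linear` linear genomes, draws
#' reads from each (wrap-around sampling guarantees junction-spanning reads
#' for the circles), and runs the circularity caller requiring at least 5
#' supporting junction reads' worth of evidence on the circular side.
#'
#' @param n_circular,n_linear number of test genomes per class.
#' @param genome_length_nt genome length.
#' @param reads_per_genome reads simulated per genome.
#' @param read_length_nt read length.
#' @param seed integer seed.
#' @return list: `sensitivity_pct`, `false_positives`, `n_eligible`
#'   (circular genomes with >= 5 junction-spanning reads).
#' @export
study_circularity_calls <- function(n_circular = 100, n_linear = 100,
                                    genome_length_nt = 3000,
                                    reads_per_genome = 200,
                                    read_length_nt = 300, seed = 1) {
  call_one <- function(i, topo) {
    g <- synthesize_genome(genome_length_nt, 0.5, seed = derive_seed(seed, 3000 + i),
                           id = sprintf("g%03d", i), topology = topo)
    sim <- simulate_reads(
      community_spec(g, read_length_nt = read_length_nt, seed = derive_seed(seed, 7000 + i)),
      neutral_bias(), reads_per_genome)
    n_junction <- sum(sim$truth$start > genome_length_nt - read_length_nt)
    call <- detect_circularity(g, sim$reads, end_segment_nt = 500)
    c(junction = n_junction, circular = call$is_circular)
  }
  circ <- t(vapply(seq_len(n_circular), call_one, c(0, 0), topo = "circular"))
  lin <- t(vapply(n_circular + seq_len(n_linear), call_one, c(0, 0),
                  topo = "linear"))
  eligible <- circ[, "junction"] >= 5
  list(sensitivity_pct = 100 * mean(circ[eligible, "circular"] == 1),
       false_positives = sum(lin[, "circular"] == 1),
       n_eligible = sum(eligible))
}

#' Primer-dimer enrichment inside low-complexity coverage peaks
#'
#' Builds a contig with low-complexity inserts, simulates SISPA-style reads
#' with hotspots at those inserts and primer-dimer prefixes concentrated on
#' hotspot reads, trims primers, maps, detects high-coverage peaks,
#' annotates them against the complexity track, and reports the percentage
#' of reads mapping inside low-complexity peaks that carry a primer-dimer
#' (trimmed > 35 bp).
#'
#' @param seed integer seed.
#' @param n_reads reads simulated.
#' @return list: `pct_dimer_in_low_complexity_peaks`, `n_peaks`,
#'   `peak_categories`, `dimer_track` (windowed percentages).
#' @export
study_dimer_peaks <- function(seed = 1, n_reads = 20000) {
  inserts <- data.frame(position = c(4000, 9000), length = 200,
                        motif = c("AT", "AAC"))
  g <- synthesize_genome(12000, 0.5, low_complexity_inserts = inserts,
                         seed = derive_seed(seed, 2), id = "sispa_ctg")
  primer <- primer_spec("K8N", "GACCATCTAGCGACCTCCACNNNNNNNN")
  sites <- data.frame(contig_id = "sispa_ctg",
                      position = inserts$position, fold = 30,
                      width_nt = inserts$length)
  bias <- bias_params(peak_sites = sites, primer_dimer_rate = 0.9,
                      dimer_at_peaks = TRUE)
  sim <- simulate_reads(community_spec(g, read_length_nt = 150, seed = seed),
                        bias, n_reads)
  tr <- trim_primer(sim$reads, primer)
  al <- map_reads(tr$reads, g)
  cov <- build_coverage(al, g)
  peaks <- detect_high_coverage_peaks(cov)
  cx <- linguistic_complexity(g)
  ann <- associate_peaks_with_signals(peaks, cx,
                                      list(K8N = scan_primer_sites(g, primer)))
  lowcx <- ann$annotations[ann$annotations$category %in%
                             c("low_complexity", "both"), , drop = FALSE]
  in_peak <- rep(FALSE, nrow(al))
  for (i in seq_len(nrow(lowcx)))
    in_peak <- in_peak | (al$start < lowcx$end[i] & al$end > lowcx$start[i])
  dimer <- tr$bases_removed[al$read_id] > 35
  dtrack <- primer_dimer_windows(al, tr$bases_removed, g)
  list(pct_dimer_in_low_complexity_peaks =
         if (any(in_peak)) 100 * mean(dimer[in_peak]) else NA_real_,
       n_peaks = nrow(peaks), peak_categories = ann$counts,
       dimer_track = dtrack)
}

#' Beta-diversity clustering of biased replicates vs unrelated viromes
#'
#' Three-group design: one base community, six amplified replicates of it
#' under varying bias (circular over-amplification, GC response, hotspots),
#' and two unrelated communities assembled from different genomes. All nine
#' read sets are mapped against the pooled cross-contig set, RPKM profiles
#' are computed, and Bray-Curtis dissimilarities are ordinated by NMDS.
#'
#' @param n_reads reads per virome.
#' @param seed integer seed.
#' @return list: `rpkm`, `bray_curtis`, `sorensen`,
#'   `nearest_is_base` (logical per biased replicate), `stress`,
#'   `min_unrelated_bray`, `min_unrelated_sorensen`.
#' @export
study_beta_design <- function(n_reads = 15000, seed = 1) {
  base_g <- study_genomes(2, 6, length_nt = 4000, seed = derive_seed(seed, 1))
  unrel1 <- study_genomes(2, 6, length_nt = 4000, seed = derive_seed(seed, 301))
  unrel2 <- study_genomes(2, 6, length_nt = 4000, seed = derive_seed(seed, 601))
  unrel1$id <- paste0("u1_", unrel1$id)
  unrel2$id <- paste0("u2_", unrel2$id)
  all_contigs <- rbind(base_g, unrel1, unrel2)
  biases <- list(
    mda1 = bias_params(circular_factor = 4),
    mda2 = bias_params(circular_factor = 4,
                       gc_response = mda_gc_response()),
    mda3 = bias_params(circular_factor = 8),
    mda4 = bias_params(gc_response = mda_gc_response()),
    sispa1 = bias_params(peak_sites = sispa_peak_sites(base_g)),
    sispa2 = bias_params(peak_sites = sispa_peak_sites(base_g, fold = 10)))
  sims <- list(base = list(genomes = base_g, bias = neutral_bias()))
  for (b in names(biases)) sims[[b]] <- list(genomes = base_g, bias = biases[[b]])
  sims$unrelated1 <- list(genomes = unrel1, bias = neutral_bias())
  sims$unrelated2 <- list(genomes = unrel2, bias = neutral_bias())
  alignments <- lapply(seq_along(sims), function(i) {
    s <- sims[[i]]
    sim <- simulate_reads(
      community_spec(s$genomes, read_length_nt = 150,
                     sample = names(sims)[i], seed = derive_seed(seed, 4000 + i)),
      s$bias, n_reads)
    map_reads(sim$reads, all_contigs)
  })
  names(alignments) <- names(sims)
  ab <- compute_rpkm(alignments, all_contigs, n_reads)
  bc <- dissimilarity_matrix(ab, "bray_curtis")
  so <- dissimilarity_matrix(ab, "sorensen")
  biased <- names(biases)
  nearest_is_base <- vapply(biased, function(s) {
    d <- bc[s, setdiff(colnames(bc), s)]
    names(which.min(d)) == "base" ||
      which.min(d[c("base", "unrelated1", "unrelated2")]) == 1
  }, TRUE)
  ord <- nmds_ordination(bc, seed = seed)
  unrel_pairs <- bc[c("base", "unrelated1", "unrelated2"),
                    c("base", "unrelated1", "unrelated2")]
  unrel_pairs_s <- so[c("base", "unrelated1", "unrelated2"),
                      c("base", "unrelated1", "unrelated2")]
  list(rpkm = ab$rpkm, bray_curtis = bc, sorensen = so,
       nearest_is_base = nearest_is_base, stress = ord$stress,
       ordination = ord,
       min_unrelated_bray = min(unrel_pairs[upper.tri(unrel_pairs)]),
       min_unrelated_sorensen = min(unrel_pairs_s[upper.tri(unrel_pairs_s)]))
}

#' Inter- vs intra-virome homologous-read sharing
#'
#' Draws two viromes from the same community and one from an unrelated
#' community, and compares resampled homologous-read counts between the
#' intra-sample pair and the inter-sample pair.
#'
#' @param n_reads reads per virome.
#' @param subsample_size,n_iterations resampling scheme.
#' @param seed integer seed.
#' @return list: `intra` and `inter` sharing distributions, `p_value`
#'   (two-sided Mann-Whitney).
#' @export
study_sharing <- function(n_reads = 2000, subsample_size = 400,
                          n_iterations = 200, seed = 1) {
  base_g <- study_genomes(1, 3, length_nt = 6000, seed = derive_seed(seed, 7))
  other_g <- study_genomes(1, 3, length_nt = 6000, seed = derive_seed(seed, 407))
  mk <- function(genomes, bias, s) simulate_reads(
    community_spec(genomes, read_length_nt = 250, seed = s), bias, n_reads)$reads
  v1 <- mk(base_g, neutral_bias(), derive_seed(seed, 5001))
  v2 <- mk(base_g, bias_params(circular_factor = 4), derive_seed(seed, 5002))
  v3 <- mk(other_g, neutral_bias(), derive_seed(seed, 5003))
  intra <- homologous_read_sharing(v1, v2, subsample_size, n_iterations,
                                   seed = derive_seed(seed, 5004))
  inter <- homologous_read_sharing(v1, v3, subsample_size, n_iterations,
                                   seed = derive_seed(seed, 5005))
  list(intra = intra, inter = inter,
       p_value = compare_sharing(inter$counts, intra$counts)$p_value)
}
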