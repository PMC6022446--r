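#' Synthesize a random genome with controlled GC and low-complexity inserts
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_target / 2` outside the
#' inserted regions; each insert is a tandem repeat of its motif, giving a
#' stretch of low linguistic complexity. Deterministic for a fixed seed.
#'
#' @param length_nt genome length.
#' @param gc_target target GC fraction in `(0, 1)`.
#' @param low_complexity_inserts optional data frame with columns `position`
#'   (1-based start), `length`, `motif`; inserts must not overlap.
#' @param seed integer seed.
#' @param id contig id.
#' @param topology `"linear"` or `"circular"`.
#' @return single-row contig table.
#' @export
synthesize_genome <- function(length_nt, gc_target = 0.5,
                              low_complexity_inserts = NULL, seed = 1,
                              id = "genome", topology = "linear") {
  stopifnot(length_nt >= 1, gc_target > 0, gc_target < 1)
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  bases <- with_seed(seed, sample(names(p), length_nt, replace = TRUE, prob = p))
  if (!is.null(low_complexity_inserts) && nrow(low_complexity_inserts) > 0) {
    ins <- low_complexity_inserts[order(low_complexity_inserts$position), ]
    ends <- ins$position + ins$length - 1L
    if (any(ends > length_nt)) stop("insert extends beyond genome length")
    if (nrow(ins) > 1 && any(ins$position[-1] <= ends[-nrow(ins)]))
      stop("low-complexity inserts overlap")
    for (i in seq_len(nrow(ins))) {
      rep_seq <- strsplit(strrep(ins$motif[i],
                                 ceiling(ins$length[i] / nchar(ins$motif[i]))),
                          "")[[1]][seq_len(ins$length[i])]
      bases[seq(ins$position[i], length.out = ins$length[i])] <- rep_seq
    }
  }
  contig_set(id, paste(bases, collapse = ""), topology)
}

#' Seven-virus mock community genomes
#'
#' Synthetic stand-ins for the seven DNA viruses of the benchmark mock
#' communities, with the published genome sizes and topologies: vaccinia WR
#' (194.7 kb linear), lambda (48.5 kb linear), adenovirus 5 (35.9 kb
#' linear), phi29 (19.3 kb linear), M13 (6.4 kb circular ssDNA), MVMp
#' (5.1 kb linear ssDNA) and PCV2a (1.8 kb circular ssDNA). Sequences are
#' random with virus-typical GC; only sizes and topologies are faithful.
#'
#' @param scale multiply genome sizes by this factor (smaller genomes keep
#'   simulations light; sizes below 1 kb are floored at 1 kb).
#' @param seed integer seed.
#' @return contig table with an extra `theoretical_pct` column per mock
#'   community design (equimolar: 14.28% each).
#' @export
mock_community_members <- function(scale = 1, seed = 42) {
  spec <- data.frame(
    id = c("vaccinia_WR", "lambda", "adenoV5", "phi29", "M13", "MVMp", "PCV2a"),
    size_nt = c(194700, 48500, 35900, 19300, 6400, 5100, 1800),
    topology = c("linear", "linear", "linear", "linear",
                 "circular", "linear", "circular"),
    gc = c(0.33, 0.50, 0.55, 0.40, 0.42, 0.43, 0.48),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    synthesize_genome(max(1000L, as.integer(round(spec$size_nt[i] * scale))),
                      spec$gc[i], seed = seed + i, id = spec$id[i],
                      topology = spec$topology[i])
  }))
  out$theoretical_pct <- 100 / nrow(out)
  out
}

#' Community specification for read simulation
#'
#' @param members contig table of member genomes (with `topology`).
#' @param abundance relative abundances (recycled, normalised to sum 1).
#' @param read_length_nt simulated read length.
#' @param paired emit both mates of each fragment.
#' @param insert_size fragment length in paired mode.
#' @param sample sample label stamped on reads.
#' @param seed integer seed.
#' @return list of class `community_spec`.
#' @export
community_spec <- function(members, abundance = 1, read_length_nt = 150,
                           paired = FALSE, insert_size = 400,
                           sample = "sim", seed = 1) {
  abundance <- rep_len(abundance, nrow(members))
  if (any(abundance < 0) || sum(abundance) <= 0)
    stop("abundances must be nonnegative with positive sum")
  if (read_length_nt > min(members$length_nt))
    stop("read length exceeds the shortest genome")
  structure(list(members = members, abundance = abundance / sum(abundance),
                 read_length_nt = read_length_nt, paired = paired,
                 insert_size = insert_size, sample = sample, seed = seed),
            class = "community_spec")
}

#' Amplification bias model parameters
#'
#' Encodes the bias modes characterised for random whole-genome
#' amplification: a multiplicative preference for circular templates
#' (MDA-like rolling-circle over-amplification), a GC-dependent sampling
#' response (under-representation of extreme-GC fragments), localised
#' coverage hotspots (SISPA-like primer/low-complexity peaks), and a
#' primer-dimer read fraction.
#'
#' @param circular_factor sampling weight multiplier for circular genomes
#'   (> 0; 1 = neutral).
#' @param gc_response `NULL` (flat), a function mapping fragment %GC (0-100)
#'   to a positive multiplier, or a data frame `gc_pct`/`mult` interpolated
#'   piecewise-linearly (constant beyond its range).
#' @param peak_sites optional data frame `contig_id`, `position` (1-based),
#'   `fold`, `width_nt`: fragments overlapping a site get weight `fold`.
#' @param primer_dimer_rate fraction of reads prefixed with a primer
#'   concatemer (two full primer instances, > 35 nt).
#' @param dimer_at_peaks when `TRUE`, the dimer prefix is applied (at
#'   `primer_dimer_rate`) only to reads sampled from peak sites, emulating
#'   dimer-driven amplification of those loci; when `FALSE` dimers are
#'   spread uniformly over reads.
#' @param primer primer string: constant 5' part plus degenerate IUPAC tail
#'   (`N`s), used to build dimer prefixes.
#' @param error_rate per-base substitution rate (0 = error-free).
#' @return list of class `bias_params`.
#' @export
bias_params <- function(circular_factor = 1, gc_response = NULL,
                        peak_sites = NULL, primer_dimer_rate = 0,
                        dimer_at_peaks = FALSE,
                        primer = "GACCATCTAGCGACCTCCACNNNNNNNN",
                        error_rate = 0) {
  if (circular_factor <= 0) stop("circular_factor must be > 0")
  if (primer_dimer_rate < 0 || primer_dimer_rate > 1)
    stop("primer_dimer_rate must be in [0, 1]")
  if (is.data.frame(gc_response)) {
    tbl <- gc_response
    if (any(tbl$mult <= 0)) stop("gc_response multipliers must be > 0")
    gc_response <- function(gc_pct)
      stats::approx(tbl$gc_pct, tbl$mult, xout = gc_pct, rule = 2)$y
  }
  structure(list(circular_factor = circular_factor, gc_response = gc_response,
                 peak_sites = peak_sites, primer_dimer_rate = primer_dimer_rate,
                 dimer_at_peaks = dimer_at_peaks, primer = toupper(primer),
                 error_rate = error_rate),
            class = "bias_params")
}

#' Neutral bias model (no amplification bias)
#' @export
neutral_bias <- function() bias_params()

# Expand a primer with IUPAC N tail into one concrete instance.
primer_instance <- function(primer) {
  ch <- strsplit(primer, "")[[1]]
  n <- ch == "N"
  if (any(n)) ch[n] <- sample(c("A", "C", "G", "T"), sum(n), replace = TRUE)
  paste(ch, collapse = "")
}

#' Simulate a biased virome read set from a community
#'
#' Fragment start positions are sampled with weight proportional to
#' `relative_abundance x circular_factor^[circular] x gc_response(fragment %GC)
#' x peak fold at covered sites`; genome-level weights use the mean position
#' weight so that, under a neutral model, per-genome read shares equal the
#' relative abundances regardless of genome length. Circular genomes are
#' sampled across the junction (wrap-around; reported start positions are
#' modulo genome length). A `primer_dimer_rate` fraction of reads carries a
#' 5' primer-concatemer prefix longer than 35 nt. Every read is recorded
#' once in the returned truth table.
#'
#' @param spec [community_spec()].
#' @param bias [bias_params()].
#' @param n_reads number of reads to simulate (>= 1).
#' @return list with elements `reads` (read table) and `truth` (data frame
#'   `read_id`, `contig_id`, `start` 0-based, `strand`, `weight_class`).
#' @export
simulate_reads <- function(spec, bias = neutral_bias(), n_reads) {
  if (n_reads < 1) stop("n_reads must be >= 1")
  members <- spec$members
  rl <- spec$read_length_nt
  with_seed(spec$seed, {
    # per-genome position weights
    pos_w <- vector("list", nrow(members))
    peak_hit <- vector("list", nrow(members))
    for (g in seq_len(nrow(members))) {
      L <- members$length_nt[g]
      circ <- members$topology[g] == "circular"
      n_starts <- if (circ) L else L - rl + 1L
      if (n_starts < 1L) stop("genome shorter than read length")
      w <- rep(1, n_starts)
      hit <- rep(FALSE, n_starts)
      seqg <- if (circ) paste0(members$seq[g], substr(members$seq[g], 1L, rl)) else
        members$seq[g]
      if (!is.null(bias$gc_response)) {
        is_gc <- strsplit(seqg, "")[[1]] %in% c("G", "C")
        cs <- c(0, cumsum(is_gc))
        frag_gc <- (cs[seq_len(n_starts) + rl] - cs[seq_len(n_starts)]) / rl
        w <- w * bias$gc_response(100 * frag_gc)
      }
      if (!is.null(bias$peak_sites)) {
        ps <- bias$peak_sites[bias$peak_sites$contig_id == members$id[g], ,
                              drop = FALSE]
        for (p in seq_len(nrow(ps))) {
          lo <- ps$position[p] - rl + 1L
          hi <- ps$position[p] + ps$width_nt[p] - 1L
          sel <- seq_len(n_starts) >= lo & seq_len(n_starts) <= hi
          w[sel] <- w[sel] * ps$fold[p]
          hit <- hit | sel
        }
      }
      pos_w[[g]] <- w
      peak_hit[[g]] <- hit
    }
    gw <- spec$abundance *
      ifelse(members$topology == "circular", bias$circular_factor, 1) *
      vapply(pos_w, mean, 0)
    counts <- as.vector(stats::rmultinom(1, n_reads, gw))

    ids <- sprintf("read_%07d", seq_len(n_reads))
    seqs <- character(n_reads)
    truth <- data.frame(read_id = ids, contig_id = character(n_reads),
                        start = integer(n_reads), strand = character(n_reads),
                        weight_class = character(n_reads),
                        stringsAsFactors = FALSE)
    k <- 0L
    for (g in seq_len(nrow(members))) {
      if (counts[g] == 0L) next
      L <- members$length_nt[g]
      circ <- members$topology[g] == "circular"
      seqg <- if (circ) paste0(members$seq[g], substr(members$seq[g], 1L, rl)) else
        members$seq[g]
      starts <- sample.int(length(pos_w[[g]]), counts[g], replace = TRUE,
                           prob = pos_w[[g]])
      strands <- sample(c("+", "-"), counts[g], replace = TRUE)
      frag <- substr(rep(seqg, counts[g]), starts, starts + rl - 1L)
      frag[strands == "-"] <- revcomp(frag[strands == "-"])
      idx <- k + seq_len(counts[g])
      seqs[idx] <- frag
      truth$contig_id[idx] <- members$id[g]
      truth$start[idx] <- (starts - 1L) %% L
      truth$strand[idx] <- strands
      cls <- ifelse(peak_hit[[g]][starts], "peak",
                    if (circ && bias$circular_factor != 1) "circular" else "neutral")
      truth$weight_class[idx] <- cls
      k <- k + counts[g]
    }
    # shuffle so genome blocks are interleaved like a real run
    ord <- sample.int(n_reads)
    seqs <- seqs[ord]
    truth <- truth[ord, ]
    truth$read_id <- ids
    rownames(truth) <- NULL

    if (bias$primer_dimer_rate > 0) {
      dimer <- stats::runif(n_reads) < bias$primer_dimer_rate
      if (isTRUE(bias$dimer_at_peaks))
        dimer <- dimer & truth$weight_class == "peak"
      if (any(dimer)) {
        # A dimer prefix is a full primer instance (realised degenerate
        # tail) followed by the second primer's constant part; the second
        # primer's tail annealed to the template, so its bases are the
        # first genomic bases of the fragment that follows.
        constant <- sub("[^ACGT].*$", "", bias$primer)
        pref <- vapply(seq_len(sum(dimer)), function(i)
          paste0(primer_instance(bias$primer), constant), "")
        seqs[dimer] <- substr(paste0(pref, seqs[dimer]), 1L, rl)
        truth$weight_class[dimer] <- "primer_dimer"
      }
    }
    if (bias$error_rate > 0) {
      seqs <- mutate_seqs(seqs, bias$error_rate)
    }
    list(reads = read_set(truth$read_id, seqs, sample = spec$sample),
         truth = truth)
  })
}

# Substitution-only error model.
mutate_seqs <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Generate a qPCR fixture: standard dilution series and sample Cq values
#'
#' Standards follow `Cq = slope * log10(copies) + intercept` over 10-fold
#' dilutions spanning at least five logs, with optional Gaussian Cq noise;
#' sample Cq values are generated identically from the true copy numbers.
#' Triplicate Cq values are emitted throughout.
#'
#' @param true_copies named numeric vector: true genome copies per virus.
#' @param slope standard-curve slope (Cq per log10 copies; must be < 0).
#' @param intercept Cq at one copy.
#' @param noise_sd_cq Gaussian noise SD on each Cq.
#' @param seed integer seed.
#' @param n_levels number of 10-fold dilution levels (>= 6 spans 5 logs).
#' @param top_copies copies at the highest standard.
#' @param n_replicates technical replicates per measurement.
#' @param sample sample label for the Cq table.
#' @return list with `standards` (virus, copies, replicate, cq) and
#'   `samples` (virus, sample, replicate, cq) data frames.
#' @export
generate_qpcr_fixture <- function(true_copies, slope = -3.3219,
                                  intercept = 38, noise_sd_cq = 0, seed = 1,
                                  n_levels = 6, top_copies = 1e8,
                                  n_replicates = 3, sample = "mock") {
  if (slope >= 0) stop("standard-curve slope must be negative")
  viruses <- names(true_copies)
  if (is.null(viruses)) stop("true_copies must be a named vector")
  with_seed(seed, {
    copies <- top_copies / 10^(seq_len(n_levels) - 1)
    std <- expand.grid(virus = viruses, copies = copies,
                       replicate = seq_len(n_replicates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    std$cq <- slope * log10(std$copies) + intercept +
      stats::rnorm(nrow(std), 0, noise_sd_cq)
    smp <- expand.grid(virus = viruses, replicate = seq_len(n_replicates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    smp$sample <- sample
    smp$cq <- slope * log10(true_copies[smp$virus]) + intercept +
      stats::rnorm(nrow(smp), 0, noise_sd_cq)
    list(standards = std, samples = smp[, c("virus", "sample", "replicate", "cq")])
  })
}
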