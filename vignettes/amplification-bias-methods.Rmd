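---
title: "Methods: quantifying amplification bias in shotgun viromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying amplification bias in shotgun viromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virobias)
```

# The problem

Shotgun sequencing of virus-enriched DNA rarely starts from enough
material, so viromes are routinely pre-amplified — either by multiple
displacement amplification (MDA; isothermal, phi29 polymerase, random
hexamer priming) or by sequence-independent single-primer amplification
(SISPA; a tagged random primer followed by PCR). Both methods distort the
sample. MDA preferentially rolls around small circular templates and
responds to fragment GC content; SISPA concentrates coverage into
primer- and low-complexity-driven hotspots and produces primer-dimer
read artefacts. `virobias` implements the quantitative toolkit needed to
measure each of those distortions, plus a synthetic mock-community read
simulator that injects them on demand, so every estimator in the package
can be validated against a known ground truth without external data.

# Model and pipeline

The analysis chain mirrors a benchmarking experiment:

1. **Mock community** — `mock_community_members()` describes a 7-virus
   panel spanning 1.8 kb (circular) to 195 kb (linear) genomes at equal
   theoretical proportions; `synthesize_genome()` generates genomes of
   chosen length, GC content and topology, optionally with embedded
   low-complexity repeats.
2. **qPCR quantification** — `fit_standard_curve()` regresses Cq on
   log10(copies); amplification efficiency is
   `(10^(-1/slope) - 1) * 100`, so the canonical slope of -3.3219 reads
   100%. `quantify_absolute()` averages technical replicates on the Cq
   scale *before* converting to copies — the order matters because the
   transform is exponential. `community_composition()` and
   `treatment_fold_changes()` track proportions across treatments.
3. **Read simulation** — `simulate_reads()` samples fragment start
   positions with weight `abundance x circular_factor^[circular] x
   gc_response(fragment GC) x peak fold`, wraps circular genomes across
   the junction, optionally prefixes reads with primer-dimer concatemers
   and applies substitution errors. Every read is recorded in a truth
   table.
4. **Mapping** — `map_reads()` enforces the strict contract used for
   contig profile comparisons: ungapped placement over the full read,
   retained only when identity is strictly greater than 0.96, with
   a deterministic best-placement tie-break (fewest mismatches, then
   lexicographic contig id, smallest start, plus strand). `write_sam()` /
   `ingest_alignments()` interoperate with standard SAM tooling.
5. **Abundance and bias** — `compute_rpkm()` normalises counts by contig
   kilobases and library millions; `fold_changes()` compares amplified
   to unamplified profiles and labels each contig with a strict
   threshold class (beyond 50x, beyond 10x, neutral, undefined);
   `classify_biased_fraction()` summarises the biased percentage;
   `gc_fold_regression()` quantifies the GC response on linear contigs.
6. **Coverage evenness** — `build_coverage()` (via IRanges),
   `coverage_cv()` (trimming `floor(0.05 L)` positions at each end
   before taking sd/mean, so assembly edge artefacts do not dominate),
   `lorenz_curve()` with `gini = 1 - 2 AUC`, `profile_correlation()`,
   and `detect_high_coverage_peaks()` (50 nt windows, 20 nt steps,
   flagged above 5x the contig median, merged across consecutive
   windows).
7. **Sequence signals** — `linguistic_complexity()` computes the
   Trifonov vocabulary-richness product over k = 1..7 in the same 50/20
   windows; `primer_spec()` derives the eight overlapping 8-mers of the
   primer's constant 3' end for site scanning and three overlapping
   15-mers for trimming; `trim_primer()` removes through the rightmost
   15-mer match (at most one mismatch) within the first 50 nt, so a
   dimer of two concatenated primers is excised in one pass and trims of
   more than 35 nt diagnose primer dimers; `detect_circularity()` calls
   a contig circular when a read splits into two arms of at least 60 nt
   that align to the contig's 3' and 5' ends with at most 3 mismatches
   and 2 indels per arm.
8. **Community comparison** — `bray_curtis()`, `sorensen()`,
   `dissimilarity_matrix()` and `nmds_ordination()` (both via vegan),
   `pearson_profile_matrix()`, and `homologous_read_sharing()` with a
   Mann-Whitney comparison of intra- versus inter-sample sharing.

# Parameter choices and why

* **Identity threshold 0.96, strict.** Full-read ungapped identity
  strictly above 0.96 keeps cross-mapping between related contigs near
  zero while tolerating up to 3 errors in a 100 nt read. The boundary is
  exclusive; a read with exactly 4% mismatches is dropped.
* **5% coverage trim.** `floor(0.05 L)` bases per end removes the
  coverage ramps that any finite-read mapping produces at contig ends;
  without it the CV of a perfectly even library would be inflated by
  geometry alone.
* **Peak rule: mean > 5x median.** The median is robust to the peaks
  themselves; a 5-fold excess over 50 nt is far outside Poisson noise at
  the depths used here (about 40x).
* **Complexity k up to 7.** For 50 nt windows, k = 7 is the largest k
  for which the vocabulary bound `min(4^k, W - k + 1)` is still driven
  by the window (44 positions versus 16384 possible 7-mers); larger k
  adds factors indistinguishable from 1.
* **Trimming rule.** Matches of the three 15-mer primer substrings are
  searched in the first 50 nt and the *rightmost* match end wins. This
  makes a single pass remove a full primer (one match, 20 nt) and a
  primer dimer (two stacked instances, ~48 nt) alike, and it is the
  behaviour that makes the "> 35 nt removed" dimer diagnostic coherent.
* **Circularity tolerances.** 60 nt minimum arm length makes spurious
  arm matches on 3 kb genomes essentially impossible (random 60-mer
  match probability ~4^-60 before mismatch allowance); 3 mismatches / 2
  indels per arm admit sequencing error without admitting repeats.
* **qPCR aggregation.** Mean-Cq-first: averaging after the exponential
  transform would bias copies upward whenever replicates disagree.

# Simulator realism and its limits

The generator is designed so that each bias mode is *identifiable*, not
so that reads look like any particular instrument. Limits worth knowing:

* Reads are single-end, fixed-length, with optional uniform substitution
  errors only — no quality profiles, indel errors or adapter read-through.
* The MDA GC response is injected as a smooth multiplier of fragment GC;
  real MDA bias also depends on secondary structure and priming density.
* SISPA hotspots are planted at chosen sites with a fixed fold; real
  hotspots arise stochastically from primer annealing.
* Primer-dimer reads are modelled as one full primer instance plus the
  second primer's constant part followed by genomic sequence — the
  second primer's degenerate tail annealed to the template, so its bases
  *are* the first template bases. This matches what trimming and strict
  mapping see in real SISPA libraries.
* The circular over-amplification factor acts as a single multiplicative
  weight per genome; rolling-circle amplification in reality produces
  length-dependent concatemer effects.

# Numerical choices

* All randomness flows through an internal `with_seed()` that saves and
  restores the global RNG state, so package functions never perturb a
  caller's random stream; study functions derive sub-seeds with an
  overflow-safe linear map, keeping every `set.seed()` input within
  integer range for any valid seed.
* Window statistics use cumulative sums (exact for integer depths);
  Gini uses the trapezoid rule on the sorted coverage distribution,
  which is exact for step functions.
* The complexity product multiplies at most seven ratios in double
  precision; the acceptance oracle verifies agreement with independent
  k-mer enumeration (Biostrings) to 1e-12 relative error.
* `fit_standard_curve()` computes R^2 from residuals directly so that a
  noiseless calibration reports exactly 1 without numerical warnings.

# Problem sizes

The bundled study designs (`study_*` functions) are sized to finish in
minutes on one CPU while leaving no statistical ambiguity: 10^5 reads
per virome for factor recovery (sampling error ~2% against a 20%
tolerance), 20 x 4 kb contigs at 40x depth for evenness ordering
(Mann-Whitney p < 1e-11), 100 + 100 genomes at 200 reads each for
circularity (every circular genome receives ~20 junction reads), and a
nine-virome design for clustering. These sizes are package choices; all
of them are function arguments and scale linearly.

# A worked example

```{r example, eval = FALSE}
genomes <- rbind(
  synthesize_genome(3000, 0.45, seed = 1, id = "circ", topology = "circular"),
  synthesize_genome(6000, 0.50, seed = 2, id = "lin"))
spec <- community_spec(genomes, read_length_nt = 150, seed = 3)
neutral <- simulate_reads(spec, neutral_bias(), 20000)
biased <- simulate_reads(spec, bias_params(circular_factor = 5), 20000)

ab <- compute_rpkm(
  list(neutral = map_reads(neutral$reads, genomes),
       mda = map_reads(biased$reads, genomes)),
  genomes, library_sizes = 20000)
fold_changes(ab, "neutral")
```

The `analysis/` directory contains six numbered scripts that run this
workflow at full scale, from simulation through qPCR, abundance bias,
coverage evenness, sequence signals and beta diversity, writing TSV
results at each step.
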