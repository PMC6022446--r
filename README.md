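# virobias

Tools to quantify the biases that virus enrichment and random
whole-genome amplification introduce into shotgun viromes.

Most DNA viromes are pre-amplified before sequencing, usually by
multiple displacement amplification (MDA, phi29 polymerase with random
priming) or sequence-independent single-primer amplification (SISPA, a
tagged random primer plus PCR). Neither method is neutral: MDA
over-amplifies small circular genomes and responds to GC content, while
SISPA piles coverage into primer- and low-complexity-driven hotspots and
generates primer-dimer read artefacts. The result is that relative
abundances, coverage profiles and even presence/absence calls in an
amplified virome can differ sharply from the underlying community.

`virobias` implements the full measurement toolkit for these effects:

* **qPCR absolute quantification** — standard curves, amplification
  efficiency, mean-Cq-first replicate handling, community composition
  and treatment fold changes (`fit_standard_curve`, `quantify_samples`,
  `community_composition`, `treatment_fold_changes`).
* **Strict-identity read mapping and RPKM abundance** — ungapped
  placement retained only above 96% full-read identity with a
  deterministic tie-break, SAM interchange, fold-change bias classes
  and the highly-biased contig fraction (`map_reads`,
  `ingest_alignments`, `compute_rpkm`, `fold_changes`,
  `classify_biased_fraction`, `gc_fold_regression`).
* **Coverage evenness** — trimmed coefficient of coverage variation,
  Lorenz curves and Gini indexes, coverage-profile correlations and
  high-coverage peak detection (`coverage_cv`, `lorenz_curve`,
  `detect_high_coverage_peaks`).
* **Sequence signals** — windowed Trifonov linguistic complexity,
  primer-site scanning, primer trimming with a >35 nt primer-dimer
  diagnostic, and junction-read circularity detection
  (`linguistic_complexity`, `trim_primer`, `primer_dimer_windows`,
  `detect_circularity`).
* **Community comparison** — Bray-Curtis and Sorensen dissimilarities,
  NMDS ordination, profile correlations and resampled homologous-read
  sharing with Mann-Whitney tests (`dissimilarity_matrix`,
  `nmds_ordination`, `homologous_read_sharing`, `compare_sharing`).
* **A bias-aware read simulator** — synthetic genomes and mock
  communities with controllable circular over-amplification, GC
  response, coverage hotspots, primer dimers and sequencing error
  (`synthesize_genome`, `mock_community_members`, `simulate_reads`),
  so every estimator can be validated against known ground truth.

## Worked example

Two genomes — a 3 kb circular and a 40 kb linear one — sequenced once
without amplification and once with a 5x circular preference, as MDA
would:

```r
library(virobias)

genomes <- rbind(
  synthesize_genome(3000, 0.45, seed = 1, id = "small_circ",
                    topology = "circular"),
  synthesize_genome(40000, 0.50, seed = 2, id = "big_lin"))
spec <- community_spec(genomes, read_length_nt = 150, seed = 3)

neutral <- simulate_reads(spec, neutral_bias(), 20000)
mda     <- simulate_reads(spec, bias_params(circular_factor = 5), 20000)

ab <- compute_rpkm(
  list(unamplified = map_reads(neutral$reads, genomes),
       mda         = map_reads(mda$reads, genomes)),
  genomes, library_sizes = 20000)
round(ab$rpkm, 1)
#>            unamplified    mda
#> small_circ    157016.7 264900
#> big_lin        12611.2   4085

fold_changes(ab, "unamplified")
#>    contig_id sample fold_change bias_class
#> 1 small_circ    mda   1.6870821    neutral
#> 2    big_lin    mda   0.3239171    neutral

cc <- detect_circularity(genomes[1, ], mda$reads)
sprintf("circular call: %s (%d junction reads)", cc$is_circular,
        cc$supporting_reads)
#> [1] "circular call: TRUE (199 junction reads)"
```

The amplified library shifts a 12.5:1 community toward the small circle
(a 1.69x / 0.32x fold-change pair, i.e. a ~5.2x relative distortion),
and the wrap-around junction reads let `detect_circularity` recover the
topology directly from the reads.

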