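# pirnakit

Quantitative machinery for studying the activation of piRNA clusters from
tandem transgene arrays in the *Drosophila* germline.

A tandem transgene array (such as the seven-copy BX2 *P-lacZ-white*
cluster) can exist as two epialleles of identical DNA sequence: OFF
(producing no piRNAs) and ON (producing abundant 23–29-nt piRNAs that
silence homologous reporters in the germline). Asking whether, how often,
and how stably the OFF state converts to ON requires a specific set of
quantitative tools, which this package implements end to end:

* **Synthetic data generation** — seeded toy genomes with a multi-copy
  tandem locus, small-RNA FASTQ libraries with controlled piRNA/siRNA/miRNA
  composition, 1U/10A biases and ping-pong pairing, qPCR plates, and
  conversion count tables (`build_reference()`,
  `simulate_small_rna_library()`, `simulate_qpcr_plate()`).
* **Exact read mapping** — adapter trimming and exhaustive 0/1-mismatch
  placement on both strands, with explicit multi-mapper handling
  (`trim_adapter()`, `map_reads()`, `filter_by_length()`,
  `unique_mappers()`).
* **Small-RNA profiles** — size/strand distributions, reads-per-million
  normalization, per-position 5′-end coverage (`size_distribution()`,
  `normalize_rpm()`, `coverage_profile()`).
* **Ping-pong signature** — overlap pair counts `O(1..29)`, z-scores
  `z(i) = (O(i) − mean(O)) / sd(O)`, and the 1U/10A composition
  percentages (`overlap_pair_counts()`, `overlap_zscores()`,
  `first_u_fraction()`, `tenth_a_fraction()`, `pingpong_signature()`).
* **Genome window scan** — 50-kb tiling, normalized per-kb piRNA
  densities, and pseudocounted log2 ratios to flag de-novo piRNA-producing
  windows between two libraries (`tile_genome()`, `window_densities()`,
  `candidate_windows()`, `log2_ratio()`, `scan_windows()`).
* **Conversion statistics** — egg-chamber totals, repression frequencies
  with Wilson intervals, homogeneity chi-square with an explicit Yates
  flag (`estimate_total_egg_chambers()`, `repression_frequency()`,
  `homogeneity_chi2()`).
* **qPCR quantification** — molecules from mass via Avogadro's number
  (`mass × 6.022e23 / (length × 650)`), standard curves and efficiencies,
  meanSq ratios, strand-specific RT background subtraction, ChIP
  enrichment, Student's t test (`copies_from_mass()`,
  `fit_standard_curve()`, `quantity_from_cq()`, `relative_expression()`,
  `strand_specific_quantity()`, `chip_enrichment()`, `two_sample_t()`).
* **Transgenerational simulator** — a stochastic model of rare, clonal,
  temperature- and target-dependent epiallele conversion with maternal
  paramutation, plus maximum-likelihood rate recovery
  (`sim_params()`, `simulate_female()`, `simulate_lineage()`,
  `recover_rate()`).
* **Pipeline** — `run_pipeline()` orchestrates simulate → trim → map →
  profile → ping-pong → window scan with plain-file intermediates and a
  JSON summary, deterministic under a seed (`demo_config()`).

The methods vignette (`vignettes/pirna-cluster-activation.Rmd`) documents
the models, parameter choices and their rationale.

## Worked example

```r
library(pirnakit)

# conversion frequency of 586 repressed egg chambers among ~21,700 scored
repression_frequency(586, 21700)
#> 2.7% (586/21700; Wilson 95% CI 2.5-2.9%)

# are complete G2 conversions homogeneous across target configurations?
homogeneity_chi2(matrix(c(17, 1447, 0, 784), 2, byrow = TRUE),
                 correct = TRUE)
#> statistic 7.69, df 1, p 0.0055

# a controlled synthetic library recovers its ping-pong structure
ref <- build_reference(locus_spec(), seed = 1)
lib <- simulate_small_rna_library(
  ref, library_spec(n_pirna = 4000, n_sirna = 500, n_mirna = 500,
                    pingpong_fraction = 0.5, seed = 2))
sig <- pingpong_signature(truth_hits(lib), lib)
#> z(10) = 5.19  (maximum at overlap 10)
#> 1U = 89.9%   10A = 90.4%   (4000 piRNA-sized reads, 2489 paired)

copies_from_mass(50e-15, 11191)
#> 4139
```

`z(10)` far above the ±2 noise band, a 5′-U fraction near 90% and a 10A
fraction near 90% among 10-nt-overlap pairs are the joint hallmarks of an
active, ping-pong-amplifying piRNA cluster; `pingpong_fraction = 0`
libraries keep `|z(10)| ≤ 2`.

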