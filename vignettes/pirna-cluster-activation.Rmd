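---
title: "Models and methods: quantifying piRNA cluster activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying piRNA cluster activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

## The biological setting

Germline transposon silencing in *Drosophila* is driven by 23–29-nt
PIWI-interacting RNAs (piRNAs) processed from heterochromatic piRNA
clusters. A tandem array of transgenes — such as the BX2 array of seven
*P-lacZ-white* insertions — can exist in two heritable epigenetic states of
the same DNA sequence: an OFF epiallele producing no piRNAs, and an ON
epiallele producing abundant piRNAs that silence any homologous reporter in
the germline. Whether the OFF state can be converted to ON by an
environmental trigger, how often, and how the converted state propagates
through generations, are quantitative questions. `pirnakit` implements the
analysis machinery those questions require — small-RNA library statistics,
a genome window scan, conversion-frequency and contingency statistics, qPCR
quantification arithmetic, and a stochastic transgenerational simulator —
together with a seeded synthetic-data generator so that every statistic can
be exercised, calibrated and tested against known ground truth.

## What the synthetic generator emulates

`build_reference()` constructs a toy chromosome with `n_copies`
byte-identical repeats of a random transgene unit (default 7 × 1000 bp on a
50-kb chromosome), a flanking gene annotated convergently (transcription
pointing into the array, the configuration that supplies antisense
read-through transcripts), and a disjoint decoy contig for miRNA reads.
`simulate_small_rna_library()` then draws three read classes:

* **piRNAs**, 23–29 nt, from the repeat block, with a configurable length
  profile (default peaked at 25–26 nt, the shape typical of germline
  piRNAs), a 5′-uridine bias, and a configurable fraction emitted as
  ping-pong pairs whose 5′ ends overlap by exactly 10 nt;
* **siRNAs**, 21 nt, strand-balanced, from the repeat block — the size
  class the OFF epiallele produces;
* **miRNAs**, 22 nt, from 20 fixed positions of the decoy contig, standing
  in for the spike-in/normalizer class of a real library.

Two design constraints shape the generator. First, *reads are never
mutated*: composition biases are realised by biased selection of 5′
positions, so that every read remains an exact substring (or reverse
complement) of the reference. This gives the suite a strong invariant —
after adapter removal every read must map back with zero mismatches — that
exercises the whole trim/map path. Second, *ping-pong pairs are genuine
reverse complements on the reference*, which couples the two composition
signals exactly as biology does: a pair whose initiator starts with U
necessarily has A at position 10 of the responder. Pair anchors are chosen
so that, with probability `a10_bias`, *both* mates carry the 1U/10A
configuration (reference base T at the anchor and A nine bases downstream);
`u1_bias` governs unpaired piRNAs independently. Setting the two biases to
the same value (the default 0.9) yields a library homogeneous in both
statistics.

Each read is extended 3′ with the sequencing adapter (recycled as needed)
and truncated to a fixed 50-cycle read length, mimicking adapter
read-through of short inserts. Qualities are constant (`I`), as the package
does not model base-calling error.

What the generator deliberately does **not** emulate: sequencing errors and
quality variation, real genome or miRBase sequence content, transcript
abundance structure along the locus, ligation biases, or PCR duplication.
Tests passing on these libraries therefore demonstrate the correctness of
the statistics and their calibration under clean conditions, not robustness
to platform artefacts.

## Read placement

`map_reads()` reports *every* ungapped placement of each read on either
strand with at most one substitution, exactly — it is a desk-scale
replacement for a genome aligner, not a heuristic. Unique sequences are
matched at C speed (`Biostrings::vmatchPattern`) and verified, and the test
suite holds the result equal to an exhaustive per-position Hamming scan.
Coordinates are 0-based half-open throughout, with converters only at
BED-style boundaries. A minus-strand hit is a placement of the reverse
complement; its 5′ end is its *highest* coordinate — all overlap arithmetic
downstream relies on this single convention.

Multi-mapping is first-class: every placement is reported and each read
carries its placement count, so downstream analyses can either drop
multi-mappers (`unique_mappers()`, the default for 23–29-nt per-position
analyses, since a 7-copy array makes its reads inherently ambiguous) or
weight placements by 1/n (`size_distribution(weighting = "fractional")`,
appropriate for whole-library size profiles where each read should count
once). Both modes exist because the two questions — "where exactly do
piRNAs map" versus "how many piRNAs of each size are there" — need
different treatments of ambiguity.

Adapter trimming truncates at the leftmost position where the read matches
a prefix of the adapter over the full remaining read length (or contains
the complete adapter), requiring at least `min_match = 6` matching bases —
the common practice for small-RNA data. Reads containing N are skipped and
counted, never errors.

## The ping-pong signature

For 23–29-nt hits on one reference, every sense/antisense pair of read
instances whose 5′ ends overlap by $i$ nucleotides increments $O(i)$, for
$i = 1..29$. The signature is standardised as

$$z(i) = \frac{O(i) - \overline{O}}{\mathrm{sd}(O)}$$

A ping-pong amplifying locus shows a sharp excess at $i = 10$. Choices made
here, both switchable:

* **Population standard deviation** (divide by 29) by default: the 29
  overlap values are the complete population of interest, not a sample
  from a larger one. `sd_type = "sample"` gives the $n-1$ variant; the two
  differ by a fixed factor of $\sqrt{29/28}$, so the ranking of overlaps is
  unaffected.
* **Read instances, not collapsed sequences**, enter the pair counts by
  default, because read multiplicity carries abundance information;
  `collapse = TRUE` counts distinct alignments once.

$\sum_i z(i) = 0$ by construction, and $z$ is invariant under uniform
scaling of the counts — both are asserted as properties in the tests. When
all $O(i)$ are equal the z-scores are undefined and a flagged all-`NA`
vector is returned rather than zeros, so "no signal" cannot be read as
"flat signal".

The composition statistics follow the field's definitions: the 1U fraction
is the percentage of 23–29-nt reads whose first nucleotide (5′→3′, read
space) is T; the 10A fraction is the percentage of reads engaged in at
least one exact-10-nt pair whose tenth nucleotide is A. Both mates of a
pair enter the 10A denominator by default (`mates = "both"`); the
single-strand variants exist because the literature is not explicit on
this point. Empty inputs return `NA` ("not determined"), mirroring how low
read counts are reported in practice. Note that on a multi-copy array,
chance pairings across copies join the designed pairs in the 10A
denominator, so the mapped-path estimate sits below the generator's
`a10_bias` while the truth-placement estimate recovers it — an expected
consequence of tandem-repeat ambiguity, not an estimator defect.

## The genome window scan

To ask whether any locus outside a known cluster started producing piRNAs
between two conditions, unique 23–29-nt mappers are assigned by 5′
coordinate to non-overlapping 50-kb windows, counts are scaled to reads per
million of a normalizer class, and densities are expressed per kb. Windows
pass the candidate filter when their density strictly exceeds 5 per kb — in
**either** library by default. The literal alternative (`mode = "both"`) is
provided, but a window silent in the OFF library and active in the ON
library — precisely the signature of a de-novo producer — would never pass
it; the default favours the reading under which the scan can find what it
is looking for. Each candidate window gets
$\log_2((c_{ON} + 1)/(c_{OFF} + 1))$; the pseudocount of 1 (a conventional
choice) keeps the ratio finite when the OFF count is zero, and windows
exceeding a caller-supplied threshold (8.5 by default) are flagged.

## Conversion statistics

Repression is scored per egg chamber; the total scored is estimated as 60
chambers per mounted ovary (three to four chambers per ovariole, 16–18
ovarioles per ovary). `repression_frequency()` reports the percentage to
one decimal with a Wilson 95% score interval — Wald intervals collapse at
zero numerators such as 0/975, Wilson intervals do not. The intervals are
an addition of this package; the original scoring scheme reported none.

`homogeneity_chi2()` is a thin, validated wrapper over Pearson's
chi-square with an explicit Yates continuity-correction flag, because
published 2×2 statistics in this literature are reproducible only when the
correction state is known: of the two tables this package reproduces in
its tests, one matches the corrected statistic (7.69 ≈ printed 7.7) and
one the uncorrected (193.0 ≈ printed 192.9, a 0.05% discrepancy of unknown
origin, tolerated at ±0.2). Each report records which was used. Low
expected counts set a flag rather than raising a warning.

## qPCR arithmetic

Absolute quantification converts a dsDNA mass to molecules as
$m \times 6.022\times10^{23} / (L \times 650)$ with $L$ the amplicon length
in bp and 650 g/mol the average base-pair weight; 50 fg of an 11,191-bp
plasmid is ≈4139 molecules. Standard curves are least-squares fits of Cq on
$\log_{10}$(quantity); efficiency follows from the slope as
$10^{-1/\text{slope}} - 1$, so the canonical slope −3.3219 means 100%
efficiency. Starting quantities (Sq) come from inverting the fitted line,
and the mean of technical triplicates (meanSq) is the unit of all
downstream ratios. Strand-specific RT quantities subtract the no-primer
control RT (self-priming background); negative differences are floored at
zero and flagged as at/below background, since a negative transcript
quantity is not interpretable. ChIP enrichment divides the target's
IP/input ratio by the mean IP/input over reference regions known to carry
the mark. Group comparisons default to Student's equal-variance *t* test
(Welch behind a flag).

## The transgenerational conversion simulator

The simulator encodes the conversion model as a small set of hard rules:

* conversion happens only at 29 °C and only when a germline-transcribed
  homologous target is present — at 25 °C or without the target the OFF
  state is absorbing;
* for an OFF female under converting conditions, each of
  `chambers_per_female / cluster_size` germline progenitors converts
  independently with probability `c_event` per generation, and a converted
  progenitor yields `cluster_size` repressed egg chambers — conversion is
  instantaneous and complete at the chamber level;
* offspring inherit the state of one uniformly chosen maternal egg
  chamber (the simplest mapping from chamber mosaicism to progeny);
* an ON mother transmits ON to each offspring with probability
  `paramutation_prob` (default 1: fully penetrant paramutation along the
  maternal line), while paternal transmission yields OFF.

Defaults are the observed study conditions: `c_event = 0.027` (the
per-chamber conversion frequency measured in a single-generation design),
120 chambers per female (2 ovaries × 60), `cluster_size = 1`. The cluster
parameter exists because the independent-chamber model with
$c = 0.027$ predicts $1-(1-c)^{120} \approx 96\%$ of females showing at
least one converted chamber, whereas ~72% was observed; clonal conversion
at the progenitor level lowers the per-female rate at a fixed per-chamber
rate, and the simulator exposes this regime for exploration rather than
asserting a fitted cluster size (no cyst-lineage data exist to fit it).

`simulate_lineage()` samples a finite number of mothers per generation
(default 50), which produces exactly the drift and between-line variance
seen in replicate lineages; `recover_rate()` gives the binomial
maximum-likelihood estimate of `c_event` from single-generation data with
its standard error, a rule-of-three-style one-sided upper bound for
all-zero data, and — as a documented diagnostic — an inferred *event
count* that is inflated by the cluster size when the independent-chamber
model is applied to clustered data.

## Numerical and testing choices

Determinism is a contract: every stochastic function takes or contains a
seed, and identical seeds give byte-identical FASTQ output and identical
trajectories. Degenerate inputs have defined behaviour (flat overlap
histograms → flagged `NA`; empty hit sets → `NA` "n.d."; zero normalizers,
degenerate contingency margins, nonnegative curve slopes → errors naming
the offender). The test suite sizes its simulations for tightness per
unit time: composition recovery uses 10⁴-read libraries (3 binomial
standard errors ≈ 1.2% at that size), the mapper oracle uses 200 reads
against a 10-kb reference, rate recovery uses 10⁴ simulated females, and
the end-to-end pipeline demonstration uses a 150-kb three-window genome.
These sizes are the package's chosen operating points for its own
validation; all scale linearly if larger runs are wanted.

## Known limitations

The mapper is exact but desk-scale: it indexes nothing and is not meant
for real genomes. The generator's miRNA decoy is synthetic, so annotation
against real miRNA catalogues is out of scope, as is any statistical test
on window ratios (the scan reports ratios and flags only). The simulator
treats partial versus complete repression in offspring only through
chamber mosaicism; it does not model the molecular mechanism of
dsRNA-triggered piRNA initiation, and `cluster_size` is a free parameter,
not an estimate.
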