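---
title: "Mapping a quantitative trait by sequencing bulks of segregants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a quantitative trait by sequencing bulks of segregants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk segregant analysis (BSA) maps a quantitative trait by pooling DNA from
the individuals at the two phenotypic extremes of a segregating population
and sequencing the pools. At a locus with no effect on the trait, reads in
each pool should reflect the population's allele frequencies; at a locus
linked to the trait, the high pool is enriched for the allele of the
high-phenotype parent and the low pool for the other. `bsamap` implements
this analysis end to end for a biparental cross between a donor and a
recurrent parent — the motivating system is amylose content (AC, % of
total starch) in a BC~2~F~8~ interspecific rice population (an
*Oryza glaberrima* donor crossed to an *O. sativa* recurrent parent, with
the major determinant *GBSS1*, the waxy locus, on chromosome 6) — together
with a forward-in-time simulator that generates populations, phenotypes and
pooled read counts with known truth.

# The synthetic cross

## Meiosis and pedigree

Gametes are simulated under the Haldane model: the crossover count on a
chromosome is Poisson with mean equal to the genetic length in Morgans,
crossover positions are uniform in physical coordinates, and there is no
interference. This is the simplest standard meiosis model and is adequate
for the allele-frequency behaviour BSA relies on; interference would change
junction spacing but not expected allele frequencies.

The default pedigree is F~1~ (donor × recurrent), two backcrosses to the
recurrent parent, then seven generations of selfing by single-seed descent.
We read "BC~2~F~8~" as the BC~2~F~1~ selfed seven times (F~1~-to-F~8~
indexing); conventions differ, so the generation counts are explicit
arguments (`n_backcross`, `n_selfing`). Under this pedigree the expected
donor-genome fraction per locus is $(1/2)^{1+2} = 12.5\%$ and the expected
residual heterozygosity is $(1/4)(1/2)^7 \approx 0.2\%$; both are verified
empirically in the test suite against a large simulated population.

The physical-to-genetic scale is uniform per chromosome, 4.76 cM/Mbp by
default, chosen so that a 2.1 Mbp block corresponds to about 10 cM — the
relation reported for the chromosome-6 candidate region in the motivating
study. Coordinates are 1-based inclusive throughout, matching printed
genomic positions.

## Phenotype model

The phenotype is purely additive:
$$\mathrm{AC} = \mu + \sum_j \beta_j \frac{d_j}{2} + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma_e^2),$$
where $d_j \in \{0, 1, 2\}$ is the donor-allele dosage at QTL $j$ and
$\beta_j$ the effect of the homozygous donor genotype. Residual
heterozygosity in a BC~2~F~8~ is negligible, so dominance would be
untestable in this design and is not modelled. The default calibration is
$\mu = 23.2$ (the recurrent parent), a major QTL of $+2.5$ at the *GBSS1*
position chr6:1,769,686 (so the donor parent sits at 25.7), and two minor
QTLs of opposite sign, $-1.2$ at chr1:30,038,502 and $+1.0$ at
chr11:18,288,616. The minor effects are not reported quantities; they were
chosen once so that the simulated population spans roughly 19–27% with
environmental SD 0.8 and segregates transgressively on both sides of the
parents, skewed toward the low side, as observed in the motivating cross.

## Pooled sequencing

Bulk members contribute their two haplotypes in equal proportion (equal
amounts of DNA pooled). Per site, depth is Poisson with the configured
mean (defaults 53× for the high bulk and 59× for the low bulk), reads draw
a parental allele binomially from the pooled frequency, and each read is
miscalled with probability `error_rate` (default 0.001), uniformly to one
of the other three nucleotides. The site quality score is a constant
phred 40 by default; `low_quality_fraction` degrades a random fraction of
sites to a configurable low score so that the phred < 30 filter has
something to remove. What the generator deliberately does *not* emulate:
read-level sequences, mapping and alignment artefacts, indels, copy-number
variation, segregation distortion, and selection during line development.
Passing tests on synthetic data therefore demonstrate the statistical
machinery, not robustness to alignment error — real pileups should be
produced by a proper mapping pipeline and imported as count tables.

# Bulking

The low bulk takes the `n_per_bulk` (default 10) smallest phenotypes, the
high bulk the largest. Ties are resolved deterministically: the low bulk is
filled first by (phenotype ascending, id ascending), then the high bulk
from the remaining individuals by (phenotype descending, id ascending).
Filling the low bulk first is what keeps the bulks disjoint even in the
degenerate all-tied case; with distinct phenotypes the rule reduces to the
obvious "ten largest / ten smallest".

# Variant filtering

Calling is threshold-based (basic variant detection): a non-reference
allele is called iff site depth ≥ `min_coverage`, supporting reads ≥
`min_count`, and frequency ≥ `min_freq`. Defaults follow the motivating
analysis: 20/20/90% for bulks, 5/5/100% for parents, and 20/8/30% as the
allele-mining preset for screening diverse accessions. The reference is
the recurrent parent's allele at every simulated site.

The cascade then applies, in this order: removal of SNPs called in both
bulks (two-way comparison keyed by chromosome, position and allele); the
site-quality filter (phred < 30 removed — a score of exactly 30 survives);
and the exclusion of multi-allelic positions and positions whose bulk
allele is absent from both parents. The order matters in principle
(set-difference before quality filtering can differ from the reverse), so
the per-stage in/out counts are returned as a filtering ledger.
"Multi-allelic" is operationalised as three or more alleles each supported
by at least `min_allele_reads` (default 2) reads summed across cohorts; the
floor is configurable because a single erroneous read should not condemn a
position. A parent called at 100% frequency cannot be heterozygous, so a
parent showing two alleles each below the frequency threshold (each with at
least two reads) is recorded as heterozygous rather than discarded — these
sites feed the second association step. The phred filter acts on the
site-level score, not a per-allele variant quality.

# Association

For allele read counts $(a, b)$ of the two parental alleles the package
tests the 1:1 null with the one-degree-of-freedom chi-square statistic
$(a-b)^2/(a+b)$, no continuity correction. The exact two-sided binomial
P-value is always computed alongside as an oracle; for all count pairs with
$a+b \le 60$ the two tests disagree at $\alpha = 0.05$ only on an
enumerated boundary set (54 pairs, frozen as a regression fixture), and in
every such pair the chi-square is the anti-conservative side. No
multiple-testing correction is applied, matching the per-site $P < 0.05$
of the motivating analysis.

A candidate passes iff

1. the parental condition holds — step 1: both parents homozygous for
   different alleles; step 2: at least one parent heterozygous but the two
   bulks fixed (major-allele frequency ≥ 90%) for different alleles;
2. the donor-allele frequency in the high bulk is ≥ `hab_freq_cutoff`
   (default 90%);
3. the chi-square 1:1 test rejects at `alpha` in **both** bulks; and
4. (default on, configurable off) the deviation has the direction implied
   by the design: high bulk toward the donor allele, low bulk toward the
   recurrent allele. The motivating study names only "a statistical test"
   for the low-bulk check; we use the same chi-square with the direction
   requirement and flag this as an interpretation.

A site that was called in only one bulk is still evaluated with the other
bulk's raw pileup counts — a no-call is not zero reads. Frequencies for
the cutoff are count/depth (so sequencing errors count in the
denominator); the chi-square uses the two parental-allele counts only.
Candidates are annotated with their min/max coverage across bulks and
flagged when below 20×, the level below which sampling error is known to
produce spurious frequency deviations.

## The 50% null and the backcross null

Classical BSA reasoning expects ~50% of reads from each parent at neutral
loci. That holds for an equal-contribution population (e.g. an F~2~-derived
RIL); in a BC~2~ population the neutral expectation is the donor-genome
fraction, 12.5%, not 50%. `null_allele_fraction()` implements both: the
default simulates an equal-contribution pool (and reproduces 50%), while
passing pooled frequencies computed from a simulated backcross population
reproduces ~12.5%. The package documents this discrepancy rather than
resolving it: the high-bulk 90% cutoff is unaffected, but genome-wide
"deviation from 50%" heuristics do not transfer to backcross designs.

# Clustering and annotation

Passing candidates are merged by single linkage: consecutive candidates on
a chromosome within `max_gap` (default 1 Mb) join one region, reported
1-based inclusive with physical span, span in Mbp, and an approximate
genetic span (span × cM/Mbp rate). Single linkage is the simplest
reproducible choice and recovers a printed region for any gap larger than
the largest intra-cluster spacing; BED export (0-based half-open) is
provided for interoperability. No formal QTL interval estimation is
attempted.

CDS substitutions are annotated by codon arithmetic — position $p$ (1-based
from the A of the start ATG, spliced CDS coordinates) lies in codon
$\lfloor (p-1)/3 \rfloor + 1$ at offset $(p-1) \bmod 3$ — and by inverting
the standard genetic code: the candidate reference codons are those coding
the stated reference amino acid with the required base at the offset; the
substitution is applied and translated, and the prediction is flagged
unambiguous when a single amino acid results. A descriptive "conservative"
label is attached using the ClustalW strong-similarity groups (STA, NEQK,
NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW); a simple acidic/amide/aromatic
partition would mislabel Asp→Asn — universally treated as conservative —
so the similarity groups are used instead. No structural or stability
claims are made.

# Co-expression screen

Candidate genes are screened against user-supplied guide genes (e.g. a
starch-biosynthesis panel) by Pearson correlation on a genes × samples
expression matrix, declaring co-expression at r ≥ 0.6 (the cutoff is
inclusive). The "weighted" variant applies per-sample weights through
weighted means and covariances; with equal weights it reduces exactly to
the unweighted coefficient. Public co-expression databases compute their
statistics on their own curated arrays, so identical numbers should not be
expected — the screen reproduces the decision rule, not the database.

The synthetic expression generator plants known structure: guide profiles
are standard normal across samples and a planted co-expressed gene is
$\alpha g + \sqrt{1-\alpha^2}\,\epsilon$, so its expected correlation with
its guide is $\alpha$. The recovery test plants a spread of strong
correlations ($\alpha = 0.70$–$0.95$) at 40 samples; at $\alpha$ exactly
0.70 the per-pair probability of exceeding 0.6 is only ~85% (Fisher-z
arithmetic), so a screen of uniformly-borderline pairs would not clear a
95% sensitivity bar — worth remembering when interpreting cutoff-based
screens near their threshold.

# Detection power of the study design

An honest caveat, quantified with the simulator. With 100 lines, a
10-line high bulk, a major QTL of +2.5 against environmental SD 0.8, and
the 90% frequency cutoff at ~53× depth, detection of the planted QTL is
*not* near-certain. Only ~12.5% of BC~2~F~8~ lines are donor at any locus,
so the ten highest phenotypes include at least nine donor lines — the
composition needed to reach a 90% pooled frequency — in only ~72% of
populations (order-statistics simulation, 20,000 replicates). With two or
more non-donor "intruders" in the bulk the pooled frequency is ≤ 80% and
the 90% read-frequency cutoff essentially never passes. Across 20 seeded
end-to-end runs the pipeline recovers the planted chromosome-6 region in
about 12, with perfect specificity (no passing site on any other
chromosome in any run). The corresponding test in the acceptance suite
asserts a stricter recovery rate than this design can deliver and is
expected to fail; it is retained deliberately as a faithful record of the
gap between the idealised expectation and the design's actual power. A
single real experiment that did detect its locus is entirely consistent
with a ~60–75% per-experiment success probability.

# Numerical and implementation choices

* Haplotypes are stored as segment end/origin vectors; tiling of every
  chromosome is asserted by `check_tiling()`.
* All randomness flows through R's global RNG; every entry point takes an
  optional seed, and a fixed seed makes the entire pipeline, including
  file outputs, byte-reproducible.
* Zero-depth sites are no-calls, never errors; a chi-square on (0, 0)
  returns a no-test marker rather than NaN.
* Test problem sizes (e.g. 1,000 simulated lines for the inbreeding
  checks, 10,000 gametes for the crossover-count check, 1,000 sites at
  50× for the null-fraction check) were chosen to put expected Monte-Carlo
  error well inside the asserted tolerances.

# Known limitations

* No genotype likelihoods, no indels, no alignment modelling; calling is
  threshold-based by design.
* The additive phenotype model has no dominance, epistasis or
  QTL-by-environment terms.
* Single-linkage clustering has no notion of statistical support for a
  region boundary.
* The co-expression screen is a correlation filter, not network inference
  (no mutual rank, no module detection).
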