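---
title: "Population consensus genomes from low-coverage pileups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population consensus genomes from low-coverage pileups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcgtools)
```

## The problem

Cohorts sequenced at low coverage (2--4x per individual) cannot be
genotyped reliably one sample at a time: at three reads per site, a
heterozygote is indistinguishable from a sequencing error, and standard
quality-score filtering has little to work with. `vcgtools` implements a
population-level alternative: treat each (sample, position) as a *unit*,
keep only units whose read evidence is internally consistent, let every
retained unit cast exactly one dominant-allele vote, and summarise the
votes across the cohort. The per-position vote distribution then drives a
four-way classification of *dynamic positions*, and the subset that
differs from the reference — the major-allele-and-indel-against-reference
set (MAIR) — is applied to the reference to produce a linear,
aligner-compatible population consensus (a "virtual" genome), together
with an indel-aware coordinate liftover map.

The design assumes many samples of modest depth from potentially
heterogeneous platforms. Equal sample weighting is deliberate: a sample
sequenced at 12x gets exactly the same one vote as a sample at 2x, so no
single deep library can dominate the population estimate.

## The unit filter

A unit's evidence is its nucleotide count vector $(c_1, \dots, c_n)$ over
the observed base types, $n \in \{1,\dots,4\}$. Its comentropy (Shannon
entropy, base 2) is

$$H = -\sum_{i=1}^{n} p_i \log_2 p_i, \qquad p_i = c_i / \textstyle\sum_j c_j ,$$

measured in bits. High $H$ means ambiguous evidence. Units are retained
when

* they carry at least `min_reads` mapped nucleotides (default **2**;
  deletion placeholders and indel events do not count), and
* $H$ is at or below an arity-specific ceiling: **0.95** bits for binary
  units, **1.50** for ternary, **1.92** for quaternary (all inclusive).
  Single-type units have $H = 0$ and always pass.

The ceilings sit just under the uniform-distribution maxima (1, 1.585
and 2 bits), so the filter discards exactly the near-uniform count
vectors — `(1,1)`, `(2,2)`, `(2,1,1,1)` — while keeping skewed ones such
as `(3,1)` ($H \approx 0.811$) or the boundary ternary `(2,1,1)`
($H = 1.5$ exactly, retained because the thresholds are inclusive). The
test suite scans every binary count vector to depth 60, every ternary to
45 and every quaternary to 32 and confirms no retained unit exceeds its
ceiling.

The dominant nucleotide of a retained unit is its count maximum. Ties are
broken toward the reference base when it is among the tied maxima,
otherwise alphabetically: deterministic, and conservative toward the
reference. Ties are only reachable at all for arities whose uniform
distribution would fail the filter in the binary case, e.g. `(3,3,1)`
($H \approx 1.449$) passes the ternary ceiling with a tied top pair.

Base qualities are parsed and discarded. In this data regime the
population-level redundancy, not per-read quality, is the usable signal;
the comentropy ceiling plays the role quality filters play in deep
single-sample calling.

## Candidate extraction

Before any statistics, the stream of pileup columns is reduced to
*candidate dynamic positions* (CDPs): positions where at least one sample
shows at least one non-reference read or one indel event. Detection is
maximally inclusive by design — all stringency lives downstream — because
rare variants supported by a handful of reads in a handful of samples
must survive this step. Positions whose reference base is `N` are never
candidates. The candidate set is identical whether computed in one
multi-sample pass or as the union of per-sample scans (property-tested),
and re-extracting from the restricted stream is a fixed point.

On real low-coverage cohorts this step discards the vast majority of
positions; the pipeline log records the achieved reduction ratio
$1 - n_{\mathrm{CDP}} / n_{\mathrm{total}}$.

## Population statistics and classification

For each CDP and population, every sample with a retained unit casts one
dominant-allele vote. With $V_b$ votes for base $b$ among $n_{\mathrm{cov}}$
covered samples, the major allele maximises $V_b$ (ties resolved as
above), its probability is $V_{\mathrm{major}} / n_{\mathrm{cov}}$, and
minor-allele frequencies are the remaining vote fractions. An indel event
*supports* a sample when the sample shows at least one read carrying that
event; its population probability is supporting / covered samples. At
2--4x per-sample indel zygosity is unknowable, so sample presence is the
only equal-weight statistic available — this is a deliberate
simplification, as is ignoring diploidy in the vote itself (a
heterozygous sample votes whichever allele dominates its reads).

A position is *dynamic* when at least one of four circumstances applies
(they may co-occur):

| category | condition | default boundary |
|---|---|---|
| `MAJOR_DIFF` | major allele differs from the reference base | — |
| `INDEL_HIGH` | an indel's population probability is high | $\ge$ 50% (inclusive) |
| `MINOR_COMMON` | a minor allele is common | $>$ 5% (exclusive) |
| `RARE` | a minor allele is rare | $\le$ 5% (inclusive), $> 0$ |

The 5% boundary is assigned to `RARE`, making rare and common minors a
partition of the observed minor alleles; the boundary value itself is a
configurable `classification_config()` field. `MAJOR_DIFF` and
`INDEL_HIGH` positions jointly form the MAIR set. Indels enter the MAIR
at exactly the classification threshold ($\ge 50\%$), which is itself
configurable. The 5% rare ceiling reflects what a cohort of one or two
hundred low-coverage samples can resolve; truly rare variation (below
1%) is outside the method's resolution.

### What the dominant-vote frequency estimator does to minor alleles

A minor allele at population frequency $f$ is carried mostly by
heterozygotes when $f$ is small. A heterozygote's unit votes for the
minor allele only when the minor reads dominate, which at Poisson-3
depth happens for roughly 40% of covered carrier units (near-balanced
units such as `(1,1)` and `(2,2)` are removed by the entropy filter).
The measured vote fraction for a planted 3% allele therefore centres
near 2.5%, and for a 10% allele near 9%, with binomial noise of a few
percent at 100 covered samples. Consequently sites planted near the 5%
boundary land on the wrong side of it with non-trivial probability
(roughly one site in ten at these settings). The end-to-end tests
therefore assert the bulk behaviour — at least 70% of detected 3% sites
classified rare, at least 70% of detected 10% sites classified common,
and *zero* of either ever called a major-allele difference — rather than
a per-site guarantee the estimator cannot give. The downward bias for
het-dominated alleles is intrinsic to one-vote-per-sample counting and
is documented rather than corrected, because the same counting rule is
what makes the estimator robust to depth heterogeneity.

## Consensus construction and liftover

The MAIR edit set is applied to the reference per chromosome.
Conventions, stated in all output headers:

* coordinates are 1-based inclusive;
* an insertion is anchored *after* its anchor base;
* a deletion of length $L$ at anchor $p$ removes bases $p{+}1 \dots p{+}L$.

Overlapping edits are resolved deterministically before application:
higher population probability wins; ties go to deletion over insertion
over substitution, then leftmost, then stable input order; every dropped
edit is logged with its winner. A substitution at a deletion's anchor is
*not* a conflict (the anchor base survives); two indels at one anchor
are. The consensus is a hard major-allele sequence — no IUPAC ambiguity
codes — so the FASTA remains usable by BWA/Bowtie-class aligners.

The liftover map stores, per chromosome, maximal unbroken segments
`(ref_start, ref_end, offset)` plus deletion gaps. Forward liftover of a
deleted position reports `NA`; reverse liftover of an inserted consensus
position likewise. The implementation is verified against a naive
string-rewriting oracle (characters expanded into a per-position list,
edits applied literally) on 1,000 random edit sets over a 10 kb
chromosome, including the full forward map at every position and its
inverse on every surviving position.

## The simulator

`simulate_pileup()` generates the regime the pipeline targets: $N$
diploid samples; per-sample, per-position depth Poisson($\lambda$) with
$\lambda = 3$ by default (the 2--4x band); genotypes drawn once per
sample at Hardy--Weinberg proportions, dosage $\sim$ Binomial(2, $f$);
each read picks a haplotype uniformly and is miscalled to one of the
three other bases with probability $\varepsilon = 0.005$ by default.
Reads on indel-carrying haplotypes emit the event at its anchor;
deletion haplotypes additionally convert reads at the deleted positions
into placeholders. Everything is reproducible from the seed, and the
emitted mpileup text round-trips through the package's own parser
exactly.

What the simulator does **not** emulate: mapping bias and alignment
artefacts, platform-specific or context-dependent error profiles, indel
sequencing errors, linked variation, and depth correlation along the
genome. Tests passing on simulated cohorts therefore demonstrate the
statistical machinery — filtering, voting, classification, consensus
building — not robustness to real-world alignment pathology, which
belongs to the upstream aligner and pileup generator. Similarly, the
mpileup dialect accepted here is whatever the upstream `samtools
mpileup` invocation produced: flags such as BAQ recalculation or mapping
quality floors change the base strings and hence the results; the
package deliberately takes the pileup as given.

## Numerical and design choices

* **Thresholds are inclusive** ($\le$, $\ge$) everywhere they are
  stated, including the exact-boundary ternary unit `(2,1,1)` and an
  indel at exactly 50%.
* **Logarithms are base 2**; entropies are in bits. `0 log 0` is 0.
* **Probability sums** are validated to 1e-9 before entropy evaluation;
  unit probability vectors are exact rationals $c_i / \sum c_j$ so no
  renormalisation is ever needed.
* **Tie-breaks** (dominant nucleotide, major allele, conflict
  resolution) are all deterministic; two runs on identical input are
  byte-identical, and the test suite hashes pipeline outputs to confirm
  it.
* **Degenerate inputs**: depth-0 columns parse to empty calls; positions
  where every unit fails are "not estimable" and are absent from the
  population tables (not zero); `N`-reference positions pass through the
  parser but can never become dynamic; empty edit sets reproduce the
  reference identically.
* **Rare-variant denominator**: frequencies are fractions of *covered*
  samples, not of the cohort manifest, because a sample without a
  retained unit carries no information at that position. The choice is
  configurable upstream of nothing — it follows directly from the
  one-vote-per-covered-sample definition.
* **Chromosome classes** (autosome / heterosome / chondriosome in the
  human default) come from a configurable map, so toy genomes summarise
  cleanly in tests.
* **Interval catalog "enrichment"** is plain hit counting (intervals
  overlapped by at least one MAIR edit, reported as hits/total per
  label), not a statistical test — no background model is implied.
* **Effect tallies** translate single codons in the annotated frame on
  either strand; codons truncated by an interval boundary and intervals
  without frame information count as `unknown`. Frameshift consequences
  of indels and splice-site effects are out of scope.

## Problem sizes used by the test suite

The shipped tests run entirely on synthetic data: exhaustive entropy
scans to depth 60/45/32 per arity; 1,000 random edit sets over 10 kb for
the consensus oracle; an end-to-end cohort of 100 samples at
$\lambda = 3$, $\varepsilon = 0.005$ over 50 kb with 50 fixed
differences and 60 planted minor alleles; and a 10 kb mutated-genome
reconstruction with 40 error-free samples. These sizes exercise every
code path at full statistical fidelity while keeping the whole suite
around a minute on one CPU.

## A worked example

```{r example}
set.seed(1)
ref <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                      collapse = ""))
alt_at <- function(p) setdiff(c("A", "C", "G", "T"),
                              substr(ref[[1]], p, p))[1]
cfg <- simulation_config(
  seed = 7, n_samples = 40, coverage_lambda = 3, error_rate = 0.005,
  reference = ref,
  snvs = data.frame(chrom = "chr1", pos = c(400L, 1500L, 2600L),
                    alt = vapply(c(400L, 1500L, 2600L), alt_at, ""),
                    freq = c(1.0, 0.25, 0.04)),
  indels = data.frame(chrom = "chr1", pos = 2000L, kind = "deletion",
                      seq = "", len = 2L, freq = 0.8))
sim <- simulate_pileup(cfg)
run <- run_pipeline(sim$pileup, sim$reference)
run
run$populations$ALL$dynamic$positions[, c("pos", "ref", "major",
                                          "major_prob", "categories")]
run$populations$ALL$mair
nchar(run$populations$ALL$vcg$consensus) - nchar(ref)
```

The fixed difference at 400 is recovered as `MAJOR_DIFF` with
probability 1, the 25% allele as a common minor, the 4% allele as rare
(when sampled into the cohort at all), and the 80% deletion enters the
MAIR, shortening the consensus by two bases.

## Known limitations

Beyond the simulator gaps above: diploid genotypes are never called (the
method outputs population vote fractions, not genotypes); the consensus
is hard, so positions with a 51/49 vote split are represented by the
majority base alone, with the split recoverable only from the statistics
tables; overlapping MAIR edits are resolved greedily rather than
jointly; and the rare/common boundary inherits the dominant-vote
estimator's downward bias for heterozygote-dominated alleles.
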