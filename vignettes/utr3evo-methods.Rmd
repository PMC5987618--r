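---
title: "Methods: comparative 3' UTR evolution with utr3evo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative 3' UTR evolution with utr3evo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

utr3evo implements a comparative pipeline for studying the evolution of
3' untranslated regions (3' UTRs) across a clade of genomes — the use
case it is sized for is five cichlid fishes against four other model
teleosts. The pipeline runs in six stages: canonical-transcript feature
extraction, 1:1 orthology from protein similarity, repeat-content
accounting, miRNA target scanning, per-gene two-regime Brownian-motion
rate estimation of 3' UTR length, and term enrichment of outlier gene
sets. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and the known limitations — in
particular the small-sample behaviour of per-gene rate ratios, which
matters for interpreting genome-wide tests.

```{r load}
library(utr3evo)
```

## Feature extraction

A gene's representative isoform is its *canonical transcript*: among
isoforms whose spliced CDS ends in a stop codon (TAA/TAG/TGA; the
annotated CDS is taken to include the stop), the one with the longest
spliced coding region. Stopless isoforms are treated as likely degraded
or mis-annotated and removed before selection; equal CDS lengths are
broken by the lexicographically smallest transcript id so the choice is
order-independent. The 3' UTR is the spliced sequence strictly
downstream of the stop codon, so for every transcript the 5' UTR, CDS
and 3' UTR lengths sum exactly to the spliced transcript length —
a conservation law the tests verify on every synthetic genome.

Coordinates follow the GFF3 convention (1-based, inclusive). Internally
all interval work is done with `IRanges`, the idiomatic 1-based closed
interval container in this ecosystem, with BED's 0-based half-open
coordinates converted at the boundary. UTRs of length zero are retained
in summaries: the annotation formats cannot distinguish "no UTR" from
"UTR not annotated", and excluding zeros would silently bias length
distributions. Length histograms use half-open, lower-inclusive 50-nt
bins (a length of exactly 50 falls in the second bin); quantiles use
linear interpolation (R's default type 7).

## Orthology

Pairwise protein similarity enters as standard BLAST tabular output.
HSPs above the E-value cutoff (default 1e-10) and self-hits are
dropped. The HSPs of one gene pair are *conjoined*: overlapping HSPs
are first trimmed to non-overlap (the higher-scoring, then longer, HSP
wins, and the trimmed HSP's bit score is scaled by its retained
fraction), then a dynamic program finds the maximum-weight chain that
is colinear and strictly non-overlapping in both query and subject.
The conjoined score is therefore never below the best single HSP. The
two directions of a pair are merged by taking the larger score.

Families are built by average-linkage agglomeration with three
parameters: a weight floor of 5 bits (edges below it are ignored), a
ratio threshold of 0.33, and a size cap of 100000. Candidate merges
are considered in descending order of between-cluster average
similarity (summed cross-edge weight over the product of cluster
sizes; absent edges count zero); a merge is accepted only when that
average is at least 0.33 times the internal average similarity of the
smaller cluster — singletons, having no internal pairs, are always
mergeable — and the merged size stays under the cap. Ties are broken
by the lexicographically smallest pair of minimum member ids, so the
partition is deterministic and invariant to input row order. This
merge rule is a documented, testable formalization keyed to the quoted
parameters of the hierarchical clustering tool used in the source
workflow, whose exact internals are not published; the unit tests pin
it to an independently written brute-force implementation on all small
graphs. A family with exactly one member in every analyzed species is
a 1:1 ortholog set; within-species paralog edges receive no special
treatment (see Open choices).

## Repeat content

Repeat annotations (RepeatMasker `.out` or BED; the dialect is chosen
by an explicit flag, never sniffed) are merged class-agnostically into
a disjoint interval set per chromosome; the repeat fraction of a
feature class is overlap bases over feature bases, and the genome row
uses full chromosome lengths. Feature intervals come from canonical
transcripts only, matching the length analyses.

The per-species comparison of genome-wide versus 3' UTR repeat
fractions uses an exact paired Wilcoxon signed-rank test. Zero
differences are dropped (the classic convention; with nine species and
continuous fractions none occur in practice). For up to 25 retained
pairs the null distribution of the rank sum is computed exactly by a
generating-function recursion — mathematically identical to enumerating
all 2^n sign assignments, and verified against literal enumeration for
n up to 12 — and the two-sided p is twice the smaller tail, capped at
one. With nine pairs all deviating the same way this gives
p = 2/2^9 = 0.00390625 analytically. Above 25 pairs a normal
approximation with continuity and tie corrections takes over.

## miRNA target scanning

A candidate target site requires perfect Watson-Crick complementarity
(no G:U wobble, no gaps) between miRNA seed positions 2-8 and the UTR —
the strict-seed convention. Each seed match is scored by extending the
duplex ungapped in both directions until the first mismatch on each
side and summing nearest-neighbor stacking free energies over the
maximal contiguous duplex. The 16 Watson-Crick stack energies
(Delta-G at 37 C, kcal/mol) ship as a plain-text table with the
package; no initiation term is added, so a degenerate zero-stack duplex
scores 0 and more pairing can only lower the energy — a monotonicity
the tests check. Sites above the -20 kcal/mol cutoff are discarded,
and overlapping sites of the same miRNA on one UTR are collapsed
greedily left to right. Per-UTR summaries divide total sites by the
number of target-bearing UTRs (those with at least one site).

This scanner is a documented stand-in for full hybrid-alignment tools:
it preserves the strict 5'-seed requirement and the -20 kcal/mol
threshold, and its plant-and-recover behaviour is exact by design, but
it does not reproduce any particular tool's alignment scores
bit-for-bit (no G:U pairs, no bulges, no 3'-compensatory site
classes).

## Two-regime Brownian-motion rates

The trait is the raw 3' UTR length in nucleotides of each 1:1 ortholog
(no transform). Branches of the rooted, time-calibrated tree are
painted into two regimes: the focal clade's crown branches plus its
stem are `focal`, everything else `background`. Assigning the stem to
the focal regime keeps a single rooted likelihood and avoids re-rooting
the paraphyletic background group.

Under painted Brownian motion the tip covariance is
`V = sig2_f * T_f + sig2_b * T_b`, where `T_r[i, j]` is the branch
length painted regime r on the root-to-MRCA path of tips i and j. The
root state is profiled analytically by generalized least squares. For
fitting, the likelihood is profiled further: with
`V = sig2_b (rho T_f + T_b)` the scale `sig2_b` has a closed-form
(RE)ML solution, leaving a bounded one-dimensional search over
`log(rho)` in [-18, 18]. A one-time generalized eigendecomposition of
`(T_f, T_f + T_b)` reduces every likelihood evaluation to O(n) vector
operations, so genome-scale fitting (thousands of genes, nine tips)
takes seconds. A coarse grid locates the basin before golden-section
refinement; estimates at the `rho` bounds or below 1e-9 are flagged
`boundary`, constant traits `degenerate`, and flagged genes are
excluded from downstream ratio tests. Maximum likelihood is the
default, matching standard comparative-methods packages; restricted
maximum likelihood (`reml = TRUE`) and a prune-and-fit mode (each
regime's induced subtree fitted separately in closed form) are
available for sensitivity analysis. The fast path is pinned against
the dense-matrix likelihood, against an independent multi-rate
implementation (`phytools::brownie.lite`), and against closed forms on
two-tip trees.

Per gene the summary statistic is `log10(sig2_f / sig2_b)`; the
genome-wide test is a one-sample t-test of these log ratios against 0.
The log10 base matches the length-ratio analysis (the clade ratio of
mean 3' UTR lengths, also log10-transformed and t-tested).

### Small-sample behaviour of the rate ratio

With nine tips there are only about four effective degrees of freedom
per regime, and a ratio of two variance estimates with so few degrees
of freedom is strongly skewed: the expectation of `1/sig2_hat` diverges
as degrees of freedom shrink, and Jensen's inequality biases the mean
log ratio. Concretely, digamma-based expectations for log chi-squared
variables predict a positive mean log10 ratio under equal true rates
whenever the background regime has fewer effective degrees of freedom
than the focal one, as here. Three practical consequences, all
reproduced by the package's own test suite rather than asserted from
theory alone:

* Under the ML default the mean background rate estimate is biased
  low (roughly 15% on the default tree); REML removes most of that
  bias, which is why the parameter-recovery checks use `reml = TRUE`.
* The per-gene mean of the *ratio* `sig2_f / sig2_b` is far above the
  true rate ratio even under REML (heavy right tail); the median and
  the distribution's centre are much better behaved. Mean-ratio
  recovery to within a few percent is not attainable on a 9-taxon tree
  with any variance-ratio estimator of this family.
* The genome-wide t-test of mean log10 ratio against 0 is
  anticonservative under the null: the per-gene bias (about +0.12
  under ML, +0.04 under REML, versus a per-gene spread of about 0.6)
  is small for any single gene but becomes a large noncentrality when
  averaged over hundreds or thousands of genes. The test suite
  measures the realized type-I error at alpha = 0.05 over 1000
  equal-rate replicates of 100 genes and records the inflation rather
  than hiding it. A positive genome-wide result under this test
  therefore means "focal rates exceed background rates by more than
  the estimator's intrinsic asymmetry", and detecting a true 2x rate
  difference — the regime this pipeline targets — is unaffected: the
  planted-rate checks reject at p < 0.001 in every replicate.

## Enrichment

Outlier sets are the top 5% of 1:1 orthologs by score (clade length
ratio or rate ratio), with `k = floor(0.05 n)` and boundary ties broken
by gene id. (For n = 2041 this gives k = 102; no standard rounding
rule yields the 101 sometimes quoted for that cutoff, and the floor
rule is used consistently.) Per term, enrichment is the one-sided
hypergeometric upper-tail probability of at least k annotated genes in
the test set given the baseline universe — identical to the one-sided
Fisher exact test on the 2x2 table — followed by Benjamini-Hochberg
adjustment across terms at 0.05. Only over-representation is tested;
no GO-graph propagation to ancestor terms is performed, so input maps
should already carry whatever ancestry closure the user wants.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of a configuration and a seed, and
each writes a truth table alongside its dataset so downstream tests
never re-derive planted values from generator internals. The default
configuration encodes the study conditions the pipeline is sized for:
a 9-taxon ultrametric tree (five focal cichlids, four background
teleosts) with round-figure node depths in the range of published
teleost divergence times (crown cichlids 30 Myr, root 230 Myr — these
are configurable defaults, not measurements, since calibrated node
ages are not part of the consumed inputs); 2041 genes; a root 3' UTR
length of 1000 nt with a 50-nt floor when lengths are materialized
into genomes (the floor prevents non-physical negative lengths;
rate-fitting tests use the unfloored values so the Brownian model
stays exact); repeat densities ordered genome > 3' UTR > 5' UTR > CDS
(0.28/0.14/0.08/0.03), bracketing the ranges observed in teleost
genomes; 271 miRNAs; 0-5 planted target sites per UTR; and a planted
annotation term at 40% frequency in the top set versus 5% baseline.

Synthetic genomes have uniform base composition, fixed-length 5' UTRs
and CDSs, a small fixed repeat library, and planted miRNA sites that
are perfect complements; real genomes have none of these simplicities.
Passing the plant-and-recover suites therefore demonstrates that the
machinery is correct — coordinates, splicing, strand handling,
chaining, clustering, scanning, rate estimation — not that any
particular biological effect size is recoverable from real data.
Decoy isoforms (a shorter stop-bearing isoform and a stopless one, at
rates 0.3 and 0.2) exercise the canonical-transcript filter; every
fifth gene carries a 150-nt intron inside its 3' UTR to exercise
spliced extraction; genes alternate strand. CDS bodies are built from
stop-free codons so truncated decoys cannot end in accidental stops,
and repeat planting never overwrites a CDS's terminal codons.

## Problem sizes used by the tests

The test suite exercises the full study scale where the claim depends
on it (2041 genes for the rate and length t-tests, ten seeded
replicates; 1000 genes for rate recovery; 1000 replicates of 100 genes
for the null calibration; 1e5 nt of scrubbed background for the
false-positive check) and small instances everywhere a brute-force
oracle must enumerate (graphs of up to 8 genes for clustering, up to 6
HSPs for chaining, up to 12 pairs for the signed-rank distribution).
End-to-end pipeline tests run at 24-60 genes, which is sufficient to
exercise every stage boundary; these sizes are the package's choices
for its own checks.

## Known limitations

* Rate-ratio inference on few tips is biased as analysed above; users
  comparing clades of this size should interpret the genome-wide
  t-test as a directional screen, not a calibrated null test, or use
  the REML and prune modes for sensitivity.
* The miRNA scanner is seed-plus-stacking only; it will not reproduce
  hybrid-alignment tools' site sets on real sequence.
* The family-merge rule is a formalization of an unpublished tool's
  parameters; on real similarity data the partition may differ from
  that tool's output even though both respect the same thresholds.
* Orthology is similarity-based only; no tree reconciliation is
  attempted, which is defensible for clades sharing one whole-genome
  duplication history but not beyond.
* Annotation maps are consumed as given: no term ancestry propagation
  and no live database queries.

## Open choices made

Where the consumed descriptions left a decision open, the package
decided once and documents it here: transcripts with annotated CDS but
no UTR records get zero-length UTRs from pure coordinate arithmetic;
within-species paralog edges are treated like cross-species edges in
clustering; per-UTR target counts collapse overlapping same-miRNA
sites; the rate log-ratio uses base 10 for consistency with the length
analysis; repeat fractions use canonical transcripts only; boundary
rate estimates are excluded from ratio tests and counted in the
report; and the log-ratio t-test treats genes as independent data
points (as in the source workflow), which the calibration analysis
above qualifies.
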