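---
title: "Tracking host-range evolution in a phage community: models and methods"
author: "phevokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking host-range evolution in a phage community: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phevokit)
```

## The experimental system

`phevokit` analyses serial-passage evolution experiments in which a community
of lytic bacteriophages is propagated on a fixed, non-evolving community of
capsulated bacterial hosts (*Klebsiella* spp., whose capsular serotype --
K-type -- is the main determinant of phage tropism). The typical design the
package targets: a dozen phages spanning several families, including one pair
of close relatives whose reads co-map; three independent evolution lines;
~70 passages with community sequencing at a few time points; spot-test and
efficiency-of-plating (EOP) assays of the evolving communities and of
plaque-isolated variants; and whole-genome comparison of isolated variants
against their ancestors, including recombinants.

Five analysis stages are implemented, each usable on real tables (FASTA,
GFF3, VCF, headed TSV) and each testable against a synthetic experiment with
known ground truth:

1. **Composition** -- relative phage abundances from mapped-read shares,
   with diagnostic-site deconvolution of the close pair.
2. **Host range** -- spot-test consensus scores, EOP with detection-limit
   handling, log-EOP differences, specialist/generalist classification.
3. **Mutational landscape** -- variant effect classification, sliding-window
   profiles, exact region-vs-genome rate enrichment, cross-line parallelism,
   and a counting dN/dS screen.
4. **Recombination** -- parental painting of recombinant genomes from
   informative sites, breakpoint intervals, RBP swap calls, consensus
   regions.
5. **Concordance** -- agreement between community variant calling and
   whole-genome alignment of isolates at designated positions, with Fisher's
   exact test.

## Composition and pair deconvolution

Short-read mapping cannot separate two phages above ~98% identity: their
reads co-map and the pair appears as one coverage unit. The package uses the
*diagnostic sites* -- positions at which the two pair members differ -- to
apportion the co-mapped reads. At each diagnostic site the allele frequency
of the minor member's allele estimates the minor member's share; the
estimator is the arithmetic mean over sites (`minor_fraction()`), and
`deconvolve_pair()` multiplies it by the pair's total mapped reads.

Two regimes are distinguished. When the minor fraction is below 0.20 (a
20/80 depth-ratio situation) the split is applied: minor reads =
round(minor fraction x pair reads), with round-half-to-even so conservation
is exact and unbiased. At or above 0.20 -- approaching 50-50, where the
"minor" allele of a site cannot be attributed to one member reliably -- the
pair is reported under a combined label. The boundary is a strict `<`:
exactly 0.20 combines. Each sample is deconvolved independently from its own
allele frequencies; no passage-0 calibration is carried forward, because the
pair ratio genuinely drifts across passages and an anchored calibration
would propagate passage-0 sampling noise into every later sample.

Sites absent from a sample's variant calls count as allele frequency 0 only
when they are covered by reads; uncovered sites are dropped, since scoring
them as 0 would deflate the mean.

With `n` diagnostic sites read at depth `d`, the standard error of the minor
fraction is about `sqrt(p(1-p)/(n d))`; at 400 sites and depth 100 this is
under 0.002 across the whole SPLIT regime, which is why the recovery tests
demand mean absolute error below 0.01.

## Host-range scoring

Spot tests are scored per phage-strain pair from 2-3 replicate outcomes:
plaques in every replicate scores 2, no spot in any scores 0, anything
inconsistent -- including turbid spots seen only at the first dilution --
scores 1. With only two replicates an inconsistent result is scored 1
provisionally and flagged `needs_third`; the flag, not a withheld score, is
the package's reading of the "third replicate for doubtful cases" rule,
so that a 2-replicate dataset still yields a complete matrix.

EOP is the titer on the evaluated strain divided by the titer on the
ancestor's isolation strain. Titers below the plating detection limit
(10^2 PFU/mL by default) are replaced by the limit itself so ratios remain
finite, and such records are flagged `at_detection_floor`; raising the limit
can only raise a floor-censored EOP, which the tests assert as a
monotonicity property. Replicates are combined as the mean of per-replicate
ratios; the ratio of means is also reported, since the two differ when
replicate titers vary and the published convention ("average of the two
replicates") does not fix one. Host-range classes count only score-2
strains: exactly one susceptible strain is a specialist, two or more a
generalist, none is reported distinctly as `no_host` -- partial
susceptibility never counts.

The growth increment is `log10(initial titer) - log10(final titer)`,
deliberately keeping the initial-minus-final sign convention of the source
assay (growth gives negative values); flipping it silently would make
cross-study comparison error-prone.

## Mutational landscape

Variant effects are classified against CDS annotations under the bacterial
genetic code (translation table 11, identical to the standard code for
translation): synonymous, non-synonymous, nonsense for SNPs; in-frame vs
frameshift for indels by the mod-3 rule; `AMBIGUOUS_N` when the codon
contains an `N`; intergenic otherwise. Minus-strand CDS are classified in
the reverse-complemented frame, and a property test asserts that a
minus-strand CDS gives exactly the effects of its reverse-complemented
plus-strand construction.

Sliding-window profiles use 500 bp windows by default. The window *size*
follows the display convention of the experiments; the *step* is not fixed
by that convention, so the default is half a window (250 bp), configurable.
Both a count metric (distinct mutated positions) and an allele-frequency sum
are emitted, because the published figure metric is ambiguous between the
two; the count metric is the default for display.

Region-vs-genome enrichment uses the exact conditional comparison of two
Poisson rates: conditional on the total count `K`, the region count is
binomial with probability proportional to region length under equal rates.
Counts are *distinct mutated positions* in the sampled passages (40/69 by
convention), per line -- a position mutated at both passages or with two
alternate alleles counts once. The two-sided p-value uses the
minimum-likelihood convention (sum of outcome probabilities no larger than
the observed one), the same convention as the common implementation of this
test; a one-sided alternative is exposed. Benjamini-Hochberg adjustment
across CDSs is available but never applied silently, since the headline
results of such experiments are reported as raw per-region p-values.

One property of exact conditional tests deserves a note: they are
*conservative* at small counts. At the scale of a 3 kb RBP region in a 45 kb
genome with ~30 distinct mutated positions, the realized type-I error at
nominal 0.05 is about 0.029 (computable exactly by summing binomial
probabilities over the Poisson-weighted support), and it approaches the
nominal level only beyond ~50-100 mutations. Calibration simulations at
this scale therefore sit *below* 0.05 -- the test never over-rejects, which
is the property that matters for the enrichment claims; power at a 10-fold
rate enrichment remains above 0.99 at the same scale.

The dN/dS screen is the Nei-Gojobori (1986) counting method with
Jukes-Cantor correction: per-codon synonymous site fractions averaged over
the two sequences, observed differences averaged over all shortest
mutational pathways (pathways through premature stop codons are discarded;
substitutions *to* stop codons count as non-synonymous sites), and
`d = -(3/4) ln(1 - (4/3) p)`. Proportions reaching 3/4 return a `SATURATED`
status instead of a distance, and `dS = 0` yields an `NA` ratio. This is an
explicitly simplified screen for diversifying selection -- codon-model
likelihood methods (branch-site tests, Bayesian site inference) are a
different tool class and are out of scope here.

## Recombination painting

Painting reduces a three-way alignment (two parents plus a recombinant) to
its *informative sites*: columns where the parents differ and neither has a
gap. The recombinant matches parent A, parent B, or neither (a private
mutation). Maximal runs of same-parent matches become segments; runs
shorter than `min_run` (default 3) are absorbed into their flanks, because
an isolated opposite-parent match is far more likely a de novo mutation
that happens to coincide with the other parent's allele than a ~100 bp
double crossover. `NEITHER` sites are simply ignored -- they carry no
ancestry signal.

The true crossover between two adjacent informative sites is unobservable,
so each breakpoint is reported as the open interval between the bounding
sites with the midpoint as a conventional point estimate. For coverage
computations (RBP swap calls, consensus regions) segment spans are extended
to the breakpoint midpoints and to the alignment ends, reflecting that the
painted state is constant between informative sites. A feature is *swapped*
when at least half its span is painted minor-parent, and a *complete swap*
at 0.95 -- the distinction matters because acquiring the central divergent
region of an RBP and acquiring the whole gene are biologically different
events. The major parent is the one with the larger painted span; exact
ties (essentially only possible in toy inputs) go to parent A with a
warning. The consensus recombinant region across variants sharing a host is
the interval intersection of their minor-parent spans.

This single deterministic painting algorithm replaces multi-method
recombination-detection suites; its validation surface is recovery of
planted truth from the generator (exact breakpoint-count recovery on clean
mosaics at 2% parental divergence and >= 2 kb spacing, midpoints within the
reported uncertainty interval, swap flags fully recovered), not agreement
with any particular external tool.

## Detection concordance

For designated positions (e.g. sites under positive selection), each
(position, sample) pair is a detection opportunity: detected by variant
calling iff some variant there has allele frequency strictly above 0.2, and
by whole-genome alignment iff at least one isolate from that sample carries
a non-reference allele. The four tallies feed Fisher's exact test. The
published tallies come with a p-value but without the 2x2 layout; the
package adopts the *method-by-outcome* construction
`[[both + vc_only, wga_only], [both + wga_only, vc_only]]`, because exact
enumeration under it reproduces the published 0.596 for the reference
tallies (10/3/1) to the printed precision. The same construction does not
reproduce the second published value (tallies 16/3/1, printed p = 1.0),
which *is* reproduced by the cross-classification
`[[both, wga_only], [vc_only, neither]]` with an empty `neither` cell --
the two published values are mutually inconsistent under any single layout.
Both constructions are implemented behind the `construction` argument, and
only the reproducible value is asserted. The p-value itself is computed by
hypergeometric enumeration with the minimum-likelihood two-sided
convention; the test suite checks it against brute-force margin enumeration
for every 2x2 table with `N <= 40` and against `stats::fisher.test`.

## The synthetic experiment generator

Because the real sequencing data require external assembly/mapping/calling
tools, every stage is validated against `simulate_experiment()`, which
emulates the design end to end with known truth. What it models:

* **Genomes**: random uniform-base sequences (lengths 40-170 kb by default,
  matching the community's range) with gene-dense tiled CDS annotations
  (10-60 CDS, >= 1 flagged RBP each). One designated close pair is created
  by copying a genome and substituting i.i.d. positions to reach the
  configured identity (0.98 default); the substituted positions are the
  diagnostic sites, so deconvolution has exact truth.
* **Dynamics**: no published population model exists for this design, so
  the generator uses the simplest scheme that produces the qualitative
  pattern (generalist dominance, decline of narrow specialists, occasional
  extinctions): replicator selection `w_i = 1 + c * sum_h matrix[i, h]`
  over a 0/1/2 host matrix, followed by a multinomial bottleneck (default
  1000 particles). The default `c = 0.05` makes a phage with no usable host
  collapse below 1e-3 within 40 passages, mirroring the reproducible
  extinction seen in such experiments. A caveat stated plainly: with
  constant fitness differences and ~70 passages, weak competitors are
  eventually lost; long-run coexistence of specialists at low abundance
  would need frequency-dependent fitness, which is beyond what the analyses
  here require of the generator.
* **Mutation**: per phage and passage, new mutations arise
  `Poisson(mu L x_i bottleneck)` (default `mu = 2e-7`/base/passage, the
  order of magnitude of dsDNA phage rates times a few generations per
  passage), placed uniformly except RBP bases weighted `rho` (default 10).
  A fraction of RBP mutations (10%) is beneficial and grows logistically
  (`da = s a (1-a)`, `s = 0.25`/passage); all alleles drift by binomial
  resampling at `Ne = 1000`. Alleles are independent sites -- exactly what
  community variant calling sees; haplotype structure is not modelled.
  Short deletions (1-30 bp) occur at a low rate. Variant calls are emitted
  at the sequencing passages for alleles above a 1% caller floor, with AFs
  reproducing truth to 4 decimals.
* **Recombinants**: mosaics of the close pair with k breakpoints drawn
  uniformly at >= `min_gap` spacing, plus optional genome-wide noise and a
  separate per-informative-site "third base" noise channel for stress
  tests.
* **Assays**: titers lognormal around class-determined true values
  (susceptible = inoculum titer 10^6 PFU/mL, partial = 1% of it, resistant
  = 0), written as `ND` below the 10^2 PFU/mL detection limit; spot
  outcomes drawn with plaque probability increasing with infectivity, and
  zero infectivity always yields `NONE`.

What the generator does *not* emulate: read-level error (variant calls are
consumed, not reads), linkage between co-segregating mutations, bacterial
coevolution (the experimental design holds hosts non-evolving), burst-size
or adsorption kinetics. Passing recovery tests therefore demonstrate the
estimators' correctness under the stated sampling models, not robustness to
mapping artefacts or caller-specific biases in real data.

All randomness flows from one master seed through deterministic per-stage
substreams (`substream_seed()`), so any stage can be regenerated
independently and identical seeds give byte-identical outputs.

## Numerical and interface conventions

* All coordinates, internal and external, are 1-based inclusive -- the
  R/Bioconductor and GFF3/VCF convention. (A 0-based half-open internal
  layer was considered and rejected: in an R package it is the conversion
  layer itself that breeds off-by-one errors.)
* Read apportioning rounds half-to-even and gives the remainder to the
  major member, so read conservation is exact.
* Both exact tests use the minimum-likelihood two-sided convention with a
  `1 + 1e-7` relative tolerance when comparing outcome probabilities,
  matching `stats::fisher.test`.
* Genomes admit `N` bases; any codon containing `N` is excluded from dN/dS
  site counting (and counted as excluded) and classified `AMBIGUOUS_N` in
  effect calls.
* Ties: equal painted parental spans resolve to parent A with a warning;
  overlapping enrichment-region intervals are unioned before length and
  count computations.

## Problem sizes used in the shipped tests

The test-suite and acceptance-script simulations are sized so the full
analysis remains a desk-scale computation: community simulations use 5
phages x 20 passages x 3 lines at 100k reads/sample (9-30 kb genomes);
deconvolution recovery uses 100 samples x 400 sites x depth 100; test
calibration and power use 1000 replicates at the 3 kb / 45 kb / ~30-mutation
scale; painting recovery uses 50 mosaics on 40 kb parents at 98% identity;
oracle equivalences run the full 2x2 enumeration to `N = 40` and 200 random
codon-sequence pairs. Reported real-data results from deposited sequencing
runs (composition trajectories, per-protein enrichment p-values, published
breakpoint maps) are not re-derived here: they require the upstream
assembly/mapping/calling pipeline, and the parameter-recovery surface above
is the package's substitute for them.

## Known limitations

* The deconvolution handles pairs only; three-way co-mapping mixtures are
  not resolved.
* Painting requires both parents; recombination with an unknown donor
  (e.g. a cryptic prophage) can only be painted once the donor sequence is
  supplied.
* The dN/dS screen is a counting method; it has no power to localise
  selection to sites and saturates quickly beyond ~75% codon divergence.
* The exact rate-comparison test is conservative at small counts (see
  above); borderline enrichment at < ~20 mutations should be interpreted
  with that in mind.
* RBP identification from annotations is a keyword/attribute rule
  (`rbp=true`, or products containing "tail fiber", "tail spike",
  "receptor-binding"); curated structure-guided RBP calls should be
  supplied via the `rbp` attribute when available.
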