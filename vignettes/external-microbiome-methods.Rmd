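---
title: "Deriving external microbiomes of micrometazoans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving external microbiomes of micrometazoans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomibe)
library(SummarizedExperiment)
```

## The problem

Animals smaller than about a millimetre — nematodes, tardigrades — cannot be
swabbed or taped, so the microbial community adherent to their cuticle (the
*external microbiome*) cannot be sampled directly. What can be measured by
single-specimen metabarcoding is (i) specimens moved through sterile washes,
whose reads reflect the internal (gut) community once the host's own
amplicons are removed, and (ii) unwashed specimens, whose reads mix internal
and external communities. `exomibe` implements the computational
construction of the external community from this paired design, together
with the community-ecology statistics needed to compare external, internal,
and environmental (microbial mat) communities.

The data model is Bioconductor-native: an `AsvExperiment` extends
`SummarizedExperiment` with ASVs (amplicon sequence variants) as rows,
samples or derived profiles as columns, per-ASV taxonomy in `rowData()`,
per-sample design metadata in `colData()`, and two slots recording whether
abundances are read counts or proportions, and which amplicon marker (16S
or 18S) the table comes from.

## The derivation

For each host taxon and each mat replicate (a stream x mat-type x replicate
cell of the design):

1. **Cleanup.** Non-target-domain ASVs are removed (non-bacterial from 16S
   tables, non-eukaryotic from 18S); ASVs matching a host's own lineage
   with a confident assignment (percent identity >= 95 and query coverage
   >= 90) are zeroed in that host's individual samples, while host-matching
   ASVs with poorer assignments are zeroed in all individual samples; the
   per-ASV maximum read count across negative controls is subtracted from
   every experimental sample (clipped at zero) and controls dropped;
   samples with fewer than 100 total reads are discarded (a 100-read sample
   survives: the rule is a strict less-than).
2. **Averaging.** Washed individuals are averaged arithmetically into one
   internal profile per replicate; unwashed individuals into one unwashed
   profile. Averaging is on raw counts, so deeper-sequenced individuals
   carry proportionally more weight; `normalize_individuals = TRUE`
   switches to depth-normalized averaging for sensitivity analysis.
3. **Subtraction.** The external profile is the elementwise clipped
   difference
   `external[a] = max(unwashed[a] - internal[a], 0)`.
   Subtractions that would go negative (reads present in washed but not
   unwashed specimens) are equalized to zero; the number of clipped ASVs
   and the clipped mass fraction are recorded in the derivation audit
   rather than silently dropped.

Two algebraic identities pin the derivation down exactly and are enforced
by tests: `0 <= external <= unwashed` elementwise, and
`external + min(internal, unwashed) = unwashed`. Derivation is always
per replicate; profiles are never pooled across streams or mat types.
Per-individual external microbiomes are out of reach by construction — the
subtraction is only meaningful between averaged, paired profiles.

A consequence of clipped subtraction worth knowing: even when unwashed and
washed specimens come from the same distribution (no external community at
all), the positive part of sampling noise leaves a nonzero residual. With
two individuals per group at ~1400 post-cleanup reads each, this noise
floor measures about 7% of unwashed mass in simulation; detected external
signal should be interpreted against that floor, which shrinks with more
individuals and deeper sequencing.

## Diversity

Alpha diversity is reported as Hill numbers — the effective number of
equally abundant taxa,

$$^qD = \Big(\sum_i p_i^q\Big)^{1/(1-q)}, \qquad
^1D = \exp\Big(-\sum_i p_i \log p_i\Big),$$

with richness at \(q = 0\), exponential Shannon at \(q = 1\) and inverse
Simpson at \(q = 2\). The metric names map to these orders; abundance
vectors are renormalized internally so counts and proportions give
identical values. Faith's phylogenetic diversity is the total branch length
of the minimal rooted subtree connecting the root and all observed tips.
The rooted/inclusive convention is stated explicitly because conventions
differ between packages; it matches `picante::pd(include.root = TRUE)`,
which serves as a cross-check in the test suite. The tree is a user input:
nothing in the pipeline constructs one from sequences.

## Community statistics

All compositional analyses run on relative abundances and Bray-Curtis
dissimilarity,
\(d_{jk} = 1 - 2\sum_i \min(x_{ij}, x_{ik}) / \sum_i (x_{ij} + x_{ik})\).
The statistics are implemented from first principles in this package, with
`vegan` used only as an independent oracle in the tests:

* **PERMANOVA** partitions the trace of the Gower-centered matrix
  \(G = -\tfrac12 J D^{(2)} J\) among design terms with sequential (Type-I)
  sums of squares built from cumulative projection matrices, in the
  user-given term order — term order therefore matters and is recorded in
  the result. p-values come from free (unrestricted) simultaneous row
  permutation with the \((1 + \#\{F^* \ge F\})/(1 + n_{perm})\) convention,
  so a permutation p-value is never 0. An exhaustive mode enumerates all
  \(n!\) permutations for small problems and is checked against brute-force
  enumeration in the tests. Confounded terms raise an error naming the
  aliased term rather than silently absorbing variance.
* **Pairwise contrasts** run one two-group PERMANOVA per level pair with
  Holm adjustment (the adjustment choice is ours; a two-level factor
  reproduces its full-model result exactly, same seed included).
* **PCoA** returns all axes, including negative-eigenvalue ("imaginary")
  axes flagged as such; the axis removed by centering is the eigenvalue
  nearest zero, not the last in sort order — dropping the last would
  discard a genuine negative axis.
* **Dispersion** follows the betadisper approach with group centroids
  (means in PCoA space, not spatial medians) and Anderson's
  real-minus-imaginary squared-distance correction, clamping negative
  corrected squares at zero with a per-sample flag. The permutation test
  permutes group labels and recomputes centroids and distances each time.
  When all dispersions are zero the result is flagged degenerate with
  p = 1.
* **Alpha-diversity group tests** use sequential-SS permutation F tests on
  the scalar metric. This deliberately replaces the mixed-effects
  (REML/Kenward-Roger) modelling sometimes used for such designs: the
  claims the pipeline makes are about group effects recoverable either
  way, and the substitution is stated in the run report header.

The three standard models mirror the combined / external-only /
internal-only structure: model A tests host, microbiome type, mat type,
stream and the host x microbiome x mat interactions on internal plus
external profiles; models B and C drop microbiome type. Term order is a
parameter; the shipped order follows the conventional main-effects-first
layout.

## The synthetic study generator

`generateStudy()` produces study-shaped inputs with known ground truth so
every stage is testable without downloads. Its defaults *are* the study
conditions: 4 streams x 2 mat types (black/orange) x 3 replicates = 24 mat
samples; 3 host taxa; 2 washed + 2 unwashed individuals per host and
replicate (scaled down from the hundreds of field specimens for desk-scale
runtime — full-scale counts are reachable through the parameters); mat
depth 20000 and individual depth 2000 reads; two sparse negative controls;
three under-sequenced individuals that exercise the depth filter.

The generative model is log-additive (softmax), a standard compositional
device — an explicit modelling choice of this module, not something the
field design prescribes:

* a base pool of S = 400 ASVs with Normal(0, 1) log-abundances and a
  random bifurcating tree with exponential branch lengths;
* mat composition per replicate: softmax of base log-abundance + stream
  effect (sd 0.8) + mat-type effect (sd 0.4) + replicate noise (sd 0.2;
  the replicate level is not specified by the design, 0.2 was fixed once
  as a plausible within-plot heterogeneity);
* host filters: per host and ASV a Normal(0, 1) weight; the internal
  composition reweights the mat by `exp(2.0 * w)` truncated to the top 25%
  of weights, the external by `exp(0.7 * w)` truncated to the top 60% —
  encoding the gradient mats > external > internal in both richness and
  selection strength;
* washed individuals draw multinomial reads from the internal composition,
  unwashed from the mixture `0.6 * internal + 0.4 * external` (phi = 0.4),
  both with 30% of reads assigned to a dedicated host ASV carrying the
  host's lineage, which exercises host-read removal realistically.

The generated table is 18S-flavoured (hosts are metazoans), so the
domain filter, host removal and control subtraction all act on their
realistic path. What the generator does *not* emulate: PCR and chimera
artifacts, sequencing error, taxonomy misassignment, overdispersion beyond
multinomial sampling, or any spatial structure within a stream. Passing
recovery tests therefore demonstrate that the algebra and statistics
recover the truth under the stated sampling model — not that field data
meet that model.

Recovery is assessed over 20 independent seeds (`evaluateRecovery()`):
mean Hill-q1 ordering mat > external > internal; internal-only PERMANOVA
R²(host) > R²(stream) under defaults; external-only R²(stream) >= R²(host)
under the environment-dominant regime (sigma_stream = 1.2,
gamma_external = 0.4 — with default settings the host filter is strong
enough that host can still edge out stream on external communities, which
is why the contrast is evaluated in the regime that encodes environment
dominance); and derived external profiles closer in Bray-Curtis to the
true external than to the true internal composition.

One caveat the recovery fractions make visible: on the generator's *true*
external compositions the environment-dominant regime puts stream clearly
ahead of host, but on *derived* profiles the contrast is attenuated. The
clipped subtraction retains the positive part of internal sampling noise,
and both that noise and the surviving support (the external-minus-internal
support set) are host-structured through the per-host support truncation;
with only two individuals per group this carryover inflates the host term
enough that the stream-over-host ordering on derived externals holds in
only roughly half to two-thirds of seeds rather than reliably. The
internal-side contrast (host over stream) and the compositional recovery
of the external community are unaffected. Practically: variance
partitioning on subtraction-derived communities inherits structure from
the community that was subtracted, and host terms on derived externals
should be read with that bias in mind.

## Numerical choices and degenerate inputs

* Permutation comparisons use a relative tolerance of 1e-12 when counting
  `F* >= F`, so ties arising from group-preserving permutations are
  counted as exceedances regardless of floating-point route.
* Hill numbers exclude zero entries from sums; the q = 1 branch is taken
  within 1e-12 of q = 1; all-zero profiles raise an undefined-diversity
  error (and are flagged, not dropped silently, in `alphaTable()`).
* Relative-mode validity demands row sums within 1e-9 of 1; round-trips
  through TSV preserve counts bit-exactly (integer formatting) and
  proportions to 17 significant digits.
* A fully separated PERMANOVA design (residual SS 0) reports infinite
  pseudo-F with R² = 1 rather than NaN.
* Seeds: every stochastic stage consumes `deriveSeed(master, stage_name)`,
  a 31-bit hash fold, so stages are independently reproducible and a rerun
  with the same master seed produces a byte-identical report (reports
  contain no clocks or environment details).

## Problem sizes used in the shipped checks

The test suite and the reproduction script run the generator at its
default scale (about 315 samples by 403 ASVs) for the 20-seed recovery
evaluation, and at a reduced scale (2 streams, 2 replicates, 60 ASVs) for
unit tests of the plumbing; calibration of the permutation tests uses 1000
null draws at n = 20 with 199 permutations each. These sizes were chosen
as the smallest at which the studied contrasts are comfortably detectable.

## Known limitations

* Host-read identification is by taxonomy-name patterns, not sequence
  alignment; it inherits whatever misassignment the upstream taxonomy has.
* Negative-control subtraction uses the per-ASV maximum across controls
  applied uniformly — per-sample control pairing is not modelled.
* Whether control subtraction should precede host removal is not
  determined by the design; the shipped order (domain, host, controls,
  depth) applies the depth filter last so that retained depth reflects
  cleaned data.
* The clipped subtraction is biased upward by the noise floor discussed
  above; report the clipped mass fraction alongside any external profile.
* NMDS is not provided; PCoA is the supported ordination.
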