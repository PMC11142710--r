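---
title: "Models and methods for green crab diet metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for green crab diet metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stomach-content DNA metabarcoding ("diet DNA") identifies what a predator
ate by amplifying and sequencing a barcode region — here a 418 bp segment
of mitochondrial COI — from stomach-content extracts of invasive European
green crab (*Carcinus maenas*). Between the raw ASV table and an ecological
conclusion sit four statistical problems, each handled by one module of
this package:

1. **Which sequences are prey?** BLAST hits must be turned into a defensible
   prey list (`filter_prey_taxa()` and friends).
2. **Does diet differ among sites?** Presence/absence and semi-quantitative
   indices feed distance-based permutation tests (`permanova()`,
   `permdisp()`, `pairwise_permanova()`).
3. **How much DNA did each prey contribute?** Read counts are biased by
   species-specific PCR amplification efficiency; mock communities of known
   composition calibrate that bias (`fit_amplification_efficiencies()`,
   `calibrate_samples()`).
4. **What does an "average" crab eat?** A zero-and-one-inflated Dirichlet
   compositional model pools highly variable individual diets
   (`fit_inflated_dirichlet()`, `average_diet_by_site_type()`).

Every stage can be exercised on synthetic data with known truth
(`simulate_dataset()`), which is how the package tests itself.

## Prey filtering rules

The filtering chain applies, in order:

* **Threshold re-check.** Hits below 94% identity (inclusive floor) or
  above e-value 1e-30 are discarded; an ASV left with no hits is
  `unassigned` and drops out.
* **Last common ancestor.** An ASV hitting several distinct species keeps
  only the deepest rank shared by all of them. Identical species reached
  via different accessions collapse before the LCA, so redundant database
  entries cannot truncate a lineage.
* **Controls, predator, non-targets.** Any read in any positive or negative
  control removes the ASV outright (the most conservative reading, since no
  contamination threshold is published for this protocol); predator ASVs are
  removed because predator and cannibalized-conspecific DNA are
  indistinguishable; bacteria, fungi, diatoms, rotifers and other
  non-target lineages are removed by label match
  (`default_nontarget_taxa()`).
* **Species plus family add-back.** Per crab, species-rank taxa are kept;
  a genus- or family-rank taxon survives only if no retained deeper-rank
  taxon of the same crab lies inside it; ranks above family never survive.
  We interpret "already represented" as *any* deeper retained rank — a
  retained genus blocks its family just as a species does.
* **Non-native decision tree.** Native taxa are kept. A previously
  *detected* non-native is kept above 95% identity, or at ≤ 95% when native
  sister taxa are in the reference database; otherwise a species-rank call
  is demoted to its genus and anything else is removed. A previously
  *undetected* non-native is kept only above 98% *with* sisters in the
  reference; otherwise it is demoted to genus when a native congener exists
  in the reference, else removed. Both thresholds are strictly exclusive
  (`> 95`, `> 98`) while the 94 floor is inclusive, matching the usual
  reporting convention ("minimum of 94%", "greater than 95%"). The
  demote-vs-remove choice is operationalized as *demote iff a native
  congener is in the curated reference*; the source protocol reports both
  outcomes but not the selection rule, and this is the criterion its genus
  wording implies.

Native status itself is an input table, not a computation: the
classification relies on registries (WoRMS, NEMESIS, regional checklists)
that are consulted manually. Unknown status is a hard error — silent
guessing would corrupt the decision tree.

## Diversity and permutation tests

The **eDNA index** converts reads to within-crab proportions and rescales
each taxon by its maximum proportion across crabs, yielding a within-taxon
abundance index in [0, 1] that is invariant to sequencing depth. Jaccard
dissimilarity is used on presence/absence, Bray-Curtis on the index
(both through `vegan::vegdist()`).

**PERMANOVA** uses the standard pseudo-F from squared dissimilarities and a
free permutation of group labels, with
$p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})$. The `≥` resolves ties
conservatively and makes the smallest attainable p equal to
$1/(n_{perm}+1)$. The default 999 permutations is the R-ecosystem
convention; the count only affects p-value resolution, never the statistic.
All-coincident data are a defined degenerate case ($F = 0$, $p = 1$).

**PERMDISP** measures each observation's distance to its group centroid in
principal-coordinate space. PCoA reports negative eigenvalues as-is (no
Lingoes/Cailliez correction); inside PERMDISP the imaginary axes subtract
their squared contribution, truncated at zero — the same convention as
`vegan::betadisper(type = "centroid")`, against which the statistic is
cross-checked in the tests. The permutation scheme re-assigns labels and
recomputes centroids each time, which is exact under exchangeability.

Post-hoc pairwise PERMANOVAs multiply raw p-values by the number of pairs
**without capping at 1**. A corrected value above 1 simply reads "not
significant"; keeping it uncapped preserves the monotone relationship with
the raw p-values as conventionally reported for these tests.

Site-level α diversity removes genus/family records already represented by
a species detected at the same site (the conservative subsumption rule),
and site-to-site β diversity is the Jaccard dissimilarity of the pooled,
subsumed site sets. Pooled sets (rather than averaged crab-pair distances)
are the natural reading of a site-by-site β table.

## Amplification-bias calibration

PCR amplifies species at slightly different per-cycle rates. With template
proportions $\beta_i$ and per-cycle log-ratio offsets $\alpha_i$ (reference
species $\alpha \equiv 0$), the expected read proportion after $n$ total
cycles is

$$\nu_i = \log\beta_i + n\,\alpha_i,\qquad
  \mathbb{E}[\text{read prop}_i] = \frac{e^{\nu_i}}{\sum_j e^{\nu_j}}.$$

Offsets of only 0.01–0.09 per cycle compound over 40–47 cycles into
order-of-magnitude distortions, which is why read proportions cannot be
compared across taxa without calibration. Replicate reads are multinomial
around these proportions. Mock communities with known $\beta$ identify
$\alpha$; fixing the reference's offset at zero removes the likelihood's
translation invariance, so the reference estimate is *exactly* zero by
parameterization, not estimation.

**Inference.** The calibration posterior (prior $\alpha \sim N(0, 0.1)$) is
maximized with BFGS using analytic gradients, and intervals come from the
Laplace (normal) approximation at the mode. At mock-community depths
(~5×10^4 reads) the likelihood is so concentrated that this approximation
is indistinguishable from full posterior sampling, and it keeps the
estimator deterministic and fast; the parameter-recovery tests (truth
within ±0.01, interval coverage) validate the choice directly. Per-crab
calibration then plugs in the estimated $\alpha$ (two-stage, matching the
calibrate-then-apply workflow), shares one $\beta$ across technical
replicates, treats species with zero reads in all replicates as structural
zeros, and reports Monte-Carlo summaries of the softmax-transformed
Laplace posterior — so posterior-mean proportions sum to one exactly.
Overdispersion beyond multinomial is not modeled by default; with three
technical replicates per crab there is little information to estimate it.

Where a crab was re-processed at two total cycle counts, only the
lowest-cycle replicates are used (`select_lowest_cycle_replicates()`):
fewer cycles mean less compounded bias. Total cycles are stored in the
metadata (35 first-round + 5/8/12 indexing cycles, i.e. 40/43/47), never
inferred.

## The average-diet model

Calibrated proportions feed a pseudo-count matrix: crab $c$'s count for
species $i$ is $\mathrm{round}(\hat\beta_{ci}\, \bar N_c / d)$ with
$\bar N_c$ the average replicate depth (after lowest-cycle selection) and
divisor $d = 100$. Rounding is to nearest with ties-to-even, which avoids
systematic upward bias in row sums. The division shrinks the effective
multinomial sample size; it is *conservative* — posterior means are
essentially unchanged while credible intervals widen — and the tests
verify exactly that (means shift < 0.02 between $d = 100$ and $d = 50$).

The model itself: each species is structurally absent from a crab with a
species-level probability; present-species compositions are Dirichlet with
mean $\mu$ (renormalized to the present set) and concentration $\phi$;
counts are multinomial. Marginalizing the Dirichlet gives a
Dirichlet-multinomial on each crab's support. Two deliberate
simplifications:

* **Observed zeros are treated as structural.** At effective sizes of
  ~200 counts (20 000 reads / 100), a species forming a few percent of a
  crab's diet is essentially never missed, so the full mixture over
  "absent vs present-but-unsampled" collapses to conditioning on the
  observed support. This makes presence probabilities conjugate
  (Beta-Bernoulli) and the likelihood cheap and stable.
* **One-inflation is the single-species support.** A crab whose counts sit
  entirely on one species contributes a degenerate (point-mass) draw: it
  informs the presence probabilities but not $(\mu, \phi)$, which is the
  natural limit of the support-conditioned likelihood.

$(\mu, \phi)$ are sampled by adaptive random-walk Metropolis on the
unconstrained scale (softmax parameterization with a fixed reference
coordinate, prior $N(0, 2)$ on the free coordinates; $\log\phi \sim
N(\log 10, 1.5)$), 4 chains × 1 500 iterations by default with the first
half as warmup and step sizes tuned to ~30% acceptance. Split-R-hat above
1.05 triggers a warning. The reported "average diet" is the posterior
expectation of the support-renormalized mixture — the expected composition
of a new crab, averaging over which species it contains — computed by
exact enumeration of the 2^K − 1 supports per draw. Species with zero
counts in every crab are excluded from the simplex and reported as exactly
0 with degenerate intervals, which keeps a three-species slough diet from
leaking probability onto never-observed species.

Separate fits per site type (clam bed vs slough) follow the study design;
no covariates are modeled.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions: 60 crabs across four
sites (two clam-bed, two slough), ~40 prey taxa of which 8 are calibrated,
3 technical replicates, replicate depths LogNormal(ln 5×10^4, 0.3), total
cycles mostly 40 with some 43/47 and three crabs deliberately mixed-cycle,
per-species efficiency offsets on the estimated COI-primer scale (−0.01 to
+0.09 per cycle, the calibrated panel at its published values), sparse
diets of typically 1–3 taxa, and a predator-read fraction of 20–60%. In
effect mode the two site types draw prey from near-disjoint pools sharing
only three calibrated species — mirroring the observed contrast between
clam-bed and slough diets — while null mode makes diets exchangeable
across site types so that permutation tests can be checked for size.
Planted edge cases (predator ASVs, a control-contaminated ASV, sub-94 hits,
a congeneric double-hit for the LCA, non-natives at 96.2/97/identities
straddling the thresholds) make every filtering branch reachable, and
`plant_filter_fixtures()` is a fixed miniature whose correct output is
enumerated by hand.

What the generator does **not** emulate: sequencing error and chimeras
(assumed handled upstream by denoising), index hopping, tag jumps,
replicate-level extraction variability beyond multinomial noise, DNA
degradation during digestion (detectability half-lives), and real
taxonomic ambiguity in reference databases. Passing tests therefore
demonstrate that the *statistical machinery* is correct under the stated
model, not that any particular field inference is right.

## Numerical choices and problem sizes

* Permutation p-values use the add-one estimator throughout; ties count as
  extreme.
* The master seed drives every stochastic stage through fixed-offset
  derived streams, so a pipeline run is byte-reproducible; seeded helpers
  restore the caller's RNG state.
* Identity thresholds live on the 0–100 percent scale everywhere.
* Count matrices are TSV, metadata and results CSV, reports JSON.
* The test suite runs the expensive properties at deliberately chosen
  sizes: type-I error over 1 000 null datasets of 12 crabs at 99
  permutations; efficiency recovery at 5 mock communities × 3 replicates ×
  5×10^4 reads; Dirichlet recovery with 40 crabs and 20-simulation interval
  coverage; one full end-to-end run at the default 60-crab configuration.

## Limitations

Calibrated proportions are proportions of *DNA in the extract*, not of
ingested biomass; converting between them needs prey-specific detectability
half-lives that do not yet exist for green crab. The plug-in use of
$\alpha$ ignores its (tiny) uncertainty in per-crab calibration. The
support-conditioning approximation would bias presence probabilities if
effective counts were pushed far below ~50 per crab. And amplification
efficiencies are primer- and pipeline-specific: a different primer set
requires new mock communities.
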