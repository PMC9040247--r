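---
title: "Dissecting gene-tree discordance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting gene-tree discordance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a clade radiates quickly, individual loci disagree with one another and
with the species tree. Two biological processes produce such discordance:
**incomplete lineage sorting** (ILS) — ancestral polymorphism persisting
across short internal branches of the species tree — and **introgression** —
gene flow between already-diverged lineages. The two leave different
statistical fingerprints: ILS is symmetric between the two discordant
resolutions of a branch, while introgression inflates one of them, skews
ABBA/BABA site-pattern counts, and leaves discordant gene trees whose
internal branches are systematically longer than ILS alone predicts.
Lineage-specific substitution-rate variation (heterotachy) is a third,
orthogonal axis that distorts branch lengths without changing topology
frequencies.

`phylodisc` packages the statistics used to separate these processes —
topology spectra, quartet concordance factors, polytomy tests, D-statistics
with block-jackknife errors, branch-length mixture tests, local-clock model
comparison, and tree-space embedding — together with a
multispecies-coalescent (MSC) simulator that plays the role of the raw
sequencing data such studies start from.

## The generative model

The simulator draws gene trees backward in time under the MSC on an
ultrametric species tree. Within a species branch, each pair among `k`
lineages coalesces at rate 1 per coalescent unit, so the total rate is
`k (k - 1) / 2`; `pop_scale` converts the species tree's time units into
coalescent units (it plays the role of the unknown effective population
size). For a taxon triplet separated by an internal branch of `T` coalescent
units, the probability that the two deeper lineages fail to coalesce on that
branch is `exp(-T)`, giving the textbook discordance frequencies
`(1 - (2/3) e^{-T}, (1/3) e^{-T}, (1/3) e^{-T})` — exposed as
`expected_topology_freq()` and used throughout the tests as an analytic
oracle.

**Introgression** is modeled as instantaneous unidirectional pulses, the
discrete analogue of a phylogenetic-network edge with inheritance
probability `gamma`: at the pulse time, looking backward, each lineage
currently in the recipient branch jumps to the donor branch independently
with probability `gamma`. This makes `gamma` directly recoverable and keeps
closed forms available for single-pulse configurations. A `gamma = 1` pulse
does *not* force the recipient to be the donor's sister in every gene tree:
the transferred lineage enters the donor *branch* and may still fail to
coalesce there, so the exact expectation is `1 - (2/3) e^{-T'}` with `T'`
the shared residence time — this is what the tests assert.

**Rate heterogeneity** is a per-clade multiplier `r` (background 1) applied
to every species-tree branch inside the clade, including its stem. Because a
gene lineage can traverse several species branches with different rates, the
simulator records each lineage's residence times per branch and
`scale_branch_lengths()` converts a gene tree to substitution units as
`mu * sum_b r_b * dt_b` per branch. Pulse-transferred segments therefore
take the donor clade's rate automatically.

Sequences evolve i.i.d. per site under JC69 (default) or HKY down the
substitution-scaled gene trees. No rate-across-sites heterogeneity is
simulated: it would break the closed-form checks that anchor the test suite.

### Bundled scenarios and their rationale

`tribe_scenario()` emulates a five-lineage radiation compressed into ~8 Ma
about 60 Ma ago (stem 62.59, crown 60.51, radiation complete by 52.47 in the
scenario's time units), with 2608 loci of 500 bp, one ancient pulse into
`Ole` from `For` at inheritance probability 0.73, and a fast `Jas` clade
(multiplier 5.58123). `subtribe_scenario()` emulates a four-lineage
divergence spread over 46.7–39.4 Ma with 1865 loci, a weak pulse
(`gamma = 0.1`, our choice: the subtribe-level gene flow is reported as
present but weak) and a fast `Lig` clade (2.29322).

The time-to-coalescent-unit scaling has no external estimate (no effective
population sizes are available for these stem lineages), so it is a free
scenario parameter. We fixed it once — 8 Ma per coalescent unit at tribe
level, 6 at subtribe level — so that the simulated discordance levels match
the qualitative regime the statistics are meant for: near-random quartet
scores at tribe level, and roughly 18% frequency for each discordant
topology at subtribe level. These values were chosen before the acceptance
checks were run and are not tuned.

## The statistics

* **Topology spectrum.** Gene trees are rerooted on the outgroup and reduced
  to canonical rooted ingroup topology strings (children sorted by smallest
  descendant label, lengths dropped). The spectrum is reported over the full
  `(2k - 3)!!` universe with zero rows included; unresolved trees are
  excluded from the denominator and reported separately; ties in rank are
  broken lexicographically so reports are deterministic.
* **Quartet scores `q1/q2/q3`.** For each internal species-tree branch, all
  quartets with one taxon from each of the four branch-adjacent subtree sets
  are tallied across gene trees.
* **gCF / sCF.** gCF counts decisive gene trees displaying the branch;
  a tree is decisive when it displays one of the branch's three resolutions.
  sCF samples 100 quartets per branch (seed recorded) and averages the
  percentage of decisive (2–2 splitting) sites supporting the species
  arrangement; the parameters follow common concordance-factor practice
  since the quantity's original description leaves them open.
* **Polytomy test.** Pearson chi-square on the decisive-tree triple against
  equal thirds, df = 2, rejecting at P < 0.05.
* **PhyParts-style mapping and ICA.** Gene-tree branches below the support
  cutoff (default 80) are ignored; each tree is classified per reference
  branch as concordant, conflicting (most-common alternative vs rest), or
  uninformative. ICA uses logarithm base equal to the number of retained
  bipartition classes, so an even split scores exactly 0 for any class
  count; classes rarer than 5% are excluded, mirroring common practice.
* **Exhaustive quartet-score species tree.** For at most 7 ingroup taxa,
  every rooted topology is scored by shared induced quartets (a desk-scale
  surrogate for summary-coalescent species-tree estimation); ties are
  reported and broken lexicographically.
* **D-statistic.** `D = (nABBA - nBABA) / (nABBA + nBABA)` on biallelic
  sites polarized by the outgroup; the standard error is a delete-one
  jackknife over blocks. Blocks default to one per locus, matching
  gene-resolution data (the original study does not state its blocking).
  `|Z| > 3` flags gene flow: (P2, P3) when D > 0, (P1, P3) when D < 0. The
  pairwise matrix shows the mean |D| over implicating triplets, zeroed for
  never-significant pairs (the usual display convention), with the raw mean
  retained alongside.
* **Branch-length mixture test.** Per (triplet, topology class), the
  internal branch lengths across gene trees are fit by a single exponential
  (ILS only, 1 parameter) versus a mixture `pi Exp(lambda) +
  (1 - pi)(C + Exp(lambda))` with shared rate (3 parameters). The
  shared-rate parameterization is the minimal one consistent with a common
  coalescent rate and keeps the models cleanly nested (`C = 0` or `pi = 1`
  recovers model 1, so `logL2 >= logL1` by construction). Models are
  compared by `BIC = -2 logL + k log N`; `dBIC < -10` on a topology
  discordant with the species tree is called introgression. A 5-ingroup
  scan yields `C(5,3) x 3 = 30` rows, a 4-ingroup scan 12.
* **Local clocks.** `clock_loglik()` is a Felsenstein-pruning likelihood
  with branch lengths `mu * r_clade * duration`. `fit_local_clocks()` fits a
  ladder M0, M1, ... adding one clade multiplier per step; models are
  compared by AICc (`-2 logL + 2K n/(n - K - 1)`) and likelihood-ratio
  tests with Bonferroni-corrected threshold `alpha / m`, `m` = number of
  local-clock parameters of the richer model. The parameter-counting
  convention — `(tips - 1)` node times + substitution parameters + 1 rate +
  1 per clock — makes `K` auditable (180 tips with a GTR-like model gives
  the familiar 188/189/190/192 ladder).
* **Tree space.** All-pairs RF distances (symmetric difference of
  non-trivial splits; normalized by `2(n - 3)`) and classical Torgerson
  PCoA: double-center the squared distances, eigendecompose, scale
  eigenvectors by the root of positive eigenvalues; negative eigenvalues
  are reported and truncated with a warning.

## Numerical choices

* The mixture fit uses EM over `(pi, lambda)` at candidate shifts `C`
  placed on data quantiles (plus 0 and just below the minimum, where a
  second, near-degenerate mode can live), short-listed by a 60-iteration
  pass, refined by full EM (tolerance 1e-8, 500 iterations max), a
  bracketed line search over `C`, and a final Nelder–Mead polish of all
  three parameters. The EM trace is asserted non-decreasing.
* The clock optimizer works on unconstrained transforms: logit of each
  internal node's depth as a fraction of its parent's (root fixed at 1),
  log global rate, log multipliers; L-BFGS-B with seeded restarts plus a
  data-driven first start (rate from mean pairwise mismatch). A richer
  model never reports a worse likelihood than its nested predecessor.
* Alignments are pattern-compressed before likelihood evaluation, with
  column rescaling against underflow.
* RF treats polytomies by symmetric difference over whatever splits exist;
  zero-length branches are never collapsed implicitly.
* Simulation seeds fan out: the scenario seed derives per-locus streams (so
  locus `i` is invariant to the total locus count), and the pipeline's
  master seed derives independent per-stage streams (so toggling one stage
  never changes another's results).

## What a green test establishes — and what it does not

The synthetic generator reproduces the statistical structure the methods
assume: MSC topology frequencies, pulse-induced asymmetries, clade rate
multipliers, i.i.d. JC69/HKY sites. It does **not** emulate recombination
within loci, continuous migration, gene-tree estimation error (simulated
trees are observed exactly; empirical gene trees are not), alignment error,
or rate variation across sites. Green acceptance tests therefore establish
that the statistics behave correctly on data satisfying their own
assumptions — not that any particular empirical claim is correct.

Several acceptance properties are run at reduced scale to fit a single-CPU
budget, with the generating model unchanged and the assertion thresholds
kept: D-statistic type-I/power at 50 replicates of 400 loci x 300 bp
(headline example: 2608 x 500), clock recovery on 5 kb six-taxon alignments
(headline: 50 kb), species-tree recovery at 10 x 300 loci (headline:
100 x 2608).

## Known limitations

* The exhaustive species-tree search is capped at 7 ingroup taxa; the
  quartet machinery assumes every gene tree carries the full taxon set
  (partial trees are out of scope).
* The mixture test interprets `C` as a generic delay; it cannot by itself
  distinguish introgression from other sources of delayed coalescence
  (e.g. ancestral population structure).
* baseml-style GTR fitting is not reproduced; the clock module's likelihood
  is JC69/HKY, with the AICc/LRT arithmetic exact for any externally
  supplied `logL`/`K`/`n`.
* The D-statistic assumes no sequencing error and equal rates across the
  four taxa; strong heterotachy in the outgroup can bias polarization.
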