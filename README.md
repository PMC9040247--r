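# phylodisc

Dissecting gene-tree discordance into incomplete lineage sorting (ILS),
ancient introgression, and lineage rate heterogeneity.

Rapid radiations leave gene trees that disagree with the species tree.
`phylodisc` is for phylogeneticists who have a collection of gene trees (and
optionally alignments or biallelic site patterns) over a small set of focal
lineages plus an outgroup, and want to ask: *is the discordance just deep
coalescence, or did lineages exchange genes — and do some clades evolve
faster than others?* The package bundles the standard statistics for that
question and a multispecies-coalescent (MSC) simulator with introgression
pulses that stands in for raw sequencing data in tests and examples.

## What it computes

* **Topology spectra** over the full `(2k-3)!!` universe of rooted ingroup
  topologies (105 for five taxa, 15 for four).
* **Quartet scores** `q1/q2/q3`, **gene/site concordance factors**, the
  quartet-based **polytomy test** (`chi² = Σ (nᵢ − N/3)² / (N/3)`, df = 2),
  PhyParts-style conflict mapping with **internode certainty (ICA)**, and an
  exhaustive quartet-score species-tree search (≤ 7 ingroup taxa).
* **ABBA-BABA D-statistics**, `D = (nABBA − nBABA) / (nABBA + nBABA)`, with
  delete-one block-jackknife Z-scores (`|Z| > 3` flags gene flow between
  (P2,P3) if D > 0, (P1,P3) if D < 0), full triplet scans and the pairwise
  mean |D| matrix.
* **Branch-length mixture tests** (QuIBL-style): per triplet topology class,
  single exponential vs `π·Exp(λ) + (1−π)·(C + Exp(λ))`, compared by BIC
  with the stringent `dBIC < −10` call.
* **Local molecular clocks**: Felsenstein-pruning likelihood with clade rate
  multipliers, model ladders compared by
  `AICc = −2 logL + 2K·n/(n−K−1)`, likelihood-ratio tests
  `Λ = 2 ΔlogL`, and Bonferroni correction `α/m`.
* **Tree space**: all-pairs Robinson-Foulds matrices and classical PCoA.
* **Simulation**: MSC gene trees with instantaneous introgression pulses
  (inheritance probability γ), clade rate multipliers, JC69/HKY sequence
  simulation and polarized biallelic pattern extraction — all seeded and
  reproducible, with closed-form expectations
  (`expected_topology_freq()`) for testing.

## Worked example

A five-lineage radiation (taxa `Myx`, `Fon`, `For`, `Jas`, `Ole` +
outgroup `Out`) with heavy ILS, a large introgression pulse from `For`
into `Ole` (γ = 0.73), and a fast `Jas` clade:

```r
library(phylodisc)

sc   <- tribe_scenario(loci = 400, seed = 42)  # default: 2608 loci
gts  <- simulate_gene_trees(sc)
subs <- scale_branch_lengths(gts)              # substitutions/site

head(as.data.frame(topology_spectrum(subs, "Out")), 3)
#>                    topology_id rank count frequency
#> 1 ((Fon,((For,Ole),Jas)),Myx);    1    55    0.1375
#> 2 (Fon,(((For,Ole),Jas),Myx));    2    37    0.0925
#> 3 ((Fon,Myx),((For,Ole),Jas));    3    34    0.0850
```

No single topology dominates — and the top-ranked ones group `For` with
`Ole`, not the species-tree pair `(Jas,Ole)`. The quartet scores show why:

```r
st <- sc$species_tree
quartet_scores(st, subs)[, c("branch", "q1", "q2", "q3")]
#>                    branch        q1         q2        q3
#> 1 Fon,For,Jas,Ole|Myx,Out 0.4883333 0.25250000 0.2591667
#> 2 Fon,Myx,Out|For,Jas,Ole 0.6468750 0.19187500 0.1612500
#> 3 Fon,For,Myx,Out|Jas,Ole 0.2150000 0.09916667 0.6858333
```

The first branch has nearly symmetric alternatives (`q2 ≈ q3`: plain ILS);
the `(Jas,Ole)` branch is wildly asymmetric (`q3 = 0.69 ≫ q2 = 0.10`), the
signature of introgression. The D-statistic localizes it:

```r
set.seed(7)
alns <- lapply(seq_along(subs$trees), function(i)
  simulate_alignment(subs$trees[[i]], 500, seed = i))
pats <- lapply(alns, extract_site_patterns, outgroup = "Out")
dtab <- triplet_scan(pats, setdiff(st$tip.label, "Out"), "Out",
                     species_tree = st)
dtab[order(-abs(dtab$D))[1], c("P1", "P2", "P3", "D", "Z", "significant")]
#>    P1  P2  P3         D        Z significant
#> 8 Jas Ole For 0.3669251 16.01660        TRUE
```

`D = 0.37` with `Z = 16` implicates the pair `(Ole, For)` — the simulated
pulse. The branch-length mixture scan agrees and quantifies it:

```r
qscan <- quibl_scan(subs, setdiff(st$tip.label, "Out"), "Out", st)
sum(qscan$call)                         # introgression calls on 20 discordant rows
#> [1] 2
pairwise_introgression(qscan)["For", "Ole"]
#> [1] 0.4656234
```

i.e. roughly half the `For`-`Ole` triplet trees are attributed to the
introgressed component. The whole analysis (plus clock ladder and PCoA) runs
as one command:

```r
cfg <- run_config(sc, out_dir = "run1", seed = 1)
run_pipeline(cfg)   # writes TSV reports + resolved config + log into run1/
```

## Design notes

See the methods vignette (`vignettes/discordance-methods.Rmd`) for the
generative model, parameter defaults and their rationale, numerical choices,
and the limits of what a green test establishes.
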