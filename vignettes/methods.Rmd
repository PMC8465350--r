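---
title: "Statistical methods for haploid multilocus genotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for haploid multilocus genotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlgpop)
```

## Scope and data model

`mlgpop` analyses haploid multilocus genotype data of the kind produced
by microsatellite (STR) panels and multilocus sequence typing (MLST) of
clonal or partially sexual fungi. The central assumptions are:

* **Haploidy.** Every isolate carries exactly one allele per locus.
  There are no heterozygotes, so diversity and differentiation
  statistics operate on haploid allele frequencies throughout.
* **Categorical alleles.** Allele labels are opaque identifiers. No
  stepwise (repeat-count) mutation model is ever invoked: distances count
  label mismatches, never label differences. This is deliberate — STR
  fragment sizes are unreliable as evolutionary distances at the
  divergences involved, and sequence haplotypes have no natural order.
* **MLST alleles are whole-locus haplotypes.** Distinct aligned sequence
  strings at a locus receive distinct integer labels
  (`collapse_sequences_to_alleles()`); individual SNP columns appear only
  in the per-locus polymorphism summary. Treating haplotypes as alleles
  is what makes the linkage and compatibility tests applicable to
  sequence data.

A dataset (`mlg_dataset`) holds the isolate table (id, population,
mating type), one allele matrix per marker system, and population
metadata (region, optional coordinates). Multilocus genotypes
(`assign_genotypes()`) are equivalence classes of identical profiles;
ids are consecutive in order of first appearance, which makes outputs
reproducible from the input file alone.

### Missing data

Isolates with a missing call at any locus of the active system are, by
default, excluded from genotype-identity grouping: calling two profiles
"the same genotype" through a missing value is an untestable claim. The
alternative policy (`missing_policy = "match_any"`) treats a missing
call as a wildcard and greedily attaches each isolate to the first
compatible genotype; it is provided for sensitivity analysis, and its
grouping is order-dependent by construction (wildcard matching is not
transitive). Distance computations are always pairwise-complete: a pair
is compared over the loci where both calls are present.

### Clonal correction

Clone correction retains the first-encountered isolate of each genotype
*within each population* by default, so a genotype found in k
populations contributes k retained isolates. A `global` scope (one
isolate per genotype overall) is also available. The within-population
default is the convention under which published corrected sample sizes
for this kind of survey data are reproducible (on the bundled
genotype-distribution fixture: 239 isolates reduce to 100
within-population, 59 globally), and it preserves the population
structure needed by downstream differentiation statistics.

## Diversity statistics

For allele frequencies $p_i$ at a locus:

* gene diversity $h = 1 - \sum_i p_i^2$, optionally with the unbiased
  $n/(n-1)$ factor;
* PIC uses the full Botstein correction
  $1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, with the conventional
  classification low ($<0.25$) / medium / high ($>0.5$). PIC is bounded
  above by gene diversity, which the shortcut form $1-\sum p_i^2$ would
  violate — the full form is the one consistent with published marker
  tables where PIC sits strictly below gene diversity at every locus;
* genotypic diversity over genotype counts $n_i$ (with $n=\sum n_i$) is
  Nei's unbiased estimator
  $D = \frac{n}{n-1}\bigl(1 - \sum_i (n_i/n)^2\bigr)$,
  the probability that two isolates drawn without replacement carry
  different multilocus genotypes. $D$ depends on $n$, not just on
  proportions: $D(1,1)=1$ but $D(2,2)=2/3$. The package's tests pin this
  property to guard against accidentally implementing the biased form.

Private alleles use strict presence/absence: an allele is private to a
population iff it occurs there and nowhere else. No frequency threshold
and no rarefaction correction is applied (allelic-richness rarefaction is
out of scope).

## Differentiation

The genotype distance is the number of loci at which two profiles carry
different labels. Distance-based AMOVA squares these distances:
$SS_{total} = \sum_{i<j} d^2_{ij}/N$, within-population sums analogous,
variance components from the mean squares with the standard
unequal-sample-size coefficient
$n_0 = (N - \sum_k n_k^2/N)/(P-1)$, and
$\Phi_{PT} = \sigma^2_{among}/(\sigma^2_{among}+\sigma^2_{within})$.
Significance permutes isolate-to-population labels with the $+1$
correction, one-sided (permuted $\Phi_{PT} \ge$ observed). Numerical
choices:

* A negative among-population component is truncated to zero in
  `phi_pt` (standard practice), but the raw value is kept
  (`phi_pt_raw`). Calibration checks on panmictic simulations use the
  raw estimator: the truncated one is non-negative by construction, so
  its null mean cannot be zero.
* If all isolates are identical, $\Phi_{PT}$ is defined as 0 with a
  warning rather than 0/0.
* Pairwise population $\Phi_{PT}$ p-values are reported raw
  (uncorrected), matching the field's usual practice of counting
  significant pairs at $\alpha=0.05$.

Nei's (1972) standard distance is computed from population allele
frequencies pooled over loci, $D = -\ln\!\bigl(J_{xy}/\sqrt{J_xJ_y}\bigr)$.
Populations sharing no allele at any locus get $D = \infty$ and are
flagged; the Mantel test excludes non-finite pairs from the correlation
(with a reported count) rather than capping them, since any finite cap
distorts $r$ arbitrarily. Geographic distances are haversine
great-circle distances on a 6371 km sphere. The Mantel test correlates
upper-triangle entries and permutes rows and columns of the second
matrix jointly; the default alternative is one-sided positive, the
isolation-by-distance direction. PCoA is classical metric scaling
(`stats::cmdscale`); negative eigenvalues (mismatch distances are not
Euclidean) are dropped with a warning and explained proportions refer to
the positive spectrum.

## Linkage disequilibrium and recombination

For all isolate pairs, $d_{ij}$ is the mismatch count. With $V_O$ the
variance of $d_{ij}$ and $V_E = \sum_L v_L$ the sum of single-locus
indicator variances, $I_A = V_O/V_E - 1$ and
$\bar r_d = (V_O - V_E) \big/ 2\sum_{L<M}\sqrt{v_L v_M}$.
All variances use the population convention (divide by the number of
pairs); any single consistent convention gives identical $I_A$,
$\bar r_d$ and p-values, and this one yields the exact identity
$\bar r_d = 1$ for perfectly duplicated loci, which the tests verify by
hand-computable example ($V_O = 8/9$, $V_E = 4/9$ for four isolates at
two perfectly linked biallelic loci).

The permutation null shuffles each locus column independently across
isolates — sampling from the linkage-equilibrium distribution with the
observed allele frequencies — and $p = (1 + \#\{\bar r_{d,perm} \ge
\bar r_{d,obs}\})/(1+n_{perm})$.

Phylogenetic compatibility generalizes the four-gamete test to
multi-allelic loci: a locus pair is compatible iff the bipartite graph
with one node per observed allele and one edge per observed allele
combination is acyclic. PrC is the compatible fraction of locus pairs.
Its permutation p-value uses the same column-shuffle null and the same
$\ge$ direction — large compatibility is the clonal signal, so a small p
means more compatibility than recombination would produce. This
direction has a structural consequence the tests pin down: observed
PrC $= 0$ can never exceed a permuted value, forcing $p = 1$.

Clonal correction before the linkage tests is the caller's choice and
defaults to off, since the reference analyses of this data type report
linkage statistics on uncorrected samples.

## Genotype networks

`build_mst()` computes a minimum spanning tree over genotypes with
mismatch-count edge weights via Kruskal's algorithm. Equal-weight ties
are resolved by ordering edges on the lexicographic order of the
endpoint representative profiles, which makes the tree deterministic
*and* invariant to isolate input order (a tie-break on genotype ids
would be deterministic but order-dependent, since ids follow first
appearance). Edges are classified ONE / TWO / THREE / FOUR_PLUS by
difference count, following the usual network-figure legend; node sizes
are genotype member counts. With missing-data policies that leave
genotype pairs incomparable the result may be a spanning forest, and is
flagged as such.

## Mating types

`mating_type_summary()` counts `mat1-1` and `mat1-2` idiomorphs, reports
the ratio, and tests 1:1 with a 1-df chi-square without continuity
correction, excluding untyped isolates from the denominator.
`shared_genotype_mating_conflicts()` lists genotypes whose members carry
both idiomorphs — in a strictly clonal lineage a genotype has one mating
type, so conflicts are direct evidence of recombinant origins.

## The synthetic generator

`simulate_dataset()` produces datasets with the statistical structure
the analyses assume, plus the ground truth needed for recovery tests.
The default preset mirrors the sampling design the package targets: 19
populations totalling 239 haploid isolates across 7 regions, 20 STR loci
with 3–21 possible alleles, 6 sequence loci with fewer (2–8) haplotype
alleles, two ancestral clusters, and a mating-type probability of 0.565
(idiomorph ratio 1:1.3). Population coordinates in the preset are
synthetic province-level approximations, sufficient for
isolation-by-distance mechanics but not real sampling sites.

Key modelling choices:

* **Divergence** acts as an inverse Dirichlet concentration: cluster
  frequencies are drawn around the ancestral base with concentration
  proportional to $1/\text{divergence}$, and population frequencies
  likewise around their cluster's. At divergence 0 every population has
  identical expected frequencies, which makes the AMOVA null calibration
  exact by exchangeability.
* **Recombination** is modelled as per-locus independent draws from the
  population allele-frequency pool — precisely the linkage-equilibrium
  null of the permutation tests, so power curves against the
  `recombination_rate` knob are directly interpretable. Drawing from
  frequencies rather than from the finite realized pool avoids
  re-importing founder drift into the recombinant fraction. There is no
  explicit mating-type-constrained mating model.
* **Clonality** expands founders into geometric-size clone groups
  (parameter `clone_p`, expected clone size $1/p$).
* **Hybrids** draw each locus's frequency source from a random cluster,
  emulating admixed genotypes between diverged clusters.

What the generator does *not* emulate: stepwise STR mutation, coalescent
genealogies, spatially explicit migration, and selection. Passing
parameter-recovery tests therefore demonstrates that the statistics
respond correctly to clonality, divergence and admixture as modelled —
not that they are robust to mutation-model misspecification in real
data.

## Bundled reference tables

Two published summary tables ship as plain TSV and are re-expanded into
datasets by code:

* `fixture_from_table3()` rebuilds 239 isolates in 19 populations whose
  MLST genotype memberships exactly encode the published
  genotype-distribution table (59 genotypes). Allele columns are
  synthesized (mixed-radix expansion of the genotype id), preserving the
  partition but not the real haplotypes.
* `fixture_from_table1()` realizes the published per-population
  per-locus allele and private-allele counts (188 alleles, 48 private)
  through a deterministic greedy design that places each shared allele
  in at least two populations; feasibility is asserted at construction.
  Isolate-level profiles cycle through the designed allele sets, so
  allele-presence statistics are faithful while multilocus genotype
  structure is synthetic.

One known inconsistency in the source table is handled explicitly: the
Gejiu (Yunnan) genotypic-diversity entry prints 0.286, but its own
genotype counts `(3, 6, 2, 4)` give 0.762 under every standard
diversity formula; the row is treated as a typographical error and
excluded from value-matching checks (the package reports the recomputed
value).

## Problem sizes and determinism

Every randomized routine takes an explicit seed; the pipeline
(`run_analysis()`) derives a per-stage sub-seed from the master seed and
the stage name, so toggling one stage never shifts another's random
stream, and a manifest (seed, options, versions) is written with each
report. Calibration and power checks in the test suite use 12–50
replicates at 60–200 isolates and 10–20 loci — sizes chosen so each
property is measured with comfortable margin (for example, the mean
linkage-equilibrium $\bar r_d$ over 50 replicates of 200 isolates has a
standard error well under the ±0.02 band asserted).

## Known limitations

* Region-level published linkage values cannot be reproduced because
  the underlying per-isolate genotype matrices are not public; the
  package validates those statistics by identity, calibration and
  power properties on synthetic data instead.
* The `match_any` missing policy is order-dependent (documented above).
* Hierarchical (region-level) AMOVA is not implemented; the analysis
  partitions variance at one level, among and within populations.
* No Bayesian cluster assignment: ordination (PCoA) plus the simulator's
  recorded cluster truth stand in for model-based structure analysis.
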