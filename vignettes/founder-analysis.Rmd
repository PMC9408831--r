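---
title: "Founder analysis: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder analysis: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderscan)
```

## The inference problem

Founder analysis formalizes phylogeography for a non-recombining locus
when a migration's *source* and *sink* populations can be designated.
Lineages sampled in the sink that nest inside source diversity mark
discrete founder events; dating each founder's cluster and aggregating
over clusters yields the timing, magnitude and geographic origin of the
migrations that carried them. `founderscan` consumes a rooted tree whose
branch lengths are **integer mutation counts** (the natural output of a
median-network or maximum-parsimony reconstruction of mitogenomes) plus
a sample-metadata table, and returns tidy tables at every stage.

## Founder detection and the f criterion

A node's haplotype counts as *attested in the source* if either

* a source leaf is reachable from it through a path of total mutation
  count zero — the identical haplotype was sampled in the source — or
* the node is an inferred (internal) ancestor with at least one
  source-leaf descendant.

Both arms are needed: reconstructed ancestral haplotypes are usually
unsampled, while shared haplotypes often survive unchanged in both
populations. We implement the first arm as haplotype-identity
components: maximal sets of nodes connected by zero-mutation branches,
computed once by union-find. Each sink leaf's **founder node** is the
most recent node on its root path (itself included) that is attested.

"Some diversity in the source" — the classical f1 criterion — is made
operational as: the founder node has at least `f = 1` source-leading
child branches carrying one or more mutations. Candidates that fail
push their sink leaves rootward to the next attested node that passes,
which also resolves the corner case of sink leaves identical to the
founder haplotype: such a leaf is technically its own (zero-diversity)
source-attested match, fails f1, and re-assigns to the intended
ancestral founder. `f` is exposed as a parameter; `f = 0` accepts any
attested match.

## Dating: rho, Saillard error, linear clock

For a cluster of $n$ sink leaves below founder node $F$, with $m_b$
mutations on branch $b$ of the sink-restricted subtree and $n_b$
cluster leaves below it,

$$\rho = \frac{1}{n}\sum_b n_b m_b, \qquad
  \sigma_\rho^2 = \sum_b \left(\frac{n_b}{n}\right)^2 m_b .$$

$\rho$ equals the mean per-leaf mutation path from the founder node
(the suite asserts this conservation identity on every simulated tree),
and for a star cluster the error reduces to $\sqrt{\text{total}}/n$.
Mutations on the branch *into* the founder node are excluded: $\rho$
dates the divergence of the sink subtree from the founder haplotype,
i.e. the migration, not the founder haplotype's own age. Ages are
$\rho \times$ `years_per_mutation`, default 2565 y per substitution — a
mitogenome rate near the present allowing for purifying selection. The
clock is strictly linear because the method requires it; over the
0–25 ka window the deviation of the full time-dependent correction is
small (under ~7%), and no attempt is made to model it.

## The migration scan

Each dated founder contributes a weight vector over a time grid
(default 0–25,000 y in 200-y steps): a Gaussian with mean `age_years`
and standard deviation `max(sigma_years, sigma_floor)`, evaluated at
the grid points and normalized to sum 1. Choices worth stating:

* **Gaussian sampling distribution.** The rho/Saillard machinery
  supplies a point estimate and a standard error; the Gaussian is the
  standard density built from those two numbers, with a uniform prior
  over grid points.
* **σ floor = one grid step** (200 y by default). A cluster with
  $\rho = 0$ has $\sigma_\rho = 0$; without a floor it would be a delta
  spike incomparable with every other founder. The same floor is used
  in epoch allocation so degenerate clusters behave identically in both
  modules.
* **Truncation, not reflection.** Mass falling below 0 y (or beyond the
  grid) is handled by renormalizing over the grid support. This is the
  simplest defensible rule, and it matters near the present: a founder
  at age 0 yields a monotonically decreasing half-Gaussian, so very
  recent episodes peak at or near the 0 grid point rather than at their
  nominal age.

The aggregate mass is the founder-weight average
$\mathrm{mass}(t) = \sum_i n_i w_i(t) / \sum_i n_i$, weighting founders
by sink-lineage count to match the method's lineage-proportion
language; `weights = "equal"` switches this off. Peaks are strict local
maxima (ends compared to their single neighbour), reported sorted by
mass.

Two numerical consequences deserve emphasis. First, the peak position
near an epoch tracks the *mean estimated age* of that epoch's founders,
whose standard error is set by the total Poisson information
($\sigma \approx 2565\sqrt{T/2565\,/\,(n_\text{founders} n)}$ years);
with few founders the peak wanders by several grid steps no matter how
the scan is computed. Second, because each founder's weight vector is
normalized, low-rho founders (smaller Saillard σ) contribute *taller*
densities, which pulls a mixture's mode slightly below the epoch time —
a few hundred years at 8 ka with ten-lineage clusters. Both effects are
visible in the recovery experiments and are properties of the method,
not of this implementation.

## Epoch allocation

Under a fixed epoch model (default 8,000 y "prehistoric" and 500 y
"historical"), founder $i$'s posterior is the same Gaussian density
evaluated at the epoch times, renormalized — equivalently, the scan
weight vector restricted to the epoch grid points (the suite asserts
this consistency where the epochs are on-grid). A uniform prior over
epochs is the minimal assumption and is deliberate; if every density
underflows, the nearest epoch takes all mass (split equally on an exact
tie). Aggregation is again lineage-weighted, so the reported
proportions are fractions of sink lineages per migration. Epoch times
are fixed by the model, never estimated from the data.

## Source-region attribution

The qualitative step "evaluate the phylogeography of each founder" is
replaced by a deterministic, auditable rule: collect the source leaves
descending from the founder node (falling back rootward to the nearest
source-attested ancestor when re-assignment left none); the region with
the most leaves wins; ties break by smallest mean tree-path mutation
distance to the founder node, then lexicographically with
`ambiguous = TRUE`. The per-epoch region composition and per-population
epoch frequencies are exact weighted tallies of these attributions and
the epoch posteriors. Negative-evidence reasoning (attributing by a
region's *absence*) is not formalized; the `support` and `ambiguous`
columns are exposed so users can apply their own judgment.

## The synthetic-data generator

`sim_config()` describes a study in miniature: founder events at given
times, each with a fixed number of sink lineages, attached to a source
tree whose branch mutation counts are Poisson in branch duration under
the same linear clock the estimators assume. Guarantees by
construction: every founder node retains one zero-mutation source leaf
(attestation) and at least one derived source branch (f1), and each
sink lineage accumulates Poisson($T$/2565) mutations so the cluster's
expected rho age is exactly $T$. Sink subtrees are stars by default —
making rho and Saillard behaviour analytically checkable — with a
`"cherry-star"` option (a quarter of the leaves paired into cherries,
the epoch time split between stem and tips) to exercise the general
branch-weighted formulas. Identical config and seed give byte-identical
Newick/TSV output.

The defaults (30 founders at 500 y from West Africa, 10 at 8,000 y from
Eastern Africa, 10 lineages per founder, 3 source leaves per clade,
5,000 y of source clade depth) emulate a recent/Holocene twin-peak
history at desk scale. What the generator does *not* emulate — and what
passing recovery tests therefore do not certify for real data —
includes: back and recurrent mutation (paths are simple sums on a
resolved tree), rate heterogeneity across sites, coalescent
non-independence within and between clusters, contaminated or
misclassified source clades, and founders whose source diversity went
unsampled. Sample sizes are chosen so the full recovery suite runs in
about a minute on one core; they are stated in the tests themselves.

## Known limitations

* The method dates *clusters*, so lineages that diversified in the sink
  before sampling inflate ages; conversely unsampled source diversity
  fragments founders.
* Peak positions near the present are biased toward 0 by truncation,
  and mixture modes sit slightly below epoch times (see above); the
  epoch *allocation* is far more stable than the peak *positions* and
  is the quantity to report when epochs are known.
* Trees must be trees: reticulations in a median network must be
  resolved upstream, and the package does not arbitrate how.
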