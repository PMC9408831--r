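# founderscan

Founder analysis of non-recombining phylogenies: identify, date and
geographically attribute migration events from a rooted tree (typically
of mitogenomes) whose branch lengths are mutation counts.

## The problem and the method

When a *source* and a *sink* population can be designated, the sink's
lineages that trace back to haplotypes attested in the source mark
discrete founder events. `founderscan` implements that inference
end to end:

1. **Founder detection.** For every sink leaf, the most recent ancestor
   whose haplotype is attested in the source (the same haplotype sampled
   there, via a zero-mutation path, or an inferred ancestral node with
   source descendants) is its founder node. The **f1 criterion** demands
   derived diversity in the source at that node (≥ *f* source-leading
   child branches with ≥ 1 mutation), screening out back-migrants;
   failing candidates re-assign their sink leaves rootward.
2. **Dating.** Each founder cluster is dated with the **rho statistic**,
   ρ = (1/n) Σ_b n_b·m_b — the mean mutation count from the founder node
   to its n sink leaves — with the **Saillard standard error**
   σ² = Σ_b (n_b/n)²·m_b, converted to years by a linear clock
   (default 1 substitution per 2565 years).
3. **Migration scan.** Each founder contributes a normalized Gaussian
   N(age, max(σ_years, one grid step)) evaluated on a candidate-time
   grid (default every 200 y from 0–25 ka); the lineage-weighted sum is
   the probability mass of migration over time, whose peaks are the
   inferred migration episodes.
4. **Epoch allocation.** Under a fixed multi-epoch model (default 8 ka
   "prehistoric" / 0.5 ka "historical") each founder is statistically
   allocated between epochs in proportion to the same Gaussian density
   at the epoch times, and lineage proportions per epoch are aggregated.
5. **Source attribution.** Each founder is attributed to the source
   region holding the majority of the source leaves under its node
   (ties broken by mean mutation distance, then lexicographically with
   an `ambiguous` flag), yielding region-by-epoch compositions and
   per-population epoch frequencies.

A seeded synthetic-data generator injects founder events at known times
under the same Poisson/linear-clock model, so every stage is testable by
parameter recovery.

## Worked example

Simulate a two-episode history — 30 founders arriving 500 years ago out
of West Africa, 10 arriving 8,000 years ago out of Eastern Africa, 10
sink lineages each — and analyse it:

```r
library(founderscan)

sim  <- simulate_founder_dataset(sim_config(seed = 42))
tree <- parse_tree(sim$newick, sim$metadata)
fa   <- run_founder_analysis(tree,
                             source_regions = c("West Africa", "Eastern Africa"),
                             sink_regions   = "Sink")
fa
#> <founder_analysis>
#>   sink lineages analysed: 400 in 40 founder clusters (f = 1)
#>   scan peaks (years): 200, 7200
#>   epoch allocation: prehistoric 25.0%, historical 75.0%
```

All 40 planted founders are recovered. The scan shows the twin-peak
structure: a recent peak (200 y; the true 500 y episode, whose mode sits
low because many recent clusters carry zero mutations) and a Holocene
peak (7200 y for this seed; scatter of roughly ±1 ka is expected with
only 10 founders at that epoch). The epoch allocation recovers the
simulated 75:25 lineage split essentially exactly. `tidy(fa)` returns
the per-founder table (rho, σ, age, source region, epoch posteriors),
`glance(fa)` a one-row run summary, and `autoplot(fa)` the scan curve.
`simulate_and_run(sim_config(seed = 42))` scores the same analysis
against the simulation's ground truth:

```r
simulate_and_run(sim_config(seed = 42))
#> <recovery_report> 40/40 founders recovered
#>   peak errors (y): 8000: 800, 500: 300
#>   allocation: epoch_8000 25.0% (true 25.0%), epoch_500 75.0% (true 75.0%)
#>   region accuracy: 100.0%
```

`run_founder_files()` (or the `exec/founderscan` script) runs the same
pipeline from a Newick file plus metadata TSV and writes one TSV per
stage and a JSON manifest.

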