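# endosym

Tools for quantifying intracellular symbiont (e.g. *Wolbachia*) dynamics in
host cell culture from whole-genome sequencing coverage — for researchers
studying mixed-strain infections, infection establishment, and strain
competition *in vitro*.

Two strains of the same symbiont species are nearly identical in sequence,
so their abundances cannot be read off alignment counts naively. `endosym`
restricts all depth statistics to **uniquely mappable sites**: positions
whose length-*k* subsequence occurs exactly once, over both strands, in the
whole composite host+symbiont reference. On that footing it computes:

* **Genomic titer** — symbiont genome copies per host genome copy:

  `titer_s = mean depth(symbiont s) / mean depth(host autosomes)`

  with host depth pooled over the 2L, 2R, 3L, 3R and 4 autosomes, after
  keeping only primary, non-duplicate alignments with MAPQ > 20. The
  host-inclusive *proportion of total coverage* (each group's mean depth
  over the sum of all three) is reported alongside.

* **Selection coefficients** under the haploid chemostat model. With
  `p_t` the focal strain's share of symbiont coverage in week `t` and
  `q_t = 1 − p_t`,

  `ln(p_t/q_t) = ln(p_0/q_0) + t·ln(ω)`,

  so the per-week selection coefficient `ω` is `exp(slope)` of an OLS fit of
  the log odds on time. The same log-linear core yields weekly titer fold
  changes (`exp(slope) − 1`, in percent) and cell doubling times
  (`ln 2 / slope`).

* **Candidate recombinant read pairs** — pairs whose mates align to the two
  different strain genomes, each anchored in a uniquely mappable interval —
  with per-alignment and per-pair normalised fractions.

* **Mixing plans** — culture volumes that combine two infected lines at a
  target symbiont-cell ratio given their cell densities and titers.

A synthetic-data generator (composite genomes with shared/unique block
structure, tiling or random alignments with exact depth calibration,
chemostat trajectories, titer and cell-count series) provides ground truth
for every estimator; see the methods vignette
(`vignettes/endosymbiont-dynamics.Rmd`) for the model assumptions and design
choices.

## Worked example

Simulate a composite genome and a sequencing run where the wMel strain sits
at 20× coverage, wRi at 2× and the host at 10×, then recover the titers:

```r
library(endosym)

genome <- generate_composite_genome(sim_genome_spec(seed = 7))
track  <- compute_mappability(genome, k = 150)
groups <- contig_groups()

aln <- simulate_alignments(genome, sim_library_spec(
  depths = c("2L" = 10, "2R" = 10, "3L" = 10, "3R" = 10, "4" = 10,
             "wMel" = 20, "wRi" = 2)))
depths <- mean_mappable_depth(filter_alignments(aln), track, groups)
genomic_titer(depths)
#> titer_estimate
#>   genomic titer (symbiont/host):
#>     wMel: 2
#>     wRi: 0.2
#>   proportion of total coverage:
#>     host: 0.3125
#>     wMel: 0.625
#>     wRi: 0.0625
```

The titers are exactly the simulated depth ratios (20/10 and 2/10): tiling
alignments cover every position uniformly, and only uniquely mappable
positions enter the means. The proportions are each group's share of summed
mean depth (e.g. wMel: 20/32 = 0.625) and sum to 1.

Fit a selection coefficient from a noise-free competition trajectory and a
weekly growth rate from a titer series:

```r
traj <- simulate_trajectory(omega = 2.81, p0 = 0.5, weeks = 6)
estimate_selection(traj, window = c(0, 6))
#>   replicate    slope     se_slope   intercept omega r_squared n t_start t_end
#> 1         1 1.033184 1.040221e-15 6.41493e-16  2.81         1 7       0     6

weekly_fold_change(simulate_titer_series(weekly_fold = 0.17, weeks = 5))
#>   replicate     slope     se_slope fold percent r_squared n t_start t_end
#> 1         1 0.1570037 9.271684e-18 1.17      17         1 6       0     5
```

`omega = 2.81` means the focal strain's fitness is 2.81× its competitor's
per week; `percent = 17` means the titer grows 17% per week.

File-based workflows (FASTA/SAM/BED/TSV in, TSV/JSON out) go through
`run_pipeline()` with a YAML config, or the thin CLI at
`inst/scripts/endosym` (subcommands `mappability`, `titer`, `chimera`,
`selection`, `growth`, `mixplan`, `run-all`).

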