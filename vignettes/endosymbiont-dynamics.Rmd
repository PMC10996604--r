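---
title: "Quantifying endosymbiont competition from sequencing coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endosymbiont competition from sequencing coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosym)
```

# The problem

Intracellular symbionts such as *Wolbachia* cannot be counted directly in a
bulk DNA sample, but whole-genome shotgun sequencing of infected host cells
yields reads from host and symbiont genomes in proportion to their copy
numbers. `endosym` turns such coverage data into three kinds of estimates:

* **genomic titer** — symbiont genome copies per host genome copy, from the
  ratio of mean read depths;
* **selection coefficients** — the per-week relative fitness of one symbiont
  strain over another in a mixed infection, from the time course of their
  coverage shares;
* **recombination candidates** — read pairs bridging the two strain genomes
  at strain-diagnostic sequence.

Host cells in continuous culture with weekly splits approximate a chemostat:
cell numbers are held within a tolerance band while resources stay
plentiful, which is what licenses the selection model below.

# Titer from depth at uniquely mappable sites

Two co-cultured strains of the same symbiont species are nearly identical at
the sequence level (for the *w*Mel/*w*Ri pair, about 99.9% over 1.3–1.4 Mb).
Reads from shared sequence align ambiguously between the two strain contigs
in a composite reference, so depth is meaningful only where a read's placement
is unambiguous. `compute_mappability()` scores every position by
$1/c$, where $c$ counts genome-wide occurrences of the $k$-mer starting
there, on both strands (a $k$-mer and its reverse complement are the same
molecule and share one count; palindromes are counted once per occurrence).
Only positions with score exactly 1 — the $k$-mer occurs once in the whole
composite genome — enter any downstream mean. The default $k = 150$ matches
the read length, so a score-1 position is one where a full-length read
starting there has a unique exact home. Matching is exact: mismatch-tolerant
mappability would blur exactly the strain-diagnostic differences the
analysis relies on. Windows containing non-ACGT characters are unscored and
treated as unmappable.

Alignments are filtered before depth is taken: MAPQ strictly greater than 20
(`mapq_min = 0` bypasses the filter entirely), duplicates and
secondary/supplementary records dropped. Per-position depth counts every
retained alignment overlapping the position, and the group mean pools all
mappable positions of a contig group (position-weighted), not per-contig
means — so a large autosome carries proportionally more weight than the dot
chromosome. The host denominator uses the five autosomal contigs
(2L, 2R, 3L, 3R, 4) only; sex chromosomes vary in copy number between cell
lines. Then

$$\mathrm{titer}_s = \frac{\bar d_s}{\bar d_\mathrm{host}}, \qquad
  \mathrm{proportion}_g = \frac{\bar d_g}{\sum_{g'} \bar d_{g'}},$$

the proportion running over host and both symbionts and summing to one.
Depth uses the full aligned span (the synthetic alignments are gapless); no
CIGAR-aware arithmetic, GC correction, or base-quality filtering is applied.

# The haploid chemostat selection model

Let $p_t$ be the focal strain's share of symbiont coverage in week $t$ and
$q_t = 1 - p_t$. Under constant selection the odds grow geometrically,

$$\frac{p_t}{q_t} = \frac{p_0}{q_0}\,\omega^t, \qquad
  \ln\frac{p_t}{q_t} = \ln\frac{p_0}{q_0} + t \ln\omega,$$

so `estimate_selection()` fits $\ln(p_t/q_t)$ on $t$ by ordinary least
squares and reports $\omega = e^{\hat\beta}$, the per-week fitness of the
focal strain relative to its competitor ($\omega = 1$: neutrality). Fitting
A-vs-B and B-vs-A gives exactly reciprocal $\omega$s, and adding a constant
to all times changes only the intercept.

Choices that matter:

* **Frequencies are symbiont-only shares**, $p_t = \bar d_A / (\bar d_A +
  \bar d_B)$: the model is defined on the two strains. The host-inclusive
  proportion of total coverage is computed separately for plotting.
* **No genome-length normalisation by default** — the two strain genomes
  differ by only a few percent in length; a `lengths` switch exists in
  `frequencies_from_depths()` for genuinely unequal genomes.
* **Points with $p \in \{0, 1\}$ are excluded**, not pseudo-counted: their
  log-odds are infinite. For mixtures where the focal strain is
  undetectable at mixing, the fit starts at the first week it appears.
* **OLS, unweighted, replicates fit independently.** Autocorrelation and
  mixed-effects refinements are out of scope here.

Near fixation this exclusion rule has a visible consequence: with binomial
sampling at depth $D$, late time points sometimes return $\hat p = 1$ and
drop out, and the draws that remain are conditioned on being below
saturation, truncating the upward noise. The estimate is pulled slightly
toward 1. At $D = 1000$, seven weekly points and $p_0 = 0.5$, the median
bias is negligible at $\omega = 1.8$, about $+1\%$ at $\omega = 2.8$, and
about $-5\%$ at $\omega = 3.6$ (measured by simulation in the test suite).
Deeper sampling or an earlier window shrinks it; users fitting strong
selection should prefer windows that end before fixation.

`weekly_fold_change()` applies the same log-linear core to titer series:
$\mathrm{fold} = e^{\hat\beta}$ per week, reported as
$(\mathrm{fold}-1) \times 100$ percent; zero titers are excluded with a
warning. `doubling_time()` is again the same regression on cell counts, with
$T_d = \ln 2 / \hat\beta$ and per-day factor $g = e^{\hat\beta}$ (so
$g^{T_d} = 2$); recorded passage dilutions are chained multiplicatively so
splits do not bias the slope. A declining culture is reported with a
half-life rather than a negative doubling time.

# Recombinant read-pair detection

A candidate inter-strain recombinant is a read pair whose mates align to the
two different strain contigs, each overlapping — by at least one base, the
permissive reading of "overlaps" — a mappability-1 interval on its own
contig. The anchor requirement is what gives the signal meaning: without
it, any pair falling in the strains' shared sequence could be assigned
cross-strain by arbitrary tie-breaking. Standard filtering runs first. Two
normalisations are reported side by side, per retained alignment record and
per retained pair; the "1 in N" headline convention corresponds to the
per-pair figure. No breakpoint inference is attempted: the detector flags
candidates only.

# The synthetic-data generator

Every estimator above is exercised against data with known ground truth:

* `generate_composite_genome()` builds host autosomes as independent random
  sequence and two symbiont contigs from alternating blocks — shared blocks
  identical between strains (hence unmappable once both contigs are in the
  reference) and unique blocks drawn independently (hence mappable). Blocks,
  rather than scattered substitutions, keep both region types large enough
  to target in tests; the realised shared length is exactly
  `round(shared_fraction * symbiont_length)`.
* `simulate_alignments()` emits alignment records directly — placement is
  ground truth, there is no read-sequence or aligner emulation, and no
  sequencing-error, indel or quality model. Contigs are treated as circular:
  reads overhanging the end are split into two truncated records. In tiling
  mode an integer target depth is decomposed into evenly spaced lanes so
  that *every* position is covered exactly the target number of times —
  which is why a tiling run at symbiont:host depth 45:10 returns titer 4.5
  exactly through the whole pipeline, not approximately. In random mode
  starts are uniform on the circle, so expected coverage equals the target
  at every position. Duplicate/secondary records are flagged copies layered
  on top, leaving the post-filter depth calibrated.
* `simulate_trajectory()`, `simulate_titer_series()` and
  `simulate_cell_counts()` generate the geometric dynamics the fitters
  invert, with optional binomial (trajectories) or lognormal (titers,
  counts) noise.

Defaults are desk-scale stand-ins chosen once: autosomes 2L/2R/3L/3R at
45 kb and 4 (the dot chromosome) at 15 kb, symbiont contigs 150 kb with
`shared_fraction = 0.999` in 2 kb blocks, read length 150 bp. Sizes are
multiples of the read length so integer-depth tiling is exactly uniform;
the identity fraction mirrors the real strain pair, and the structure — five
named autosomes beside two near-identical symbiont contigs — is what the
downstream contracts depend on, not absolute scale. One top-level seed
drives everything; each contig, replicate and flag draw uses a substream
derived by hashing its label, so adding a contig never perturbs another's
sequence.

What the generator does **not** emulate — mismatches and sequencing error,
alignment ambiguity beyond the MAPQ/flag plumbing, GC and library-prep
coverage bias, insert-size structure — bounds what green tests mean: they
validate the estimators' arithmetic and contracts, not robustness to real
library artifacts.

# Numerical and interface conventions

* Coordinates are 1-based closed in R (the IRanges/GRanges convention);
  BED output is 0-based half-open via `rtracklayer`, SAM I/O is 1-based via
  `Rsamtools`.
* The MAPQ threshold is strict (`> 20`); `mapq_min = 0` keeps everything.
* A contig group with zero mappable positions yields `NA` depth; a zero host
  mean makes the titer an error rather than `Inf`.
* `plan_mixture()` solves
  $V_A = V / \left(\frac{X_A}{X_B}\frac{Y_A}{Y_B}\frac{1}{R} + 1\right)$,
  $V_B = V - V_A$, which satisfies
  $(V_A X_A Y_A)/(V_B X_B Y_B) = R$ identically.
* Test problem sizes: property suites run on 0.5–5 kb genomes against
  brute-force oracles; the large chimera check uses a 345 kb genome and a
  500,000-pair library; stochastic recovery uses 1,000 seeds per
  $\omega$ at sampling depth 1,000.

# Limitations

Titers assume the reference strain genomes match the resident strains —
novel structural variation shifts mappable space. The selection model
assumes constant $\omega$ across the window; the initial expansion phase
seen after mixing violates this, which is why windows are a first-class
argument. The chimera detector's specificity rests entirely on exact
mappability; with real reads, sequencing error can break or create exact
uniqueness near strain-diagnostic sites. And the per-day growth factor and
doubling time are both derived from the same fit here; independently
averaged summaries of each (as sometimes reported) need not satisfy
$g = 2^{1/T_d}$.
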