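---
title: "Methods: seascape genomics for low-dispersal reef builders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seascape genomics for low-dispersal reef builders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

seascapr joins two strands of evidence about connectivity among discrete
coastal populations of a sessile marine invertebrate: genome-wide SNP
differentiation (what gene flow *has* done) and simulated larval transport in
ocean currents (what dispersal *can* do), together with selection scans and a
temperature-driven genotype–environment association (GEA) analysis. This
vignette explains each model, the tunable parameters, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The synthetic study system

Every stage is testable offline because the generator reproduces the
statistical structure of the motivating dataset: a honeycomb-worm RADseq
panel of 9 reef sites with 4–12 individuals each and 482 biallelic SNPs,
strong differentiation (mean pairwise FST ≈ 0.28 ± 0.10) with one strongly
isolated deme, and a pronounced heterozygote deficit (Ho/He ≈ 0.2,
consistent with inbreeding and/or a Wahlund effect in gregarious settlers).

`simulate_genotypes()` uses the Balding–Nichols construction: per locus an
ancestral frequency p ~ Uniform(`ancestral_maf_range`), per deme a frequency
drawn from Beta(p(1−c)/c, (1−p)(1−c)/c), where the drift parameter c is the
locus-class FST: `target_fst` for neutral loci, `target_fst/5` for
"balancing" loci (selection preserving polymorphism shrinks locus-specific
FST, the FDIST intuition), and min(5·`target_fst`, 0.9) for divergent loci.
Genotypes are drawn with within-deme inbreeding F: P(het) = 2pq(1−F).
Defaults are the study conditions: `n_per_site = c(6, 8, 9, 11, 12, 7, 4, 5,
6)`, `n_loci = 482`, `target_fst = 0.28`, `inbreeding_f = 0.8` (so Ho/He ≈
0.2), `frac_balancing = 0.05`, and `isolated_site = 2` with drift multiplier
2, mimicking the isolated North-Atlantic-type deme. `missing_rate = 0.02`
inserts missing calls uniformly — there is no locus×site dropout structure,
which suffices for filter testing but not for studying allele-dropout
artefacts. The generator makes no attempt at coalescent realism (no
migration history, no linkage); passing tests demonstrate estimator and
pipeline correctness under the beta-binomial island world, not robustness to
demographic history.

Temperature series emulate a mid-intertidal logger: 0.5 °C quantisation, a
fixed 6-hour alternation between submerged ("water", high tide) and emersed
("air", low tide) readings, an annual sinusoid, and air noise (default sd
4 °C) much larger than water noise (1 °C). Only the water/air partition
matters downstream, so no tidal model is attempted.

Velocity fields are analytic. The `double_gyre` field uses the standard
time-dependent stream function; `coastal_retention` sums Gaussian eddies
(default radius 25 km) centred on the reef sites, giving closed local
circulation and hence high self-recruitment. Gridded (u, v) are obtained
from the stream function by *central differences on the grid*, so the
discrete central-difference divergence cancels identically (to rounding) at
interior cells — nondivergence holds on the grid by construction rather
than to truncation error.

## Genotype panel, filters and summary statistics

Genotypes are biallelic diploid dosages (0/1/2, NA missing) in a
tibble-first container (`geno_tbl`). Retention filters follow the usual
RADseq protocol, in order: mean depth ≥ 10×; locus present in ≥ 70% of
populations; ≥ 50% of individuals typed within a population for it to count
as covered (again in ≥ 70% of populations); within-population minor allele
frequency > 0.01 in at least one population; one SNP per RADtag. The RADtag
tie-break (unstated in the upstream callers) keeps the SNP with the highest
minor allele frequency, ties broken by lowest position. A zero threshold
disables a rule, which keeps the rules individually testable.

Per site we report n, mean alleles per locus, unbiased expected
heterozygosity He = (2n/(2n−1))(1 − Σp²), observed heterozygosity, θ (the
mean per-locus gene diversity) and π (the *sum* over loci of the per-locus
mean pairwise difference probability, so values scale with panel size).
These definitions are stated because the reference tables were produced by
software whose θ/π estimators are not fully documented; only column means
of the bundled tables are used as worked examples.

The Hardy–Weinberg test is exact: full enumeration of heterozygote counts
conditional on allele counts, two-sided by probability-mass ordering.
Linkage disequilibrium uses a permutation test on the squared genotypic
correlation within a site; p = (1 + #{perm ≥ obs})/(1 + n_perm), so p is
floored at 1/(1 + n_perm). Bonferroni corrections use m = the number of
tests actually performed in the family (e.g. 0.05/9 = 0.0056 for nine
tests); for pairwise FST both the per-site and the all-pairs family sizes
are defensible and the package defaults to the number of pairwise tests.

## Differentiation

FST is Weir–Cockerham θ with multi-locus combination by ratio of sums of
the a, b, c variance components (not the average of per-locus ratios),
which is stable at the small per-site sample sizes here. Negative
multi-locus estimates are reported as computed but clamped to zero for
distance-based uses (neighbour-joining trees, Mantel). Pairwise
significance permutes individuals between the two sites. AMOVA decomposes
sums of squared dosage differences (one allele difference contributes 1/2)
into among- and within-group components with the standard n′ correction;
Φ-significance permutes individuals among groups; missing calls are
excluded pairwise and distances rescaled to the panel size.

Geographic separation uses haversine distances (Earth radius 6371 km), and
"ocean" distance the shortest path over the 8-connected graph of sea cells
(elevation ≤ 0) with haversine edge weights; sampling sites snap to the
nearest sea cell within 2 cells because coastal sites routinely fall on
land cells at coarse raster resolution. Mantel tests are one-tailed for
positive association by default (the isolation-by-distance convention),
with a two-sided option.

## Outlier scans and consensus

The FDIST-style scan simulates a neutral null of (He, FST) pairs using the
same beta island approximation as the generator — not a coalescent island
simulator; the conditional-on-FST logic is what matters at this scale and
the deme count (default 500) is retained as configuration. The drift
parameter is calibrated iteratively (≤ 20 rounds) until the median
simulated FST is within ±0.01 of the target; the pipeline targets the
observed per-locus *median* FST, because calibrating on the (mean-like)
ratio-of-sums estimate leaves the right-skewed per-locus distribution
off-centre and inflates the lower tail. Ancestral heterozygosity above
`max_he` (default 0.5) is rejected, and the ancestral He of each draw is
stored so the rule is auditable. Empirical p-values condition on He bins
(width 0.05, widened by 50% steps until ≥ 200 draws fall inside). Both
tails are tested at α = 0.05 each — balancing outliers are first-class
here — so the combined type-I rate is ≈ 2α by design.

The F-model scan follows the BayeScan decomposition
logit(FST_lj) = α_l·I_l + β_j with a beta-binomial likelihood (deme
frequencies integrated out) and a spike-and-slab prior on the locus effect:
prior odds 1:10 against inclusion, slab N(0, 3²). Sampling is
Metropolis-within-Gibbs; trans-model moves propose α from the slab so the
acceptance ratio reduces to a likelihood ratio times the prior odds.
Defaults are 50 000 iterations, 10 000 burn-in, thinning 10 — a desk-scaled
analogue of the full-size million-iteration runs, which remain available
through the same arguments. A split-trace diagnostic on the post-burn-in
log-likelihood flags non-convergence. The decision rule defaults to
posterior probability ≥ 0.95 at prior odds 10; 0.99 is available where the
stricter convention is wanted. Consensus outliers are the conservative
intersection of the two scans, and downstream population-structure analyses
run on the neutral (non-consensus) panel, as the motivating study
prescribed.

## Clustering and DAPC

`admixture_gibbs()` implements the classic admixture model with
*independent* Dirichlet cluster frequencies (λ = 1, α = 1 fixed) rather
than correlated frequencies — a deliberate simplification that costs some
sensitivity to subtle structure but removes a layer of tuning; the planted
two-cluster recovery tests quantify what it achieves. The model-selection
summary fed to the Evanno ΔK statistic is the post-burn-in mean of the data
log-likelihood under the sampled (P, Q); which likelihood summary the
classic "estimated Ln P(D)" corresponds to is ambiguous, and this choice is
flagged rather than resolved. ΔK = mean|L(K+1) − 2L(K) + L(K−1)| / sd(L(K))
is undefined at the range ends and wherever the replicate sd is zero. Label
switching across replicates is resolved post hoc by greedy permutation
matching (`align_clusters()`).

DAPC centres dosages (missing → locus mean), retains `n_pc` principal
components (default 30, matching the motivating analysis) and fits linear
discriminant axes (default 2); `n_df` is clipped to groups − 1 with a
warning. Assignment quality is leave-one-out cross-validated.

## Larval dispersal

Particles step hourly: 4th-order Runge–Kutta advection on the bilinearly
interpolated field, then a Gaussian diffusive kick per horizontal axis with
σ = sqrt(2·Kh·Δt) (Kh = 15 m² s⁻¹; the kick distribution is unstated
upstream, and a Gaussian is the natural choice for a diffusion-matched
random walk; Kv = 0.05 m² s⁻¹ is held in the configuration for a future 3-D
core and unused in 2-D). Metre→degree conversion uses cos(latitude) for
longitude. A step ending on land has its kick redrawn up to 5 times, then
the particle holds position for that hour — avoiding artificial beaching
mortality that the source protocols do not describe. Leaving the grid is a
terminal "exited" fate.

Release scenarios: conservative = 6-hourly releases over one week (28
events/site, anchored on a plain calendar date — no tidal model behind
"centred on the spring tide"); optimistic = daily releases over the year.
The historical "100 propagules" is read as 100 per release event and is
configurable, since per-event vs per-site-year is ambiguous. Larvae are
competent from 4 weeks and settle at the first hourly position within 5 km
of any reef site (nearest site wins; settlement absorbs immediately);
maximum PLD is 12 weeks with checkpoints at 5/8/10/12 weeks. Connectivity
counts are cumulative per checkpoint; dispersal resistance is R_ij = 1 −
proportion(i→j), symmetrised by the mean of the two directions for use with
symmetric-matrix methods. Tides, behaviour, mortality and multigenerational
stepping stones are out of scope, as in the motivating single-generation
analysis.

## Thermal metrics and GEA

Sixteen per-site descriptors: over all readings the mean, max, min, range,
sd, 95th−5th percentile, average daily range and average daily sd (daily
metrics per calendar day, days with < 50% of expected readings excluded);
then mean/max/min/range separately for water and air readings.

The GEA scan controls for neutral structure through a population covariance
Ω estimated from neutral loci: site frequencies standardised linearly by
the pooled-frequency proxy, y_j = (p_j − p̄)/sqrt(p̄(1−p̄)), Ω = the average
outer product across loci plus a ridge of 10⁻⁶·trace. Centring on the
cross-site mean fixes off-diagonal correlations of exchangeable demes at
−1/(J−1) — the common component is unidentifiable after the projection —
which is harmless for the scan because the tested coordinates are centred
identically. Per locus and variable, standardised frequencies are modelled
as N(βx, Ω) and the Bayes factor integrates β over a symmetric grid prior
(N(0, 1) discretised at 201 points over ±5 prior sd) against β = 0 — a
deterministic replacement for MCMC-based marginal likelihoods that is exact
to the grid (the likelihood is Gaussian in β, so the quadratic form is
evaluated in closed form; a 4001-point grid agrees to well under 1%).
BF > 3 flags a locus. Only sites with temperature data enter the scan, via
the covariance model's site set.

## Orchestration, seeding and problem sizes

`run_pipeline()` executes filter → summary statistics/AMOVA → dual outlier
scan → neutral/outlier split → clustering/DAPC/FST/distances → dispersal →
FST-vs-resistance Mantel tests → thermal GEA, writing each artefact as TSV
and a manifest. Per-stage seeds derive from the global seed by hashing the
stage name (`stage_seed()`), so toggling one stage never shifts another's
randomness, and a repeated run with the same seed is byte-identical.

The test-suite and acceptance problem sizes are the package's chosen desk
scale: calibration panels of 9 × 50 × 500 (estimator recovery), 9 × 50 ×
400–500 with 20 000 null draws (FDIST rates), 150-locus panels with
3000–4000 MCMC iterations (F-model rates), 5 replicates × K ∈ 1..5 at 400
iterations (Evanno recovery), 10 000 particles × 24 h (diffusion law), and
a full pipeline at the study's default panel with reduced permutation and
chain lengths. Full-size settings (16 000 AMOVA permutations, 100 000 null
draws, million-iteration chains, 100 propagules per event) are plain
configuration values.

## Known limitations

The generator's island world has no linkage, no coalescent history and no
spatially structured missingness; FDIST approximates a finite-island
coalescent null by its beta conditional; the clustering prior is
independent-frequency; the dispersal core is 2-D and tide-free; and the
bundled reference tables are worked-example anchors, not fitting targets —
quantities that depend on the deposited sequencing data or operational
ocean-model fields (the real panel's AMOVA split, its 27-locus consensus
set, K = 2 on the real individuals, observed Mantel r, real connectivity
percentages) are emulated qualitatively, not numerically.
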