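---
title: "Detecting and dating a selective sweep at a pigmentation locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating a selective sweep at a pigmentation locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepsel)
```

## The scientific problem

The SLC45A2 gene encodes a melanosomal transporter; its missense variant
L374F (rs16891982) is one of the strongest contributors to light skin
pigmentation in Europeans.  The derived 374F allele is nearly fixed in
Europe, essentially absent in Africa and East Asia, and its frequency
tracks latitude.  Three questions motivate the analyses in this package:

1. **Is the locus under recent positive selection?**  Addressed with
   site-frequency-spectrum (SFS) neutrality statistics whose p-values
   come from coalescent simulation under a realistic Out-of-Africa
   demography, with an extended-haplotype-homozygosity (EHH) scan and a
   haplogroup-specific Tajima's D as haplotype-level corroboration.
2. **How strong and how old is the sweep?**  Addressed by maximum
   likelihood on the lengths of the unbroken ancestral haplotype around
   the selected site.
3. **Does the selected allele matter medically and geographically?**
   Addressed with case-control association statistics (melanoma),
   phenotype association (skin reflectance, hair/eye colour) and an
   allele-frequency-versus-UV-irradiation cline.

Because the underlying study data are individual-level human genotypes,
the package ships a first-class synthetic-data layer: a coalescent
simulator for sequence-level data and a cohort generator for
phenotype-level data.  Every statistical guarantee the package makes is
tested against data from these generators.

## Haplotype data model

All sequence-level functions work on a `hap_matrix`: an
`n_hap x n_site` matrix of 0/1 alleles over strictly increasing
physical positions, with 0-based half-open coordinates internally (VCF
positions are converted at the boundary).  Sites are biallelic SNVs
only.  Ancestral/derived orientation comes from `polarize()` against an
outgroup (chimpanzee in the motivating application): the allele
matching the outgroup becomes 0, and sites where the outgroup carries a
third state are flagged and excluded from polarization-dependent
statistics rather than guessed.  FASTA alignments, phased VCF and
ms-style text blocks are supported for interchange.

## SFS statistics

`diversity_summary()` computes S, nucleotide diversity
(pairwise-complete at columns with missing data), haplotype diversity
and the unfolded SFS; from it derive Tajima's D, the outgroup
(singleton-based) Fu & Li's D, Fay & Wu's H (raw and normalised),
Zeng's E and the Ewens-Watterson homozygosity F.  The normalised H and
E use the Zeng et al. (2006) variances with theta estimated by
Watterson's estimator and theta-squared by S(S-1)/(a1^2+a2).  Both
variance formulas were verified against Monte-Carlo oracles evaluated
at the true theta (agreement within 1-3% at 4000 replicates).

A consequence worth knowing: with estimated normalisation the realised
variance of the normalised H at n = 20, theta = 10 is about 0.76, not
1 — the same finite-sample underdispersion Tajima's D shows (variance
about 0.80 there).  The statistic is still correctly centred and its
Monte-Carlo p-values are exactly calibrated, because significance never
relies on the asymptotic scale.

## The coalescent null

No pre-packaged coalescent simulator with recombination and demography
is available to this package in R, and the simulation model is part of
the package's contract, so `simulate_neutral()` implements a
Hudson-style ancestral-recombination-graph simulator (in C++) with:

* multiple populations, relative sizes in units of a reference diploid
  size N0, exponential growth, a migration matrix in 4\*N0\*m units, and
  timed events (population merges, size changes, growth changes,
  migration changes) — the classic ms parameterisation;
* a piecewise-constant recombination map: a basal scaled rate rho for
  the region plus hotspot intervals with intensity multipliers;
* infinite-sites mutations dropped on the marginal trees at scaled rate
  theta.

`ooa_model()` encodes the three-population Out-of-Africa demography
used for the European null distributions, with the exact printed
parameter values (sizes 1.68202/3.73683/7.29205, growths
116.010723/160.246047, the migration matrix, the merge events at
0.028985 and 0.197963, and the ancestral size change at 0.303501);
`slc45a2_flank_map()` provides the two flanking-region hotspot maps.
The two flanking regions carry different hotspot coordinates and are
treated as two independent fixtures, not reconciled.

The simulator is verified against closed-form expectations rather than
another implementation: Watterson's E[S] = theta \* a1(n), the
migration-rate-invariant mean pairwise coalescence time of the
symmetric two-deme island model, hotspot breakpoint enrichment
proportional to the multiplier, and an independent tree-based
simulation route for the mean of Tajima's D.

Per-replicate theta and rho are redrawn from a normal distribution with
standard deviation equal to the mean (`sample_scaled_params()`),
redrawn until positive; the positivity truncation is the package's
choice where the procedure leaves it unstated, and raises the mean of
the draws by the truncated-normal factor 1.288.

`simulate_sweep()` is the selected-locus counterpart: a structured
coalescent in a single constant-size population conditioned on a
deterministic logistic trajectory of the derived allele from 1/(2N) to
its present frequency.  Lineages are labelled by genetic background;
coalescence within a background uses the background's time-varying
size, and recombination re-draws the background of the part not
carrying the core with the current allele frequency.  The sweep phase
uses thinned small time steps (event probability at most 0.1 per step),
which is an approximation accurate at the per-generation scale of the
rates involved.  The sampled number of carriers is binomial with
rejection until within a tolerance (default 2%) of the requested
frequency.  The sweep back-end supports single-population constant-size
models only; that is the regime in which it is used for power and
recovery studies.

## Monte-Carlo p-values and the compound DHEW test

`empirical_pvalue()` is the plus-one-corrected tail proportion, so
p is never 0 and rejection at 5% has exact 5% size for continuous
statistics.  `null_distribution()` bundles the per-replicate D,
normalised H, E, F and S under a chosen demography, optionally
conditioned on the observed S by rejection.

The compound DH/DHEW tests require joint extremeness of Tajima's D
(low), normalised H (low) and, for DHEW, the Ewens-Watterson
homozygosity (high).  The raw joint tail probability — the proportion
of null replicates at least as extreme in every component — is reported
(`p_DH_joint`, `p_DHEW_joint`) but is **not** uniform under the null:
for dependent components its 5% rejection rate measured 27% here.  The
test therefore rejects by the compound-rejection construction: reduce
every replicate to the maximum of its component-wise marginal empirical
p-values and report the empirical tail probability of that maximum
(`p_DH`, `p_DHEW`).  This is a probability-integral transform, so the
calibrated p is uniform under the null (measured 3-5% rejection at
nominal 5%), and it rejects exactly when all components are
simultaneously extreme at a common marginal level — the construction
the DHEW test is built on.

## EHH scan and the simulation envelope

`ehh_at()` computes, among carriers of the core allele, the probability
that two random carriers are identical over the span from core to
target — the combinatorial sum of C(c_h, 2)/C(c, 2) over extended
haplotype classes.  Curves are non-increasing outward by partition
refinement.

`build_envelope()` reproduces the published null-envelope procedure:
simulated replicates are kept only if their SNP count is within a
relative tolerance of the observed count (default 10%; "similar" is
unquantified in the source procedure, so the tolerance is configurable)
and they contain a site whose derived count *exactly* matches the
observed carrier count (that site, nearest the core position, becomes
the simulated core).  At each listed scaled distance (defaults 0.1-0.5,
with 1.0 equal to the region length), the replicates attaining the 95th
percentile of EHH (type-1 quantile; ties all selected) are pooled; the
pooled curve points are deduplicated by distance (keeping the larger
EHH) and forced non-increasing outward.  `ehh_significance()` flags
distances where the observed curve strictly exceeds the
piecewise-linearly interpolated envelope.

These filters are severe: under neutrality a site at the carrier
frequency of a swept allele is rare, so acceptance rates are well below
1% — matching the published experience of needing tens of thousands of
runs to accept a few hundred.  The test suite therefore uses 40
haplotypes, a 100 kb region, theta/rho sampler means 10/40, a
6000-replicate pool shared across 50 sweep datasets, SNP tolerance 0.2
and a minimum of 25 accepted replicates; an envelope that cannot be
built counts as a miss in the power check, not in its favour.

Mutation rates for matching theta to data come from outgroup divergence
via `jc69_rate()` (Jukes-Cantor correction, divergence time split over
both branches).

## Haplogroup-specific Tajima's D

`partition_by_core()` splits haplotypes by their allele at the core SNP
and removes the core column.  `matched_tajima_pvalue()` obtains
p-values from simulations with a core designated at the **last**
segregating site (honouring the published procedure literally),
accepted when the simulated core frequency is within ±10% (absolute) of
the observed one, and retained per haplogroup when the group's S is
within ±20% (relative) of the observed group's.  The derived haplogroup
is tested lower-tail (the sweep direction), the ancestral upper-tail;
two-sided doubling is available by configuration.  Type-I calibration
of the full matched procedure was verified on neutral data (200
observations, shared simulation pool, rejection within 3 percentage
points of nominal 5%).

## Sweep strength and age

The inference chain is: carrier consensus (`columnwise majority, ties
to the derived allele`) → per-carrier ancestral-segment endpoints by an
absorbing two-state HMM (`hmm_segment_endpoints()`) → composite
likelihood over endpoints (`fit_sweep()`).

The HMM scans outward from the core: state A (on the sweeping
background) emits a match to the consensus with probability 1 - eps
(default eps = 0.01, absorbing genotyping error and recurrent
mutation); state B (recombined) emits the consensus allele with its
population frequency and is absorbing; the per-interval switch
probability is 1 - exp(-rho_interval \* tau), with tau a switch scale
of the order of the sweep duration.  Because state B is absorbing, the
Viterbi path reduces to exhaustive enumeration over the m + 1 switch
hypotheses; the endpoint is the switch interval's midpoint, or censored
at the window edge.  tau is set by a two-pass scheme: a pilot fit with
tau = 1000 generations, then a refit with tau equal to the fitted sweep
duration.

The likelihood is a star-genealogy approximation: during a sweep of
duration T(s) = ln(p(1-x0)/((1-p)x0))/s generations (logistic
trajectory from x0 = 1/(2N)), off-background recombinations accrue at
intensity lambda(s) = ln(p/x0)/s per Morgan — the closed form of the
integral of (1 - x(t)).  Each uncensored side contributes
log lambda - lambda m at map distance m; censored sides contribute
survival terms -lambda m_edge rather than being discarded.  The
estimate is the argmax over a log-spaced grid (default 200 points,
1e-3 to 1e-1); the 95% CI is the profile set within 1.92 log-units; age
in years is T(s_hat) times the generation time (default 29 years).
lambda(s) is strictly decreasing in s, so longer ancestral segments map
to stronger selection.  Parameter recovery at s = 0.02, N = 10^4, 200
chromosomes gives median relative error under 5% and CI coverage around
92%; estimates order correctly across s in {0.005, 0.02, 0.05} on full
simulated sweeps.  End to end (HMM endpoints rather than model-drawn
endpoints) the estimator keeps the correct ordering but acquires a
downward bias of roughly a third to a half at weak selection: post-sweep
mutations and mid-frequency background sites make the HMM call some
switches early, shortening segments and hence deflating s-hat.  The
profile CI does not account for that endpoint-detection error, so
end-to-end intervals are optimistic.

Model limitations worth stating: the star approximation ignores the
shared genealogy of carriers (composite likelihood; CIs are
approximate), the logistic trajectory is deterministic, and N enters
both the map scaling and x0.

## Synthetic cohorts

`cohort_model()` fixes the generative model: Hardy-Weinberg genotypes
at the derived-allele frequency (default 0.88, the resequencing-panel
value); Gaussian reflectance with genotype means FF 73, FL 69, LL 66
and SD 3 instrument units at 685 nm — calibration constants chosen so a
500-individual cohort's 34 + 34 reflectance extremes are at least as
differentiated as the published extreme groups (dark-group derived
frequency below 0.794, light-group above 0.971), not estimates of real
effect sizes; hair/eye colour category probabilities with darker
categories more likely for L carriers; melanoma risk as a
multiplicative per-allele odds model (default allelic OR 4, the order
implied by the published case/control genotype counts) — under which
the plug-in allele-count OR is exactly the model OR in expectation; and
a UV-band frequency line with binomial sampling noise.  The UV defaults
(intercept 1.85, slope -4e-5 per J/m^2, 50 chromosomes per band) are
chosen so the cline is detectable (|r| > 0.95) in at least 90% of
seeds at that per-band sample size; the implied cline is steeper than
the real Iberian one, which was measured on larger per-band samples.

What passing tests on these generators show — and what they do not:
they validate the statistical machinery (calibration, power, parameter
recovery) under the stated models; they do not validate the biological
parameter values, and real data bring ascertainment, phasing error and
population structure that the generators deliberately omit.

## Association statistics

Fisher's exact test uses the sum-of-less-likely-tables two-sided rule.
The Cochran-Armitage trend test offers the asymptotic score test and an
exact conditional test by complete enumeration of tables with the
observed margins (up to 10^4 candidate tables; beyond that a seeded
Monte-Carlo permutation), two-sided by |deviation from the conditional
mean|.  The Hardy-Weinberg exact test exposes both two-sided
conventions in use: "selome" (sum of configurations no more probable
than observed; the default) and "dost" (double one-sided tail) — the
published control-sample value corresponds to dost.  Allelic odds
ratios use the log-Wald CI with Haldane-Anscombe correction on zero
cells.  The two-proportion Z test is pooled-variance.  D' and r^2 come
from phased gamete frequencies.  UV correlation is Pearson's r with the
t-test p, with a band-exclusion argument for the with/without-outlier
comparison.  Bonferroni adjustment across control groups is applied at
the reporting layer, mirroring the published tables.

## Problem sizes used by the test suite

Chosen to keep the full suite within a few minutes on one CPU while
leaving every Monte-Carlo margin interpretable: neutral calibration at
n = 20, theta = 10 with 2000 null and 500 observed replicates; DHEW
power at s = 0.02 with 100 sweep and 100 neutral datasets against a
1000-replicate null; the EHH envelope study as described above; sweep
recovery with 100 endpoint datasets of 200 chromosomes; cohort null
calibration with 500 case-control draws; exact-test oracles by complete
enumeration over all tables with totals up to 12.  The acceptance
script repeats the same computations at the same or slightly reduced
sizes and additionally recomputes the association statistics from the
published summary tables, which are inputs printed in full (genotype
counts 107/12/0 vs 659/276/35; coding-region derived frequencies
0.052/0.022/0.882 of 136 chromosomes; the 0.960 vs 0.949 proportion
comparison).

## Known limitations

* The ARG simulator targets locus-scale regions (up to a few Mb of
  scaled rho ~ 10^3); it is not a chromosome-scale engine.
* The sweep simulator conditions on a deterministic trajectory and a
  single population; no background selection, no standing variation.
* The sweep-age likelihood is composite (star approximation); its CIs
  are approximate and, on real data, sensitive to the assumed N and
  recombination map — consistent with the published point estimates
  from two panels differing by a factor of two.
* The EHH envelope procedure inherits the severe acceptance filters of
  its source; with small simulation budgets the envelope is built from
  few curves and is accordingly conservative-noisy.
* Synthetic cohorts use calibration constants, not estimated effect
  sizes; they are for validating machinery, not for biological
  inference.
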