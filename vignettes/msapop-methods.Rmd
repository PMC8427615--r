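---
title: "Methods: joint AFLP/MSAP population (epi)genetics in msapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint AFLP/MSAP population (epi)genetics in msapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `msapop`, the
assumptions behind them, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. Marker model and MSAP scoring

AFLP and MSAP bands are **dominant** markers: a band is present when at
least one chromosome carries the amplifiable allele, so heterozygotes and
dominant homozygotes are indistinguishable. All analyses start from binary
individuals × loci matrices (0 absent, 1 present, `NA` missing), with every
individual assigned to a site nested in a habitat.

For MSAP, each locus is assayed twice — once with *Hpa*II, once with
*Msp*I. The joint pattern maps to four states:

| (*Hpa*II, *Msp*I) | state | binary view |
|---|---|---|
| (1, 1) | unmethylated | 0 |
| (1, 0) | hemimethylated (external cytosine) | 1 |
| (0, 1) | internal (CG) cytosine methylation | 1 |
| (0, 0) | uninformative: full methylation *or* absent target | missing |

The (0,0) state is ambiguous by design of the assay and is treated as a
missing score in the binary view. It is, however, a legitimately *observed*
concordant pattern, so it stays in the denominator when a locus's
*Hpa*II/*Msp*I discordance is computed — only cells with a missing input
score in either digest are excluded.

**MSL/NML classification.** A locus is *methylation-susceptible* (MSL) when
its discordance — the fraction of informative individuals with states (1,0)
or (0,1) — *strictly exceeds* a threshold ε equal to the expected
per-individual probability of an enzyme mismatch due to scoring error.
`estimate_error_rate()` estimates this probability as the pooled discordance
between replicate runs of the same individuals. When no replicates are
available the default is ε = 0.05, announced loudly. The strict inequality
follows the "exceeds the threshold" convention; a locus with discordance
exactly ε is NML.

Why 0.05 and not the measured error rate itself? A threshold set *at* the
expected error-mismatch rate misclassifies roughly half of the truly
nonmethylated loci, because their sampled discordance straddles its own
mean. With realistic duplicate discordance of 1–2%, a 5% threshold keeps
essentially all error-driven discordance below the cut while any genuinely
methylated locus with more than ~5% methylated carriers clears it.

**Band filters** follow standard MSAP practice: loci outside the 150–500 bp
scorable window are dropped (skipped with a warning when fragment sizes are
unknown), loci carried by fewer than 4 individuals are dropped, and
singleton loci (exactly one individual deviating from the consensus) are
dropped. The first rule triggered is logged per locus.

Downstream, MSL loci are analysed as the binary methylated/unmethylated
indicator (raw *Hpa*II banding available via `split_msap(msl_source =
"hpa")` since the original choice is not observable from the outside), and
NML loci as ordinary dominant bands from the *Msp*I profile.

## 2. Dominant-marker diversity

Under Hardy–Weinberg equilibrium the band-absent phenotype fraction x̄₀
estimates q², so the default estimator is q̂ = √x̄₀ (the classical POPGENE
assumption). `lynch_milligan` applies the Taylor bias correction
q̂ = √x̄₀ / (1 + Var(x̄₀)/(8x̄₀²)), only where x̄₀ > 3/n; `bayes_uniform`
uses q̂ = √((k₀+1)/(n+2)), the posterior mean of q² under a uniform prior.
Per locus: H_E = 2p̂q̂, N_E = 1/(p̂²+q̂²), N_A = number of observed band
states; Shannon's I = −(f ln f + (1−f) ln(1−f)) is computed on the
band-state frequency f with natural logs (the convention of the MSAP
literature, which compares MSL and NML on the same index). Population
values are across-locus means, by default over *sites* (the sampling
populations); a `grouping` argument switches to habitats. P is the
percentage of loci with both band states observed, P5 the percentage with
estimated minor allele frequency ≥ 0.05. G_ST = (H_T − H_S)/H_T uses locus
sums, and Nm = 0.5(1 − G_ST)/G_ST.

Two estimator facts worth knowing, both verified by the test suite:

* **He is not symmetric under band relabeling.** The estimator is anchored
  to the band-absent homozygote class; relabeling presence/absence changes
  which homozygote is observable. Only the phenotype-based Shannon index is
  relabel-invariant.
* **G_ST estimates θ(K−1)/K, not θ.** With the unweighted pooled H_T over K
  sampled demes, the expected G_ST under an island model with dispersion θ
  carries the classical (K−1)/K factor (θ/2 for two demes), plus an upward
  finite-sample term from the variance of p̂ that vanishes with dozens of
  individuals per deme.

Nei's identity I = J_xy/√(J_xJ_y) and distance D = −ln I are computed from
the estimated allele frequencies with pairwise deletion of loci missing in
either population; a degenerate identity (I ≤ 0, possible only with
opposite fixation) yields an infinite distance sentinel.

## 3. AMOVA

The distance input is the squared Euclidean distance between band profiles,
rescaled for missingness: d²ᵢⱼ = (L/Lᵢⱼ) Σ (xᵢ−xⱼ)² over the Lᵢⱼ mutually
observed of L loci. A pair with no mutually observed loci is an error.

One-level AMOVA partitions SS_total = (1/N)Σᵢ<ⱼ d²ᵢⱼ into among- and
within-group parts with the standard unequal-size coefficient
n₀ = (N − Σn_k²/N)/(K−1); Φ_PT = σ²_A/(σ²_A+σ²_W). The two-level nested
design uses the three unequal-size coefficients of the classical
molecular-variance framework and reports Φ_CT (among groups), Φ_SC (among
subgroups within groups) and Φ_ST (both levels jointly). For balanced
designs the variance components agree with a direct per-locus nested ANOVA
to 10⁻¹⁰ (tested).

Permutation tests use the add-one convention p = (#{Φ* ≥ Φ} + 1)/(B + 1):
Φ_PT/Φ_ST permute individuals among all units, Φ_SC permutes individuals
among subgroups within their group, and Φ_CT permutes whole subgroups among
groups (recomputing coefficients each time, since subgroup sizes travel
with the subgroup). Negative variance components are retained in the Φ
computation, but the %-variation column truncates them at zero and
renormalises; the raw components stay in the table. When all components
vanish (identical individuals) Φ is reported as 0 with a `degenerate` flag.

`locus_by_locus_amova()` runs the one-level analysis per locus (d² is the
mismatch indicator) fully vectorised across loci, permuting individuals
jointly; monomorphic loci are excluded with a flag. On binary single-locus
data the permutation distribution is discrete; at the study size (4 × 20
individuals, 999 permutations) the null rejection rate is within the
binomial band of nominal at both α = 0.05 and α = 0.01 (tested), while very
small samples and few permutations make it conservative.

**Dominance amplification.** Φ statistics computed on dominant band
phenotypes are intraclass correlations *of the band indicator*, not of the
underlying allele frequencies. Under a nested Balding–Nichols model with
HWE dominance (presence probability 1 − (1−p)²), the phenotype-level Φ_CT
exceeds the allele-level θ by a factor ≈ 4q̄/(1+q̄) (about 1.3 averaged
over a uniform ancestral-frequency mixture). The test suite verifies the
generator + AMOVA chain against a Monte-Carlo evaluation of the
model-implied phenotype-level components, and separately verifies that
AMOVA recovers θ within ±0.03 when the binary scores themselves follow the
Balding–Nichols model. Practitioners comparing Φ from AFLP bands with
sequence-based F_ST should expect this inflation.

## 4. Matrix association tests

`mantel()` correlates the n(n−1)/2 off-diagonal entries of two matrices and
builds the null by jointly permuting rows and columns of the second matrix;
for n ≤ 7 all n! permutations can be enumerated exactly. The default tail
is `upper` (positive association), and the signed r is always reported —
with distance matrices on both sides, the sign convention of published
partial-Mantel tables is ambiguous, so no sign "fixing" is attempted.

`partial_mantel()` residualises the off-diagonals of A and B on C by linear
regression and correlates the residuals (the partial correlation r_AB·C).
The null permutes the *residualised A matrix* (residual-permutation
scheme), chosen for its type-I control under confounding; the permutation
scheme of legacy matrix-correlation software is not documented, so exact
reproduction of published partial-Mantel r values is not claimed. A
constant conditioning matrix falls back to the simple test with a warning;
all-identical inputs yield a flagged degenerate result. Soil-difference
matrices assign each individual its site mean and take absolute
differences, so they are constant within sites.

`chi2_2x2()` defaults to the Pearson statistic without continuity
correction because the published 2×2 association statistics reproduce
exactly under it (verified to 3 decimals in the acceptance suite); the
likelihood-ratio G variant is available. `offdiag_correlation()` is the
plain Pearson correlation of two pairwise-statistic matrices with a t-test
p — the descriptive statistic usually quoted alongside Mantel tests.

## 5. Selection scans

**FDIST-style outlier scan.** Per locus, F_ST = (H_T − H_S)/H_T and
heterozygosity H_T come from the dominant-marker estimator. The neutral
null is a Balding–Nichols island-model surrogate: ancestral presence
frequency uniform on (0.01, 0.99), group frequencies Beta(p̄(1−θ)/θ,
(1−p̄)(1−θ)/θ), dominant phenotypes binomially sampled per group, and the
*same estimator chain* applied to the simulated loci. The envelope is the
(0.005, 0.995) conditional quantile band per heterozygosity bin (20
equal-width bins by default; bins with fewer than 200 simulated loci are
merged with a warning). Loci above the upper band are directional
candidates, below the lower band balancing candidates.

Two properties matter in practice:

* **Calibration.** The multilocus F_ST of small-sample dominant data is
  strongly inflated on the estimation scale (12 sites of 6–8 individuals
  can estimate ≈ 0.34 for a true ≈ 0.15). Feeding that raw estimate to the
  null model as θ would double-count the bias, so `fdist_scan()` calibrates
  θ by trial simulation until the neutral simulations reproduce the
  observed multilocus F_ST on the estimation scale, with one
  outlier-trimming pass — the same practice as the original FDIST tools.
* **Power.** With K groups a single-locus F_ST estimate has ~K−1 degrees of
  freedom of between-group information, so the 0.995 null quantile sits at
  ≈ θ·qχ²(0.995, K−1)/(K−1) — about 4.3θ for K = 4 habitats. Planted loci
  at 5× the background θ therefore exceed the envelope only ~25–35% of the
  time under the 4-habitat study design; detecting most of them at this
  quantile would require on the order of 30 groups. This is a property of
  the method at this design, not of the implementation: the envelope's
  false-positive rate is on target (~1%, tested), and planted outliers are
  flagged at many times the neutral rate.

**Environmental logistic scan.** For every polymorphic locus × soil
variable, band presence is regressed on the variable (individuals inherit
their site means, as the original landscape-genomics tools do with sampled
individuals). Significance requires *both* the likelihood-ratio G and the
Wald statistic to pass the Bonferroni-corrected threshold α/(n_loci ×
n_variables); perfect separation suppresses the Wald test and flags the
record. The published study quotes a corrected threshold that does not
equal α divided by its printed locus × variable count, so the exact test
count used there is unknowable; the threshold is therefore configurable via
`threshold =` and defaults to the literal Bonferroni formula.

## 6. Ordination

`pcoa()` double-centers −½D∘D (Gower) and eigendecomposes; coordinates are
eigenvectors scaled by √λ for eigenvalues above a relative tolerance of
10⁻⁹. Negative eigenvalues are reported, excluded from the
proportion-explained denominator, and not corrected by default; a Lingoes
correction (add −2c to the off-diagonal squared dissimilarities, c = |min
λ|) is available. Note that AMOVA consumes *squared* distances while PCoA
and UPGMA consume distances — take `sqrt()` of `squared_distance_matrix()`
output first.

`distlm_marginal()` uses the trace identity pseudo-F = tr(GH)/[(tr G −
tr GH)/(n−2)] on the Gower-centered G, permuting the units of the distance
matrix (the single-factor default of the original DistLM software); on
Euclidean distances of raw data this equals the univariate regression F
summed over response columns (tested to 10⁻⁸). `distlm_forward()` adds
greedy forward selection by added proportion of total SS, with sequential
pseudo-F tested by permuting the reduced-model-residualised G
(Freedman–Lane style), a collinearity skip at added proportion < 10⁻¹²,
and a stop rule at p ≥ 0.05. `rda_forward()` applies the same machinery to
Euclidean distances of the column-centered (mean-imputed) binary matrix —
equivalent to RDA — with a global 999-permutation Monte-Carlo test and the
double stopping rule (α and the global adjusted R²).

`storey_qvalues()` estimates π₀ on the λ grid 0.05…0.95 with a cubic
polynomial evaluated at λ = 0.95, clamped to (0, 1], then applies the
step-up transformation; with fewer than 20 p-values π₀ is fixed at 1
(Benjamini–Hochberg fallback) with a warning.

`upgma()` is average-linkage agglomeration (ties broken deterministically
by merge order); bootstrap support resamples *loci* with replacement,
rebuilds the distance matrix and tree, and reports the percentage of
replicates containing each bipartition as node labels (Newick export via
`ape`).

## 7. The synthetic-data generator

`simulate_dataset()` emulates the sampling design of a four-habitat,
three-sites-per-habitat field study (default 6/7/7, 7/6/7, 7/6/7, 6/6/8
individuals = 80; 2,478 AFLP and 2,884 MSAP loci; ~2/3 of MSAP loci
methylation-susceptible):

* **Genetic structure.** Ancestral presence frequencies uniform on
  (0.05, 0.95); habitat frequencies Balding–Nichols around them with
  θ_habitat = 0.10; site frequencies Balding–Nichols around their habitat
  with θ_site = 0.05; bands rendered as dominant phenotypes under HWE.
  The θ defaults are moderate differentiation values typical of outcrossing
  grasses sampled at landscape scale.
* **Outliers.** 25 AFLP loci (~1%) drawn with θ = 0.5 at the habitat level.
* **Epiloci.** MSL methylation indicators are a mixture of *obligate*
  (deterministic in an underlying structured genotype), *facilitated*
  (Bernoulli with P(methylated | genotype 1) = 0.8) and *pure* (logistic in
  one standardised soil variable, slope ±2 per SD, baseline uniform on
  0.3–0.7), one third each by default — the field's obligate / facilitated /
  pure trichotomy has no published quantitative model, so the mixture is an
  operational stand-in. Underlying genotypes use ancestral frequencies on
  (0.2, 0.8) so that methylated fractions stay away from 0.
* **Rendering and error.** Methylated cells render as (1,0) or (0,1) with
  equal probability (configurable via `p_internal`), unmethylated as (1,1);
  NML loci are concordant dominant bands. Scoring error flips each cell of
  both enzyme matrices independently with probability 0.01, giving an
  expected enzyme-mismatch rate of 2e(1−e) ≈ 2%, a realistic
  duplicate-discordance figure for curated AFLP scoring.
* **Soil.** Site values are normal draws around habitat means chosen to
  mimic a waterlogged meadow / alkalinised saline patch / meadow steppe /
  sandy habitat contrast (pH 8.2/10.3/8.8/8.3, high EC and ions in the
  saline habitat, high nutrients in the wet meadow), with an 8% coefficient
  of variation between sites.
* **Determinism.** One master seed; each component (soil, AFLP, MSAP,
  error) draws from its own derived sub-stream, so enlarging one block does
  not reshuffle another. Identical seeds give byte-identical datasets.

What the generator does **not** emulate: clonal propagation and spatially
explicit gene flow; linkage between loci; shared drift between the AFLP
block and the MSL underlying genotypes (their realised habitat frequencies
are independent draws, so pairwise-Φ matrices of the two marker sets are
uncorrelated at the population level even though individual-level genetic
and epigenetic distances correlate strongly through the obligate and
facilitated loci); fragment-size-dependent scoring artefacts; and
per-primer error heterogeneity. Passing tests on this generator therefore
demonstrate the correctness and calibration of the statistical machinery,
not that real reed populations behave like the model.

## 8. Problem sizes used by the test and acceptance suites

The automated suites run on one CPU in well under their time budgets using:
2,000-locus datasets for the recovery properties (MSL classification,
two-level θ recovery, planted-outlier power), 20–40 null replicates at
modest sizes for the type-I calibration checks (Mantel n = 20; locus-AMOVA
at the 4 × 20 study size with 999 permutations; FDIST coverage on 20 × 250
fresh neutral loci against a 60,000-simulation envelope; environmental scan
on 20 replicates of 50 loci × 2 variables), and a 600 + 800-locus pure-epilocus
dataset for the directional partial-Mantel contrast. The acceptance script
runs the full 2,478 + 2,884-locus study-condition analysis in ~2 minutes.

## 9. Known limitations

* Φ statistics on dominant phenotypes exceed allele-level θ (section 3);
  G_ST carries the (K−1)/K island-sampling factor (section 2).
* The FDIST-style scan has intrinsically low per-locus power with 4 groups
  (section 5); its value at this design is enrichment, not exhaustive
  recovery.
* He-based quantities depend on the HWE assumption of the dominant-marker
  estimators; partial selfing or clonality biases them.
* The partial-Mantel permutation scheme and the Φ_ST convention for
  two-level designs ("both levels jointly" vs GenAlEx-style labels) vary
  between legacy tools; both conventions are emitted where they differ.
* The MSL binary view discards the hemimethylated / internal-methylation
  distinction; state proportions are available via
  `methylation_state_profile()`.
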