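---
title: "Models and methods behind herdgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind herdgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`herdgen` packages the genomic analyses a conservation/selection program
for a small, fragmented livestock breed runs on 50K-chip genotypes:
quality control, runs-of-homozygosity (ROH) inbreeding, LD-based ancestral
effective population size, pedigree BLUP with deregressed breeding values,
and a stratification-corrected association scan. This vignette explains
each model, the tunable parameters and their defaults, the synthetic
cohorts used for validation, and the numerical and design choices that were
genuinely open.

## Quality control

Filters run in a fixed, logged order, so removal tallies are reproducible
and add up step by step: (1) non-autosomal or unmapped markers (autosome
set 1–29, the cattle karyotype, configurable), (2) samples with call rate
< 0.95, (3) SNPs with call rate < 0.95, (4) SNPs with MAF < 0.01 computed
on non-missing calls, (5) SNPs failing an exact Hardy–Weinberg test at
p ≤ 0.001. The ordering itself is a convention — sample-level filtering
before marker-level filtering, as PLINK does — because tallies depend on
it; the `qc_result` report records it.

The HWE test is the exact conditional test: given the allele counts, the
probability of `h` heterozygotes is proportional to
`2^h / (n_AA! h! n_aa!)`, and the two-sided p-value sums the probabilities
of all heterozygote counts no more probable than the observed one. It is
computed with log-gamma arithmetic, normalised over the support, and the
test suite verifies it against an independent `choose()`-based enumeration
for random tables up to 200 individuals. Monomorphic tables return p = 1
by convention (they carry no evidence either way).

LD pruning is pairwise-r² based: within 50-SNP windows shifted by 5 SNPs
(never spanning a chromosome boundary), while any retained pair has
genotype correlation r² > 0.5, the lower-MAF member of the worst pair is
removed (ties: the later-positioned SNP). Tool implementations of
`indep`-style pruning historically use a variance-inflation-factor
criterion even where an "r² threshold" is quoted; we implement the stated
pairwise-r² contract directly, and a post-hoc test verifies that no
surviving within-window pair exceeds the ceiling.

## Runs of homozygosity and F_ROH

Detection is the sliding-window consensus scheme used by the standard ROH
callers for array data. A window of 15 SNPs slides one SNP at a time; a
window is *homozygous* if it contains at most 1 heterozygous and at most 1
missing call; a SNP is in run state if at least 5% of the windows covering
it are homozygous. Maximal stretches of run-state SNPs become segments
after (i) splitting at inter-SNP gaps > 1 Mb (the gap terminates, never
discards, the run), (ii) requiring ≥ 40 SNPs, (iii) length ≥ 4 Mb, and
(iv) SNP density ≥ 1/100 kb. The window allowances and the 5% consensus
threshold are the documented defaults of the established callers; all are
configurable in `roh_params()`. At 50K density a 4 Mb minimum corresponds
to ~80 markers, so chance runs of the required length are vanishingly rare
— the het/miss allowances trade a little boundary inflation (a few hundred
kb per side, bounded by the window span) for robustness to genotyping
error.

F_ROH divides the summed length of segments at or above a threshold (4 Mb
by default; 8 Mb as the "recent inbreeding only" variant) by the autosome
length. "Autosome length" is ambiguous on array data; the default
denominator is the SNP-covered length (last − first marker + 1 per
chromosome, summed), which is robust to array coverage and matches common
F_ROH practice; assembly lengths can be supplied instead via the `genome`
argument. Coordinates are 1-based inclusive throughout (BIM convention),
so segment length is `end − start + 1`; at ROH scale the difference from
`end − start` is sub-ppm but fixing one convention keeps outputs
byte-deterministic.

Length-class frequencies are *truncated* (not rounded) to one decimal:
the breed-survey tables this mirrors print 217/639 as 33.9%, which only
truncation reproduces; the three class percentages may therefore sum to
slightly under 100.

One caveat surfaced in the field literature: "mean number of ROH" is
sometimes quoted per chromosome and sometimes per individual for the same
value. `roh_summary()` defines MN_ROH strictly per individual
(total segments / cohort size), the reading under which a 639-segment,
42-animal cohort gives 15.2.

## LD decay and ancestral Ne

`pairwise_r2()` computes the squared Pearson correlation of genotype
dosages for within-chromosome pairs over samples non-missing at both
markers; pairs with fewer than two informative samples or zero variance
are skipped and counted. Means are taken in 10 kb half-open distance bins.
The drift expectation at genetic distance `c` Morgans,

E[r²] = 1/(α + 4·Ne·c) + 1/(β·n),

is inverted per bin: the sampling term 1/(β·n) (β = 2 for unphased
dosages) is subtracted, and Ne(t) = (1/r²_adj − α)/(4·f(c)) is dated to
t = 1/(2·f(c)) generations ago. Defaults are the cited estimator's
conventions: mutation adjustment α = 2 (options 1 and 2.2), linear
f(c) = c with a Haldane-inverse option, and a constant 1 cM/Mb map
(10⁻⁸ Morgans/bp) since no breed-specific map is shipped. Bins whose
adjusted r² would give a non-positive 1/r²_adj − α are *dropped with a
warning, never clamped* — clamping would manufacture spurious Ne points —
as are bins with fewer than 50 pairs (configurable), which are noise
dominated at small n. On closed-form input the inversion is exact to
1e-9, which the tests assert per bin.

Two caveats: with ~40–50 samples the sampling correction is a third or
more of the observed r² at long distances, so trajectory points far in the
past are fragile; and the 1 cM/Mb map makes `t` only as good as that
assumption. The validation suite therefore checks *recovery*, not point
identity: a constant-Ne = 100 Wright–Fisher population (20 chromosomes ×
30 Mb, 150 generations, 50 samples — sizes chosen to put the bulk of the
binned distances at quasi-equilibrium) must give a median trajectory Ne
within [50, 200], and it lands near 90–95 in practice.

## Pedigree BLUP, EM-REML, deregression

Inbreeding coefficients come from the Meuwissen–Luo ancestor-tracing
recursion; A⁻¹ is assembled sparsely with Henderson's rules using
inbreeding-adjusted Mendelian-sampling variances
(d_i = 0.5 − 0.25(F_s + F_d); unknown parents count as F = −1, which
reduces to the familiar 0.75 − 0.25·F_known and founder 1 cases). Unknown
parents form a single unrelated base population — no genetic groups, which
shallow herdbook pedigrees cannot support anyway. The test suite checks
A⁻¹ against the dense inverse of an independently implemented tabular-method
A to 1e-10 on pedigrees up to 50 animals.

`solve_mme()` builds Henderson's equations for the three model families
used in routine evaluation: direct effects only; direct + permanent
environment (repeated records such as calving interval); and direct +
maternal + permanent environment for maternally influenced calf traits.
The maternal model optionally fits the direct–maternal covariance as a
2×2 kronecker block `A⁻¹ ⊗ G₀⁻¹σ²_e` — fitted by default when a maternal
term is present, because evaluations of such traits conventionally report
r_AM even where the model is written without the covariance. Reliability
is r² = 1 − PEV/σ²_a from the inverse coefficient matrix diagonal, without
the (1+F) refinement (the simpler convention; switchable in principle by
post-processing PEV). Solutions are verified against a
generalised-least-squares oracle on the full V = ZAZ'σ²_a + ... matrix to
1e-8, including a negative-covariance maternal case.

Variance components for the direct model come from classic EM-REML on the
MME: σ²_a ← (â'A⁻¹â + tr(A⁻¹C^{aa})σ²_e)/q and
σ²_e ← (y'y − b̂'X'y − â'Z'y)/(n − rank X), iterated to a relative change
below 1e-8 (cap 500 iterations, flagged if hit). EM is slow near
convergence but monotone — the REML log-likelihood is asserted
non-decreasing in the tests — and has no step-size tuning, which suits a
validation-oriented reference implementation. Parameter recovery is
checked at n = 400 records on a two-generation, 40-couple pedigree:
ĥ² must fall within ±0.15 of the simulated 0.3 (the sampling SD of ĥ² at
this design is roughly 0.06).

Deregression is the simplified Garrick form without parent-average
removal: DEBV = EBV/r² with association weight
w = (1 − c)/(c + (1 − r²)/r²), where c = 0.10 is the fraction of genetic
variance not captured by markers. Parent-average removal needs parent EBV
reliabilities that shallow pedigrees rarely provide; the simplified form
is the stated contract, and the monotonicity and limit identities
(r² = 1 ⇒ DEBV = EBV, w = 9 at c = 0.1) are tested exactly. Animals below
a reliability floor of 0.05 are excluded with a warning — their quotients
explode.

## Association scan

The scan residualises both the DEBV phenotype and each SNP dosage on an
intercept plus `n_axes` principal-component axes (default 3, the referenced
implementation's default; the axes come from the eigendecomposition of the
sample covariance of 2p̂-centred, √(2p̂(1−p̂))-scaled genotypes, missing
calls mean-imputed for the decomposition only, signs fixed by making the
largest-magnitude loading positive). The statistic is the score form
χ²₁ = (n − n_axes − 1)·r²(residuals), with β the residual slope and
SE = |β|/√χ². With zero axes this is the plain score test, which the tests
verify by reduction.

Genomic control estimates λ as median(χ²)/0.4549 (or a through-origin
quantile regression) and, by default, adjusts p-values as
min(1, p·λ) — the literal published deflation rule. Multiplying p by a
λ > 1 would be anti-conservative, so a conventional χ²/λ divisor mode sits
behind `lambda_mode = "divide"`; both modes are recorded in the result.
Significance tiers are fixed at 5×10⁻⁶ (genome-wide, ~10,000 independent
tests Bonferroni) and 5×10⁻⁵ (suggestive). Per-SNP variance explained
defaults to 2p̂(1−p̂)β²/Var(y) capped at 1, with a statistic-based
alternative χ²/(χ² + n − 2) selectable — the formula in use is visible in
the options so results declare it. Deregression weights are accepted but
unused by the default score test (a weighted mode would change the null
distribution; the published analysis did not state one).

Calibration is tested, not assumed: on a 2,000-SNP null at n = 42 the
type-I error at α = 0.05 must lie in [0.03, 0.07] and λ in [0.85, 1.15];
on a two-subpopulation confounded null, λ without axes must exceed λ with
axes, and the corrected λ must return to the null band.

**Power at realistic cohort size — a deliberate caution.** The acceptance
suite also measures the probability that a planted QTL explaining 30% of
the phenotypic variance at n = 42 clears the suggestive threshold. The
answer, by the package's own 50-replicate simulation, is ~12–16%. This is
arithmetic, not a defect of the implementation: p < 5×10⁻⁵ requires
χ² ≥ 16.4, i.e. a *sample* r² above 0.44 when the true r² is 0.30, an
event two standard errors into the tail of the sampling distribution at 38
residual degrees of freedom. Single-SNP scans at this cohort size can only
surface associations whose sample effect happens to be large; this is
exactly why small-cohort studies report few hits and why those hits'
effect sizes are inflated by selection (winner's curse). The corresponding
recovery test is intentionally left asserting the (unattainable) higher
power so the limitation stays visible rather than silently rationalised.

SNP feature annotation is a strand-aware interval lookup against a GFF3
gene model (via `GenomicRanges`): exon overlap → "exon variant", gene
without exon overlap → "intron variant", within a 5 kb strand-aware
upstream window → "upstream gene variant", else intergenic.

## The synthetic cohorts: what they emulate, and what they do not

The generators exist so that every stage is testable against exact truth.

* `sim_pedigree()` builds discrete generations over founder couples;
  each offspring of the second generation onward arises from a full-sib
  mating with probability `close_kin_prob`. A close-kin probability of
  0.36 gives an expected mean F of 0.25 × 0.36 = 0.09 in the cohort — the
  inbreeding level of a small island-fragmented breed — with the
  right-skewed individual distribution (a third of animals above 0.15)
  such breeds show.
* `gene_drop_genotypes()` drops founder haplotypes through the pedigree
  with Poisson crossovers (Haldane, no interference — interference is
  irrelevant at multi-Mb ROH scale) on a 1 cM/Mb map, SNPs uniform at ~1
  per 50 kb (50K-chip density), founder frequencies Uniform(0.05, 0.5).
  Because founder alleles carry unique labels, autozygous segments are
  known *exactly*, giving truth for ROH sensitivity and F_ROH accuracy.
  The breed-scale validation cohort is 42 genotyped animals on 29 × 90 Mb
  chromosomes.
* `sim_constant_ne_population()` is a discrete-generation Wright–Fisher
  simulation of 2Ne haplotypes per chromosome with recombination, from
  linkage-equilibrium founders. LD accumulates toward the drift
  equilibrium from above generation scales of ~1/(2c), so validation reads
  the trajectory at distances whose time depth the simulated history
  actually covers.
* `sim_phenotypes_and_ebv()` draws breeding values down the pedigree with
  inbreeding-adjusted Mendelian sampling (bivariate direct–maternal when
  m² > 0), optional additive QTL overlaid on gene-dropped genotypes with
  the polygenic share reduced to keep the h² budget, and runs the animal
  model at the true variances to attach EBVs and reliabilities.

What the simulator does **not** emulate — and hence what green tests do
not certify about real data: ascertainment bias of commercial chips (real
founder MAF spectra are U-shaped and breed-dependent; roughly a third of
chip SNPs are monomorphic in an unrepresented local breed), genotyping
error and nonrandom missingness (available only via explicit injection,
off by default), real recombination-map heterogeneity, selection, and
migration/admixture. Real-data headline numbers from any particular breed
(its mean F_ROH, its Ne at 5 generations, its specific GWAS hits) depend
on the actual genotypes and are treated as qualitative context, not as
reproduction targets.

All generators are seed-deterministic; identical configurations reproduce
outputs byte for byte, which the tests assert.

## Numerical and engineering choices

* Genotypes are dosage-coded 0/1/2 with `NA` (never 0) for missing; the
  PLINK 2-bit decoder/encoder is exact and round-trip tested at all four
  byte paddings.
* All solvers are dense base-R linear algebra except A⁻¹ (sparse
  `Matrix`); at herdbook scale (10³–10⁴ animals) the MME remain small.
* Ties in LD pruning resolve lower-MAF-first, then later-position — any
  deterministic rule works, but one must be fixed for reproducibility.
* `detect_roh` warns and skips chromosomes with fewer SNPs than one
  window rather than erroring: sparse chromosomes are a data property,
  not a caller bug.
* The pipeline writes every stage table as TSV (floats at full precision;
  percentages truncated to one decimal where the corresponding table
  convention applies) plus a JSON run report embedding the configuration
  echo, so a run can be replayed exactly; stage failures abort with the
  stage name and leave a `FAILED` marker beside the partial outputs.
* Test and acceptance problem sizes (e.g. 29 × 90 Mb gene drops, 20 × 30
  Mb drift simulations, 400-record REML) were chosen as the smallest
  designs at which the checked property is stable across seeds.

## Known limitations

* No imputation, phasing, sex chromosomes, or assembly lift-over; input
  maps must already be on a single assembly.
* ROH calling is window/consensus-based; an HMM-based autozygosity model
  would date inbreeding more sharply on low-density or error-prone data.
* EM-REML is single-trait, direct-effects only; maternal-model variance
  estimation must come from elsewhere (the solver accepts any
  `variance_components`).
* The Ne trajectory inherits every assumption of the closed-form drift
  expectation (constant map rate, no admixture); recent admixture inflates
  distant-past Ne, and trajectories should be read qualitatively.
* Single-SNP association at n ≈ 40 has the power ceiling quantified
  above; the package reports it rather than papering over it.
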