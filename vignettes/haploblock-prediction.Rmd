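---
title: "Haploblock-based genomic prediction: models, simulator and design choices"
author: "haplopred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploblock-based genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopred)
```

This vignette is the package's account of its science: the models it fits,
the assumptions they make, what the bundled simulator does and does not
emulate, and the numerical and design choices taken where more than one
defensible option existed.

## The problem

Genomic prediction estimates the additive genetic merit (GEBV) of selection
candidates from dense SNP genotypes and the phenotypes of a training
population — in dairy cattle, typically progeny-tested bulls whose
phenotypes are de-regressed proofs (DRP), pseudo-phenotypes derived from
estimated breeding values with a per-bull reliability r². On high-density
panels, individual bi-allelic SNPs may each be in weak LD with a causal
variant even when a short multi-SNP haplotype tags it well, and the sheer
number of markers is computationally burdensome. Grouping SNPs into
LD-defined haplotype blocks addresses both: block variants can be in
stronger LD with QTL than any single SNP, and when local haplotype
diversity is low, a block of k SNPs contributes fewer model columns than
2k.

## Haploblock construction

A haploblock is a maximal run of *contiguous* markers in which Lewontin's
D′ between **every pair** of markers is at least a threshold `d`. D′ is
|D|/Dmax with D the two-locus allele-indicator covariance and Dmax its
frequency-bound; it is 1 exactly when at least one of the four haplotype
classes is absent, and we define it as 0 at exact independence (D = 0) to
avoid 0/0. Frequencies are obtained by direct counting over the 2n phased
haplotypes — the panel is phased by contract, so no EM step is involved.

The all-pairs criterion defines which sets qualify as blocks but not how to
search for them. `build_blocks()` uses a deterministic greedy
left-to-right maximal extension: grow a candidate block marker by marker,
admit the next marker only if its D′ with every current member meets the
threshold, emit the candidate when extension fails (blocks need at least
two SNPs; singletons become "non-blocked" SNPs, a separate variable class).
Contiguity is implied by the goal of grouping physically close markers, and
the greedy scan is order-stable and O(within-block pairs). Tests verify the
implementation against an independently coded brute-force oracle and
re-certify every emitted block pair-by-pair.

Two limit behaviours anchor the threshold scale: at `d = 0` each whole
chromosome is one block; above the panel's largest pairwise D′ every SNP is
non-blocked. The conventional grid `dprime_threshold_grid()` spans 0.25 to
0.75 in steps of 0.10. D′ (rather than r²) is used for blocking because its
inflation at rare alleles yields longer blocks and fewer non-blocked SNPs;
the marker QC step, by contrast, uses r² (see below).

### Encodings

`build_design()` produces three encodings, all with entries 0/1/2:

* `snp` — minor-allele dosage per marker;
* `blocks_plus_nonblocked` — one column per observed block variant (the
  count of that haplotype string among the animal's two phased haplotypes)
  plus dosage columns for non-blocked SNPs;
* `blocks_only` — variant columns alone.

Within each block an animal's variant counts sum to exactly 2 — an
invariant the test suite asserts on fuzzed panels. Three deliberate
choices: no rare-variant collapsing (every observed variant gets a
column); no reference-variant drop for identifiability, because both
models are shrinkage estimators for which the within-block sum-to-2
collinearity is tolerable; and variants are enumerated on the full panel
(training plus candidates) so candidates never present unseen variants. A
genuinely external animal carrying an uncatalogued variant maps to
all-zero columns with a warning.

### When does blocking reduce the variable count?

The number of columns a block contributes is the number of *distinct*
haplotype strings observed in it. Reduction relative to SNP coding
therefore requires local haplotype diversity to be small relative to block
length — the situation on dense chips in livestock populations with small
effective size, where a 5–10-SNP window typically segregates only a
handful of ancestral haplotypes. In the bundled simulator, local diversity
is governed by the adjacent-copy probability: a fresh allele is drawn at
rate (1 − `adjacent_corr`) per locus per haplotype, so distinct variants
per block grow roughly like 1 + 2n(1 − c)·size. With `adjacent_corr`
around 0.98–0.995 and panels of a few hundred haplotypes — the HD-density
analogue — the reduction property holds at every threshold and the
non-blocked count grows with `d`; at moderate density (c ≈ 0.9) blocking
can *increase* the column count, which the README's worked example shows
honestly. Passing the reduction tests therefore demonstrates behaviour in
the dense-panel regime, not a universal property of blocking.

## Prediction models

Both models fit, to the training records,

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{M}\mathbf{g} + \mathbf{Z}\mathbf{a}
 + \boldsymbol\varepsilon,$$

with **y** the DRP, **M** the chosen design matrix, **a** the residual
polygenic effect with prior N(**0**, **A**σ²ₐ) over *all* animals (the
numerator relationship matrix **A** comes from the pedigree by the tabular
method), and heterogeneous residuals
ε ~ N(**0**, **D**σ²ₑ), dᵢᵢ = 1/wᵢ, wᵢ = r²ᵢ/(1 − r²ᵢ). The weight
formula is the standard de-regression variance argument: a DRP with
reliability r² carries an effective error variance proportional to
(1 − r²)/r². Weights are undefined at r² ∈ {0, 1}, which is why the DRP
reader rejects boundary reliabilities.

* **Weighted BLUP**: gⱼ ~ N(0, σ²_g), one common variance.
* **Bayesian mixture**: gⱼ ~ Σₖ πₖ N(0, σ²ₖ), k = 1..4, with fixed
  proportions (default 0.889, 0.1, 0.01, 0.001) and component variances
  constrained σ²₁ ≤ σ²₂ ≤ σ²₃ ≤ σ²₄. Most effects live in the
  smallest-variance component; a few may be large. Variances and effects
  are estimated simultaneously.

### Gibbs sampler

Both models are fitted by a single-chain Gibbs sampler written in
RcppArmadillo:

* μ has a flat prior; scalar normal update.
* Effect columns are updated one at a time in fixed map order (a
  randomized sweep would also be valid; the fixed order is chosen for
  reproducibility — chains are byte-identical given the seed).
* Polygenic effects are updated animal-by-animal from the conditional
  given **A**⁻¹; animals without records (selection candidates) receive no
  data term, so their effects are draws from the conditional prior given
  their relatives. GEBV prediction then needs no separate projection:
  GEBVᵢ = Σⱼ mᵢⱼĝⱼ + âᵢ at posterior means.
* All variance components carry bounded-uniform priors — the prior family
  the mixture model states for its component variances, adopted for the
  BLUP variances too for internal consistency. The bounds are data-scaled
  (lower 10⁻¹⁰ × var(y), upper 10⁴ × var(y)); draws are scaled inverse
  chi-squares truncated by rejection (100 attempts, then clamped to the
  conditional scale).
* The mixture adds a categorical component-indicator update per column and
  per-component variance updates. The ordering constraint is enforced by
  rejecting violating joint draws (up to 100 redraws, else the previous
  values are kept; the rejection count is reported as a diagnostic). A
  component currently holding fewer than three columns has an improper
  conditional, and draws uniformly from the prior interval instead.
* Default schedule: 50,000 cycles, 20,000 burn-in, the conventional
  production setting. The test suite uses scaled-down chains — 10,000/2,000
  for the sampler-vs-MME oracle check, 3,000/1,000 for the
  1,000-training-animal prediction runs, a few hundred cycles for pure
  plumbing tests — sizes chosen so Monte-Carlo error is small relative to
  each test's tolerance.

Sampler correctness is established two ways: at fixed variances the
posterior mean of (μ, **g**, **a**) must equal the direct solution of the
weighted mixed-model equations (checked within 3 batch-means Monte-Carlo
standard errors on a 50-animal, 30-column instance), and the degenerate
mixture with proportions (1, 0, 0, 0) must reproduce the BLUP fit on a
shared-seed instance.

### Starting values

Variances start from a heuristic split of var(y): 40% marker, 10%
polygenic, 50% residual, with the marker share divided by the summed
column variance; mixture component variances start on a 1:10:100:1000
ladder rescaled so the prior-weighted marker variance matches the same
40% share. These affect burn-in only.

## Evaluation

* **Reliability**: cor(DRP, GEBV)²/mean(r²_DRP) over validation animals —
  the squared correlation corrected for the fact that DRP are themselves
  noisy. "Mean reliability of the DRP" is read as the arithmetic mean over
  validation animals. Note the estimator may exceed 1 in finite samples.
* **Bias**: the OLS slope of DRP on GEBV; 1 is unbiased, below 1 indicates
  inflated GEBV spread.
* **Hotelling–Williams test** for H₀: cor(DRP, GEBV₁) = cor(DRP, GEBV₂),
  two correlations sharing the DRP vector:
  $$t = (r_{1y}-r_{2y})\sqrt{\frac{(n-1)(1+r_{12})}
  {2\frac{n-1}{n-3}|R| + \bar r^2(1-r_{12})^3}},\quad df = n-3,$$
  with |R| the determinant of the 3×3 correlation matrix. Both one- and
  two-sided p-values are exposed (the one-sided form addresses
  H₀: cor₁ ≥ cor₂). Identical GEBV vectors give t = 0 and two-sided p = 1
  by definition (the formula is 0/0 there). Monte-Carlo calibration at the
  validation scale (n = 1,400, 2,000 null replicates) keeps the empirical
  type-I error within [0.035, 0.065] at α = 0.05.
* **Top-k overlap**: percentage of the top-k ranked animals shared by two
  GEBV tables, ties broken by animal id for determinism.
* **Scenario driver**: per trait and model, one SNP scenario plus
  (blocks + non-blocked) and blocks-only at each threshold — 13 scenarios
  per trait per model on the standard six-threshold grid — each compared
  with the SNP baseline by the Hotelling–Williams test.

## Marker quality control

Two sequential rules mirror standard HD panel editing: remove markers with
MAF < 0.01 (computed over all haplotypes of all panel animals, before any
training/validation split), then remove markers in "complete LD" with the
nearest retained marker to their left on the same chromosome. Complete LD
is operationalized as r² = 1 within 10⁻¹²  — not D′ = 1 — because r² = 1
means the two markers are informationally redundant, whereas D′ = 1 also
holds when one haplotype class is merely absent. The left member of each
redundant pair is kept (deterministic, order-stable), and the filter is
idempotent.

## The simulator

`simulate_dataset()` chains four stages, all deterministic given the seed:

1. **Founder haplotypes**: along each chromosome, a haplotype copies its
   previous allele with probability `adjacent_corr` and otherwise draws
   fresh at that locus's MAF (uniform on `maf_range`). This first-order
   Markov model was chosen because it gives direct single-parameter
   control of adjacent-pair D′ — the only LD feature the block builder
   consumes — while making blocking non-trivial.
2. **Pedigree**: random sire×dam matings among the previous generation,
   sexes alternating within a generation, generation sizes near the
   founder count. Generation labels drive the training/validation split,
   the analogue of a birth-date cut-off.
3. **Gene dropping**: each non-founder inherits one recombinant gamete per
   parent; crossovers occur independently per marker interval with
   probability `recomb_prob_per_interval`, never across chromosomes.
4. **Phenotypes**: QTL sampled without replacement, effects from a
   four-component normal mixture; TBV = dosage × effects, centred. The
   environmental deviation is orthogonalized against TBV and scaled so the
   realized h² is exact. DRP = TBV + e with var(e) = var(TBV)(1 − r²)/r²
   and r² uniform on `drp_reliability_range` — a stand-in distribution,
   since real DRP reliability distributions are population-specific.

What it does **not** emulate: coalescent genealogy, mutation, selection,
non-additive effects, genotyping error, or the bounded ancestral haplotype
diversity of real low-Ne populations (see the variable-reduction
discussion above). Consequently, passing tests demonstrate correctness of
the machinery and the qualitative behaviour of the methods — e.g. that the
sparse mixture prior outperforms BLUP under a 10-QTL architecture, that
prediction beats a permuted-phenotype null — not the specific
reliabilities reported for any real cattle population.

### Default study conditions in the test suite

The prediction-scale tests simulate 250 founders and five generations
(1,250 animals; the 1,000 animals of generations 0–3 train, generation 4
validates), 3 chromosomes × 200 SNPs with `adjacent_corr` 0.95, 10 QTL
drawn from the largest mixture component only, h² = 0.39, and DRP
reliabilities uniform on (0.80, 0.95) — heritability and reliability
levels typical of a production trait. The Hotelling calibration uses
n = 1,400, matching typical validation-set sizes.

## Degenerate and edge inputs

* Monomorphic loci have undefined D′/r²; `ld_dprime()` and
  `ld_rsquared()` raise an error, `dprime_matrix()` returns NA for such
  markers, and the greedy builder treats NA as a failed extension. MAF
  filtering removes them in any realistic pipeline.
* A design with zero columns (blocks-only on a panel with no blocks) is
  skipped by the scenario driver rather than fitted.
* `additive_relationship()` tolerates one unknown parent (the known
  parent's half-relationship is kept); a singular **A** gets a 10⁻⁸
  diagonal jitter before inversion.
* Frequency-sum and reliability identities are enforced at 10⁻¹²;
  positions are 1-based (VCF convention); block index ranges are stored as
  1-based inclusive `start`/`end` columns, the idiomatic R convention.

## Known limitations

* The polygenic update is single-site and **A** is dense; pedigrees beyond
  a few thousand animals would need blocked updates and sparse **A**⁻¹
  machinery.
* Only bi-allelic, fully phased, non-missing panels are accepted;
  imputation and phasing are upstream concerns.
* The mixture's empty-component variances wander over their uniform prior
  between occupations; their posterior summaries are only meaningful for
  occupied components.
* Reliability as defined can exceed 1; it is reported as computed.
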