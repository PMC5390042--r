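---
title: "Methods: categorical correlation screening of bioactivity against LC-MS profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorical correlation screening of bioactivity against LC-MS profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

A panel of plant species is screened three ways: an agar-diffusion assay
against *B. subtilis* (inhibition-zone radius, cm), and MTT viability assays
of extracts on two mammalian cell lines (HaCaT keratinocytes, IEC-6
intestinal epithelial cells) against a solvent control.  Each assay is
reduced to a binary classification per species.  Independently, an LC-MS
feature table records intensities of thousands of peaks — each uniquely
identified by an (m/z, retention time) pair — per species, and is reduced to
presence/absence at a detection threshold.  Treating a feature's
presence profile and a bioactivity classification as two binary raters,
Cohen's kappa measures their chance-corrected agreement; screening all
features against all three classifications, combining the three
coefficients, and extending the screen to Boolean pair combinations yields
candidate compounds that are antimicrobially active but non-cytotoxic, plus
evidence for synergistic and functionally redundant compound pairs.
Finally, the Fritz–Purvis D statistic asks whether each bioactivity is
phylogenetically clumped on the species tree.

## Binary classifications ("raters")

* **Antimicrobial (AM)**: active ⟺ mean replicate inhibition radius ≥ 0.6 cm.
  The tie at exactly 0.6 cm resolves to *active* (the threshold is
  inclusive).  Raising the threshold can only shrink the active set
  (monotonicity, asserted in the tests).
* **Cytotoxicity (HaCaT, IEC-6)**: viability is
  $100 \cdot \bar A_\text{treated} / \bar A_\text{control}$ (percent).  Per
  species and cell line, treated absorbances are compared with the solvent
  control by a two-group one-way ANOVA (identical to the two-sided
  pooled-variance t-test, $F = t^2$; asserted numerically in the tests);
  p-values are corrected across the species of one cell line by
  Benjamini–Hochberg at FDR $\alpha = 0.05$.  A species is *cytotoxic* when
  the corrected test is significant **and** mean viability is below 100% —
  a significant increase indicates induced hyper-proliferation and is
  deliberately not labelled cytotoxic.

The grouping of the cytotoxicity ANOVA was genuinely open: a single pooled
model with post-hoc contrasts would also produce per-species calls.  We use
independent per-species two-group comparisons against the (shared) solvent
control because the analysis output is a per-species significance call and
the per-species test makes the BH family explicit (all species of one cell
line).  Species where treated and control replicates both have zero
variance have an undefined p; they are flagged (`p_value = NA`) and treated
as not significant.

Note that BH controls the false discovery *rate*, not the family-wise
error: even with very large effect sizes, a run over ~90 species has an
appreciable chance of one null species slipping into the rejection set.
The test suite therefore asserts full recovery of planted cytotoxic species
together with a bounded false-discovery proportion, not exact recovery of
the planted set in every run.

## The feature table

Features are binarized at intensity ≥ $10^4$ (inclusive).  Peaks present in
*all* species are discarded before screening (`filter_ubiquitous`,
idempotent): such ubiquitous signals — solvent impurities, shared primary
metabolites — cannot discriminate any classification.  Missing intensity
cells are read as 0 (absent) with a warning, never imputed: the analysis is
presence/absence.  For reporting, a feature is rendered as its (m/z, rt)
pair with m/z to 2 decimals and retention time (minutes) to 1 decimal;
internally ids are opaque labels.

The PCA overview uses mean-centering followed by Pareto scaling (divide by
$\sqrt{sd}$, sd with the $n-1$ denominator); zero-variance columns are
dropped with a warning.  Group score clouds are summarized by a
2-standard-deviation ellipse from the group's 2×2 score covariance (mean
center, semi-axes $2\sqrt{\lambda_i}$ of the covariance eigenvalues);
groups with fewer than 3 members get no ellipse.  Whether the original
screen ran the PCA on raw or binarized intensities is not fully
determined; the default here is raw intensities with `use_binary` as an
option.

## Cohen's kappa screen

For a 2×2 table with $a$ = present & active, $b$ = present & inactive, $c$
= absent & active, $d$ = absent & inactive ($n = a+b+c+d$):

$$\kappa = \frac{p_o - p_e}{1 - p_e}, \qquad
p_o = \frac{a+d}{n}, \qquad
p_e = \frac{(a+b)(a+c) + (c+d)(b+d)}{n^2}.$$

$\kappa$ is undefined when $p_e = 1$ (all mass in one agreeing cell); such
features are flagged and excluded from ranking — consistent with the
upstream removal of all-present peaks.  Strength tiers are phenomenological:
*strong* at $\kappa \ge 0.68$, *moderate* in $[0.35, 0.68)$, *low* below.

Per-feature significance is not prescribed by the upstream analysis; we use
the two-sided Fisher exact test on the 2×2 table (exact, parameter-free,
valid with sparse cells at $n \approx 90$), followed by BH at
$\alpha = 0.05$.  The choice is configurable in spirit: p-values are a
column of the screen output, and `compute_p = FALSE` skips them in large
simulations where only kappas and ranks matter.

Ranks are *competition (min) ranks* on descending kappa: tied values share
the smallest rank of their block and the next distinct value skips
accordingly (three features tied at the top give ranks 1, 1, 1, 4).  Output
order ties are broken lexicographically by feature id for reproducibility.

## Combined score and candidate selection

$$\bar\kappa_C = \kappa_{AM} - (\kappa_{HaCaT} + \kappa_{IEC\text{-}6})$$

rewards agreement with antimicrobial activity and penalizes agreement with
either cytotoxicity classification; the linear combination is unweighted,
exactly as printed in the source analysis.  A feature is **selected** as a
candidate for an antimicrobial-but-non-cytotoxic compound when
$\bar\kappa_C \ge 0.68$ *and* $\kappa_{AM} \ge 0.68$ (the conjunction: a
high combined score cannot rescue a weak antimicrobial signal).  Features
missing from any assay's screen, or with undefined kappa in any, are
excluded with a warning.

## Boolean pair screen

Binarized profiles of every unordered feature pair are combined
elementwise with AND (a synergy/additivity proxy: the putative response
needs both compounds) or OR (functional redundancy: either suffices), and
the combined profile's kappa against the AM classification is evaluated for
all $\binom{F}{2}$ pairs.  A pair is *outperforming* when its kappa
strictly exceeds the best defined individual-feature kappa on the same
inputs — strict inequality generalizes the data-specific cutoff a
particular study would print.  Pairs whose combined profile is constant
(undefined kappa) count as evaluated but join neither the strong nor the
outperforming tally.

**Kernel.** Contingency counts for a whole block pair come from two matrix
cross-products of the presence matrix restricted to active and to inactive
species: for AND, $a_{ij} = (X_A^\top X_A)_{ij}$ and
$b_{ij} = (X_I^\top X_I)_{ij}$ directly; for OR by inclusion–exclusion from
the same products and the column sums.  The counts are exact integers, the
per-pair cost is $O(n)$ inside BLAS, and iterating over feature blocks
bounds memory, so the screen streams over pairs without materializing them:
only records at or above the report threshold (default 0.68) or beating the
best individual feature are kept, while summary tallies always cover all
pairs.  A bit-packed popcount kernel would reduce the constant further; at
the scales this package targets (~$2 \cdot 10^6$ pairs per run, exercised
in seconds) the cross-product formulation is exact, simpler, and fast
enough, and the tests pin it against a naive per-pair oracle exactly.

Only pairs are screened; triples and higher-order combinations are out of
scope, as are quantitative synergy models (Loewe additivity, Bliss
independence), which frame the interpretation but are not part of the
computation.

**Selection-maximum caveat.** On label-independent random matrices the
best pair kappa exceeds the best individual kappa in median — the maximum
over ~$10^6$ pairs is inflated relative to a maximum over $10^3$ features.
Outperformance counts must therefore be read against this null, not as
evidence by themselves; the planted-recovery tests condition on ground
truth instead.

## Phylogenetic signal: Fritz–Purvis D

For a binary trait on a rooted, strictly bifurcating tree, tip values are
the trait and each internal node takes the mean of its two daughters
(post-order recursion); $d_{obs}$ is the sum over internal nodes of the
absolute daughter difference.  Two permutation nulls are simulated on the
same tree: random shuffles of the tip states, and a Brownian threshold
model (liabilities from Brownian motion with variance proportional to
branch length, rate 1 — the scale cancels through thresholding — root value
0, thresholded so the tips with the $k$ largest liabilities are 1, $k$ =
observed prevalence count).  Then

$$D = \frac{d_{obs} - \overline{d_b}}{\overline{d_r} - \overline{d_b}},$$

so $E[D] \approx 1$ for a random trait and $\approx 0$ for Brownian
clumping.  `p_random` is the fraction of shuffled $d_r \le d_{obs}$ (small
⟹ more clustered than random — the orientation used to report clustering);
`p_brownian` the fraction of Brownian $d_b \ge d_{obs}$.  Defaults:
`n_perm = 1000`, the two nulls on independent seed substreams.  Polytomies
must be resolved first (`resolve_polytomies`: random bifurcations,
zero-length branches replaced by $10^{-3}$ × the smallest positive branch
length so Brownian variances stay positive).

The nodal estimator is pinned to the daughter-mean recursion for
reproducibility; published implementations differ in subtleties, so
equality to any particular package to machine precision is not claimed —
the calibration properties (mean D within $\pm 0.15$ of 0 and of 1 under
the matching generative models, 200 replicates on 64-tip trees) are what
the tests assert.

## The synthetic study generator

The generator exists so every downstream stage is testable against known
ground truth; its defaults *are* the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 87 | panel size of the emulated study |
| `active_fraction` | 17/87 | observed antimicrobial prevalence |
| `n_features` | 2000 | desk-scale stand-in for a $\sim 5 \cdot 10^4$-peak matrix (within the $10^3$–$10^4$ band the screens are exercised at) |
| `background_prevalence` | 0.15 | typical sparse occupancy of aligned LC-MS feature tables |
| `flip_noise` | 0.05 | per-species presence flips on planted profiles |
| `replicates` | 3 | triplicate assays |
| `effect_radius_cm` / `inactive_radius_cm` | 0.9 / 0.2 | active mean well above, inactive well below, the 0.6 cm threshold |
| `radius_sd`, `absorbance_sd` | 0.05 | assay noise; free parameters, no published noise model exists |
| `control_absorbance` / `cytotoxic_absorbance` | 1.0 / 0.4 | cytotoxic extracts at 40% viability |
| `intensity_log_mean_present/absent` | 5 / 3 (sd 0.3) | log10-normal intensities either side of the $10^4$ threshold |
| `hacat_prevalence` / `iec6_prevalence` | 1/87 / 0.3 | one HaCaT-cytotoxic species; IEC-6 cytotoxicity widespread and phylogenetically random |

Trees are Yule pure-birth with unit rate (simple, realistic topology
spread; real trees are inferred from sequence data, which is out of scope
here).  The antimicrobial trait is simulated under the Brownian-threshold
model (clumped, matching the observed phylogenetic clustering of
antimicrobial activity); cytotoxicity traits are random subsets.

**Planting schemes.**  A *causal* feature reproduces the activity vector
with independent per-species flips (probability `flip_noise`) — at zero
noise its kappa is exactly 1.  An *AND-synergy* pair takes the flipped
active set $z$ and two disjoint padding sets $X, Y$ from its complement:
component A is present on $z \cup X$, B on $z \cup Y$, so $A \wedge B = z$
while each component alone is weak — the padding size starts at 35% of the
available species and grows until the component's worst-case kappa against
the true activity is below 0.45, a construction-time guarantee.  This
mirrors the idea of an accessory compound: individually uninformative,
jointly predictive.  An *OR-redundancy* pair partitions $z$ between the two
components, so $A \vee B = z$; the components are individually moderate
(roughly half the active set each), which means a redundancy component can
occasionally clear the strong threshold on its own — by design, only the
union is perfect.  Background features are independent Bernoulli draws;
any feature that would come out present in all species has one presence
removed, keeping the ubiquitous-filter precondition.  Intensities are
log10-normal around the present/absent means, clamped 0.01 log units clear
of the $10^4$ threshold so binarization recovers the planted pattern
exactly; only the binary value matters downstream — intensities exist to
exercise the threshold.

All randomness flows through one seeded generator per call with named
substreams derived from the master seed (`tree`, `peaks`, `bioassay`,
`dstat-shuffle`, ...), so every artifact is a pure function of (config,
seed), stages can be rerun independently, and reruns are bit-identical.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: chromatographic artifacts, adducts, isotopes
and retention-time drift (upstream peak processing); fragment/adduct ions
making features ≠ compounds; correlated feature co-occurrence from shared
biosynthesis; dose dependence of the assays; non-Yule tree shape and
branch-length error.  Recovery rates measured here are recovery under the
planted model, not field performance.

## Numerical choices and degenerate inputs

* Kappa undefined at $|1 - p_e| < 10^{-12}$; undefined values propagate as
  `NA` and are excluded from ranks and tallies, never coerced to 0.
* Fisher p-values are clamped at 1 (tail sums can exceed 1 by a few ulp).
* BH rejection uses `p_adj <= alpha` with the monotone adjusted values;
  the test suite pins the rejection set to a brute-force evaluation of the
  step-up definition.
* Truncations: radii at 0, absorbances at $10^{-6}$ (clamping, recorded
  here rather than resampling — the tails involved are negligible at the
  default sigmas).
* Ties: classification thresholds are inclusive (≥); ranking ties share the
  minimum rank; heatmap feature selection breaks ties by individual kappa,
  then id.

## Problem sizes used by the test and acceptance runs

Oracle equivalences run at 1,000 random 2×2 tables, a 100-species ×
200-feature full pair screen (19,900 pairs, both operators), and 1,000
random p-vectors.  Recovery properties run 50 seeds each at 87 × 2,000
(~$2 \cdot 10^6$ pairs per seed); D calibration runs 200 replicates per
mode on 64-tip trees at 500 permutations per null.  These sizes keep the
whole suite in a few minutes while leaving the planted-effect margins wide.

## Known limitations

* Kappa on a 17/70 split is bounded away from fine resolution; competition
  ranks on ~2,000 features produce frequent ties at low kappa.
* The combined score subtracts kappas measured on different marginals; it
  is a screening heuristic, not a calibrated statistic, and is used only
  for ranking and thresholding.
* The per-species cytotoxicity ANOVA shares one solvent control per cell
  line, so the per-species tests are not independent; BH is applied as if
  they were (it is robust to positive dependence).
* D is estimated from a single trait realization; its sampling spread on
  87 tips is wide (the calibration bands are about means over replicates,
  not single runs).
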