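# phytokappa

Screening plant-extract bioactivity against LC-MS phytochemical profiles by
categorical correlation.

## The problem

Crude plant extracts are mixtures of thousands of unidentified compounds.
Given, for a panel of species, (i) an antimicrobial agar-diffusion assay
(inhibition-zone radius against *B. subtilis*), (ii) MTT cytotoxicity
assays on two mammalian cell lines (HaCaT keratinocytes, IEC-6 intestinal
epithelial cells), and (iii) an LC-MS feature table (one peak = one
(m/z, retention-time) pair), which peaks mark compounds that are
antimicrobially active **but not cytotoxic** — and is the activity carried
by single compounds, synergistic pairs, or functionally redundant
alternatives?

`phytokappa` implements that screening pipeline for R users in natural
products / metabolomics research:

* **Binary classifications** — active ⟺ mean inhibition radius ≥ 0.6 cm;
  cytotoxic ⟺ per-species two-group ANOVA vs the solvent control,
  BH-corrected at FDR α = 0.05, with mean viability < 100%.
* **Per-feature Cohen's kappa** — presence (intensity ≥ 10⁴) vs each
  classification:
  κ = (p_o − p_e)/(1 − p_e) on the 2×2 table, with Fisher-exact p, BH
  flags, and competition ranks; tiers *strong* (κ ≥ 0.68), *moderate*
  (0.35–0.67), *low*.
* **Combined score** — κ̄_C = κ_AM − (κ_HaCaT + κ_IEC-6); a feature is a
  selected candidate when κ̄_C ≥ 0.68 **and** κ_AM ≥ 0.68.
* **Boolean pair screen** — kappa of every pairwise AND (synergy proxy)
  and OR (redundancy proxy) combination of profiles, streamed over all
  C(F,2) pairs by an exact block cross-product kernel; pairs beating the
  best individual feature are *outperforming*.
* **Phylogenetic signal** — Fritz–Purvis D of each binary classification
  on the species tree (D ≈ 1 random, D ≈ 0 Brownian-clumped), with
  permutation p-values.
* **Synthetic study generator** — Yule trees, Brownian-threshold or random
  traits, peak tables with planted causal features / AND pairs / OR pairs
  at controlled flip noise, triplicate bioassays — so the whole analysis is
  testable against known ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script states what it found and writes its tables under `results/`.

```sh
Rscript analysis/01_simulate.R      # synthetic study fixtures
Rscript analysis/02_bioactivity.R   # assay readings -> binary labels
Rscript analysis/03_kappa_screen.R  # per-feature kappa + combined score
Rscript analysis/04_pair_screen.R   # Boolean AND/OR pair screen
Rscript analysis/05_phylo_signal.R  # Fritz-Purvis D per classification
Rscript analysis/06_pca_diversity.R # PCA overview + chemical diversity
```

Output of stages 3–5 on the default synthetic study (87 species, 17
active, 2000 features, 5% flip noise, seed 20241):

```
Screening 2000 features (0 ubiquitous removed)
AM     strong: 2 | moderate: 6 | BH-significant: 5 | top kappa: 0.866
HaCaT  strong: 0 | moderate: 1 | BH-significant: 0 | top kappa: 0.389
IEC-6  strong: 0 | moderate: 1 | BH-significant: 0 | top kappa: 0.358

Planted causal feature F00001: kappa_AM = 0.866, rank 1
Selected candidates (kappa_C >= 0.68 and kappa_AM >= 0.68): 2

AND: 1999000 pairs | strong (>= 0.68): 6 | outperforming (> 0.866): 2 | best pair kappa: 0.963
   outperforming pairs containing a strong individual feature: 100%
OR: 1999000 pairs | strong (>= 0.68): 222 | outperforming (> 0.866): 1 | best pair kappa: 0.930
   top pair F00004+F00005 (kappa 0.930) IS the planted OR pair

AM     D = -0.154 | p (vs random, D=1) = 0.000 | p (vs Brownian, D=0) = 0.699
HaCaT  D =  2.240 | p (vs random, D=1) = 0.488 | p (vs Brownian, D=0) = 0.463
IEC-6  D =  0.964 | p (vs random, D=1) = 0.388 | p (vs Brownian, D=0) = 0.000
```

Reading: the planted causal peak is recovered at rank 1 with κ_AM = 0.87;
the best AND pair (0.963) and OR pair (0.930) both outperform every
individual peak, and the top OR pair is exactly the planted redundancy
pair (the top AND pair combines the causal peak with a synergy component —
an even stronger composite, so the screen reports it honestly).  The
antimicrobial classification is phylogenetically clustered (D = −0.15,
p_random < 0.001) while IEC-6 cytotoxicity is indistinguishable from a
random tip arrangement (D = 0.96) — the qualitative pattern this kind of
survey is designed to expose.

The same end-to-end run is available programmatically:

```r
library(phytokappa)
res <- run_pipeline(pipeline_config(seed = 1), "out/")
res$summary$n_selected_candidates
```

## Repository layout

```
R/                  package code (feature table, bioactivity, kappa screen,
                    Boolean pair screen, phylogenetic signal, synthetic data,
                    pipeline)
analysis/           numbered workflow scripts (the narrative drivers)
scripts/acceptance.R  headline-quantity reproduction
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, parameters, design choices)
```
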