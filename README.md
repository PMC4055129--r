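# qsarforge

Ligand-based 2D/3D-QSAR modelling for folate-pathway inhibitor discovery.

Methotrexate treats acute lymphoblastic leukemia by inhibiting dihydrofolate
reductase (DHFR), with its polyglutamated metabolites additionally inhibiting
thymidylate synthase (TS), but its toxicity motivates the search for gentler
inhibitors — for example among natural-product libraries. `qsarforge`
implements the ligand-based half of such a campaign as a tested, reusable R
package: given a series of inhibitors with measured potencies
(pIC50 = −log10 IC50), it builds quantitative structure–activity models,
validates them, and applies them — together with docking scores and ADMET
levels consumed as data — to rank and filter candidate compounds.

## What it computes

**Molecule preparation** — SMILES/SDF input (via ChemmineR/OpenBabel), seeded
distance-geometry-style 3D embedding, Gasteiger–Marsili partial charges, and
Shrake–Rupley solvent-accessible surface areas.

**Descriptors** — eleven named descriptors: HBD_Count, Num_RotatableBonds,
Kier–Hall valence connectivity CHI_V_1, composition entropy IAC_Mean,
Balaban-type indices JX/JY (electronegativity- and covalent-radius-weighted),
third-order cluster count SC_3_C, the Jurs charged-partial-surface-area trio
(Jurs_FNSA_1, Jurs_RPCS, Jurs_SASA) and Shadow_Xlength.

**Descriptor selection** — genetic function approximation (GFA): a genetic
algorithm over linear term sets scored by the Friedman lack-of-fit
LOF = LSE / (1 − (c + d·p)/m)².

**2D regressors** — multiple linear regression
pIC50 = a₀ + Σ aᵢxᵢ; epsilon-SVR with the Gaussian kernel
K(x, x′) = exp(−‖x − x′‖²/2σ²) solved by an SMO-style dual optimizer; and a
Bayesian-network category regression (BNCR): discretize activity, fit
per-category OLS β̂ᵢ = (XᵢᵀXᵢ)⁻¹Xᵢᵀyᵢ, learn a discrete network by BDeu hill
climbing, predict via k = argmaxᵢ P(i | D) and pIC50 = X_k β̂_k.

**3D field models** — CoMFA-style Lennard-Jones/Coulomb fields and
CoMSIA-style Gaussian similarity fields (S/E/H/D/A) on a rectangular lattice
over pre-aligned molecules, NIPALS PLS1 with leave-one-out q², optimal
component selection, SEE/F statistics, per-field fraction contributions, and
numeric contour export.

**Candidate evaluation** — ADMET-level filtering, dock-score ranking, and
reproduction reports that recompute the bundled study tables' arithmetic
(all tables ship as plain-text fixtures under `inst/extdata/`).

## Worked example

Validating the bundled CoMFA predictions against the experimental activities:

```r
library(qsarforge)
t5 <- loadFixture("table5"); t1 <- loadFixture("table1")
exper <- t1$pic50[match(t5$id, t1$id)]
validationReport(t5$comfa_pred, exper, subsets = t5$set, ids = t5$id)
#> ValidationReport: 45 compounds
#>   R2[test] = 0.9812
#>   R2[train] = 0.9572
#>   R2[overall] = 0.9627
```

The training-set R² of 0.957 is the squared Pearson correlation between
CoMFA-predicted and experimental pIC50 over the 36 training compounds;
residuals are experimental − predicted (compound 22: 8.699 − 8.127 = 0.572).

Selecting descriptors for a planted linear activity model:

```r
d <- genLinearDataset(n = 60, p = 20, terms = c(x3 = 2, x7 = -1),
                      intercept = 5, noiseSD = 0.1, seed = 1)
runGFA(d$table, d$y, seed = 1)[[1]]
#> MLRModel: intercept 5.007 + 3 term(s) (LOF 0.7698)
#>   +1.99*x3 -0.9828*x7 +0.03199*x16
```

GFA recovers the two planted terms (with a small spurious third term whose
coefficient is near zero at this noise level).

Preparing a molecule and computing descriptors:

```r
f <- tempfile(); writeLines("CCO ethanol", f)
mol <- prepareMolecule(readMolecules(f, "smiles")[[1]], seed = 1)
round(topologicalDescriptors(mol), 4)
#>  HBD_Count Num_RotatableBonds  CHI_V_1  IAC_Mean     JX     JY  SC_3_C
#>     1.0000             0.0000   1.0233    1.2244 1.8662 1.5183  0.0000
```

A command-line front end covering every stage
(`descriptors`, `gfa`, `fit`, `predict`, `comfa`, `comsia`, `filter`,
`rank`, `reproduce`, `simulate`, `run`) is installed at
`system.file("scripts", "qsarforge", package = "qsarforge")`; `run` drives
the whole pipeline from a YAML config.

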