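---
title: "Models and methods in qsarforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in qsarforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarforge)
```

`qsarforge` packages a ligand-based QSAR workflow for folate-pathway
inhibitor discovery: molecule preparation, eleven named descriptors,
GFA descriptor selection, three 2D regressors, CoMFA/CoMSIA-style field
models with PLS, and a candidate filtering/ranking stage. This vignette
records the models, their assumptions, the tunable parameters, and the
design decisions taken where the underlying methodology left choices open.

## Molecule preparation

Molecules enter as SMILES or SDF V2000 (parsed by ChemmineR, with OpenBabel
behind SMILES conversion). Three preparation steps precede any descriptor or
field computation; all are deterministic given their seed.

**3D embedding** (`embedCoordinates`). Commercial packages build conformers
with proprietary procedures, so the package uses a transparent
distance-geometry-style scheme: explicit hydrogens are added, atoms start at
seeded random positions, and a pseudo-energy is minimized by BFGS. The
energy holds harmonic terms for bond lengths (targets from covalent radii,
shortened for higher bond order), for 1–3 distances (law of cosines at the
ideal angle implied by the central atom's degree and hybridisation), and
one-sided repulsion for atom pairs three or more bonds apart (lower bound
0.8 × the van der Waals sum). This yields a single plausible conformer —
conformer ensembles and tautomer enumeration are out of scope. Failed
relaxations retry from a new seeded start (default 5 attempts). Identical
(molecule, seed) input gives byte-identical coordinates.

**Partial charges** (`assignPartialCharges`). Gasteiger–Marsili iterative
partial equalization of orbital electronegativity: per-element,
per-hybridisation polynomials χ(q) = a + bq + cq², six damped iterations
with damping 0.5 (both configurable). Charge moves along each bond from the
less to the more electronegative atom, scaled by the donor's cation
electronegativity, so the total charge equals the net formal charge exactly
— the conservation invariant the tests assert at 1e-6.

**Surface areas** (`computeSASA`). Shrake–Rupley numerical SASA with a
1.4 Å probe (water) and 960 deterministic golden-spiral points per atom on
Bondi radii. A single sphere reproduces 4π(r+p)² to well under 1%.

## Descriptors

The eleven registered descriptors (`descriptorSet()`) carry the definitions
published for their families, not any vendor implementation; numerical
parity with commercial descriptor engines is explicitly not a goal, because
those definitions are not public. Conventions:

* Topological descriptors use the hydrogen-suppressed graph; `IAC_Mean`
  (composition entropy in bits) includes hydrogens, since the element
  distribution of an organic molecule is trivial without them.
* `CHI_V_1` uses the Kier–Hall valence delta δv = (Zv − h)/(Z − Zv − 1),
  which reduces to Zv − h for second-row atoms.
* `JX`/`JY` are Balaban-type distance-connectivity indices on a weighted
  distance matrix; edges are weighted by inverse products of Sanderson
  electronegativities (JX) or covalent radii (JY), both relative to carbon.
  This is the most common reading of that descriptor pair; the weight
  tables live in `atomParameterTable()` and are swappable.
* `BD_Count` is accepted as an alias of `HBD_Count` (hydrogen-bond donors):
  the two names denote the same quantity in the source material.
* The Jurs CPSA trio and `Shadow_Xlength` operate on the full
  explicit-hydrogen structure with charges and SASA attached;
  `Jurs_RPCS` is defined as 0 when no atom carries positive charge.
* `Shadow_Xlength` rotates onto the principal axes of the coordinate
  covariance before measuring the van der Waals extent, making it rigid-
  rotation invariant.

## GFA descriptor selection

`runGFA` evolves descriptor subsets as linear-model genomes: tournament
selection (size 2), single-point crossover on sorted term lists, a mutation
that adds/removes/swaps one term, elitism of one (the best LOF is therefore
non-increasing over generations), OLS fit per genome, and the Friedman
lack-of-fit score LOF = LSE/(1 − (c + d·p)/m)² with smoothing d = 1 by
default. Defaults (population 50, 50 generations, ≤ 3 terms) solve
small instances to the exhaustive-search optimum — the test suite checks
equality with full enumeration over all ≤ 3-term subsets of 8 descriptors
across 20 seeds.

The single-descriptor activity-correlation prefilter (r² ≥ threshold,
`prefilterDescriptors`) is implemented but defaults off: on most datasets no
single descriptor correlates with activity at r² > 0.8, so applying it
blindly empties the table. Whether such a filter should apply per descriptor
or to the final model is genuinely ambiguous in the source methodology; both
readings are reachable (threshold argument vs. inspecting fitted models).

## 2D regressors

**MLR** (`fitMLR`) is exact OLS via QR with a hard error on rank deficiency
— no silent regularization; the error names the offending columns.

**SVR** (`fitSVR`) minimizes the standard epsilon-insensitive dual with the
Gaussian kernel exp(−‖x−x′‖²/2σ²) under Σβ = 0, |βᵢ| ≤ C. The printed form
of this kernel in the source material lacks the negative sign; the standard
negative exponent is implemented, since the printed form is unbounded and
not a kernel. The solver is pairwise coordinate descent (SMO-style) with
exact piecewise-quadratic line search across the |β| kinks; convergence is
declared when the Karush–Kuhn–Tucker multiplier interval closes to the
requested tolerance (default 1e-3). On tiny instances the solution matches
an independent reference solver (libsvm via e1071) to 1e-6 in the dual
objective. Defaults C = 10, ε = 0.1, σ = median pairwise distance;
`tuneSVR` adds a seeded 3-fold grid search.

**BNCR** (`fitBNCR`) is the category-regression scheme: activity is
discretized (default 5 equal-frequency bins — the source bin count is not
recoverable, so reproducing its printed R² is not attempted), each category
gets its own OLS fit, descriptors are quantile-binned (3 bins), and a
discrete Bayesian network over binned descriptors plus the category node is
learned by greedy hill climbing (add/delete/reverse moves) on the BDeu
score (equivalent sample size 1, ≤ 3 parents, 5 seeded restarts) — a
locally score-optimal DAG, standing in for heavier stochastic searches.
Prediction discretizes the evidence (out-of-range values clamp to the
nearest bin, with a message), computes P(category | evidence) by exact
enumeration, takes the argmax (ties resolve to the lower category, logged),
and evaluates that category's regression. Columns constant within a
category are dropped from that category's design; with one category the
model is exactly MLR, an equivalence the tests assert at 1e-9.

**Validation** (`validationReport`) reports R² as the squared Pearson
correlation between predicted and experimental activity — the convention
the reported study statistics use — alongside the coefficient of
determination 1 − SSres/SStot, which differs whenever predictions are
miscalibrated in scale or offset.

## 3D field models

Molecules must arrive pre-aligned; no alignment is ever auto-invoked, since
an alignment choice silently changes every field value. The lattice
(`buildGrid`) uses 2.0 Å spacing and a 4.0 Å margin by default.

CoMFA steric fields use the Lennard-Jones A–B form
ε[(rmin/r)¹² − 2(rmin/r)⁶] with rmin = atom vdW radius + probe radius and
geometric-mean well depths, which places the minimum exactly at −ε at
r = rmin; electrostatics use Coulomb with distance-dependent dielectric
D(r) = r and k = 332.0637 kcal·Å/(mol·e²). The probe is sp³-carbon-like
(radius 1.9 Å, well depth 0.1 kcal/mol, charge +1); both fields truncate at
±30 kcal/mol and a lattice point coinciding with an atom maps to +cutoff
(logged). CoMSIA similarity indices use the Gaussian form
−Σ w·exp(−αr²) with α = 0.3 Å⁻², atom properties r³ (S), partial charge
(E), coarse atomic hydrophobicity increments (H), and rule-flagged
donor/acceptor indicators (D/A). These probe and grid defaults are standard
literature values; reproducing any commercial engine's printed PLS table
numerically is a non-goal — those tables are treated as report-format
targets only. One printed anomaly is deliberately not emulated: a component
count equal to the number of training compounds is impossible under the
PLS constraint c ≤ m − 1.

PLS is NIPALS PLS1 on centered data. Reported statistics follow the CoMFA
conventions: r² = 1 − SSres/SStot on the training fit,
SEE = √(SSres/(m − c − 1)), F = (r²/c)/((1 − r²)/(m − c − 1)), and
q² = 1 − PRESS/SStot from leave-one-out refits (zero components = the mean
predictor, q² = 0 by convention). The optimal component count is the argmax
of q², ties resolving to fewer components. Per-field fractions divide the
|coefficient| × column-standard-deviation mass per block; contour export
back-projects those products onto the lattice at the 80th/20th percentiles.

## Candidate evaluation and fixtures

ADMET levels are consumed as opaque ordinals — the predictors behind them
are commercial, so the package only range-checks values against the
documented level ranges and applies conjunctive user rules
(`admetFilter`). Absent dock scores stay absent: they never compare
greater or less than any number and sink to the end of rankings.

The bundled study tables ship verbatim as TSV fixtures. Their internal
inconsistencies are preserved and *flagged*, never silently repaired: the
stated CoMFA residual range conflicts with the table's own extremes; one
compound's experimental pIC50 differs in its last digit between two tables;
and the narrative selects a compound as low-hepatotoxicity that the ADMET
table marks toxic. `reproduceReport()` surfaces each as a note. Residual
recomputation joins the full-precision experimental values by compound id,
because the prediction table's own experimental column is rounded one digit
short of what the printed residuals require; recomputed residuals then
match all 135 printed cells exactly at printed precision, with a ±1-last-
digit tolerance held in reserve for rounding artifacts (none are needed).

## Synthetic data: what it emulates, and what it does not

The three generators produce data with exactly the statistical structure
each model class assumes: `genLinearDataset` plants a sparse linear model
with Gaussian noise in standard-normal descriptors; `genCategoryDataset`
plants piecewise-linear regimes marked by a discrete driver descriptor
(written as an exactly discrete column so that any quantile binning
separates the regimes — the property BNCR needs to be testable at zero
noise); `genAlignedSeries` builds a rigid pseudo-atom scaffold with a
varying substituent and writes activity as a known linear function of a
field block, perfectly aligned by construction. Passing tests on these data
demonstrate correctness of the estimators under their own assumptions —
recovery of planted truth, agreement with oracles, null behaviour under
permutation. They deliberately do not demonstrate predictive validity on
real chemistry: real descriptor distributions are collinear and heavy-
tailed, real conformers and alignments are contested, and real activity
noise is not Gaussian. Problem sizes in the tests (tens of compounds,
hundreds of lattice points, 20-seed GA replicates) were chosen as the
smallest sizes at which the planted structure is identifiable with margin.

## Numerical choices and limitations

* All randomness flows through per-call seeds into an isolated RNG stream;
  the caller's RNG state is never touched. Reruns with identical
  (input, seed) are bit-identical, including the pipeline runner.
* OLS uses QR; PLS deflation stops early at numerically zero score
  variance; the SVR solver declares non-convergence (with the residual KKT
  gap) rather than returning a silently loose solution.
* Equal-frequency activity bins place edges at midpoints between order
  statistics; ties that would collapse edges raise an error suggesting
  fewer categories.
* Elements beyond H/C/N/O/S/P and the halogens have no parameters and fail
  fast with the element named.
* The embedder is adequate for the small organic molecules the descriptor
  and field tests need; it is not a conformer-search engine, and strained
  ring systems may require more restarts.
* Descriptor-level reproduction of the bundled inhibitor series is not
  possible from the fixtures alone: the tables record substituent labels,
  not full structures, so real-structure modelling requires user-supplied
  SDF input.
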