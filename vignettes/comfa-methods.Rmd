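---
title: "CoMFA 3D-QSAR with docking-based alignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoMFA 3D-QSAR with docking-based alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comfa)
```

## The method

Comparative Molecular Field Analysis (CoMFA) correlates the biological
activity of a ligand series with the steric and electrostatic fields the
ligands project into the space around them. The ingredients, in the order
the pipeline runs them:

1. **Alignment.** All compounds must share one coordinate frame. This
   package consumes docking poses in the receptor frame and selects, per
   compound, a pose in which a protonatable nitrogen contacts the conserved
   binding-site carboxylate (for aminergic GPCRs such as the dopamine D2
   receptor, the TM3 aspartate 3.32). The salt bridge is the anchoring
   interaction of orthosteric aminergic ligands, which is what makes a
   docking-based alignment of chemically unrelated series defensible.
2. **Charges.** Atomic point charges by iterative partial equalisation of
   orbital electronegativity (PEOE, Gasteiger–Marsili), optionally augmented
   with simple-Hückel π increments (the "Gasteiger–Hückel" scheme of the
   Sybyl tradition).
3. **Fields.** On a regular lattice enclosing the aligned set, an sp3-carbon
   probe with charge +1.0 e reports a Lennard-Jones 6–12 energy (Tripos
   force-field parameters) and a Coulomb energy with distance-dependent
   dielectric at every grid point, for every compound.
4. **Regression.** Activities (pIC50) are regressed on the field columns by
   partial least squares (PLS1, NIPALS), with leave-one-out (LOO)
   cross-validation selecting the number of latent components.
5. **Validation.** External test-set prediction and progressive scrambling.
6. **Interpretation.** STDEV*COEFF contour maps exported as OpenDX grids for
   overlay on the receptor structure.

## Activities

pIC50 = 9 − log10(IC50/nM). Records whose IC50 exceeds the quantitation
limit (default 100,000 nM), or recorded only as "> X", are kept as
left-censored inactives fixed at pIC50 = 5.0. The fixed value follows the
convention of the modelled workflow rather than the arithmetic −log10 of the
limit (which would be 4); both the limit and the censor value are arguments
of `ic50_to_pic50()`.

The train/test split (`split_train_test()`) sizes the test set as a fraction
of the *training* set (10% gives 160/16 from 176 records). The published
protocol requires both sets to span pIC50 5 to above 9 and to be
structurally diverse, but does not say how that was enforced; we stratify by
chemotype family crossed with activity quartile and redraw (deterministically
under the seed) until both criteria hold. This is a design choice, not an
attempt to reconstruct the original assignment.

## Charges

The PEOE σ scheme uses the published Gasteiger–Marsili electronegativity
parameters χ(q) = a + bq + cq², 8 damped iterations (damping 0.5^k), and
seeds the iteration with formal charges. Per-atom charges agree with an
established reference implementation within 0.02 e on small molecules
(regression-tested against frozen reference values).

The π term builds a topological Hückel matrix per conjugated fragment
(standard heteroatom parameters h, k in units of α, β), fills orbitals by
electron count — degenerate shells are occupied uniformly so symmetric
molecules get exactly symmetric charges — and adds the resulting π-charge
increments to the σ charges. Two bookkeeping conventions matter:

* A cationic aromatic nitrogen (pyridinium-type) donates two π electrons and
  the fragment's electron count is Σz − (net formal charge), which is the
  only convention under which a pyridinium fragment yields closed-shell
  occupation with increments summing to +1.
* In the combined mode the formal charge of π-system atoms is allocated to
  the π step (their σ seed is 0); otherwise it would be counted twice.
  Total charge equals the sum of formal charges in both modes, to 1e-6.

The exact Hückel parameterisation used by the commercial implementation is
unpublished, so `method = "peoe"` — reproducible against open references —
is the tested default throughout, and `method = "gh"` is the structurally
faithful option.

## Alignment

A pose passes the salt-bridge filter when any protonatable nitrogen (formal
charge +1; fallback: neutral sp3 amines that are not amide- or
aniline-conjugated) lies within `max_dist` of either carboxylate oxygen.
The cutoff defaults to 4.0 Å, a typical salt-bridge distance; the source
protocol says only that the nitrogen "interacts" with the aspartate.
Among passing poses the representative is chosen by a deterministic triple
key: smallest anchor distance, then largest heavy-atom overlap with the
reference pose (the selected pose of the most active compound of the same
family; overlap = fraction of reference heavy atoms with a same-class atom
within 1.5 Å), then smallest pose index. Compounds with no qualifying pose
are dropped and reported, never force-aligned.

## Fields

Grid spacing 2.0 Å with a 4.0 Å margin, snapped outward to whole steps —
the conventional CoMFA region defaults; the source protocol states only
"default settings". Steric energies are capped at +30 kcal/mol (a probe
position inside an atom reports exactly the cap); electrostatic energies use
332.0636 kcal·Å·mol⁻¹·e⁻² with ε(r) = r and are clamped to ±30 kcal/mol.
At lattice points inside a molecule's steric envelope (any atom within its
Lennard-Jones radius) the electrostatic value is replaced by the column mean
over compounds for which the point is solvent-side — the convention of the
commercial implementation, which prevents meaningless intramolecular
Coulomb spikes from dominating the column variance.

Columns with standard deviation below `min_sigma` (2.0 kcal/mol) are
dropped, and each field block is scaled to equal total variance
(CoMFA-STD). The filter and scaling are fit on the training set once and
re-applied to test compounds; LOO refits re-center but do not re-select
columns (the convention of the original software).

## PLS, component selection and statistics

PLS1 by NIPALS on centered, block-scaled descriptors. The LOO Q² is
1 − PRESS/SS_tot; SEP = √(PRESS/(n−c−1)) (the n−c−1 convention is the
default; plain n is available via `df_correction = FALSE`). The component
count is chosen to maximise Q², ties broken by smaller SEP then smaller c.
Training statistics: R², SEE = √(RSS/(n−c−1)), and

F = R²(n−c−1) / (c(1−R²)),

the convention under which the published statistics panel (n = 160, c = 5,
R² ≈ 0.92, F = 338.9) is internally consistent — adopted by inference from
that consistency, since the formula itself is not printed. Field
contributions are Σ|b_j|·sd_j per field, normalised to 100%. External
predictivity is reported as the squared Pearson correlation between observed
and predicted test activities, the only convention under which training and
test predictivity are the same statistic.

## Progressive scrambling

Activities are sorted, partitioned into N contiguous bins (N from 2 to 10,
10 repetitions each) and permuted within bins; fewer bins mean stronger
perturbation. For every perturbation the LOO Q² is recomputed, a quadratic
of Q² against R²yy (squared correlation of perturbed with original
activities) is fitted per component count, and three numbers are read off
at the critical perturbation level (0.85): the adjusted Q², cSDEP, and the
slope dQ²/dR²yy. Slopes at or below 1.2 — ideally near 1 — indicate a
stable model; slopes that grow with the component count expose redundant
components. The bin range, repetition count and critical point follow the
published methodology's defaults, since the modelled study names none.

## The synthetic benchmark

Real inputs to this workflow (curated IC50 sets, receptor structures,
docking poses) cannot ship with a package, so `generate_dataset()` produces
a synthetic benchmark with the same shape as the modelled study and a known
ground truth:

* 176 compounds from two pseudo-scaffold families (benzamide-like and
  arylpiperazine-like), each with a cationic nitrogen fixed near a
  synthetic aspartate carboxylate, so alignment holds by construction;
  jitter of 0.15 Å per coordinate emulates pose variation.
* Six substituent sites with independent occupancy (none/methyl/propyl/
  chloro/hydroxyl, probabilities 0.35/0.20/0.15/0.15/0.15). The first five
  are signal sites: sparse coefficients are planted on the field columns
  within 2.2 Å of each site (three steric, two electrostatic, alternating
  sign, importances 1.0 down to 0.6), so the activity signal has five
  independent latent factors. The sixth site is a decoy.
* y = Xb mapped affinely onto pIC50, plus Gaussian noise (0.3 pIC50
  units), re-mapped so the span invariant holds exactly: the bottom of the
  scale sits at 5.1 and the top ~3% of compounds (at least two) exceed 9,
  mirroring series whose most potent members all clear pIC50 9. The lowest
  5% of records are left-censored to exactly 5.0.
* In multi-pose mode each compound gets 20 poses, exactly one of which
  satisfies the salt-bridge criterion, so the alignment stage is exercised
  for real.

What the generator does *not* emulate: chemically exhaustive structures,
docking-pose scoring noise, correlated substituent patterns across sites,
assay heterogeneity, and activity cliffs unrelated to the planted fields.
Passing tests on this benchmark therefore demonstrate that the pipeline
recovers a planted field-linear structure–activity model under realistic
noise, censoring and multi-family alignment — not that any real series is
field-linear.

Problem sizes in the tests and the acceptance analysis (176 compounds, a
~2,800-column field matrix filtered to a few hundred columns, LOO over 160
training compounds, 91 scrambling perturbations) were chosen so a complete
run takes well under a minute on one core while keeping the statistics
stable across seeds.

## Worked run

```{r run, eval = FALSE}
report <- run_comfa(list(output = "run"))
report$onc            # selected components
report$q2             # LOO Q2 at the ONC
report$r2; report$f   # training fit
report$contributions  # steric / electrostatic split
report$external_r2    # 16-compound test set
report$scrambling     # progressive-scrambling table
```

On the default benchmark (seed 42) this selects 6 components — one more
than the 5 planted factors, a typical PLS response to correlated field
columns — with LOO Q² ≈ 0.81, R² ≈ 0.92, external R² ≈ 0.93, contributions
≈ 59/41, every scrambling Q² above 0.55 and dQ²/dR²yy ≈ 0.82 at c = 5,
rising for c > 5 exactly as the diagnostic intends. (These numbers are
recomputed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`; the vignette states no result the code does not
itself produce.)

## Numerical notes and limitations

* NIPALS deflation stops early (with a truncated model) if the residual
  weight norm falls below 1e-12; zero-variance responses are an error.
* Degenerate Hückel shells are filled uniformly; open-shell fragments are
  skipped with a warning rather than guessed at.
* The quadratic scrambling fit requires at least three distinct
  perturbation levels and errors otherwise.
* `select_onc()` ties are resolved within 1e-12 of the maximal Q².
* Energies at r → 0 are capped/clamped before they can overflow.
* The package models the CoMFA field pipeline only: no conformer
  generation, protonation-state enumeration, docking, CoMSIA fields,
  region focusing, or bootstrap analyses.
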