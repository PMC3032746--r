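---
title: "A quantum-chemical fragment-interaction scoring function for protein-ligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantum-chemical fragment-interaction scoring function for protein-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmoscore)
```

## The problem

Estimating how strongly a small molecule binds a protein is the central
quantitative question of structure-based drug design. Classical force-field
scoring functions miss much of the physics — charge transfer, polarisation,
dispersion — that dominates interactions in a kinase ATP pocket. The
fragment molecular orbital (FMO) method makes full *ab initio* treatment of
a protein-ligand complex tractable by cutting the system into one-residue
fragments, solving each fragment (monomer) and fragment pair (dimer)
quantum-mechanically in the Coulomb field of the rest, and assembling the
total energy from the pieces:

$$E_{\mathrm{FMO}} \;=\; \sum_I^N E_I \;+\; \sum_{I>J}^N \big(E_{IJ} - E_I - E_J\big).$$

The by-product that matters for scoring is the set of pair interaction
energies (PIEs, also called inter-fragment interaction energies): summing
the PIEs between the ligand fragment and every receptor fragment gives a
gas-phase binding enthalpy $\Delta H_{\mathrm{gas}}$ without the three
separate supermolecule calculations that the conventional difference
$E_{\mathrm{complex}} - E_{\mathrm{receptor}} - E_{\mathrm{ligand}}$
requires (the supermolecule route is also provided, as
`supermoleculeEnthalpy()`).

A raw quantum-mechanical enthalpy is not a binding free energy. fmoscore
completes the thermodynamic cycle with three cheap terms and then — because
the absolute sum badly overshoots experiment — rescales the four terms
through a partial least squares (PLS) regression against measured
affinities:

$$\Delta G_{\mathrm{bind}} = \Delta G^{\mathrm{gas}}_{\mathrm{bind}}
 + \Delta G^{\mathrm{complex}}_{\mathrm{solv}}
 - \Delta G^{\mathrm{receptor}}_{\mathrm{solv}}
 - \Delta G^{\mathrm{ligand}}_{\mathrm{solv}}, \qquad
\Delta G^{\mathrm{gas}}_{\mathrm{bind}} = \Delta H^{\mathrm{gas}}_{\mathrm{bind}} - T\Delta S^{\mathrm{gas}}_{\mathrm{bind}}.$$

The four descriptors of one complex are therefore

* `dH_gas` — the ligand-row PIE sum, kcal/mol (`pieSum()`);
* `dG_psolv` — polar solvation from a Poisson-Boltzmann solver. This is an
  *input*: the package deliberately contains no PB solver, because that
  step belongs to specialised electrostatics codes and its values are
  supplied with the bundled dataset;
* `dG_npsolv` — nonpolar solvation, $\gamma\,\mathrm{SASA} + b$ with
  $\gamma = 5.0$ cal/(mol·Å²) and $b = 0.86$ kcal/mol over the solvent
  accessible surface area traced by a 1.4 Å water probe;
* `TdS` — a conformational entropy penalty of 1 kcal/mol per ligand
  rotatable bond.

Experimental potencies enter as
$\Delta G = RT\ln \mathrm{IC}_{50}$ (IC50 in mol/L) at $T = 310$ K with
$R = 1.986$ cal/(mol·K). Note the sign: written with a leading minus the
formula would give positive free energies for sub-molar potencies; the form
implemented is the one that makes every bundled experimental value
reproduce from its IC50 to better than 0.001 kcal/mol. The slightly
old-fashioned $R$ is likewise the value consistent with the bundled data
(1.9872 leaves a systematic ~0.008 kcal/mol offset).

## The bundled CDK2 reference set

`loadCdk2Dataset()` ships 28 inhibitors of cyclin-dependent kinase 2 from a
single congeneric series: 14 with their own X-ray structure (training set)
and 14 modelled into a template complex (test set), each with IC50, the
four descriptors, the experimental $\Delta G$, and the reference model's
prediction and residual. Two storage decisions deserve a note:

* **Free-energy column assignment.** The original compilation of this
  table prints its two free-energy columns under interchanged headers. The
  assignment stored here is fixed by two identities that must (and do)
  hold for all 28 rows: `residual_reported = dG_experimental -
  dG_predicted_reported`, and `dG_experimental = RT ln IC50`. The loader
  re-verifies both on every load, together with an md5 checksum of the data
  lines, the 14/14 split and the integer range of the entropy column.
* **Modelled compounds** carry the PDB code of their template structure, a
  `modelled = "yes"` flag and no resolution.

## The PLS engine

Descriptors are autoscaled (mean-centred, unit sample variance) and the
response likewise; a NIPALS fit extracts `nComponents` latent components.
With a single response the NIPALS weight vector has the closed form
$w \propto X^\top y$, so no inner iteration (and hence no convergence
tolerance) is involved; each component extracts scores $t = Xw$, loadings
$p = X^\top t/t^\top t$, $c = t^\top y/t^\top t$ and deflates. The latent
structure collapses to coefficients $B = W(P^\top W)^{-1}c$, which are
back-transformed so `predict()` consumes raw descriptor rows. Two
components are the reference configuration for the CDK2 model; at full
rank the fit coincides with ordinary least squares, which the test suite
uses as an independent oracle.

The response is the free energy in kcal/mol rather than $-\ln\mathrm{IC50}$
or pIC50. The two differ only by an affine map, and PLS predictions are
exactly affine-equivariant in the response (asserted to 1e-8 in the suite),
so the choice changes nothing except the units of the reported errors —
kcal/mol matches the reference residuals.

Validation statistics follow the conventions of the SIMCA lineage of PLS
software:

* $r^2 = 1 - SS_{res}/SS_{tot}$ on the training fit;
* RMSEE $= \sqrt{SS_{res}/(n - 1 - A)}$ — the estimation denominator
  charges one degree of freedom for centring and one per latent component.
  This is the only convention consistent with the bundled reference
  residuals and their recorded RMSEE;
* RMSEP $= \sqrt{SS_{res}/n}$ on external predictions;
* $q^2 = 1 - \mathrm{PRESS}/SS_{tot}$ from grouped cross-validation: the
  rows are split into 7 groups, autoscaling and fit are redone with each
  group held out (scaling is part of the model, so it must be re-estimated
  per fold), and PRESS pools the held-out squared residuals.

The default grouping is deterministic round-robin by row order (row $k$
to group $(k-1) \bmod 7 + 1$), matching the default behaviour of the
software the reference statistics come from; a seeded random partition is
available and the scheme used is stamped into every result. The exact
reference grouping is not recoverable, which is why the $q^2$ check
carries a ±0.05 band while every deterministic statistic is checked to
±0.005 or ±0.01. Spearman ranks use average ranks on ties.

The test-set agreement statistic is reported twice, as the unsquared
Pearson correlation (`test_pearson_r`) and its square
(`test_pearson_r2`): conventions differ on which is quoted as a test-set
"$r^2$", and on the bundled data the unsquared value (0.82) is the one
matching the reference report while the square is ≈0.68.

## Geometry descriptors

**SASA** is computed by the Shrake-Rupley construction with a
deterministic golden-section spiral point set (default 960 points per
atom) instead of the traditional random sphere points — results are then
reproducible without a seed. A surface point is buried when it lies
strictly inside any neighbour's probe-expanded sphere. Bondi van der Waals
radii are the default, overridable per element. Two consequences of the
fixed point set are worth knowing: an isolated sphere is exact by
construction, and a rigid rotation of the whole molecule changes the
result only at the point-set resolution (≲1% at 960 points; raise
`nPoints` to tighten). The test suite checks a random cluster against a
100 000-points-per-atom random-sampling oracle at 1%.

**Rotatable bonds** follow the standard medicinal-chemistry convention:
single, acyclic, both end atoms bonded to at least two heavy atoms
(i.e. not terminal), amide C–N excluded; hydrogens never count. The
exclusion of amides is configurable (`includeAmides = TRUE`) because the
convention behind any given tabulated entropy count cannot be verified
without the structures. Ring membership is perceived exactly — a bond is
in a ring iff its removal leaves its endpoints connected — which is
affordable because ligands are small.

**Input formats.** V2000 connection tables (MOL/SDF) are read directly;
PDB-style HETATM records get distance-based bond perception (1.3 × the
covalent-radius sum), adequate for a ligand extracted from a complex but
not meant for whole proteins.

## The FMO log dialect and synthetic data

FMO program output arrives as large free-format text; fmoscore consumes a
compact, versioned rendering of the two tables that matter (monomer
energies; pair energies with optional dimer energies and optional
ES/EX/CT/DI decomposition components). Two column orders are supported —
`v2009` (dimer energy before PIE) and `v2008` (the reverse) — selected by
a dialect flag, since outputs of the two program eras differ. Monomer and
dimer energies are in Hartree, PIEs and components in kcal/mol, converted
at 627.5095 kcal/mol per Hartree. When components are present the parser
enforces ES + EX + CT + DI = PIE to 0.01 kcal/mol; missing pairs are
treated as zero interaction, because distance-thresholded FMO runs omit
far dimers.

`makeSyntheticFmoLog()` writes logs with known ground truth: monomer
energies of realistic magnitude, PIEs drawn at a few kcal/mol, components
that sum exactly, dimer energies constructed as
$E_{IJ} = E_I + E_J + \Delta E_{IJ}$. It emulates the *format and the
bookkeeping identities* of real output — it does not emulate the physics
(no distance decay, no charged-residue dominance, no correlation between
PIE and fragment separation). Passing the round-trip and summation suites
therefore demonstrates that parsing and aggregation are exact, not that
the package reproduces any particular quantum chemistry.
`makeSyntheticMolecule()` similarly provides shapes whose reference values
are analytic (isolated spheres, separated dimers, alkane chains with
$n-3$ rotatable bonds, aromatic rings with none).

## Degenerate inputs and numerical choices

* Zero-variance descriptor columns abort autoscaling with the column
  named; a response with zero variance aborts the fit.
* NIPALS aborts informatively if the deflated X block loses all
  covariance with y before the requested component count is reached.
* `rmsee()` requires $n > A + 1$; $r^2$ and the correlations refuse
  constant vectors rather than returning NaN.
* Cross-validation refuses empty groups (more groups than rows).
* The solvation descriptors are interpreted as *net* binding-state changes
  (complex minus parts), which is how the bundled table stores them;
  users holding three per-species values can difference them explicitly
  with `bindingSolvation()`. Whether the $b$ intercept of the nonpolar
  term should appear once or per species is not decidable from the
  bundled data; the net interpretation is adopted throughout.

## Problem sizes

The suite runs entirely on desk-scale inputs chosen to keep every oracle
exact or near-exact: FMO systems of 2–20 fragments (round-trip, summation
and assembly oracles), molecules of 1–7 heavy atoms (analytic SASA and
enumerable bond counts), the 14 + 14 compound reference set for all
statistics, and simulated regressions of up to 200 rows for the
noise-recovery checks. The whole suite completes in a few seconds.

## Limitations

* The package aggregates and models FMO results; it never runs quantum
  chemistry, fragments a structure, or evaluates electrostatic potentials.
* Polar solvation must come from an external Poisson-Boltzmann (or
  similar) calculation.
* The PLS model is a *rescaling within a congeneric series*: coefficients
  fitted on one chemical series and one binding site have no claim to
  transferability, and the descriptors carry no conformational sampling —
  one minimised structure per complex.
* Entropy as 1 kcal/mol per rotatable bond is deliberately crude; it
  encodes series-internal flexibility differences, not absolute entropy.
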