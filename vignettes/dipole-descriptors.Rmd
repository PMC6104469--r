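---
title: "Point-charge dipoles, charge-partitioned descriptors and random-forest dipole prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-charge dipoles, charge-partitioned descriptors and random-forest dipole prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipolegrid)
```

## The problem and the model

DFT-quality molecular dipole moments (DMs) are accurate but expensive.
A much cheaper estimate treats each atom's partial charge as a point
charge at its nucleus:

$$\vec\mu = \sum_{i=1}^{n} q_i\,\vec r_i,$$

where $\vec r_i$ runs from the center of mass to atom $i$.  This
package computes that estimate for any attached charge scheme, turns
the charged geometry into fixed-length descriptor vectors, and trains
random-forest regressors that learn the residual mapping from
point-charge information to DFT-quality dipole magnitudes.  Two charge
schemes are carried side by side — a built-in PEOE (Gasteiger)
assigner under the reserved scheme name `"P"`, and externally predicted
NBO-style charges ingested under `"N"` — because the two empirical DMs
are only weakly inter-correlated and therefore complementary as
features.

Conventions worth stating once:

* **Units.** Coordinates in Å, charges in elementary charge units, so
  the dipole vector is in e·Å; magnitudes are converted with
  1 e·Å = 4.803205 D (`DEBYE_PER_EA`).
* **Origin.** The center of mass, computed with conventional (IUPAC)
  atomic weights; isotope annotations are ignored.  For neutral
  molecules the dipole vector is origin-independent (verified as a
  tested invariant); for ions it is not, and `pointChargeDipole`
  notes the origin dependence when it encounters a net charge.
* **Masses.** Used both for the center of mass and for the mass series
  of the projection descriptors.

## Charge schemes

`assignPEOE` implements partial equalization of orbital
electronegativity with the classic published parameterization
($\chi(q) = a + bq + cq^2$ per atom type; H, C/N/O by hybridization,
F, Cl, Br, S, P).  On iteration $k$ each bond transfers
$(\chi_j-\chi_i)/\chi^+_{lo} \cdot d^k$ of charge toward the more
electronegative atom, with damping $d = 1/2$ and $\chi^+$ the cation
electronegativity of the donor (20.02 for hydrogen, per the original
scheme).  The default of 12 iterations runs the geometric series to
numerical convergence (residual transfers < 1e-4 e), which is where the
widely used toolkit implementations operate; at the original six
iterations the charges still differ from convergence by about 1e-3 e.
The package's unit tests pin the resulting charges, for a set of small
reference molecules, against values from an independent implementation
of the same scheme.

External (e.g. ML-predicted NBO-style) charges are never computed here;
`externalCharges` attaches them from a table keyed by molecule id and
1-based atom index (SDF atom-block order).  Because ML-estimated
charges need not conserve charge exactly, a deviation of the charge sum
from the formal charge beyond 0.02 e warns rather than rejects; the
built-in assigner, by contrast, must conserve to 1e-3 e or it errors.

## Descriptor families

**RDF pair descriptors.**
$RDF(r) = \sum_{i<j} p_i p_j e^{-B (r - r_{ij})^2}$, with unordered
pairs counted once and *signed* charge products retained (no absolute
value), evaluated separately for three pair classes: one positive and
one negative charge, two positives, two negatives.  The sign partition
makes each block sign-coherent (the mixed block is ≤ 0 everywhere).
Atoms with charge exactly zero belong to no class — the classes are
defined by strict sign.  The grid is $r_k = k \times 0.1$ Å for
$k = 1..128$ (128 equally spaced radii between 0 and 12.8 Å): $r = 0$
is excluded because no atom pair can sit at zero distance, so the first
sampled radius is one step in.  The fuzziness default is
$B = 100$ Å⁻², under which a pair contributes essentially nothing
(< 1e-40) one Å away from its true distance.  All of this is
configurable through `rdfConfig`.

**PchmDM projections.**  Each atom is projected onto the dipole axis,
$t_i = (\vec r_i - \vec r_{com})\cdot\hat\mu$, and accumulated into 60
half-open bins $[lo, lo+0.5)$ covering $[-15, 15)$ Å, lower edge
inclusive.  Six series, in fixed order: all charges, positive charges,
negative charges, charges on non-hydrogens, charges on hydrogens,
atomic masses — 360 values.  Three conventions required decisions the
underlying method leaves open:

* *Axis of the same scheme.*  PchmDM under scheme `"N"` uses the dipole
  axis computed from scheme `"N"`'s charges, and likewise for `"P"` —
  axis and weights always come from the same charge model.
* *Degenerate axis.*  If $|\vec\mu| < 10^{-10}$ e·Å the axis falls back
  to the principal axis of the mass distribution (largest gyration
  eigenvalue), sign-fixed so its first nonzero component is positive; a
  single atom yields $(1,0,0)$ by convention and all projections are 0.
* *Out-of-range projections.*  Projections outside $[-15, 15)$ are
  clamped into the terminal bins with a warning rather than dropped:
  this preserves the conservation identities (per-bin
  all = positive + negative = non-H + H; bin sums equal the total
  charge and the molecular weight), which the tests rely on.  Molecules
  of the intended size fit well inside the range, so clamping is a
  pathological-input safeguard, not a modeling choice.

**MACCS keys.**  The standard 166-bit substructure fingerprint is
delegated to OpenBabel (through `ChemmineR`/`ChemmineOB`) and exposed
as 0/1 columns `MACCS_1..MACCS_166`.  For structures without a bond
block (the synthetic clouds below) the keys are evaluated on the atoms
as given — no bond perception is attempted — so only composition-type
keys can fire; that degraded-but-deterministic behavior is intentional,
as bond perception on random point clouds would be meaningless.

**Feature recipes.**  `assembleFeatures`/`featureMatrix` produce fixed,
labeled layouts: `C` = RDF(`N`) + PchmDM(`N`) + DM_N + DM_P
(746 columns), `F` = `C` + MACCS (912), `MACCS_DM` = MACCS + DM_N +
DM_P (168).  The two dipole scalars are always the last two columns.
Labels are `<family>_<scheme>_<series or class>_<index>`, so trained
models can be serialized and safely re-applied: prediction requires
exactly the training manifest, in order, and missing features are a
hard error — silent imputation could corrupt the dipole-scalar columns
that carry most of the signal.

## Modeling protocol

Random forests (the `randomForest` package) with 500 trees by default.
The per-split feature count `mtry` is tuned by out-of-bag RMSE over the
grid $\{p/3, \sqrt p, p/2\}$ — the OOB estimate costs nothing extra and
avoids a validation split.  Feature selection ranks columns by
permutation importance (mean decrease in accuracy, averaged over trees
out of bag), with ties broken by column order; `importanceSelect`
defaults to the top 75.  Evaluation reports MAE, RMSE and R².  R² is
the squared Pearson correlation between predicted and observed values
by default — the convention that matches reading accuracy off a
predicted-vs-reference scatter plot — with the coefficient of
determination available via `r2Method = "cod"`; the two differ exactly
when predictions carry a systematic offset, in which case Pearson-R²
stays high while MAE exposes the bias.  `yRandomization` retrains on
permuted training labels (features untouched) and evaluates on the
untouched test rows, the standard guard against chance correlation.
All stochastic steps take explicit seeds and are exactly reproducible.

## The synthetic generator, and what it does not emulate

`generateMolecule` produces charged point clouds emulating the
composition envelope of small neutral organics: 3–19 atoms drawn from
H/C/N/O/F/S/Cl/Br/P with organic-like frequencies, coordinates
rejection-sampled in a 12 Å cube with a 0.9 Å minimum separation, and
per-atom charges drawn from a centered Gaussian of scale 0.3 e, then
mean-shifted so the sum hits the net charge exactly.  The `"N"` and
`"P"` sets are drawn independently, so the two schemes' dipoles
genuinely differ, as they do on real molecules.
`generateLabeledDataset` plants the label |DM under scheme `"N"`| plus
Gaussian noise (default sd 0.3 D, clipped at zero), which makes the
expected outcome of every downstream test known by construction.

What the clouds do **not** emulate: covalent geometry, bonds and
meaningful substructure (so PEOE and informative MACCS bits are
exercised on hand-written real molecules instead), and charge
correlations imposed by bonding.  Uncorrelated charges spread over a
12 Å cube produce dipole magnitudes an order of magnitude larger than
real DFT DMs of comparable molecules — random charges do not cancel
the way bonded ones do.  Passing tests on this data therefore
demonstrate that the descriptor engines, invariances and the modeling
protocol are correct, not that any particular accuracy carries over to
real chemistry; accuracy claims require real labeled structures read
through `readSDF`.

## Numerical choices and problem sizes

Brute-force reference implementations (`oracleRDF`, `oracleDipole` —
plain double loops sharing no code with the vectorized engines) are
part of the package and are compared against the engines at tolerance
1e-12 in the test suite, over 100 random molecules at every grid
point.  Rigid-motion invariance is checked at 1e-8 (rotation matrices
from QR factorizations carry ~1e-15 per-element error, amplified by
the $B = 100$ Gaussian).  The planted-signal model checks use 500
molecules with a one-third test split and 500 trees — large enough
that test R² ≥ 0.8 and the top-5 importance ranking of DM_N/DM_P are
stable, small enough that the whole suite runs in well under a minute.

## Known limitations

* PEOE parameters cover the supported element set in common organic
  valence states; exotic hybridizations (e.g. hypervalent S beyond the
  single S type) all map to the base type, which is the classic
  scheme's own simplification.  Different PEOE software differs at the
  1e-2 e level in such corners.
* OpenBabel's MACCS definitions implement the published key set with
  minor pattern-level differences from other toolkits; bit-for-bit
  interchange of fingerprints across toolkits is not guaranteed
  (the nitrile key and other headline keys agree, and are tested).
* Null-model (y-randomized) test R² is noisy at small test sizes:
  squared-Pearson values near 0.1 can occur with a few hundred test
  molecules, whereas at thousands of molecules the null collapses to
  ~1e-3.  Judge y-randomization against the real model's R², not
  against zero.
* Dipole magnitudes of charged species are origin-dependent; the
  center-of-mass convention is applied and noted, but comparisons
  across packages using other origins will differ.
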