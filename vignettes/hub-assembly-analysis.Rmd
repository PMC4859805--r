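---
title: "Models and methods for CaMKII hub assembly and subunit exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for CaMKII hub assembly and subunit exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubkit)
```

CaMKII holoenzymes are organised around a central hub: an oligomerization
domain that stacks 12 or 14 subunits into two rings. Activated holoenzymes
exchange subunits between one another, a behaviour with consequences for
the persistence of kinase activation. This vignette documents the models
implemented in `hubkit`, the assumptions behind them, the defaults, and the
numerical choices — in the spirit of a methods supplement, without claiming
any empirical result that the package's tests do not themselves compute.

## Fluorescence-polarization binding models

**Direct titration.** A trace amount (nM) of fluorophore-labeled peptide is
titrated with hub subunit at micromolar concentrations. Because the label
is present in vast deficit, free hub equals total hub and the bound
fraction is hyperbolic:

$$A(P_{tot}) = A_{free} + (A_{bound} - A_{free})\,
  \frac{P_{tot}}{P_{tot} + K_D}.$$

`direct_polarization()` implements this; `fit_fp(mode = "direct")` fits
$K_D$, $A_{free}$ and $A_{bound}$.

**Competition titration.** Because direct titrations of the CaM-binding
element against the hub show some non-saturable binding at high hub
concentration, the dissociation constant is better determined by
competition: labeled peptide is pre-bound to the hub and displaced by the
unlabeled peptide. With two simplifying assumptions — the labeled and
unlabeled peptides share one $K_D$, and the labeled concentration (2 nM)
is negligible next to the hub (10 µM) — the exact three-species (cubic)
equilibrium reduces to the 1:1 quadratic for the hub/unlabeled-peptide
complex:

$$[PL] = \frac{(P_{tot} + L_{tot} + K_D) -
  \sqrt{(P_{tot} + L_{tot} + K_D)^2 - 4 P_{tot} L_{tot}}}{2},$$

$$A(L_{tot}) = A_f + (A_0 - A_f)\,
  \frac{K_D + P_{tot}}{P_{tot}}\,\frac{[PL]}{L_{tot}}.$$

Two limit identities pin this model and are enforced as unit tests:
$A(0) = A_0$ (evaluated analytically, since the ratio $[PL]/L_{tot}$ is
0/0 at the origin and tends to $P_{tot}/(P_{tot}+K_D)$) and
$A(\infty) = A_f$. The package also verifies the reduction numerically: in
the trace-label regime the model agrees with a three-species equilibrium
solver to better than 1% of the polarization span.

Numerically, $[PL]$ is computed in the rationalised form
$2P_{tot}L_{tot}/(s + \sqrt{s^2 - 4P_{tot}L_{tot}})$ with
$s = P_{tot}+L_{tot}+K_D$; the textbook $(s-\sqrt{\cdot})/2$ form loses
all significant digits when $4P_{tot}L_{tot} \ll s^2$, which is exactly
the dilute regime the assay visits.

**Total hub concentration.** The competition assay mixes equal volumes of
labeled peptide, hub at 30 µM, and unlabeled peptide, so the final hub
concentration is 10 µM. `p_tot = 10` is the default everywhere and can be
overridden.

**Fitting.** `fit_fp()` uses Levenberg–Marquardt least squares
(`minpack.lm`), with $K_D$ log-parameterised to enforce positivity and a
multi-start over $K_D \in \{1, 10, 100, 1000\}$ µM; the lowest-deviance
converged start wins. A titration whose polarization never changes is
rejected with a "no binding signal" error rather than fit. Standard errors
come from the scaled inverse Hessian, with the delta method mapping
$\log K_D$ back to $K_D$. The fit object is a classed S3 model with
`print`, `summary`, `coef`, `predict`, `residuals`, `simulate` and `plot`
methods.

**IC50.** `ic50_from_model()` solves $A(L_{tot}) = (A_0+A_f)/2$ by
bracketed root-finding (the bracket is widened geometrically and failure
to bracket is an error, never a silent default). The midpoint condition
cancels the end points, so the IC50 depends only on $K_D$ and $P_{tot}$;
with $K_D = 90$ µM and $P_{tot} = 10$ µM it evaluates to 105.3 µM. We
treat the reported inhibition constant as this model-derived midpoint
rather than an empirical half-way reading; at these parameter values the
two differ by far less than the precision of the assay.

**Effective concentration.** A ligand tethered so that it stays within a
reach $r$ of its target behaves as one molecule in a sphere of radius $r$:
$c_{eff} = 1/(N_A \cdot \tfrac{4}{3}\pi r^3)$. A full sphere (not a
hemisphere) is used; at $r = 50$ Å this gives 3.17 mM, the scale that
makes an intramolecular micromolar interaction effectively saturated.

## Native mass spectrometry

Native electrospray keeps mega-Dalton hub assemblies intact, so the
spectrum of a hub preparation is a superposition of charge-state
envelopes, one per stoichiometry. The package works from centroided peak
lists (`mz`, `intensity`); profile processing is out of scope.

- `mz_series()`: positive-ion relation $m/z = (M + z \cdot 1.00728)/z$.
  Salt adducts are not modelled; the tolerance absorbs them.
- `infer_charges()`: adjacent-spacing method. For peaks $a > b$ of one
  envelope with consecutive charges, $z_a = \mathrm{round}((b -
  1.00728)/(a - b))$. All peak pairs are screened, pairs whose two implied
  neutral masses agree within `tol_ppm` vote, and votes are single-link
  clustered by mass. Envelopes need at least two supporting peaks; peaks
  that fit nothing stay unassigned.
- `deconvolve()`: intensity-weighted mean mass per envelope, weighted SD
  as uncertainty, summed intensity as abundance. Oligomers of a common
  subunit share exact m/z positions (a 12-mer at $z = 18k$ coincides with
  the 14-mer at $z = 21k$); such shared peaks are attributed to every
  matching envelope and their intensity is split in proportion to each
  species' Gaussian envelope as estimated from its unshared peaks.
  Without the split, an equimolar 12/14-mer mixture deconvolves to a
  visibly biased ratio.
- `assign_stoichiometry()`: nearest lattice point $n \cdot m_{sub} - t
  \cdot m_{tag}$ with $0 \le t \le n$; tags are counted as *absent*
  relative to the fully tagged oligomer, matching "n-mer − t His tags"
  species labels. Default tolerances: 500 Da for mega-Dalton species,
  5 Da appropriate for dimers.
- `cid_products()`: collisional activation of a large complex ejects one
  highly charged monomer, so the products of an n-mer are a monomer and
  the (n−1)-mer.

## The exchange-unit model

If oligomers of $n$ subunits are assembled from units of $u$ subunits
drawn from a mixed pool with long-subunit fraction $f$, the number of long
subunits per oligomer is $u B$ with $B \sim \mathrm{Binomial}(n/u, f)$
(`composition_distribution()`). Dimer-unit exchange ($u = 2$) therefore
predicts *exactly zero* odd-count oligomers, for every $f$ and $n$ — the
parity signature. `parity_fraction()` measures it;
`infer_exchange_unit()` turns it into a multinomial log-likelihood ratio
of the $u=2$ against the $u=1$ model, with an $\varepsilon = 10^{-9}$
floor on zero-probability bins so that a single odd observation penalises
the dimer model heavily but finitely. The decision rule (prefer dimers
when the ratio is positive) is this package's formalisation; the data it
mimics were described qualitatively ("predominantly" even). Off-pathway
odd species (e.g. trace trimers) should be filtered before inference.

`simulate_exchange()` is the stochastic counterpart: each step swaps one
uniformly chosen unit between two uniformly chosen oligomers, conserving
both unit totals exactly; its long-run composition converges to the
binomial law, which the tests check by a $\chi^2$ goodness-of-fit.
`interconversion_step()` encodes stoichiometry changes by whole dimers
(12 ↔ 14 in closed-ring mode).

$f$ defaults to 0.5 (equimolar mixing of the two labeled pools).

## FRET ratio

`fret_ratio()` is deliberately primitive: acceptor emission at 614 nm
divided by donor emission at 510 nm, each read at the nearest grid point
of the 500–700 nm emission scan. No interpolation, no background
subtraction, no bleed-through unmixing, no labeling-efficiency correction
— the ratio is used as a monotone index of co-assembly, not an absolute
transfer efficiency, and none of those corrections change monotonicity.
`ratio_timecourse()` reduces a spectrum series and classifies the trend
with a sign test on consecutive differences; with fewer than about seven
time points the test cannot reach significance at $\alpha = 0.05$, which
is the honest answer for so short a series. No kinetic model is fitted.

## Structural geometry

All structural operations work at the Cα level, in Ångström, with author
residue numbering preserved.

- `kabsch_superpose()`: SVD-based least-squares rotation with the
  determinant correction that excludes reflections; collinear or
  under-determined selections are errors. Tests pin it against a
  brute-force random-rotation search.
- `displacement_field()`: arrow conventions for conformational-change
  figures — vectors scaled by 2 and drawn only where the Cα moves ≥ 2 Å
  (both configurable; the threshold is inclusive).
- `ring_geometry()`: screw-axis fit to ordered subunit centroids. The
  axis direction comes from the second differences of the centroid
  sequence (for any circular helix they lie in the plane perpendicular to
  the axis); the rise is the least-squares slope of the axial coordinate
  per step; the rotation is the mean angular increment about the axis
  after an algebraic circle fit. The axis is oriented so the rotation is
  positive; the assembly is `"closed"` when |rise| < 0.5 Å, right-handed
  when it advances along the axis like a standard screw (rise > 0), else
  left-handed. A hexagonal P6₁-like spiral (60°/step, pitch/6 rise) and
  its mirror image are the canonical test cases. Subunit order must be
  supplied by the caller; ring tracing is not inferred.
- `enm_modes()`: Tirion-style anisotropic network — uniform springs
  between all Cα pairs within a 10 Å default cutoff, analytic Hessian,
  full eigendecomposition. Mode shapes, not frequencies, are the
  deliverable; the uniform-spring Cα network is a deliberate
  simplification of block-based server implementations, whose
  low-frequency mode shapes it reproduces in character. Exactly six
  eigenvalues vanish for a connected, non-collinear structure
  (tolerance: $10^{-8} \times$ the largest eigenvalue); a disconnected
  contact graph is an error naming the component sizes. A collinear bead
  chain is degenerate for a pure pairwise-distance potential — transverse
  displacements cost nothing — so it has $2N+1$ zero modes, not the five
  a potential with bending terms would give; this is documented and
  tested as such.
- `polar_contacts()`: N/O heavy-atom pairs across a stated interface
  within 3.5 Å (inclusive), a proxy for the hydrogen-bond count whose
  decrease signals a cracked interface. Requires full-atom records;
  Cα-only input is an explicit error.

## Synthetic data: what it does and does not emulate

Every analysis stage has a seeded generator (`gen_*`) that embeds its
truth parameters in the output attributes, so estimator correctness is
testable by round trip. The defaults are the study conditions and are not
tuned per test:

| Generator | Emulates | Key defaults |
|---|---|---|
| `gen_direct_curve` | hub-into-label titration | $K_D$ 100 µM, span 0.05–0.20, grid 0–1000 µM, 2% noise |
| `gen_competition_curve` | unlabeled-peptide competition | $K_D$ 90 µM, hub 10 µM, 12-point 0–500 µM dilution grid, 2% noise |
| `gen_mass_spectrum` | native ESI envelopes of oligomer mixtures | Gaussian envelope (width 2 charges), 5% intensity noise, 20 ppm m/z noise |
| `gen_exchange_populations` | mixed-pool oligomer compositions | $n=4$, $u=2$, $f=0.5$ |
| `gen_fret_series` | donor/acceptor emission scans vs. time | 510/614 nm Gaussian bands, 1 nm grid, 1% noise |
| `gen_ring_assembly` | closed rings, lock-washers, P6₁ spirals | radius 50 Å, 10-residue rigid template |

The generators reproduce the *statistical structure* each estimator
assumes: saturable 1:1 binding with additive Gaussian noise, resolvable
Gaussian charge-state envelopes, binomial composition mixing, spectra
whose ratio is affine in exchanged fraction, exact screw geometry. They
deliberately omit instrument pathologies — salt adducts, detector
saturation, non-saturable binding backgrounds, bleed-through, coordinate
noise — so a passing test shows the estimator is correct *under the
model*, not that the model exhausts real data. The FP noise level (2% of
span) and MS noise (5%) are conservative relative to visually clean
published titrations; they are free knobs, and the recovery tests are
statements about those levels.

Simulation sizes used by the tests and the acceptance script — 200
titration replicates, 10–20 spectra, $10^5$ swap steps, 1000-oligomer
populations — were chosen as the smallest sizes at which the medians and
frequencies under study are stable to well within the tolerances asserted.

## Known limitations

- The competition model inherits its two assumptions (shared $K_D$,
  trace label); outside that regime the exact cubic treatment would be
  needed, which is out of scope.
- Charge inference needs at least two peaks per envelope and charges
  ≤ 60; single peaks are unassignable by design.
- The exchange model is combinatorial, not kinetic: no rates, no
  free-energy model of ring opening.
- The ENM is a uniform-spring Cα network; absolute frequencies are not
  meaningful, and comparisons should use mode shapes and overlaps
  (`mode_overlap()`).
- Printed crystallographic RMSDs against deposited structures are not
  reproduced: the relevant coordinates are not bundled, and the package's
  geometric claims are validated on constructed assemblies instead.
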