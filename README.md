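# hubkit

Quantitative models of CaMKII hub assembly and subunit exchange.

The hub (association) domain of Ca²⁺/calmodulin-dependent protein kinase II
assembles 12 or 14 subunits into stacked rings, and activated holoenzymes
exchange subunits with one another — a process implicated in the persistence
of synaptic CaMKII activity. Characterising that behaviour quantitatively
takes several different measurements, each with its own model. `hubkit`
implements those models for R users (structural biologists and biophysicists
analysing titrations, native mass spectra, FRET series and coordinate sets):

- **Fluorescence-polarization binding.** Direct titration
  (`direct_polarization`) and the competition model
  `A = A_f + (A_0 − A_f)·((K_D + P_tot)/P_tot)·[PL]/L_tot`, with `[PL]`
  the 1:1 quadratic root. `fit_fp()` performs multi-start
  Levenberg–Marquardt fitting and returns a classed model object;
  `ic50_from_model()` derives the midpoint inhibition constant and
  `effective_concentration()` the tethered-ligand concentration
  `1/(N_A·(4/3)πr³)`.
- **Native ESI-MS.** Charge-state inference from envelope spacing
  (`infer_charges`), neutral-mass deconvolution with shared-peak intensity
  splitting (`deconvolve`), oligomer/His-tag stoichiometry assignment on the
  `n·m_sub − t·m_tag` lattice (`assign_stoichiometry`), CID product
  prediction (`cid_products`) and abundance ratios (`abundance_ratio`).
- **Exchange-unit combinatorics.** Composition distributions `u·B`,
  `B ~ Binomial(n/u, f)` (`composition_distribution`), the even-parity
  statistic (`parity_fraction`), a dimer-vs-monomer likelihood-ratio test
  (`infer_exchange_unit`), dodecamer↔tetradecamer interconversion by dimer
  units and a conserving stochastic swap simulator (`simulate_exchange`).
- **FRET.** The 614 nm / 510 nm acceptor/donor ratio (`fret_ratio`) and
  trend-tested time courses (`ratio_timecourse`).
- **Structure.** Kabsch superposition, displacement-arrow fields (scale 2,
  ≥ 2 Å threshold), screw-axis ring/spiral geometry with handedness,
  Tirion Cα elastic-network normal modes and interface polar contacts.
- **Synthetic data.** Seeded `gen_*` generators for every input type, each
  embedding its ground truth, so the whole pipeline is testable offline.

## Worked example

Simulate a competition titration at the conditions of the peptide assay
(hub at 10 µM, unlabeled peptide 0–500 µM, 2% noise), refit it, and read
off the dissociation constant and implied IC50:

```r
library(hubkit)
curve <- gen_competition_curve(kd = 90, p_tot = 10, noise = 0.02, seed = 42)
fit   <- fit_fp(data = curve, mode = "competition", p_tot = 10)
summary(fit)
#> Fluorescence-polarization binding fit (competition mode), n = 12
#>    Estimate Std. Error
#> kd 84.16759    8.82344
#> a0  0.20143    0.00133
#> af  0.05779    0.00415
#> Residual standard deviation: 0.002621
#> Model-implied IC50: 99.45 uM at p_tot = 10 uM
```

The fitted `kd` of 84 ± 9 µM brackets the generating 90 µM; the implied
IC50 (~99 µM) is the competitor concentration at the polarization midpoint.

Deconvolve a synthetic native mass spectrum of an equimolar 12-mer/14-mer
hub mixture (15 kDa subunit, 5% intensity noise, 20 ppm m/z noise):

```r
sp <- gen_mass_spectrum(c(12, 14) * 15000, c(1, 1), z_centers = c(24, 26),
                        mz_noise_ppm = 20, intensity_noise = 0.05, seed = 42)
st <- ms_stoichiometry(sp, m_subunit = 15000)
st[c("mass", "mass_sd", "intensity", "n", "t")]
#>       mass  mass_sd intensity  n t
#> 1 180002.1 2.850271 0.9635157 12 0
#> 2 210001.0 3.786322 0.9913702 14 0
abundance_ratio(st, 12, 14)
#> [1] 0.9719031
```

Both stoichiometries are recovered within a few Da of 180/210 kDa and the
abundance ratio is ~1:1, as generated. Finally, test whether a mixed
population exchanged by dimers or monomers:

```r
g <- gen_exchange_populations(1000, n = 4, u = 2, f = 0.5, seed = 42)
g$counts
#>   0   1   2   3   4
#> 268   0 486   0 246
infer_exchange_unit(g$counts)$log_ratio
#> [1] 852.3688
```

Only even long-subunit counts occur (parity fraction 1) and the
log-likelihood ratio strongly favours the dimer-unit model.

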