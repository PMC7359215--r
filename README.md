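# celldose

Cellular dosimetry and radiobiology for Auger-electron-emitting
radiopharmaceuticals in R.

When a radionuclide such as <sup>99m</sup>Tc decays inside a cell, most of
its electron emission is carried by very short-range Auger electrons and
low-energy conversion electrons, so the absorbed dose depends critically on
*where* in the cell the decays happen: a compound that carries the
radionuclide into the nucleus — onto the DNA — can deliver an order of
magnitude more dose to the genome than one that stays in the cytoplasm.
`celldose` implements the full analysis chain used to quantify this for
cell-culture experiments with DNA-intercalating <sup>99m</sup>Tc complexes
in PC3 prostate-cancer cells:

1. **Activity bookkeeping** — gamma-counter measurements (cpm) of
   surface-bound, internalized and nuclear fractions are converted to
   activity at the counter efficiency, back-extrapolated to the start of
   incubation with the exponential decay law
   `A(t) = A0 exp(−ln2 · t / T_p)`, and integrated into the cumulated
   activity `Ã = 1.44 T_p A0 (1 − exp(−ln2 · Δt / T_p))` (Bq·s), split
   between nucleus and cytoplasm by the measured nuclear fraction.
2. **MIRD cellular dosimetry** — absorbed doses from the 2×2 cellular
   S-value matrix (Gy per Bq·s for every nucleus/cytoplasm source–target
   pair): `D_N = Ã_N S(N←N) + Ã_Cy S(N←Cy)`, and likewise for the
   cytoplasm. The published <sup>99m</sup>Tc matrix for a 2 µm nucleus in a
   4 µm cell ships as `s_value_tc99m()`.
3. **Monte Carlo transport** — a continuous-slowing-down (CSDA) electron
   transport engine in a concentric-sphere phantom, with the source either
   a central 0.7 µm "chromatin" sphere or homogeneous in a compartment,
   used to compute energy partitions and S-values for arbitrary discrete
   electron spectra down to a 10 eV transport floor.
4. **Radiobiology** — plating efficiency, survival fractions, the
   single-hit exponential survival model `SF = exp(−κD)` fitted on the log
   scale, IC₅₀ on the activity axis, and relative biological effectiveness
   against a reference radiation: `RBE_0.5 = κ_test/κ_ref` and
   `RBE_2Gy = exp(2(κ_test − κ_ref))`, with delta-method uncertainties.
5. **Synthetic data** — seed-deterministic generators for uptake tables
   (saturable internalization, Poisson counting noise, truncated-normal
   nuclear fractions) and survival curves, so the whole pipeline is
   testable end to end without any measured data.

## Worked example

```r
library(celldose)

# synthetic uptake experiment for the high-nuclear-uptake compound
tab <- generate_uptake_table(uptake_model_params("C3"),
         activities_bq = c(1.85e5, 7.4e5, 1.85e6, 7.4e6), seed = 1)

res <- run_dose_mird(tab, cells_per_sample = 5e4)
res$summary
#>   compound mean_nuclear_dose_share mean_cell_dose_gy
#> 1       C3                  0.8459              6054
```

With this seed the generated nuclear uptake fractions average close to
0.45, and the S-value arithmetic puts **84–85% of the total cell dose in
the nucleus** — the signature of a DNA-binding Auger emitter. (Absolute
doses scale with the measured count magnitude and the per-cell
normalization `cells_per_sample`; the dose *share* is scale-invariant and
is the robust output.)

The Monte Carlo engine, with all decays in a central 0.7 µm chromatin
sphere and a Tc-99m-like fixture spectrum:

```r
mc <- run_dose_mc(toy_spectrum("tc99m_like"), n_histories = 1e5, seed = 1)
mc
#> MC transport [central_sphere source, 100000 histories/line, seed 1]
#>   E/decay emitted 15.94 keV: nucleus 2.517, cytoplasm 0.1837, escaped 13.24 keV
#>   S(N<-src) = 0.01203 +/- 2.5e-07, S(Cy<-src) = 0.0001255 +/- 1.6e-08 Gy/(Bq.s)
#>   nuclear dose share 98.97%
```

The sub-keV Auger lines and the ~1.8 keV conversion electrons stop within
a fraction of a micron of the source, so ~99% of the intracellular dose
lands in the nucleus; the ~120 keV conversion electrons (13.2 of the
15.9 keV emitted per decay) simply leave the cell. In the MIRD-like
homogeneous-nucleus configuration the same engine reproduces the published
S(N←N) within a few percent:

```r
v <- validate_mird_agreement(toy_spectrum("tc99m_like"), n_histories = 1e5, seed = 1)
#> S_MC = 0.01161 +/- 2.8e-06, ref 0.0119, deviation -2.46%
```

RBE from two fitted survival slopes:

```r
rbe(survival_fit(0.3, 0.02), survival_fit(0.6, 0.05))
#> RBE vs 60Co: RBE_0.5 = 2 +/- 0.19, RBE_2Gy = 1.82 +/- 0.2
```

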