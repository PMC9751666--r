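# osteorad

Tools for mouse radiobiology studies that compare **chronic internal
low-dose-rate (LDR) exposure** to bone-seeking β emitters (Ca-45, Sr-89)
with **acute external high-dose-rate (HDR) irradiation**, and ask what the
two regimes do to lifespan, blood counts, serum bone-turnover markers, and
the microstructure of long bones.

The package provides four things a desk analyst needs for such a study:

1. **Internal β dosimetry.** A closed-form dose model for an injection
   schedule of a β emitter fixed in mineralized bone.  Each injection `i`
   at age `t_i` contributes a dose rate `r0_i · 2^(−(t−t_i)/T½)` (physical
   half-life `T½`; for calcium in bone the biological half-life is decades,
   so physical decay dominates — `retention_consistency()` checks that
   assumption against excretion data).  Cumulative dose follows the closed
   form `D(t) = Σ_i r0_i · (T½/ln 2) · (1 − 2^(−(t−t_i)/T½))`.  Supporting
   constants: the equilibrium dose constant `Δ = n̄ Ē × 1.602·10⁻¹³`
   Gy·kg/(Bq·s) and the Katz–Penfold β range
   `R[g/cm²] = 0.412 E^(1.265 − 0.0954 ln E)`.
2. **μCT morphometry.** Trabecular and cortical microstructure metrics on
   3D binary volumes: BV/TV, Tb.Th and Tb.Sp by distance-transform sphere
   fitting, Tb.N = 1/(Tb.Th + Tb.Sp), the structure model index
   SMI = 6·V·S′/S² (0 plates, 3 rods, 4 spheres), connectivity density
   Conn.D = (1 − χ)/TV with the 3D Euler characteristic χ computed on the
   closed cubical complex (26/6 connectivity), and midshaft cortical
   Tt.Ar, Ct.Ar, Ct.Ar/Tt.Ar, Ct.Th.  Preprocessing matches μCT practice:
   5×5×5 median filter and an inclusive density threshold at 334 mg/cm³
   from phantom calibration.
3. **Cohort statistics.** The statistical layer such studies report:
   per-group Kolmogorov–Smirnov normality gate choosing Welch's t or the
   Mann–Whitney U test, one-way ANOVA with Tukey contrasts, Kaplan–Meier
   curves with the Gehan–Breslow–Wilcoxon weighted log-rank test
   (weights = number at risk; asymptotic or label-permutation p), marker
   fold-change-over-time summaries, and biopsy-table percentages.
   Significance at p < 0.05, trend at p < 0.075, two-sided throughout.
4. **Synthetic data.** Deterministic bone phantoms with closed-form metric
   values (plates, rods, balls, tori, loop lattices, annular shafts, a
   stylized femur) plus grayscale/noise wrappers, and cohort/excretion
   simulators that emulate the study design (group sizes and sex splits,
   Gompertz lifespans with a proportional-hazards exposure effect,
   transient vs sustained WBC suppression, the marker trend pattern).

## Worked example

```r
library(osteorad)

# Two i.p. injections of 1 uCi/g Ca-45 at 4 and 7 weeks of age; calibrate
# the model so the dose rate just after the second injection is 29 mGy/day.
m <- dose_model()
summary(m)
#> <dose_model> Ca-45, 2 injection(s) at 4, 7 wk [pinned_peak_rate]
#>   r0: 15.15, 15.15 mGy/day; phi = 0.9, retention = 0.879, ddref = 1
#> Absorbed dose summary:
#>  age_weeks dose_rate_mGy_day cumulative_Gy
#>       34.3            12.867         4.098
#>       57.6             6.431         5.612
#>       80.9             3.214         6.368
```

The three cumulative doses (4.10, 5.61, 6.37 Gy) fall inside the published
envelopes for this protocol (3.7–4.8, 5.4–7.1, 6.3–8.2 Gy at 34.3, 57.6
and 80.9 weeks of age), and the dose-rate column spans the chronic LDR
range (≤ 29 mGy/day).

```r
# Morphometry on a synthetic femur through the full pipeline:
ph  <- make_phantom("femur_like")
g   <- make_gray_phantom(ph$volume, noise_sd = 50, seed = 1)
seg <- threshold_density(median_filter_3d(g$volume), g$calibration)
trabecular_metrics(select_voi(seg, ph$voi$trabecular))
#>   BV/TV Tb.Th Tb.Sp Tb.N      SMI    Conn.D
#> 1    20   0.1   0.4    2  4.8e-14 -2.441406
```

which recovers the phantom's analytic values (BV/TV 20 %, Tb.Th 0.100 mm,
Tb.Sp 0.400 mm, Tb.N 2.0 /mm, plate-like SMI ≈ 0) despite the added scanner
noise.  `run_end_to_end_demo(seed = 17)` chains cohort simulation,
survival testing, marker fold changes, phantom morphometry and the dose
model into one reproducible report.

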