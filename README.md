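# spinefea

Dual-modality analysis of lumbar vertebral bone for R. Osteoporosis
and diffuse osteoblastic (bone-forming) metastases both remodel
vertebrae, in opposite directions: metastatic sclerosis stiffens the
bone and displaces fatty marrow, osteoporosis weakens the bone while
marrow fat accumulates. The package implements the two quantitative
probes that capture this, and the statistics that compare them:

* **CT-based finite elements.** Hounsfield units are calibrated to
  density and then to a transversely isotropic constitutive model
  (axial modulus `E_z = 4730 ρ_app^1.56` MPa, strength limits
  `σ_max = 137 ρ_ash^1.88` / `114 ρ_ash^1.72` MPa around
  ρ_ash = 0.317 g/cm³, `σ_min = 65.1 ρ_ash^1.93` MPa, post-yield
  strain cap `ε_AB = −0.00315 + 0.0728 ρ_ash`). The segmented body is
  meshed with linear tetrahedra (C3D4, Kuhn subdivision), compressed
  under displacement control with principal-stress yield and
  crack-band-regularized element kill, and the **failure load** (N)
  and **failure displacement** (mm) are read off the load-displacement
  curve.
* **Chemical-shift-encoded MRI.** Six-echo complex gradient-echo
  signals (TE = 1.12 + 0.96 k ms) are modelled as water plus a
  seven-peak fat spectrum with a single R2\* and a smooth field map;
  voxel-wise variable projection inverts the model and
  **PDFF = 100 · |ρ_F| / (|ρ_W| + |ρ_F|)** (%) is averaged per
  vertebra.
* **Cohort statistics.** Fracture-flagged vertebrae are excluded;
  medians and type-7 IQRs summarize each group; Mann-Whitney
  (asymptotic, uncorrected) compares groups on patient-level medians;
  Spearman's rho with Fisher-z 95 % CIs correlates PDFF with the FE
  measures; Friedman tests within-patient level differences.

Synthetic generators (CT phantoms with a cortical shell and
stochastic trabecular interior, multi-echo signal simulation, cohort
tables) make the whole pipeline runnable without patient data, and a
packaged 7-patient × 4-level measurement fixture
(`table1_fixture()`) anchors the statistics stage to reference
values. See the methods vignette
(`vignettes/vertebral-strength-and-marrow-fat.Rmd`) for model
details, parameter rationale and limitations.

## Worked example

```r
library(spinefea)

## cohort statistics from the packaged fixture
print(cohort_report(table1_fixture()))
```

```
Pooled group summaries (non-fractured vertebrae):
        group                 measure  n median      q1      q3
   metastasis            pdff_percent 12  11.85    9.25  24.625
 osteoporosis            pdff_percent 11   43.8    41.3   45.75
   metastasis failure_displacement_mm 12  0.874 0.79675 0.95125
 osteoporosis failure_displacement_mm 11  0.348   0.306   0.503
   metastasis          failure_load_N 12  29589 26251.5   46902
 osteoporosis          failure_load_N 11   3095  2669.5    3926

Group comparisons on patient medians (Mann-Whitney):
  pdff_percent: U = 0, p = 0.034
  failure_displacement_mm: U = 12, p = 0.034
  failure_load_N: U = 12, p = 0.034

PDFF correlations on patient medians (Spearman):
  pdff_vs_displacement: rho = -0.679 (95% CI -0.947 to 0.152), p = 0.094
  pdff_vs_load: rho = -0.893 (95% CI -0.984 to -0.427), p = 0.007
```

Metastatic vertebrae show low marrow fat (pooled median PDFF 11.9 %
after rounding) but high strength (29,589 N), osteoporotic vertebrae
the reverse (43.8 %, 3,095 N); PDFF correlates strongly and
negatively with both FE measures across the seven patients.

```r
## synthetic vertebra: phantom -> mesh -> materials -> compression
ph   <- make_vertebra_phantom(phantom_truth("osteoblastic", seed = 1))
mesh <- mask_to_mesh(ph$mask, ph$ct, edge_length_mm = 2)
res  <- run_compression(mesh, map_elements(ph$ct, mesh),
                        max_displacement_mm = 0.04 * 26,
                        n_increments = 80, max_state_iter = 2000)
coef(res)        # failure load (N) and failure displacement (mm)
plot(res)        # load-displacement curve with the failure point

## PDFF round trip on a simulated voxel
fit_voxel(forward_signal(0.6, 0.4, psi_hz = 30, r2star_s = 40))
```

The voxel fit recovers PDFF 40 %, ψ = 30 Hz and R2\* = 40 s⁻¹ to
numerical precision from the noiseless six-echo signal.

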