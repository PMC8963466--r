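# imucheck

Independent monitor-unit (IMU) second-check QA for high-field MR-Linac
online adaptive plans, as an offline, file-based R pipeline.

## The problem

Online adaptive radiotherapy on a 1.5 T MR-Linac produces a fresh plan at
every fraction, under time pressure, and each plan needs an independent dose
verification before delivery. The pragmatic second check is a recalculation
in a conventional treatment planning system (TPS) — but the MR-Linac's
planning system writes DICOM in its own dialect (SAD 143.5 cm, collimator
fixed at 0°, MLC positions under tag `MLCY`, a fixed 22 cm
superior–inferior jaw with no Y jaw entries in the file), and a conventional
dose algorithm knows nothing of the magnetic field that laterally distorts
dose in the patient, nor of the posterior RF coil that attenuates posterior
beams.

`imucheck` implements the full second-check chain for medical physicists
and QA-tool developers:

1. **Plan conversion** — the three-rule Monaco→Eclipse dialect transform:
   rescale all collimation from the 143.5 cm to the 100 cm plane (factor
   `100/143.5`, i.e. ÷1.435; the ±11 cm physical jaw projects to ±7.67 cm),
   switch to extended-SSD technique so the physical source distance is
   retained, relabel the energy 7MV-FFF→6MV-FFF, swap `MLCY`→`MLCX` with
   collimator 0°→90°, and derive X jaws from the open-leaf envelope + 5 mm
   margin (or fixed ±7.67 cm). MU are untouched.
2. **Plane comparison** — per beam, both 3D dose grids are resampled on the
   BEV-parallel plane through the plan reference point; the reference
   (B-field-aware) plane is shifted 2 mm along the BEV-Y axis
   (perpendicular to both the B-field and the beam axis) to stand in for
   the magnetic-field effect, and the evaluated dose of posterior beams
   (gantry in [100°, 260°]) is multiplied by 0.978 for the 2.2%
   posterior-coil attenuation.
3. **Gamma scoring** — 2D gamma restricted to the beam's complete
   irradiated area outline (CIAO), with global normalization to the
   reference maximum over the ROI:

   γ(r) = min over e of √( |e−r|²/δ² + (Dₑ(e)−Dᵣ(r))²/(p·D_max/100)² )

   at 3%/3 mm (primary, 95% per-beam threshold) and 3%/2 mm
   (informational), plus a point-dose cross-check and a pass/fail
   contingency analysis against a second QA modality.
4. **Synthetic fixtures** — a deterministic toy divergent-beam engine
   (inverse square × attenuation × penumbra-convolved aperture fluence ×
   FFF falloff × couch/coil slabs; 1 cGy/MU at depth 5 cm, SSD 138.5 cm)
   generates matched and deliberately mismatched cases, so the whole chain
   is testable without either commercial engine.

## Worked example

Build a four-beam synthetic case, sabotage beam 3 with an 8% MU error, and
run the check from files:

```r
library(imucheck)
case <- make_synthetic_case(n_beams = 4, seed = 42, dir = "demo")
case <- inject_mismatch(case, "mu_error", 8, beam = 3)
case <- write_case(case, "demo")
report <- run_imu("demo/rtplan.dcm", "demo/reference", "demo/evaluated")
report
#> <imu_report> synth: 4 beams, plan verdict FAIL
#> <pass_rate_summary> 3/4 beams pass at 95%; mean 84.3% (sd 31.3, range 37.4-100.0)
render_report(report, "demo/report.txt")
```

The rendered report:

```
independent monitor-unit second check -- per-beam gamma report
plan: synth   machine: SyntheticMRL
criteria: 3%/3 mm, 3%/2 mm (primary first); threshold 95%; reference shift -2.0 mm along BEV-Y
posterior coil factor 0.978 for gantry in [100, 260] deg

 beam  gantry post.    coil pass_3%/3 mm pass_3%/2 mm   ptdiff%  verdict
    1    41.2    no   1.000       100.0%       100.0%      0.00     pass
    2   133.8   yes   0.978       100.0%       100.0%     -0.00     pass
    3   222.0   yes   0.978        37.4%        31.4%      8.00     fail  <-- FAIL
    4   307.0    no   1.000       100.0%       100.0%      0.00     pass

plan summary: 3/4 beams pass at 95%; mean 84.3% (sd 31.3, min 37.4, max 100.0)
plan verdict: FAIL
```

Reading it: the three untouched beams agree to 100% at both criteria — the
2 mm shift undoes the emulated B-field displacement and the 0.978 factor
undoes the coil attenuation of the two posterior beams (gantry 133.8° and
222.0°), so reference and evaluated overlay almost perfectly. The
mismatched beam fails decisively (37.4% ≪ 95%), and its +8.00% point-dose
difference names the cause. A command-line wrapper with `convert`,
`simulate`, `check` and `contingency` subcommands lives at
`inst/cli/imucheck.R`.

## Layout

| Path | Contents |
| --- | --- |
| `R/dicom-core.R` | minimal DICOM Part-10 codec (explicit VR LE, sequences) |
| `R/rt-model.R` | plan/beam/control-point/dose-grid model, RT Plan & RT Dose I/O, validation |
| `R/plan-convert.R` | the three-rule dialect conversion |
| `R/dose-ops.R` | BEV plane frames, trilinear resampling, shift, coil correction |
| `R/ciao.R` | aperture polygons, CIAO rasterization, ROI exclusion |
| `R/gamma.R` | gamma engine + exhaustive brute-force oracle |
| `R/synth.R` | toy dose engine, synthetic cases, mismatch injection |
| `R/pipeline.R`, `R/sensitivity.R` | end-to-end run, reports, contingency, sensitivity suite |
| `vignettes/imu-second-check.Rmd` | the methods vignette: model, parameters, design choices, limitations |
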