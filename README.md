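# spotrobust

Spot delivery errors meet plan robustness for pencil-beam scanning (PBS)
proton therapy.

In intensity-modulated proton therapy (IMPT) a plan is delivered spot by
spot, and the machine logs what it actually delivered — pulse by pulse.
Delivered spot positions and monitor units (MU) differ slightly from the
plan, but conventional robustness evaluation perturbs only patient setup
(± rigid shifts) and stopping-power calibration (± density), never the
delivery itself. `spotrobust` implements the full workflow that closes
that gap, end to end, on synthetic data:

1. **Synthesize** voxel phantoms, optimized-like treatment plans
   (beams → energy layers → spot lattices → aperture polygons), pulse-level
   machine log files with a known injected error structure, and 11×11 QA
   spot grids measured at 0.5 mm detector resolution.
2. **Aggregate** pulses into delivered spots by the MU-weighted mean, and
   quantify measured-vs-recorded agreement (per-axis Δ statistics, RMS,
   combined RMS, Gaussianity summary).
3. **Learn** the planned→delivered mapping with a shallow feedforward
   network — 6 inputs (target x, y, MU, gantry angle, snout extension,
   energy) → 5 tanh hidden neurons → 3 linear outputs (delivered x, y,
   MU) — trained 70/15/15 with Levenberg–Marquardt least squares and
   validation-based early stopping.
4. **Inject** the predictions back as a *pseudo log file* (PLF) and
   recompute dose with an analytic pencil-beam engine
   (plateau + Bragg-peak depth dose × lateral Gaussian, aperture
   collimation with boundary-inclusive spot deletion, D99-based
   normalization).
5. **Evaluate robustness** over the standard 16-scenario set
   (8 corner setup shifts × ±3.5% density), producing per-scenario DVHs,
   banded-DVH envelopes, worst-case DVH index tables, plan-vs-plan
   difference tables and a 95/95 verdict
   (pass iff every scenario keeps ≥95% of the CTV at ≥95% of
   prescription).

The core statistic of the QA module is the root-mean-square disagreement
per axis, RMS_x = [(Δx₁² + … + Δxₙ²)/n]^½ with Δ = (log-recorded −
measured), combined in quadrature as RMS_xy = √(RMS_x² + RMS_y²). The
delivered spot is x_del = Σᵢ xᵢ·MUᵢ / Σᵢ MUᵢ over its pulses.

## Worked example

```r
library(spotrobust)

# a phantom with a spherical CTV, and a two-beam plan with generous margins
ph <- generate_phantom(phantom_spec(
  dim_vox = c(40, 40, 32), spacing_mm = c(2.5, 2.5, 2.5),
  structures = list(struct_sphere("CTV", c(0, 0, 0), 15))))
plan <- generate_plan(ph, plan_spec(preset = "apbi", spot_spacing_mm = 7,
  layer_spacing_mm = 5, depth_margin_mm = 12, aperture_margin_mm = 18))
norm <- normalize_plan(plan, ph)    # D99(CTV) = 3000 cGy(RBE)

# deliver it (synthetically), train the error model, predict the delivery
truth <- error_truth(systematic_x_mm = 0.8, systematic_y_mm = -0.5,
                     random_sigma_x_mm = 0.4, random_sigma_y_mm = 0.4)
logs  <- generate_log_files(norm$plan, truth, pulses_per_spot = 3, seed = 5)
ds    <- assemble_dataset(logs)
model <- train_error_model(ds$features, ds$targets, train_config(seed = 6))
model
#> <spot_error_model> 6-5-3 network (levenberg_marquardt)
#>   split 1159/248/249; test MSE(std) 0.0004313; test R2 raw 0.99985 / std 0.99946

# robustness of the plan as-predicted, under the 16 standard scenarios
plan_ml <- plan_with_spots(norm$plan, predict_plan(model, norm$plan))
ev  <- evaluate_scenarios(plan_ml, ph, structures = "CTV",
                          scenarios = generate_scenarios(scenario_config(shift_mm = 5)))
chk <- robustness_check(ev)
chk$pass
#> [1] TRUE
chk$worst_v95_pct
#> [1] 100
```

The model report reads: trained on 1159 spots, validated and tested on
~249 each; the standardized-target test MSE and R² say the network
explains >99.9% of the target variance. The verdict says
that even with every spot displaced as the model predicts, all 16
setup/density scenarios keep 100% of the CTV above 95% of the
prescription — the plan's margins absorb both delivery and setup error.

A QA-style agreement table (the same layout clinics print for
measured-vs-logged spot positions) comes from
`qa_agreement_table(lapply(c(0, 90, 180), generate_qa_grid, truth = truth))`,
and `run_pipeline(pipeline_config(workspace = "ws"))` orchestrates all
stages (synth → qa/train → predict → dose → robust → report) with
per-stage manifests and byte-reproducible reruns from one seed.

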