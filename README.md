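# retlesion

An R toolkit for the computational pipeline of image-guided retinal laser
lesioning with multimodal OCT/SLO imaging in the mouse eye. Laser-induced
photodamage is a standard way to model retinal injury, but manual laser
aiming is imprecise and gives no quantitative feedback on lesion location or
severity. The pipeline implemented here addresses that end to end, entirely
in software:

- **Aiming calibration** — fit a 2D polynomial mapping galvanometer command
  voltages to retinal positions, `x(v) = Σᵢⱼ cᵢⱼ vxⁱ vyʲ` per axis, from
  lesion offsets measured on a grid target; invert it by damped Newton
  iteration for sub-0.1 µm targeting.
- **OCT volume processing** — repeat-averaging of B-scans, robust RPE/OPL
  surface detection, digital flattening, and layer-bounded en face
  projections over the half-open [OPL, RPE) slab.
- **SLO stack processing** — respiratory-motion frame rejection
  (phase-correlation score and displacement gates), sub-pixel rigid
  registration, averaging, and quantification of tdTomato red→green
  fluorescence photoconversion as the bounded index `p = G′/(G′+R)`.
- **OCT–SLO co-registration** — grid-landmark detection, robust matching,
  and a polynomial SLO→OCT unwarp with inverse-mapping resampling.
- **Lesion planning** — focal site plans and extended-area raster patches at
  50 % spot-size overlap (centre pitch = half the spot diameter), with
  treatment/exclusion masks, coverage reports, and compilation into
  calibrated firing schedules (per-pulse voltages, onsets, powers).
- **Automated lesion segmentation** — a compact 2D U-Net over flattened
  B-scans (implemented natively in R, backprop verified against numerical
  gradients), trained with cross-entropy + soft-Dice, evaluated by seeded
  80/20 splits and 5/10-fold cross-validation with the Dice coefficient,
  plus per-lesion volume/area/thickness morphometrics.
- **A synthetic retina phantom** — layered murine retina with curvature,
  vessel shadows, multiplicative speckle, a saturating RPE-anchored lesion
  dose–response, photoconversion, and Poisson-timed respiratory motion —
  generating every input with exact ground truth, so the whole pipeline is
  testable without hardware.

See `vignettes/methods.Rmd` for the models, defaults, and their rationale.

## Worked example

Plan a lesion patch on a synthetic retina, compile it against a calibration,
and quantify the outcome:

```r
library(retlesion)

# a small phantom retina (96 x 96 A-scans, 3 repeats) with vessel shadows;
# SLO geometry scaled down from the default 1024 px / 200 frames
p <- phantom_params(shape = c(y = 96, x = 96, z = 96),
                    pitch = c(x = 6, y = 6, z = 3), repeats = 3,
                    slo = list(size = 256L, n_frames = 30L, frame_rate = 7.8,
                               tdtomato_level = 0.6, gfp_baseline = 0.12,
                               texture_amp = 0.15, texture_scale_um = 100,
                               noise_sd = 0.02),
                    seed = 1)
g <- generate_retina_volume(p)
n_frames(g$volume)
#> [1] 288

# process: average repeats, detect surfaces, flatten, project
proc <- process_oct(g$volume)
round(stats::sd(detect_surface(proc$flat, "RPE")$depth), 2)
#> [1] 0.12          # flattened RPE is level to ~0.1 voxel

# calibrate aiming from a simulated grid target with quadratic distortion
cx <- matrix(0, 3, 3); cx[2, 1] <- 750; cx[3, 1] <- 12
cy <- matrix(0, 3, 3); cy[1, 2] <- 750; cy[2, 2] <- 8
gt <- generate_grid_target(distortion = list(coeffs_x = cx, coeffs_y = cy))
cal <- fit_voltage_map(data.frame(vx = gt$landmarks$vx, vy = gt$landmarks$vy,
                                  x_um = gt$landmarks$x_obs_um,
                                  y_um = gt$landmarks$y_obs_um), degree = 2)
glance(cal)
#> # A tibble: 1 × 3
#>   degree n_pairs rms_residual_um
#>    <int>   <int>           <dbl>
#> 1      2      49        5.39e-14

# raster a 50%-overlap patch between vessels and compile the schedule
treat <- matrix(FALSE, 96, 96); treat[20:70, 55:90] <- TRUE
plan <- plan_patch(treat, g$truth$vessel_mask, pitch_um = 6,
                   spot_diameter_um = 50, overlap = 0.5,
                   laser = laser_params(6, 200, repeats = 4, interval_ms = 50))
plan
#> <lesion_plan> 56 sites, spot 50 µm, overlap 50%
sched <- compile_schedule(plan, cal)
nrow(sched); sum(sched$power_mw * sched$duration_ms) / 1000
#> [1] 224        # 56 sites x 4 pulses
#> [1] 268.8      # total delivered energy, mJ

# deliver the plan in the phantom and read the damage out on SLO
les <- g
for (i in seq_len(nrow(plan))) {
  les <- apply_lesion(les$volume, c(plan$x_um[i], plan$y_um[i]),
                      laser_params(6, 200, repeats = 4), p, les$truth)
}
gen_post <- generate_slo_sequence(p, les$truth$sites)
pre  <- process_slo(generate_slo_sequence(p, NULL)$sequence, max_disp_px = 4)
post <- process_slo(gen_post$sequence, max_disp_px = 4)
pmap <- photoconversion_map(pre, post)
round(conversion_in_mask(pmap, gen_post$truth$phi_map > 0.5), 2)
#> [1] 0.88       # near-complete conversion at 4-pulse severity
```

The numbers printed above are what the code produces at these seeds: 288
acquisition frames (96 positions × 3 repeats), a flattened RPE level to
0.12 voxel, a machine-precision calibration fit on noise-free synthetic
offsets, a 56-site patch whose 224 pulses carry 268.8 mJ in total, and a
mean photoconversion index of 0.88 inside the strongly converted footprint —
high-severity (4-pulse) damage converts most of the tdTomato signal.

Training and evaluating the segmenter on the standard synthetic benchmark:

```r
ds <- make_segmentation_benchmark(n = 60, seed = 5)
sp <- split_dataset(ds, 0.8, seed = 3)          # 48 train / 12 held out
m  <- train_segmenter(ds, seg_config(max_epochs = 8, seed = 2), split = sp)
round(mean(sapply(sp$val, function(v)
  dice(segment(m, ds$volumes[[v]])$mask, ds$masks[[v]]))), 2)
#> [1] 0.93       # held-out Dice
```

## Command-line use

A thin CLI over the same functions is installed at `inst/cli/retlesion`
(`simulate`, `calibrate`, `coregister`, `process-oct`, `process-slo`,
`plan-patch`, `compile`); run it with `Rscript` and `--help`-style usage in
the script header.

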