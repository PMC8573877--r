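# psirsynth

Calculated bright-blood and dark-blood PSIR LGE from joint cardiac T1/T2
mapping — a simulation and analysis toolkit for the "all-in-one"
multi-parametric cardiac MR workflow.

## The problem

Late gadolinium enhancement (LGE) imaging nulls normal myocardium so that
focal scar appears bright, but conventional bright-blood (BB) LGE often has
poor contrast between subendocardial scar and the adjacent blood pool, and
quantitative post-contrast T1/T2 maps lack the visual contrast clinicians
expect for scar. Acquiring BB LGE, dark-blood (DB) LGE and both relaxation
maps separately costs several breath-held or free-breathing scans.

A single free-breathing multi-parametric saturation-recovery acquisition
(mSASHA: 30 single-shot images over 45 heartbeats — anchor images with long
recovery, saturation-recovery images with TS = 300 ms, and
saturation-recovery images with an additional T2 preparation, TE = 55 ms)
supports a pixel-wise *joint* three-parameter fit of amplitude, T1 and T2.
From the fitted rate maps (R1 = 1000/T1, R2 = 1000/T2, in Hz) both LGE
contrasts are then *calculated* rather than acquired, using a formulation
that is linear in gadolinium concentration:

- **Bright blood:**  `BB = R1 − R1m`, which nulls normal myocardium
  (R1 = R1m) and grows linearly with contrast uptake;
- **Dark blood:**  `DB = R1 − R1m / (a_DB · R2/R2m + (1 − a_DB))`, which
  still nulls normal myocardium (R2 = R2m there) while pinning the blood
  pool at an adjustable level `LGEb` (−0.5 Hz by default). The weight

  `a_DB = (R1m·R2m/(R1b − LGEb) − R2m) / (R2b − R2m)`

  is the analytic solution of the blood-anchoring condition
  `DB(R1b, R2b) = LGEb`.

Here (R1m, R2m) and (R1b, R2b) are the normal-myocardium and blood-pool
rates, estimated as the median T1/T2 over segmentation masks.

The package provides the closed-form signal models, a heartbeat-accounted
protocol scheduler, digital phantoms (a nine-vial relaxometry plate and a
short-axis cardiac slice with scar), the joint nonlinear least-squares
fitter, the PSIR synthesis (including blood-suppression sweeps and an
edema-attenuation analysis), and a Monte-Carlo procedure for SNR/CNR of the
calculated images, plus NIfTI + JSON-sidecar I/O and a `psirsynth` command
line (`exec/psirsynth`).

## Worked example

Simulate a chronic-infarct short-axis slice, fit the maps, and calculate
both LGE images:

```r
library(psirsynth)

p <- default_msasha_protocol()
p
#> Protocol 'msasha-default': 30 images over 45 heartbeats (RR = 1000 ms)
#>   anchor     x 3
#>   SR         x 21
#>   SR+T2prep  x 6

ph     <- make_cardiac_phantom("chronic_mi")
series <- simulate_series(ph, p, snr = 40, seed = 1)
maps   <- fit_maps(series, p, mask = matrix(ph$label_map > 0, 128))

ref <- tissue_reference_from_maps(maps,
  myo_mask   = region_mask(ph, c("remote", "MI")),
  blood_mask = region_mask(ph, "blood"))
ref
#> PSIR tissue reference (Hz): R1m = 1.5, R2m = 23.54, R1b = 2.145, R2b = 7.011
#>   LGEb = -0.5 -> a_DB = 0.6165

bb <- calc_bb_psir(1000 / maps$T1, ref)
db <- calc_db_psir(1000 / maps$T1, 1000 / maps$T2, ref)
for (r in c("MI", "remote", "blood"))
  cat(sprintf("%-7s BB %+6.3f Hz   DB %+6.3f Hz\n", r,
              mean(bb$values[region_mask(ph, r)]),
              mean(db$values[region_mask(ph, r)])))
#> MI      BB +0.768 Hz   DB +0.734 Hz
#> remote  BB -0.003 Hz   DB +0.000 Hz
#> blood   BB +0.647 Hz   DB -0.498 Hz
```

Reading the numbers: in both images the scar is strongly positive
(~0.75 Hz, it enhances) and the remote myocardium is nulled (~0 Hz). In the
bright-blood image the blood pool (+0.65 Hz) is nearly as bright as the
scar — the classic subendocardial-detection problem — while in the
dark-blood image the blood is pinned near the requested LGEb = −0.5 Hz,
well below the nulled myocardium, so the scar–blood border stands out.

The same rate maps support quantitative reasoning: blood T2 shortening from
a native 250 ms to 142 ms post-contrast implies

```r
gd_concentration_from_r2(250, 142)   # r2 = 5.85 /s/mmol/L
#> [1] 0.52
```

i.e. about 0.52 mmol/L of gadolinium.

One call runs the whole chain and writes the four co-registered NIfTI
outputs (T1 map, T2 map, BB PSIR, DB PSIR) plus a provenance report:

```r
run_all("chronic_mi", snr = 40, seed = 1, out = "bundle/")
```

or from a shell: `psirsynth run-all --scenario chronic_mi --snr 40 --seed 1 --out bundle/`.

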