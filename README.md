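# ewtqc — withdrawal quality control for colonoscopy video

Adenoma detection during colonoscopy depends on how carefully the mucosa is
inspected while the scope is withdrawn. Total withdrawal time (WT) is the
traditional quality indicator, but WT also counts time spent on biopsies and
polypectomies and time lost to irrigation, darkened screens and motion blur.
`ewtqc` implements frame-level accounting of the **effective withdrawal
time**

```
EWT = WT − Time 1 − Time 2
```

where WT runs from the first sustained detection of the ileocecal landmark
to the end of the video, Time 1 is the duration of instrument operations,
and Time 2 is the duration of non-interpretable frames. The package is
aimed at endoscopy quality-control researchers who want a testable,
self-contained reference pipeline for EWT accounting and withdrawal-speed
monitoring.

Three per-frame signals drive the accounting:

* **Classification** — each frame is labelled `ileocecal`, `instrument` or
  `normal`. The classifier is a pluggable contract: a sidecar stub (reads a
  ground-truth CSV), a marker heuristic matched to the synthetic generator,
  or any external callable (e.g. an exported network) via
  `adapter_classifier()`.
* **Blur detection** — the variance of the 3×3 Laplacian response,
  `Var_L = Var(∇²I)`; a frame with `Var_L < 50` (configurable) is blurred
  and, when not an instrument frame, counts toward Time 2.
* **Speed monitoring** — a 64-bit DCT perceptual hash per frame; the
  Hamming distance `D` between consecutive hashes proxies scope speed,
  colour-coded blue/normal (`D ≤ 20`), yellow/warning (`21 ≤ D ≤ 30`),
  red/danger (`D > 30`).

A deterministic synthetic-video generator (`generate_scenario()`) renders
withdrawal-like sequences — textured mucosa, an ileocecal marker segment,
instrument chords, blur episodes of controllable Laplacian variance, and
camera motion of controllable hash distance — together with a
ground-truth timeline, so the whole engine is testable without any
clinical data. Evaluation utilities cover the standard classifier metrics
(sensitivity, specificity, precision, accuracy, F1, AP, trapezoidal AUC,
sample-weighted averages) and rater-agreement statistics for paired timing
series (ICC(A,1) with 95% CI, Bland–Altman bias and limits of agreement,
Pearson r, Wilcoxon signed-rank).

## Worked example

Generate a 151-second withdrawal containing a 24 s instrument episode and a
12 s blur episode, then run the engine with the ground-truth stub
classifier:

```r
library(ewtqc)
scenario <- generate_scenario(scenario_case2(seed = 0))
res <- run_engine(scenario$frames, stub_classifier(scenario$sidecar),
                  engine_config(fps = 10))
print(res$summary)
#> Withdrawal summary @ 10 fps
#>   start frame : 80
#>   WT      151.00 s (1510 frames)
#>   Time1    24.00 s (240 frames, instrument)
#>   Time2    12.00 s (120 frames, non-interpretable)
#>   EWT     115.00 s (1150 frames)
#>   speed zones: normal 866 / warning 415 / danger 308
```

The engine recovers the generator's ground truth exactly: the withdrawal
starts at frame 80 (the first of five consecutive ileocecal frames), WT is
2 min 31 s, and after subtracting the instrument and blur time the
effective withdrawal time is 1 min 55 s. The zone counts show how many
inter-frame steps fell in each speed band.

Comparing two timing series (e.g. AI vs. expert EWT measurements):

```r
rep <- agreement(c(310, 451, 288, 522, 384, 406, 333, 476),
                 c(305, 466, 295, 515, 396, 401, 341, 469))
print(rep)
#> Agreement over 8 paired measurements
#>   ICC(A,1) 0.994 (95% CI 0.973-0.999)
#>   Pearson r 0.994 (p = 4.94e-07)
#>   Bland-Altman bias -2.25 s (95% LoA -20.24 to 15.74)
#>   Wilcoxon W = 11.0 (p = 0.36)
```

## Command line

A thin Rscript shim exposes the pipeline as subcommands:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ewtqc.R", package = "ewtqc"))')
Rscript $CLI simulate --scenario case2 --seed 0 --out sim/
Rscript $CLI analyze  --frames-dir sim/frames --labels sim/sidecar.csv \
                      --fps 10 --out results/
Rscript $CLI evaluate --pred pred.csv --truth sim/sidecar.csv --out metrics.json
Rscript $CLI compare  --a ai.csv --b senior.csv --out agreement.json
```

`analyze` writes a per-frame CSV log, a summary JSON and (unless
`--no-overlay`) annotated PNG frames with the WT/EWT timers and the
colour-coded speed scale bar rendered in the upper-left corner.

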