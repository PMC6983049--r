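# fabricmotion

Tools for asking a practical question in wearable sensing: **how well does
an accelerometer mounted on clothing stand in for one worn on the body at
the same site?** Garment-mounted sensors are unobtrusive enough for
long-term activity monitoring, but fabric lags, swings and rotates relative
to the limb underneath. `fabricmotion` implements the full comparison
pipeline for paired tri-axial streams (units of g, 50 Hz by default):

1. **Synchronisation** — detect the jump/tap markers struck at the start of
   a recording, coarse-align on them, then estimate the residual
   inter-sensor lag $\hat\ell$ as the integer shift maximising the
   normalised cross-correlation,
   $\hat\ell = \arg\max_{|k| \le K} r(x_{1:n-k},\, y_{1+k:n})$,
   with ties broken toward synchrony, and trim to overlap.
2. **Orientation** — estimate each stream's gravity direction $\hat g$ and
   rotate it onto the y-axis with the axis–angle (Rodrigues) closed form
   $R = I + \sin\theta\,K + (1-\cos\theta)K^2$, axis
   $\hat g \times e_y$, angle $\operatorname{atan2}(\lVert\hat g \times
   e_y\rVert, \hat g \cdot e_y)$.
3. **Similarity** — cut 30–40 s instances of each diary activity and
   compute per-axis Pearson correlations under five cumulative variants
   (original → time-aligned → rotated → aligned+rotated →
   aligned+rotated with per-activity re-alignment), aggregated as
   median ± variance across instances.
4. **Classification agreement** — classify every sample of both streams
   with a threshold decision tree on the y-axis acceleration and its
   250 ms moving variance (walking/running, transition, sitting,
   standing), and tabulate clothing-vs-body agreement as a row-normalised
   confusion matrix with the body-worn labels as reference.

A synthetic paired-stream generator (gravity-on-y postures, double-peak
gait oscillation at 0.7 s / 0.3 s stride periods, marker spikes, and a
clothing channel distorted by lag, rotation, fabric swing, scaling and
noise) makes the whole pipeline runnable and testable with no recorded
data. See `vignettes/fabricmotion-methods.Rmd` for the models, parameter
choices and limitations.

## Worked example

Simulate a five-segment wear session (stand / walk / sit / run / stand)
whose clothing channel lags by 38 samples, is rotated 15°, swings and is
10% amplitude-scaled — then run the full pipeline:

```r
library(fabricmotion)

cfg <- pipeline_config(
  synth = list(
    config = synth_config(seed = 42, schedule = data.frame(
      label    = c("standing", "walking", "sitting", "running", "standing"),
      duration = c(60, 60, 60, 60, 30))),
    params = clothing_params(lag_samples = 38L, angle = 15 * pi / 180,
                             swing_amp = 0.1, amp_scale = 1.1,
                             noise_sd = 0.02)),
  seed = 42)
rep <- run_pipeline(cfg)
```

The report recovers the injected lag exactly and converts it to seconds:

```
lag: 38 samples = 0.76 s, peak r = 0.9936
```

The five-variant ladder for a walking instance (y-axis) shows what each
correction buys — the raw correlation is destroyed by the 0.76 s lag,
time alignment restores it, and rotation adds the rest:

```
 activity                      variant axis  median_r
  walking                     original    y 0.2268026
  walking                 time_aligned    y 0.9969315
  walking                      rotated    y 0.2670993
  walking              aligned_rotated    y 0.9989694
  walking aligned_rotated_activitywise    y 0.9989694
```

And the classification agreement (rows = body-worn reference, %):

```
                 test
ref               walking_running transition sitting standing
  walking_running           100.0        0.0     0.0        0
  transition                  1.9       98.1     0.0        0
  sitting                     0.0        0.1    99.9        0
  standing                    0.0        0.0     0.0      100
```

Every activity class agrees above 80% on the diagonal; only the brief
transition samples smear, as expected for a per-sample classifier with no
smoothing. (The reported clothing rotation angle, ~31° here, is the
whole-record gravity correction — it folds the seated stretch, whose
gravity is off-axis by design, in with the 15° mounting offset.)

A thin command-line wrapper over the same functions lives at
`inst/cli/fabricmotion.R` (`synth | align | rotate | compare | classify |
run` subcommands); `run_pipeline()` also accepts a YAML config path.

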