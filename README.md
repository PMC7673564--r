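# perfquant

Quantitative perfusion assessment from dynamic indocyanine green (ICG)
fluorescence angiography, with fluorescent-microsphere reference flows and
permutation-based statistics.

## The problem

Visual judgment of tissue perfusion during visceral surgery (gastric tube
formation, colonic resection) is subjective. Dynamic ICG fluorescence
imaging records, at video rate, the first passage of a dye bolus through
the microcirculation; the time–intensity curve *I(t)* of a region of
interest (ROI) carries quantitative perfusion information. `perfquant`
extracts the three standard curve parameters:

- **BSFI** (background-subtracted peak fluorescence intensity):
  `BSFI = max_{t ∈ (t_inj, t_inj + W]} I(t) − I_baseline`, with the
  pre-injection baseline subtracted to cancel residual dye pooled from
  earlier injections (analysis window `W` = 60 s by default);
- **SFI** (slope of fluorescence intensity): the maximal least-squares
  slope of `I(t)` over sliding windows between bolus onset and peak
  (a.u./s) — the parameter most directly driven by vessel blood flow;
- **TTS** (time to slope): the delay from injection to the first
  detectable signal increase, reported as the ratio to a reference ROI at
  the arterial radix.

Absolute regional flow comes from fluorescent microspheres by the
reference-sample method: with a constant-rate arterial withdrawal `R_w`
(mL/min) and microsphere signals `F_s` (tissue) and `F_ref` (reference),

```
Q_s = (F_s / F_ref) · R_w        [mL/min],   q_s = Q_s / w_s   [mL/min/g].
```

ROIs are compared across hemodynamic states with a fixed-effects
area-by-time model on reciprocal-transformed metrics, using restricted
(within-block) permutation tests and an animal-level bootstrap, plus a
rank correlation between SFI and microsphere flow.

Because no raw in-vivo data are public, the package ships a seeded
gamma-variate bolus simulator of a single-vessel gastric-tube experiment
(ROIs D1 fundus, D2 corpus, D3 prepyloric; states T0–T3; 25 fps, 8-bit,
120 s) with known ground-truth flows; the test suite validates the whole
chain against that truth. See the methods vignette
(`vignettes/perfusion-quantification.Rmd`) for the model and all defaults.

## Worked example

```r
library(perfquant)

ex <- simulate_experiment(acquisition_config(seed = 7))  # 3 ROIs x 4 states
an <- analyze_experiment(ex, animal_id = "A1")
an$table[an$table$state == "T2", c("roi","state","bsfi","sfi","tts","tts_ratio")]
#>  roi state   bsfi   sfi  tts tts_ratio
#>   D1    T2  62.24 14.51 9.80     2.112
#>   D2    T2  80.36 26.29 6.56     1.414
#>   D3    T2 101.18 34.62 4.64     1.000
```

The proximal-to-distal flow gradient of the simulated arcade (relative
flows D3:D2:D1 = 1:0.8:0.6) shows up as decreasing BSFI and SFI and an
increasing TTS ratio from D3 to D1 — D1, the watershed fundus tip, has the
weakest and latest signal. Microsphere flows recover the same truth in
absolute units (ground truth here: 0.72 / 0.96 / 1.20 mL/min/g):

```r
assay <- simulate_microsphere_assay(c(0.72, 0.96, 1.20),
                                    regions = c("D1","D2","D3"), seed = 7)
flow_per_sample(assay$tissue, assay$reference)
#>  sample_id region signal per_gram_flow_ml_min_g
#>        s01     D1   2054                 0.6894
#>        s02     D2   2744                 0.9210
#>        s03     D3   3510                 1.1781
```

The full pipeline (simulate → metrics → flows → statistics → report) runs
with `run_pipeline(load_run_config("inst/extdata/demo_config.json"), out)`
or from the shell:

```sh
Rscript inst/cli/perfquant.R run --config inst/extdata/demo_config.json --out run1
```

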