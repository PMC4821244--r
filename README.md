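# frapkit

Quantification of **fluorescence recovery after photobleaching (FRAP)** for
proteins bound in pericellular matrix — plus a synthetic image-series
generator with known ground truth, so the entire pipeline is validated by
parameter recovery.

## The problem

Growth factors such as FGFs bind the glycosaminoglycan chains (heparan
sulfate, chondroitin/dermatan sulfate) of the matrix around cells. FRAP
measures whether, and how fast, they move while bound: a 2.5 µm disc is
bleached in a labelled field and fluorescence return is recorded (here: a
22.49 µm / 256 px square field, 6 pre-bleach frames, then 994 frames over
195.6 s). Two model-free statistics summarize each experiment:

* **Final recovery level** `I_f` → the **mobile fraction** (`100·I_f` %);
  its complement is the immobile fraction.
* **Half recovery time** `τ½` → the time at which the doubly normalized
  curve reaches `I_f/2`, a proxy for diffusion speed.

With `I`, `I_b`, `I_r` the mean intensities of the bleach, background and
reference ROIs and `⟨·⟩_pre` the pre-bleach mean, the estimator chain is

    I_c[k]   = (I[k] − I_b[k]) · ⟨I_r − I_b⟩_pre / (I_r[k] − I_b[k])   (photobleach correction)
    I_cn[k]  = I_c[k] / ⟨I_c⟩_pre                                      (pre-bleach normalization)
    I_dcn[k] = (I_cn[k] − I_cn[b]) / (1 − I_cn[b])                     (renormalization; b = bleach frame)
    I_f      = tail mean of I_dcn;   τ½: first smoothed crossing of I_f/2,
               interpolated between τ_a (sample below) and τ_b (sample above)

Companion modules compute photobleach-corrected **radial recovery profiles**
around the disc (the 'U' → 'V' evolution) and **per-cell binding
intensities** from segmented single-frame images (Otsu + morphology cell
edge detection, background-subtracted means, normalization to an untreated
baseline).

The simulator implements a two-population model: a mobile fraction `f_m`
diffusing freely with coefficient `D` (spectral Gaussian propagation on a
padded domain; exact for free diffusion), an immobile remainder, disc bleach
with a soft edge, per-frame monitor bleaching, optional clustered
binding-site heterogeneity, a cell-free corner for the background ROI, and
Poisson + read noise. `make_preset()` calibrates `(D, f_m)` so the pipeline
reproduces the reported per-FGF kinetics (FGF1 52% / 49 s, FGF2 81% / 22 s,
FGF6 82% / 16 s, FGF10 immobile, low-concentration FGF1 50% / 45 s).

## Worked example

```r
library(frapkit)

cfg <- make_preset("FGF2", seed = 1)   # calibrates D to 22 s, f_m to 81%
sim <- simulate_frap(cfg)              # 256x256 x 1000-frame stack + truth
res <- analyze_frap(sim$series, default_roi_set(cfg))
print(res)
#> FRAP result: I_f = 0.8069, mobile = 80.7%, immobile = 19.3%
#>   tau_1/2 = 21.70 s (tau_a = 21.65, tau_b = 21.84)
```

The printed numbers mean: 80.7% of the labelled protein exchanged into the
bleached disc within the acquisition (vs the 81% target encoded in the
preset), 19.3% stayed immobile, and recovery reached half its final level
21.7 s after the bleach (target 22 s). Multi-seed summaries:

```r
run_recovery_experiment("FGF2", n_seeds = 5)$summary
#>   preset n_seeds mobile_mean mobile_sd tau_half_mean tau_half_sd
#> 1   FGF2       5    80.78647 0.1583874      21.85332   0.1299209
```

Stacks round-trip through ImageJ-compatible TIFF plus a JSON sidecar
(`write_stack()` / `read_stack()`), and the same pipeline is scriptable:

```sh
inst/exec/frapkit simulate --preset FGF2 --seed 7 --out stack.tif
inst/exec/frapkit analyze --stack stack.tif --out results/
inst/exec/frapkit radial  --stack stack.tif --out results/
```

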