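---
title: "Quantifying intracellular glucose dynamics from FRET biosensor movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular glucose dynamics from FRET biosensor movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucofret)
library(dplyr)
```

## Scope

`glucofret` quantifies intracellular glucose dynamics in neurons expressing a
ratiometric FRET glucose biosensor (CFP donor / YFP acceptor; the
acceptor/donor emission ratio *R* increases with glucose binding). It covers
the full chain from two-channel time-lapse stacks to group statistics:
translation registration, pixelwise ratio imaging, nucleus-excluded somatic
ROI traces, baseline drift correction, relative-ratio metrics, and
nonparametric group comparisons. Because raw movies of this kind are rarely
shared, the package ships a synthetic-data module — a mechanistic glucose
model, a sensor response, and a movie renderer with controlled corruptions —
so that every downstream stage can be validated against known ground truth.
A companion module analyses single-cell RT-multiplex-PCR detection panels of
glucose-metabolism genes.

## The glucose transport and consumption model

Intracellular glucose $G$ (mM) obeys

$$\frac{dG}{dt} = v_T\!\left(\frac{G_{ext}}{K_T+G_{ext}} - \frac{G}{K_T+G}\right)
 \;-\; g_{HK}(t)\,\bigl(v_{gly} + v_{ppp}(t) + v_{hbp}(t)\bigr)\,\frac{G}{K_C+G}.$$

The first term is a symmetric facilitative carrier (GluT1/GluT3 lumped into
one Michaelis–Menten transporter working in both directions); the second
lumps all consumption behind a common hexokinase gate with half-saturation
$K_C$. Three pathway fluxes sit behind the gate:

* $v_{gly}$ — the resting glycolytic flux. IAA (iodoacetic acid, a
  glyceraldehyde-3-phosphate dehydrogenase inhibitor) does not remove this
  flux directly; instead, the glucose-6-phosphate that accumulates behind
  the block progressively inhibits hexokinase. We model this as the gate
  $g_{HK}(t) = e^{-(t-t_{IAA})/\tau_{HK}}$ closing with time constant
  `tau_hk_inhibition` after IAA onset, which produces the *delayed* glucose
  accumulation characteristic of glycolysis blockade.
* $v_{ppp}$ — the pentose phosphate flux, zeroed from the moment 6-AN
  (6-aminonicotinamide, a glucose-6-phosphate dehydrogenase inhibitor) is
  applied.
* $v_{hbp}(t)$ — a transient hexosamine flux, disclosed by IAA and decaying
  with `tau_hbp_transient`. It is zero in the wild type
  (`hbp_transient_scale = 0`) and produces the biphasic dip-then-rise IAA
  response of the disease genotype: the extra flux consumes glucose while
  the hexokinase gate is still open, then both the transient and the gate
  decay and transport refills the cell.

This is deliberately the smallest structure with one knob per pathway: no
explicit G6P/F6P pools, no lactate or oxidative metabolism, no astrocyte
compartment. Genotypes differ only through three scale factors
(`glycolysis_scale`, `ppp_scale`, `hbp_transient_scale`), defaulting to
(1, 1, 0) for `nonTg` and (1.4, 0.3, 1) for `3xTgAD` — higher glycolysis,
hampered pentose phosphate pathway, and a disclosed hexosamine transient.

The sensor maps glucose to a ratio through single-site binding,
$R(G) = r_{min} + (r_{max}-r_{min})\,G/(K_d+G)$, with $K_d = 0.7$ mM
following the nominal affinity of the "700"-series sensor. $r_{min} = 0.70$
and $r_{max} = 1.70$ are conventions: the sensor's absolute dynamic range is
not quantified by the imaging protocol, and only baseline-relative ratios
enter any downstream statistic. They do, however, set the scale of percent
changes, so they were chosen jointly with the kinetic rates (below).

### Parameter defaults and calibration

Defaults live in `inst/extdata/kinetic_defaults.yaml` (units: fluxes mM/min,
affinities mM, time constants min):

| parameter | default | role |
|---|---|---|
| `v_transport` | 0.038 | carrier $V_{max}$ |
| `k_transport` | 0.64 | carrier half-saturation |
| `v_glycolysis`, `v_ppp` | 0.0126 each | resting pathway fluxes |
| `k_consume` | 0.026 | hexokinase half-saturation |
| `v_hbp_max` | 0.02 | peak transient hexosamine flux |
| `tau_hk_inhibition` | 10 | hexokinase gate closure under IAA |
| `tau_hbp_transient` | 6 | decay of the hexosamine transient |

The shared rates were calibrated once, by least squares against the
experimental design the simulator emulates, so that wild-type defaults give
a relative-ratio slope of about $-2$ %/min in the 2–7 min window after a
2.5 → 0.2 mM restriction and about $+10$ % at 50 min of a 2.5 → 10 mM step,
with the intermediate time courses of both protocols tracking the reported
group means. These are calibration targets of the generator, not claims
about data: the acceptance script recomputes what the full pipeline actually
recovers. The resting state (about 0.18 mM intracellular at 2.5 mM
extracellular) and the half-saturations that emerged from the calibration
are physiologically unremarkable — consumption saturates at tens of
micromolar, as hexokinase does.

The initial condition defaults to the resting steady state of the baseline
condition, so simulated baselines are flat by construction.

### Integration

A fixed-step classical Runge–Kutta (RK4) scheme at a 1 s internal step,
resampled onto the 15 s imaging grid. The rates involved give time constants
of minutes, nowhere near stiff at this step; a fixed step keeps trajectories
bit-reproducible across platforms, which the determinism contract of the
renderer and pipeline relies on. Non-finite states abort with an explicit
error rather than propagating NaN. Glucose is clamped at zero (the clamp only
engages when a trajectory approaches full depletion).

## The movie renderer

`render_movie()` paints each cell's ground-truth ratio series into
acceptor/donor frame pairs (uniform elliptical somata; nuclei rendered at a
fixed sensor-free ratio), then corrupts them in a fixed order:

1. **photobleaching** — per-channel linear intensity decay (fraction/min),
   matching the linear-drift correction downstream;
2. **focus artifacts** — with probability `artifact_prob` per frame the
   donor frame is dimmed, producing the sharp single-frame ratio spikes a
   five-point median filter removes;
3. **stage drift** — a per-frame x–y translation path, applied with bilinear
   interpolation;
4. **photon noise** — Gaussian with variance proportional to intensity,
   adequate at camera-count scales and analytically convenient (the
   noise-free renderer is exactly checkable against closed forms).

One integer seed drives everything through named substreams, so adding or
removing one corruption never changes another's draws, and the same seed
yields bit-identical stacks.

Ground-truth ROIs are drawn one pixel inside the painted cell border
(`roi_margin_px`), the way a manual delineation avoids boundary pixels;
without this margin, the bilinear resampling of a drifting cell mixes
boundary pixels with the surround and systematically attenuates relative
changes by several percent.

**What the generator does not emulate:** out-of-focus light and real point
spread functions, rotation or non-rigid deformation, spectral bleed-through
between channels, autofluorescence gradients, and inhibitor
pharmacokinetics. Passing recovery tests on these movies therefore
demonstrates the correctness of the analysis chain under the stated
corruption model, not robustness to every nuisance in real slices. The
inhibitor-response *amplitudes* are emergent rather than calibrated: the
simulated wild-type IAA and 6-AN accumulations overshoot the reported ones
(the minimal gate model removes consumption entirely as the gate closes),
and the simulated 3xTg-AD restriction slope comes out slightly shallower
than the wild type rather than slightly steeper. Only the qualitative shape
contracts — monotone versus biphasic IAA response, deeper combined-inhibition
dip in 3xTg-AD — are asserted.

## The imaging chain

* **Registration** is translation-only phase correlation on the
  donor+acceptor sum image (channel-independent geometry, better SNR), with
  the two-point subpixel peak estimator of Foroosh et al. and Hann
  windowing; rotation is out of scope because slice drift is dominated by
  translation. Estimated shifts are applied identically to both channels by
  bilinear interpolation; pixels leaving the field become `NA` and are
  excluded from ROI means. Blank frames are flagged and inherit the previous
  frame's shift. Integer drifts are recovered to rounding; subpixel accuracy
  is about 0.1 px RMS on these scenes (interpolation blur, not the peak
  estimator, is the limit).
* **Ratio images** are computed pixelwise (acceptor/donor where the donor
  exceeds a floor of 1% of the frame's 99th-percentile donor intensity) and
  *then* averaged over the cytosolic ROI. The alternative —
  ratio-of-ROI-means — is not equivalent in general; pixelwise-then-average
  matches a workflow that divides the registered YFP stack by the CFP stack
  and measures ROIs on the ratio stack.
* **ROIs** are somatic masks with the nucleus excluded (the sensor is
  absent from nuclei); frames with no defined cytosolic pixel yield missing
  values, never interpolated.

## Trace statistics

The order is fixed: drift-correct → relative-ratio → (median filter for
display and timepoint metrics; unfiltered for slopes).

* **Drift correction** fits a least-squares line to the baseline window
  only and subtracts its extrapolation, re-adding the baseline mean.
  Fitting through stimulus periods would absorb real signal into the
  "drift". A post-event step riding on a linear drift is preserved exactly.
* **Relative ratio** is $100\,(R - R_0)/R_0$ with $R_0$ the baseline-window
  mean; the baseline window defaults to the 10 min preceding the first
  protocol event.
* **Five-point median filter** with symmetric window shrinkage at the edges
  (3-point at the penultimate samples, passthrough at the endpoints); it
  removes any single-frame spike and never changes a constant baseline.
* **Timepoint values** are read at the nearest sample to the requested
  post-event time, with the earlier sample winning exact ties.
* **Slopes** are OLS over the post-event window (canonically 2–7 min after
  restriction), in %/min, on the *unfiltered* relative trace — the filter
  exists to remove display artifacts, and a median filter biases local
  slopes. Both the timepoint and the slope source are config-switchable
  (`filter`, `slope_on_filtered` in `run_config()`); when artifact
  injection is enabled, unfiltered OLS slopes are corrupted by ratio spikes
  and `slope_on_filtered = TRUE` is the right setting.
* **Group summaries** are per-timepoint mean ± SEM over cells with defined
  values, requiring a common time grid.

## Statistical tests

Both tests are implemented from first principles and validated against
independent enumeration oracles.

* **Fisher's exact test (two-sided)** uses the point-probability tail: with
  margins fixed, $p$ sums the hypergeometric probabilities of all tables no
  more probable than the observed one (with a $10^{-7}$ relative tolerance
  against floating-point ties, the convention of the classical packages).
  Computation is in log space via `lchoose`. This convention reproduces the
  reference dataset's worked examples analytically — e.g. the 0 of 31
  versus 2 of 28 table gives exactly $378/1711 \approx 0.2209$.
* **Mann–Whitney U** uses midranks; the statistic is reported as
  $\min(U_1, U_2)$. The two-sided $p$ is exact by full enumeration of rank
  assignments when both groups have at most 10 untied observations,
  otherwise a tie-corrected normal approximation with continuity
  correction. The exact two-sided tail is the symmetric one,
  $P(|U-\mu| \ge |u-\mu|)$, which coincides with the doubling convention
  for untied samples.
* **Percent occurrence** rounds half away from zero. Two reported percents
  in the reference dataset (2/31 and 11/31) are inconsistent with any
  nearest-integer rounding of their own counts and are treated as printed
  typos; all other count/percent pairs reproduce exactly.

## The expression dataset

`expression_fixture()` reconstructs the 59-cell detection table (31 wild
type, 28 3xTg-AD; 13-gene panel) deterministically from the reported
marginal counts. The GluT1/GluT3 joint distribution is fully determined by
the reported composite counts and is reproduced exactly; for all other genes
only marginals are known, so detections are assigned to the first cells of
each genotype in a fixed documented order. Any analysis depending on the
joint structure across those genes is unsupported by construction — the
fixture invents no joint claims beyond the GluT pair. Two of the reported
per-gene Fisher p-values (PFK1p, PFK1l) match the one-sided rather than the
two-sided test and are validated against the enumeration oracle instead of
the printed number.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on generated data:
scenes of 1–20 cells at 32–114 px on a side, protocols of 35–60 min at 15 s
sampling (141–241 frame pairs). Slope-recovery checks use 6 noise-free and
20 noisy cells; these sizes give per-cell OLS standard errors around
0.2 %/min, small enough that a 3-standard-error recovery criterion is
informative. All randomness flows from one integer seed per run;
`run_experiment()` reports are byte-identical given the same configuration
and seed, and every output file carries the seed and a configuration hash.

## Known limitations

* The kinetic model is a caricature with one flux per pathway; inhibitor
  response amplitudes are emergent and not calibrated (see above).
* Registration is translation-only; rotation or warping in real slices
  would require a richer model.
* No spectral bleed-through or background subtraction is modelled or
  corrected.
* The expression fixture's joint structure outside the GluT pair is a
  convention, not data.
* Between-cell variability is modelled as lognormal scaling of transport
  and consumption rates only; real heterogeneity (expression level, sensor
  saturation, geometry) is richer.
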