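---
title: "Methods: peroxisomal Ca2+ uptake and motility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peroxisomal Ca2+ uptake and motility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroxdyn)
```

This vignette is the package's own account of its models, the choices
made where the design was genuinely open, and what the synthetic-data
generators do and do not establish about real microscopy data.

## The SOCE stimulation paradigm and its forward model

The experimental paradigm images cells expressing a peroxisome-targeted
ratiometric Ca²⁺ sensor for 100 cycles at 3–5 s intervals. Stimulants are
3× stocks added at 50 % of the bath volume, so final concentrations
follow $c_\mathrm{final} = c_\mathrm{stock}\, f/(1+f)$ with $f$ the
added volume fraction (300 µM histamine → 100 µM after cycle 10; 3 mM
CaCl₂ → 1 mM after cycle 50). `final_concentration()` implements this;
`final_concentration_dilution()` covers plain dilution ratios.

`simulate_ca_traces()` generates the cytosolic trace as baseline
(default 100 nM) plus two double-exponential transients (rise τ 4 s,
decay τ 12 s, amplitudes 400 and 300 nM). The peroxisomal trace is the
cytosolic trace rescaled to the 600 nM peroxisomal baseline, passed
through a first-order lag (default τ 15 s) that emulates the delayed
equilibration of the peroxisomal lumen, with per-condition multipliers on
baseline and the two transients (the built-in knock-down condition
blunts the ER- and PM-driven uptake). Per-cell amplitude variability is
lognormal with 10 % CV. These constants are the package's own choice of
plausible study conditions — resting concentrations follow the ~100 nM
cytosolic / ~600 nM peroxisomal regime of the system; transient shapes
and the lag are not calibrated against any measurement.

The sensor forward model is a Hill curve,
$R(\mathrm{Ca}) = r_\mathrm{min} + (r_\mathrm{max} - r_\mathrm{min})
\frac{\mathrm{Ca}^n}{\mathrm{Ca}^n + K_d^n}$, defaulting to
$K_d = 600$ nM, $n = 1$, $r \in [1, 3]$. No published calibration of the
sensor's constants is assumed; they are configurable plumbing whose
defaults put the baseline near half-saturation so both transients are
visible in the ratio.

## Channel rendering and the exact inverse identity

`render_fret_channels()` composes observed channels from pure donor
signal $D$ (per-cell normal draw), pure acceptor signal $A$ (a fixed
fraction of $D$, default 0.5) and sensitized emission $S = R \cdot D$:

* donor = $D + A\,\beta_{ad}$ + background,
* acceptor = $A$ + background,
* FRET = $S + (\mathrm{donor} - bg)\,\beta_{df} + (\mathrm{acceptor} -
  bg)\,\beta_{af}$ + background,

with noise (none / multiplicative-sd Gaussian / Poisson-gain) applied
after composition. The donor→FRET crosstalk is deliberately applied to
the background-corrected *observed* donor channel — which itself carries
the small acceptor→donor term — because that is exactly the quantity the
correction subtracts. With noise off, `correct_ratio()` therefore
recovers the true ratio to machine precision for any parameter set; this
inverse identity is the package's strongest internal check and is
enforced to 1e-9 in the tests. Had the crosstalk been applied to pure
$D$ instead, the correction would carry a second-order residual of order
$\beta_{ad}\beta_{df} A / D$ (about 0.6 % at the defaults), which is why
the exact-inverse convention was chosen.

Bleed-through coefficients are estimated as least-squares slopes through
the origin over all observations of single-fluorophore control cells,
not as means of per-cell ratios: regression through the origin weights
bright observations more, which is standard practice for crosstalk
calibration and is what makes noise-free recovery exact.

## SOCE metrics, windows, gating

Windows are inclusive and 1-based exactly as specified in the protocol:
baseline mean over cycles 1–9, ER search max over 9–25, PM reference
mean over 47–49, PM search max over 49–70. Cycle 9 belongs to both the
baseline and ER windows, and cycle 49 to both PM windows; the overlaps
are preserved as printed rather than "fixed". Cycles whose corrected
denominator falls at or below a configurable positivity floor (default
0) are flagged invalid and excluded from window statistics; a window
with no valid cycle raises an error naming the window rather than
returning a silent NA.

One property worth stating plainly: the ER- and PM-based responses are
*maxima* over windows, and a maximum over noisy values is upward-biased
whenever several cycles sit within the noise scale of the true peak.
With the default broad (lagged) peroxisomal transient and 1 % channel
noise this bias is real and measurable (the acceptance script reports
it), while the mean-based baseline metric stays unbiased. The package
computes the metric exactly as defined and applies no debiasing; users
comparing conditions should rely on the bias cancelling between groups
acquired identically.

mRFP gating compares the background-corrected mean gray value against
0.5 with strict inequalities; a value exactly at the threshold is
classified "pos" with a warning, since the gate definition leaves the
boundary open and silently picking a side would hide the ambiguity.

## Particle linking and motility statistics

Frame-to-frame linking solves a global minimum-cost one-to-one
assignment (an $O(n^3)$ Hungarian implementation) rather than greedy
nearest-neighbour matching: the result is deterministic,
order-independent, and optimal — it maximises the number of links
allowed by the 0.5 µm gate and, among those, minimises total distance.
Unmatched detections seed new tracks; with max gap 0 any miss closes a
track. A brute-force enumeration oracle in the tests confirms optimality
on hundreds of random instances.

The 0.03 µm exclusion radius is far below optical resolution, so
same-frame detections closer than it are treated as duplicates of one
object and merged to their centroid (single-linkage, applied until all
points are pairwise separated). Track duration is (last − first) frame
time and the `>=` rule keeps boundary tracks; the minimum (5 s baseline,
10 s stimulation experiments) is an explicit parameter. "Histogram bin
size 35" is interpreted as 35 equal-width bins spanning [0, max speed];
the alternative reading (35 nm/s bin width) is noted as open. Mean track
speed is the mean of step speeds, which over-estimates true speed under
localization noise; no debiasing is applied, matching the direct
computation the tracking software performs.

## The random-intercept mixed model

The motility records are cell-level mean speeds under
siRNA (NC / siACBD5) × nocodazole (DMSO / noco) — between subjects — and
stimulation (EGTA / histamine / Ca) — within subjects. Treatment coding
with references NC, DMSO, EGTA makes the intercept the mean speed of the
control conditions. The estimator is written directly against the
single-grouping-factor structure: the marginal covariance is
$\sigma^2_e (I + \lambda Z Z^\top)$ with
$\lambda = \sigma^2_b / \sigma^2_e$, each subject block inverts in
closed form, and the REML criterion profiled over $\sigma^2_e$ is
minimised over $\lambda \ge 0$ by a deterministic coarse grid
(0 and $10^{-4}$–$10^4$, quarter-decade steps) followed by bounded
`optimize()` refinement, with the boundary $\lambda = 0$ checked
explicitly. The profile was unimodal on every fixture examined; restarts
from different brackets agree to well below the optimizer tolerance.

Satterthwaite degrees of freedom follow the variance-of-variance
recipe: the covariance of $(\hat\sigma^2_b, \hat\sigma^2_e)$ is the
inverse observed REML information, obtained by central finite
differences of the restricted log-likelihood (relative step $10^{-4}$),
and the gradient of each coefficient variance with respect to the
components comes from the same differencing of
$\mathrm{Var}(\hat\beta)(\theta)$. For a rank-$q$ contrast the
denominator df aggregates per-eigenvector dfs as
$2E/(E-q)$ with $E = \sum \nu_m/(\nu_m - 2)$. When
$\hat\sigma^2_b = 0$ the fit reduces exactly to OLS and all dfs fall
back to the residual df, which is the correct limit. Against
lme4/lmerTest the estimates, standard errors, variance components and
dfs agree to the tolerances asserted in the test suite; lme4 is never
called by the package itself.

Backward reduction proceeds in the fixed order: joint F-test of the
three-way terms, of the two-way terms involving nocodazole, of the
siRNA × stimulation terms, then a 1-df test of histamine = Ca that, when
accepted, pools the two stimulated levels into one factor; finally a
joint F-test of every dropped direction against the full model. Each
step records its F, dfs, p and decision whether or not the drop happens.
α = 0.05 by default and configurable — the drop threshold is a policy
choice, not an estimate. One rule is the package's own: a term set whose
drop test accepts is still retained while a retained higher-order
interaction contains it, because non-hierarchical factor models produce
rank-deficient codings; the trace labels such steps explicitly. A
consequence worth knowing: reaching the fully pooled model requires four
independent-ish hypothesis tests to *all* accept, so even when the
generating truth has no interactions the pooled model is recovered in
roughly $0.95^4 \approx 81\,\%$ of replicates, not ~100 %; the rest stop
one step early. The per-step tests themselves are correctly sized (the
type-I simulation in the acceptance suite checks this).

## Generators for the mixed model and tracking

`simulate_motility_dataset()` draws
$y = X\beta + b_\mathrm{subject} + \varepsilon$ with the factorial
design above. Defaults emulate the study conditions: control mean
390 nm/s, knock-down +139.1, nocodazole +95.7, both stimulation steps
−69.7 (no interactions), $\sigma_b = 60$, $\sigma_e = 50$ nm/s, 10 cells
per between-subject condition over 3 experiments. The effect sizes are
the magnitudes reported for the final model of the motility experiment;
the variance components and design size were chosen once so that the
implied standard errors land in the reported range, and are not
revisited.

`simulate_trackset()` is a two-state (tethered/free) Markov switching
model with isotropic Gaussian steps of per-axis sd
$\sqrt{2 D \Delta t}$, localization jitter and detection dropout. The
two-state mechanism is the minimal one reproducing "tether disruption
increases motility" and claims no biological fidelity; directed
microtubule runs are deliberately out of scope. A useful closed form for
verification: pure diffusion gives Rayleigh step lengths with mean
$\sqrt{\pi D \Delta t}$, so the mean track speed is
$\sqrt{\pi D \Delta t}/\Delta t$ — the acceptance suite checks this to
5 % over 1,000 tracks of 2,400 steps.

Every generator derives one RNG stream per cell/particle/replicate from
the base seed, so enlarging a dataset never alters the units already
generated, and all outputs are bit-reproducible for a fixed seed.

## Counting

The IsoData threshold iterates $T \leftarrow (\mu_{\le T} + \mu_{>T})/2$
from the image mid-range until the change is below 0.5 gray levels — the
iterative-intermeans "default" of common image software, without
replicating that software's histogram-binning quirks (a documented
approximation). Watershed seeds are regional maxima of the Euclidean
distance transform merged within 0.5 px (via EBImage); disjoint objects
are never merged, and tangent disks of radius ≳ 3 px are reliably split.
Below that the discrete distance transform's peak-to-saddle height drops
under the merge tolerance and tangent pairs can survive as one object —
a resolution limit of binary watershed, not a parameter to tune away.
Particles are assigned to the ROI containing their centroid, so boundary
particles are counted exactly once, independent of label numbering and
ROI order.

## What the synthetic data does and does not show

The generators emulate the *structure* of the study's data: trace
shapes, linear crosstalk, factorial designs with subject intercepts,
diffusive switching motion, disk-shaped spots. They do not emulate
photobleaching, FRET kinetics, point-spread functions, directed
transport, non-Gaussian speed distributions, or segmentation of real
cell outlines. Passing tests therefore establish that the *analysis
chain* is correct — corrections invert, estimators are calibrated,
assignments are optimal, counts are exact in their operating regime —
not that any biological conclusion drawn from real data is right. The
problem sizes used throughout the tests (200 × 100-cycle cells, 500-cell
noise studies, 500–1,000 mixed-model replicates at 10 cells per
condition, 200 reduction replicates, 100 spot fields) were chosen as the
smallest sizes at which the Monte-Carlo error is comfortably below the
asserted tolerances.

## Known limitations

* The max-over-window response metrics are upward-biased under noise for
  broad transients (see above); the baseline metric is not.
* The exclusion-radius semantics of the original tracking vendor are
  proprietary; only internal optimality, not vendor equivalence, is
  asserted.
* "Subject" is whatever identifier the records carry; the package does
  not guess whether it is a cell, a sample or an experiment, and fits a
  single random intercept for it (the experiment identifier is carried
  as a column for users who need a different grouping).
* No MSD-based motion classification, no 3-D trajectories, no absolute
  Ca²⁺ calibration of the sensor, no photobleaching correction.
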