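---
title: "Hypothesis-based localization on a circular track: models and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypothesis-based localization on a circular track: models and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ringnav)
```

# The task

A simulated agent runs along a circular track (radius 0.5 m) for 10 s in
0.1 s steps, starting at rest from an unknown angle. The environment
contains two to four perceptually identical landmarks. The agent receives
a noisy velocity signal and, on coming within `d_enc = pi/20` rad of a
landmark *different from the one it last visited*, a brief landmark
observation. Because landmarks are indistinguishable, a single encounter
leaves the agent's location ambiguous: it knows it is *at a* landmark, not
*which* landmark. Disambiguation requires holding multiple location
hypotheses and combining them with integrated self-motion until a second
encounter (or the telling absence of one) resolves them. `LM0/LM1/LM2`
label the phases with zero, one, and two distinct landmarks encountered;
location uncertainty is uniform, bimodal, and unimodal, respectively.

Two information regimes are implemented. In the *external map* scheme the
landmark geometry is delivered as an input pattern at each encounter (70
von Mises map cells, rotated coherently by fresh `N(0, sigma_l^2)` noise
per encounter); in the *internal map* scheme a single binary cell signals
"at some landmark" and the geometry of the four fixed environments
(`fixed_environment("e1")` ... `"e4"`) must be inferred and stored in the
recurrent weights.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `dt`, `duration` | 0.1 s, 10 s | 100 steps per trial |
| `v_max` | pi/2 m/s | speed cap; also scales the velocity noise |
| `sigma_a` | pi/4 m/s^2 | acceleration s.d. of the random trajectories |
| `d_enc` | pi/20 rad | landmark observation threshold (pi/40 m on the 0.5 m ring) |
| `delta_sep` | pi/9 rad | minimum landmark separation in sampled environments |
| `sigma_v` | `v_max*dt/10` m/step | velocity-report noise |
| `sigma_l` | pi/50 rad | coherent map-rotation noise per encounter |
| `sigma_o`, `sigma_w` | pi/6 rad | place-cell target and map-input tuning widths |

`sigma_w` is not pinned down by the task definition; we default it to the
place-cell width `sigma_o = pi/6` so that the map input and the trained
output code positions at the same angular resolution, and expose it in
`sim_config()`. "Truncated" sampling of accelerations and velocities is
read as clipping at the bound (a `truncation = "resample"` option
redraws instead). An encounter comparison uses `<= d_enc` ("within" is
inclusive), and the trial starts with no previous landmark, so the first
approach to any landmark triggers.

# Baseline agents

*Path integration with correction* starts its estimate at `y = 0`,
integrates the noisy displacements, and snaps to the nearest landmark at
each encounter (ties to the lowest landmark index). The snap is lossy by
construction: the agent triggers an encounter up to `d_enc` away from the
landmark, so even noiseless inputs leave a residual error unless
encounters happen exactly at landmark coordinates.

The *basic particle filter* (`pf_run`) represents the location posterior
with `N_p = 1000` weighted particles: uniform initialization, random-walk
prediction with the reported displacement and s.d. `sigma_v`, weight
multiplication at encounters by the mixture-of-von-Mises landmark
likelihood of width `sigma_l`, renormalization to sum 1, and systematic
(low-variance) resampling whenever `N_eff = 1/sum(w^2) < N_p/5`. Estimates
are the weighted circular mean with circular variance `1 - |resultant|`.

The *enhanced particle filter* additionally exploits the *absence* of
encounters: a particle that comes within `d_enc` of a landmark other than
its own last-encountered one, at a step with no encounter signal, is
deleted (weight zero). We track the "last landmark" per particle — each
particle records the landmark nearest to it at each encounter — because
the filter has no access to a global landmark identity (encounters carry
none), and a global rule would kill the alternative-hypothesis cluster
the moment it forms. If every particle dies, the cloud re-initializes
uniformly.

The *grid-Bayes oracle* (`grid_bayes_oracle`) performs exact inference on
a 360-bin circular grid (FFT convolution with a wrapped Gaussian for
prediction; the same landmark likelihood at encounters). It exists to
test the particle filters: at `N_p = 10^4` the particle cloud's kernel
density matches the oracle posterior to total-variation distance < 0.1.
A caveat worth knowing: during the bimodal LM1 phase the *weighted
circular mean* is a brittle summary — its sensitivity to the mode-mass
split is about 3.5 rad per unit of probability mass, and the Monte-Carlo
error of that split at `N_p = 1000` (a few dozen effective particles per
mode) produces ~0.2 rad of scatter around the oracle mean even when the
posterior itself is accurate. Agreement to 0.05 rad therefore holds
essentially always after disambiguation (LM2) but only rarely during LM1.

With `sigma_l = 0` the von Mises likelihood degenerates; we replace it by
its limit, the indicator that a location is within `d_enc` of a mapped
landmark.

# The recurrent network

Three layers of rate units: inputs (80 external-map / 11 internal-map)
into 128 recurrent tanh units into 70 tanh outputs,
`h_t = tanh(Wx x_t + Wh h_{t-1} + b)`, `o_t = tanh(Wo h_t + b_o)`; the
non-negative variant rectifies the preactivation before the tanh. Ten
input cells code velocity linearly onto per-cell rate ranges (minima in
[0, 0.2], maxima in [0.8, 1], drawn once per network and stored with it);
the remaining cells carry the landmark input during the encounter step
and the three steps after. Training minimizes the mean squared error to
von Mises place-cell targets (width `sigma_o`), with Adam, global
gradient-norm clipping at 100, and selection of the parameters with the
smallest validation error. The hidden state starts at zero each trial
(trials begin with no information); input and output weights start
uniform at `1/sqrt(fan-in)`, the recurrent matrix orthogonal, and the
output bias at `atanh` of the marginal target mean so that early training
refines structure rather than fitting the mean.

## Desk-scale training

The reference setting — one pass over $10^6$ freshly generated trials —
is deliberately oversized for a laptop-class reproduction. Learning in
this task has a long plateau: the mean-squared-error gap between the
trivial constant output and the exact-Bayes output is only ~0.11 to
~0.073, so the gradient signal toward the structured solution is weak,
and the network needs tens of thousands of updates before hypothesis
retention crystallizes. The desk preset therefore keeps the same
optimizer and trial distribution but makes the update budget affordable:
39,375 Adam updates at batch size 32 under a stepped learning-rate
schedule (3e-4 for the first 38% of updates, 1e-4 to 79%, 3e-5 after),
where each phase draws a fresh pool of 15,000 independently generated
trials, revisits it in random batch order, and warm-restarts the Adam
moments. The schedule was chosen on training/validation loss and
decoding error alone: 3e-4 escapes the constant-output plateau within a
few thousand updates where 1e-3 wanders for tens of thousands (and batch
16 never escapes), the 1e-4 phase is where the LM1/LM2 computations
differentiate, and the 3e-5 tail consolidates. Validation on 500 freshly
generated trials (never the pool) every 2000 updates controls the mild
overfitting that recycling finite pools could cause. The C++ gradient
kernel runs in single precision by default; its gradients agree with the
double-precision path to ~1e-6 relative error, far below SGD's own
noise.

What the desk-scale network reproduces: localization well below the
half-uniform-error mark and better than path integration with
correction, hidden dynamics on a low-dimensional manifold (correlation
dimension ~3), tuning-correlation structure preserved across phases, and
*dual-hypothesis output coding* — on trials where the absence of
encounters has not yet resolved the ambiguity, the output cells at the
true and at the alternative location are activated at nearly equal
strength (~0.45 each, close to the posterior-optimal 0.5/0.5 split).
Two desk-scale caveats. First, a probe for hypothesis coding must
condition on the absence information: a near-optimal agent discards the
alternative hypothesis as soon as its implied trajectory silently passes
a landmark zone, so late-LM1 snapshots are often legitimately unimodal.
Second, output *sharpness* converges last: at this budget the two
equal-strength hypothesis bumps are broader than the place-cell targets
and can merge into a single elevated plateau, so a bump count based on
distinct local maxima can under-report hypothesis coding that the bump
heights clearly show. Absolute error also remains above the fully
trained reference, which is why no error values from the original study
are asserted anywhere — only orderings and structural signatures.

# Population analyses

**Tuning curves and preferred locations** (`tuning_curves`): mean unit
activation in position bins (50 bins for preferred-location analyses, 20
for phase-conditioned ones); preferred location = bin center of the
maximum, ties to the lowest bin. `preferred_location_density` compares
the density of preferred locations within `d_enc` of a landmark to the
density elsewhere.

**State-space PCA** (`state_pca`): principal directions fitted on
training-distribution hidden states; test states are projected with the
training means.

**Correlation dimension** (`correlation_dimension`): after reduction to
20 principal components, neighbors of 1000 random base points are counted
at 20 log-spaced radii; the minimum radius is set where the log mean
neighbor count is ~1 (natural log — only slopes matter, so the base is a
free convention), the maximum at 10x that, and the dimension is the slope
of the linear part of log count vs log radius. Two definitional gaps are
resolved as follows, calibrated only on known-dimension oracles (circle,
hypercubes of dimension 1–3, Gaussian clouds of dimension 3 and 5,
synthetic sessions of known latent dimension):

* *"linear part"*: the window seeded at the four consecutive local slopes
  of minimum relative spread, extended while slopes stay within 10% of
  the window median. This finds the power-law plateau between the
  measurement-noise regime (inflated slopes at small radii) and the
  boundary/density-falloff regime (depressed slopes at large radii).
* *temporal neighbors*: densely sampled smooth trajectories put each
  point's temporal neighbors at tiny distances, which reads as a spurious
  one-dimensional manifold. An optional Theiler window
  (`time_index`/`theiler`) excludes neighbors closer than a time
  threshold; analyses of rate or state time series here always pass one.

A known limitation: compact-support clouds (hypercubes) of dimension 5
and above are under-estimated by a few tenths at any feasible sample
size, because a ball holding even ~3 neighbors already spans ~15% of the
support, so boundary truncation bites at every probed radius.

**Disambiguation** (`disambiguation_metrics`): the alternative-hypothesis
trajectory is the true one shifted by the signed inter-landmark distance;
bump heights are the activations of the output units nearest the true and
alternative positions; the disambiguation time is the earliest step after
which one bump stays below 0.1 to trial end; correctness compares the
decoded estimate at the last encounter to the true versus wrong landmark.

**Tuning-correlation structure** (`tuning_correlation_structure`):
Pearson correlations between all unit pairs' tuning curves within each
phase; the summary is the correlation between the off-diagonals of the
LM1 and LM2 matrices.

# Synthetic population sessions

`synth_session` stands in for the retrosplenial recordings: 50–90 neurons
(drawn per session), a 500 mm circular arena with a smooth reflected
random-walk trajectory, scripted first/second landmark encounter times
per trial defining LM0 → LM1a/LM1b → LM2 (the LM1 sub-label records which
landmark the second encounter will be), a `latent_dim`-dimensional AR(1)
shared latent (time constant `latent_tau`), per-neuron conjunctive
position tuning (von Mises in arena angle, Gaussian in radius) scaled by
`pos_gain`, and per-neuron phase offsets scaled by `phase_gain`. The
summed drive passes through a softplus and is calibrated so each neuron's
mean rate equals `base_rate`; spikes are inhomogeneous Poisson. Phase
offsets are drawn at 1.5x the shared-latent scale so that `phase_gain = 1`
is by construction a clearly decodable hypothesis code (the generator's
defined full-strength endpoint) and `phase_gain = 0` leaves no trace.

Scripted phase transitions (rather than emergent landmark-visibility
physics) are deliberate: the module exists to test the analyses under
known ground truth, not to model behavior. What passing tests show is
that the pipelines *recover planted structure at realistic noise levels*;
they cannot show that real recordings contain such structure.

Two practical notes that the tests encode:

* The 0.05 Hz phase-decoding filter of the original pipeline suits
  trials lasting minutes; on synthetic trials of ~15 s the filter
  timescale must stay well below the phase dwell times, so synthetic
  phase decoding uses a 0.3 Hz single-pole filter.
* Latent-dimension recovery by correlation dimension needs the Poisson
  measurement noise below the latent-manifold scale: generous rates
  (~50 Hz), strong smoothing (0.2 Hz third-order), temporal subsampling,
  and a Theiler window of a few latent time constants.

# Population statistics

`entropy_rel_uniform` implements the histogram entropy relative to a
uniform histogram of the same size, `log2(n) - H(X)` bits, with a 1e-10
offset added to all bins when zeros appear (this reproduces the worked
examples to printed precision). `spatial_maps` + `spatial_map_entropy`
give 8x8 arena rate maps and their spatial information;
`map_distance_test` compares across-condition map distances to
split-half within-condition controls on nonoverlapping time segments.
`phase_decoder` is the categorical linear decoder ((n_neurons + 1) x 3
parameters, least squares onto one-hot states, class-balanced training,
held-out trials). `pairwise_correlations` yields per-phase correlation
matrices and the correlation of correlations;
`rate_prediction_r2` the L1-regularized (lasso, lambda ~ 1e-4)
cross-population rate prediction on 0.01–0.5 Hz band-passed rates
subsampled to 3.3 Hz with 8 lags, fit within one condition and evaluated
with frozen coefficients in another; `group_distance_test` the
within- versus across-group state-distance comparison with bootstrap CIs;
`window_distance_correlation` the correlation of pairwise trial
distances between a pre-encounter baseline window of raw spike counts
and a sliding window, with a neuron-identity shuffle control;
`frame_tuning_entropy` the tuning entropy in the global versus
landmark-relative angular frame under a 70%-of-radius eccentricity gate
with phase-matched sample counts; `pca_spectrum` the sum-normalized
eigenvalue spectrum against a circular-shift control.

The eccentricity gate is stated in the source material as "70% of the
arena diameter", which is dimensionally ambiguous for a gate that must
lie inside the arena; we use 70% of the radius. LM1/LM2 sample matching
subsamples uniformly at random. Bootstrap CIs are percentile intervals
at 95%.

# Numerical choices and degenerate inputs

* Angles are wrapped to `[0, 2*pi)`; circular distance is the minor arc.
* A particle cloud or posterior whose resultant vanishes has no mean
  direction: estimates are flagged `NA` with circular variance 1 and are
  excluded (and counted) by `localization_error`.
* The grid oracle switches from FFT convolution to exact spectral
  rotation when `sigma_v` is far below the grid spacing.
* Tuning bins with no samples are `NA` and excluded from preferred
  locations and correlation structure; constant tuning curves are
  excluded (and counted) from correlation matrices.
* `decode_location` breaks output-activation ties toward the lowest cell
  index; `which.min`-style tie-breaks are used for nearest landmarks.

# Problem sizes used by the tests and the acceptance script

Entropy examples are exact. The filter-hierarchy comparison uses 500
training-distribution trials (bootstrap CIs over trials); the
oracle-equivalence check 100 constant-speed trials; dimension oracles
use 4000–20000-point clouds; network analyses use 400 training-
distribution trials (hidden-state dimension) and 1500 fixed-landmark
trials (tuning structure); synthetic-session recovery uses sessions of
12–30 trials with 40–64 neurons. These sizes give sampling error
comfortably below the asserted tolerances while keeping a full run in
the minutes range.
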