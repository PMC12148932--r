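# ringnav

Spatial reasoning with perceptually identical landmarks, in silico. An
agent moves along a circular track among landmarks that all look the
same; a single landmark encounter therefore fixes position only up to
*which* landmark it was. Solving the task requires carrying several
location hypotheses forward in time — combining noisy self-motion with
the presence *and absence* of further encounters — until the ambiguity
resolves. `ringnav` implements the full computational side of this
problem for R users in computational neuroscience:

* **Task simulation** (`sim_config`, `sample_environment`,
  `sample_trajectory`, `detect_encounters`, `encode_inputs`,
  `make_targets`, `make_experiment`): noisy velocity trajectories on a
  0.5 m ring, 2–4 landmark environments, encounter detection, and the
  population-coded inputs/targets for learning agents.
* **Bayesian baseline agents** (`path_integrate_correct`, `pf_run`,
  `grid_bayes_oracle`): path integration with landmark resets, basic and
  enhanced (absence-aware) particle filters with systematic resampling,
  and an exact grid-Bayes oracle for validating them.
* **A trainable recurrent network** (`init_network`, `train_network`,
  `rnn_forward`, `decode_location`): 128 recurrent tanh rate units
  mapping velocity + landmark-map inputs to von Mises place-cell
  targets, trained with Adam and validation-based selection
  (external-map, internal-map, and non-negative variants), with fast
  RcppArmadillo kernels.
* **Population-activity analyses** (`tuning_curves`,
  `preferred_location_density`, `state_pca`, `correlation_dimension`,
  `disambiguation_metrics`, `tuning_correlation_structure`,
  `conditional_rate_histograms`): the state-space and coding analyses
  used to characterize hypothesis-dependent computation.
* **Synthetic population recordings** (`session_config`,
  `synth_session`, `matched_trial_subset`): Poisson spike sessions with
  controllable position, phase and latent-dimensionality structure,
  standing in for retrosplenial recordings so that every statistic can
  be tested against known ground truth.
* **Population statistics** (`entropy_rel_uniform`, `spatial_maps`,
  `map_distance_test`, `phase_decoder`, `pairwise_correlations`,
  `rate_prediction_r2`, `group_distance_test`,
  `window_distance_correlation`, `frame_tuning_entropy`,
  `pca_spectrum`): histogram entropies relative to uniform, spatial
  maps and their distances, categorical linear state decoding,
  correlation-of-correlations, L1-regularized cross-population rate
  prediction, and bootstrap group-distance tests.

The methods vignette (`vignettes/ringnav-methods.Rmd`) documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not establish.

## A worked example

Simulate a fixed-landmark trial, run the basic particle filter, and
compare it with exact Bayesian inference:

```r
library(ringnav)
set.seed(7)
cfg <- sim_config()                      # 100 steps of 0.1 s, radius 0.5 m
tr  <- make_trial(cfg, env = fixed_environment("e1"))
tr$encounters
#>    t landmark
#> 1  1        1
#> 2 59        2

pf <- pf_run(tr$noisy_disp, tr$encounters, tr$noisy_maps, tr$env, cfg,
             filter_config(N_p = 1000))
gb <- grid_bayes_oracle(tr$noisy_disp, tr$encounters, tr$noisy_maps,
                        tr$env, cfg)
round(c(pf  = localization_error(pf$est, tr$traj, "post_lm2", tr$encounters),
        bayes = localization_error(gb$est, tr$traj, "post_lm2", tr$encounters),
        pi  = localization_error(
          path_integrate_correct(tr$noisy_disp, tr$encounters, tr$env, cfg),
          tr$traj, "post_lm2", tr$encounters)), 3)
#>    pf bayes    pi
#> 0.244 0.229 0.299
```

The agent meets landmark 1 immediately and landmark 2 only at step 59,
so both hypotheses must be carried for almost six seconds; after the
second encounter the particle filter's remaining error (0.24 rad,
averaged over the post-disambiguation steps) sits essentially at the
exact-inference bound (0.23 rad), ahead of path integration with
correction (0.30 rad). Between the encounters the particle-filter
posterior is bimodal, with hypothesis modes 2π/3 apart — the landmark
separation.

The entropy statistic used for firing-rate histograms:

```r
entropy_rel_uniform(c(1, 0))        # 1 bit:  all mass in one of two bins
entropy_rel_uniform(c(1, 1, 1, 1.3))  # ~0.01 bit: nearly uniform
```

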