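# gaitlrp

Explainable deep-learning classification of running-gait stance-phase
waveforms.

Higher-mileage and lower-mileage runners differ in their stance-phase
biomechanics, and classifiers trained on joint-angle (kinematic) and
joint-moment (kinetic) trajectories can tell the two groups apart — but a
deep network alone cannot say *which* trajectory, or *when* in stance, the
decision rests on. `gaitlrp` is for movement scientists who want that
answer: it trains a fully-connected tanh network on trials-by-features gait
matrices and decomposes every prediction back onto the inputs with
Layer-wise Relevance Propagation (LRP), yielding per-trajectory,
per-percent-of-stance contribution maps.

The package covers the full chain:

* **Synthetic cohorts** (`cohort_spec()`, `generate_cohort()`): seeded
  two-class hierarchies — subjects, trials, 18 trajectories (ankle/knee/hip
  x sagittal/frontal/transverse x angle/moment) x 100 stance points — with
  smooth subject- and trial-level variability and class effects injected
  into known trajectory windows as ground truth.
* **Signal preparation** (`detect_stance()`, `lowpass_filter()`,
  `time_normalize()`, `hip_joint_centers()`): 10 N stance detection from
  vertical GRF, fourth-order zero-phase Butterworth filtering, 100-point
  time normalization, hip-joint-center regression.
* **Feature matrices** (`assemble()`, `split_matrix()`, `standardize()`):
  kinematic (n x 900), kinetic (n x 900) and combined (n x 1800) matrices
  in a frozen canonical column order, with subject-grouped class-stratified
  train/test splitting (reference design: 800 trials, 640/160 split).
* **The classifier** (`network_config()`, `train_network()`,
  `predict_network()`): deep fully-connected tanh stack, pre-activations
  `z = W'x + b`, softmax cross-entropy trained with mini-batch Adam
  (batch 25), fully seeded.
* **LRP** (`lrp_propagate()`, `batch_relevance()`): the epsilon-stabilized
  z-rule `R_{i<-j} = z_ij / z_j * R_j` applied layer by layer from the
  pre-softmax score of the explained output unit down to the inputs, with
  exact conservation (zero biases) and audited bias absorption
  `sum_i R_{i<-j} = R_j (1 - b_j/z_j)`.
* **Contribution maps** (`aggregate_relevance()`, `top_k()`,
  `contributions()`): per-sample max-normalization, averaging,
  rectification, three passes of (0.25, 0.5, 0.25) smoothing within each
  trajectory, 0-1 rescaling; top-k variable selection and percentage
  contributions by joint, plane, trajectory and stance window.
* **Evaluation** (`confusion_matrix()`, `classifier_metrics()`,
  `roc_curve()`): accuracy, sensitivity, specificity, precision, F1, MCC,
  TPR/FPR, the single-operating-point AUC `(TPR - FPR + 1)/2`, and the
  trapezoidal AUC of the full ROC staircase.
* **One-call experiments** (`experiment_config()`, `run_experiment()`):
  simulate -> assemble -> split -> standardize -> train -> evaluate ->
  explain for any subset of the three input scopes, reproducible from a
  single master seed, with CSV/JSON outputs.

## Worked example

Simulate a two-class cohort whose only true difference is a boxcar offset
on the knee internal-external rotation angle over 10-35% of stance, train
a reduced network, and ask LRP where the classifier looked:

```r
library(gaitlrp)

cfg <- experiment_config(
  cohort = cohort_spec(n_subjects_per_class = 16, n_trials = 10,
                       subject_sd = 0.05, trial_sd = 0.25,
                       effects = list(gait_effect("knee_transverse_angle",
                                                  c(10, 35), 0.75)),
                       seed = 1),
  scopes = "kinematics", n_hidden_layers = 3, hidden_width = 64,
  max_epochs = 60, learning_rate = 2e-3, weight_decay = 1e-2,
  train_frac = 0.75, seed = 1)

res <- run_experiment(cfg)
print(res)
#> experiment_result (master seed 1)
#>   kinematics accuracy 96.25%  F1 0.9630  MCC 0.9253  AUC(trap) 0.9862

r <- res$scopes$kinematics
print(r$confusion)
#>        pred + pred -
#> true +     39      1
#> true -      2     38

r$contributions$window
#>   group  percent
#> 1 early 83.56545
#> 2  late 16.43455

head(r$top_k[, c("name", "score")], 5)
#>                        name     score
#> 1 knee_transverse_angle_t14 1.0000000
#> 2 knee_transverse_angle_t15 0.9990605
#> 3 knee_transverse_angle_t13 0.9921171
#> 4 knee_transverse_angle_t16 0.9885214
#> 5 knee_transverse_angle_t17 0.9710240
```

The held-out confusion matrix (40 trials per class from subjects never seen
in training) gives 96.25% accuracy, and the processed relevance map puts
its highest-scoring variables squarely inside the injected 10-35% window of
the injected trajectory: the early-stance window (1-47%) carries 83.6% of
the total relevance, and all top-ranked variables are
`knee_transverse_angle` timepoints 13-17. The explanation recovers the
planted ground truth.

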