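# futsalr

Action recognition for team-sport wearables, with futsal as the case study.
A player is observed by two devices: an ultra-wideband tracker (position in
metres and body orientation in degrees, 30 Hz) and a six-channel surface-EMG
leg garment (rectified/smoothed envelopes, nominal 25 Hz with sample
drop-outs). `futsalr` turns those two streams into per-frame feature
sequences and classifies contiguous single-action *trials* into seven
classes — running, running with ball, passing, walking, walking with ball,
shooting, jumping — comparing three approaches:

* a frame-wise **ANN** (tanh hidden layer, softmax output);
* an **LSTM** sequence classifier (Glorot input weights, unit-forget-gate
  bias, BPTT with Adam, final-frame readout);
* the **Dynamic Bayesian Mixture Model (DBMM)**: per frame *t*, base
  classifiers (Gaussian naive Bayes, k-NN, the ANN) emit posteriors
  `P_i(A|C_t)` that are fused as

  `P(C_t|A) = β · P(C_t|C_{t−1}) · Σ_i w_i^t P_i(A|C_t)`,

  where the prior is uniform at `t = 1` and the previous fused posterior
  afterwards, and the classifier weights update online by Bayes rule with
  the entropy confidence `1 − H(P_i)/log c` as likelihood:
  `w_i^t ∝ conf_i^t · w_i^{t−1}`.

The nine per-frame features are the six min–max-normalised EMG envelopes,
speed `v = |Δ(x,y)|/Δt`, distance to the opponent goal
`d = |(x,y) − (x₂,y₂)|`, and orientation towards the goal
`θ = wrap(W − atan2(y₂−y₁, x₂−x₁))`.

Because the original match recordings are not deposited, the package
includes a first-class session simulator (`sim_session()`) reproducing the
structure the analysis assumes: seven actions with the reference corpus's
class imbalance, action-dependent speed/EMG signatures, 30 Hz positional vs
irregular ≤25 Hz EMG sampling, and trial lengths dispersed around the
25-frame usability floor. Readers and writers for the two sensor CSV
dialects (`read_traxports()`, `read_mbody3()`) and a frame-interval label
format are included.

## Worked example

Simulate a 10-minute session, preprocess, featurise and benchmark the three
classifiers on one stratified 70/30 split:

```r
library(futsalr)

report <- run_pipeline(pipeline_config(
  seed = 7, duration_s = 600, methods = c("ann", "lstm", "dbmm"),
  repeats = 1))
report
#> <benchmark_report> 1 repeat(s), mask 'all'
#>  method repeats mask accuracy precision   recall       f1
#>     ann       1  all 87.96992  8.270677 14.28571 10.47619
#>    dbmm       1  all 95.48872 35.302198 37.50000 36.30952
#>    lstm       1  all 93.98496 21.611722 28.57143 24.52381
```

Each row is the macro ("Total") average of the per-class metrics, in
percent. The ordering is the package's central result at this corpus size:
the DBMM ensemble clearly outperforms both single networks, and the
frame-wise ANN collapses onto the majority class ("walking") — its high
accuracy is the one-vs-rest accuracy of rarely predicting minority classes,
while its precision and F1 stay low. Inspect per-class rows and confusion
matrices with `tidy(report)`, `report$confusion$dbmm$mean`, and
`autoplot(report)`; `feature_ablation()` reruns the benchmark with the EMG,
EMG+velocity, EMG+distance, EMG+orientation and all-features masks.

Longer sessions sharpen the picture; the shipped acceptance run uses a
4 800 s corpus (~1 000 trials) and five repeated splits.

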