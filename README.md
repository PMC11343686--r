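# grcltd

Analysis toolkit for simultaneous cerebellar granule-cell (GrC) and
climbing-fiber (CF) two-photon calcium-imaging sessions recorded during a
delayed-reward forelimb reaching task — and for the question those
recordings pose: **can reward-evoked climbing-fiber spikes, through
classical GrC→Purkinje-cell LTD, convert a delay-spanning granule-cell
temporal basis into synaptic weights that read out elapsed time?**

It is written for systems neuroscientists working on cerebellar timing and
reward processing who want the full chain — fluorescence conditioning,
spike inference, behavioral event detection, trial alignment, response
classification, the LTD/LTP plasticity simulation with its null controls,
and population time decoding — as tested, composable R functions, plus a
ground-truth synthetic session generator so every stage can be validated
without recorded data.

## The model at the core

For each imaged PkC dendrite (reporting its CF input) and each CF spike
within [0, 0.25] s of reward, every GrC's mean z-scored activity *F* over
the eligibility window [−150, −25] ms before the spike becomes an LTD
event of magnitude

&nbsp;&nbsp;&nbsp;&nbsp;*m* = 1 / (1 + e^(−F/s)),&nbsp;&nbsp; *s* = the cell's 95th-percentile fluorescence,

with *F* rectified at zero by default. Event magnitudes are averaged over
all (trial, spike) events into one GrC weight vector per PkC, each vector
is normalized to unit sum, mean-subtracted, averaged across PkCs, and
negated (the sign of depression). GrCs most active just before the CF
teaching signal end up most depressed — and, it turns out, the weights
order GrCs by the *center time* of their delay activity, even for cells
whose activity peaks long before the eligibility window. A weighted GrC
sum with these weights is the predicted PkC component; its quality is
compared against time-shuffled LTD, randomly reordered weights, the
uniform GrC average, an LTP-adjusted variant, and the optimal 10-fold
cross-validated OLS time decoder.

## Worked example

```r
library(grcltd)

report <- run_pipeline(list(seed = 1,
                            synth = list(n_grc = 150, n_cf = 20,
                                         n_trials = 100)),
                       output_dir = "expert_run")

round(report$classification$frac_anticipatory_grc, 2)
#> [1] 0.36
round(report$plasticity$ltd_center_spearman, 2)
#> [1] 0.8
report$readout$comparison
#>        provenance     abs_r        r2
#> 1            true 0.7832226 0.6134376
#> 2    ltp_adjusted 0.8682478 0.7538542
#> 3   time_shuffled 0.4408596 0.1943572
#> 4       reordered 0.3270603 0.1069685
#> 5         uniform 0.2875705 0.0826968
#> 6 optimal_decoder        NA 0.8006552
```

Reading the numbers: on a synthetic expert session, 36% of GrCs are
classified anticipatory (the generator planted 34%); the Spearman
correlation between each GrC's predicted LTD magnitude and the center time
of its delay activity is 0.80; the LTD-weighted readout correlates with
elapsed time at |r| = 0.78, roughly doubling every trivial control and
approaching the optimal decoder's cross-validated R² of 0.80. The pipeline
persists the trial table, cell labels, weight vectors per provenance, and
a machine-readable `report.json`; identical configs give byte-identical
reports.

The same stages are available piecemeal: `simulate_session()`,
`condition_traces()`, `infer_cf_spikes()`, `detect_reaches()`,
`align_to_trials()`, `classify_anticipatory_grcs()`,
`compute_session_weights()`, `control_weights()`, `weighted_readout()`,
`decode_time_cv()`. See the methods vignette
(`vignettes/methods.Rmd`) for the model, the generator's design, and every
numerical choice.

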