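# farrowcast

Continuous prediction of farrowing onset in late-pregnancy sows from
video-derived activity time series.

## The problem

Knowing *when* a sow will start farrowing — continuously, in minutes, not as
a one-off alarm — lets farm staff time interventions that reduce stillbirth
and dystocia losses. Sows housed in farrowing crates show a characteristic
behavioral signature: activity is stable until roughly a day before onset,
then rises steadily until shortly before the first piglet is born, with
strongly increased variability on the final day, all superimposed on a 24-h
diurnal rhythm.

`farrowcast` implements the full pipeline for exploiting that signature:

1. **Activity quantification from dense optical flow.** For a flow field
   with per-pixel displacements \((u_i, v_i)\), the per-frame activity is
   the mean displacement magnitude
   \(A = \frac{1}{N}\sum_i \sqrt{u_i^2+v_i^2}\) (pixels/frame); per-segment
   activity is the sum \(A' = \sum_t A_t\) over the segment's frames (600
   frames for a 5-min segment at 2 fps), min–max normalized to \([0,100]\).
   Flow estimators (RAFT or any other) plug in as backends; a reference
   block-matching estimator and Middlebury `.flo` I/O are included, along
   with the standard flow scores EPE and Fl-all.
2. **Sliding-window remaining-time datasets.** Each sow's 96-h pre-onset
   series (1152 points at 5-min resolution) is cut into 6-h windows (72
   points, step 1 → 1081 windows/sow), each labeled with the minutes from
   its final point to farrowing onset, with strict subject-level
   train/validation/test splits.
3. **CLA-PTNet**, a hybrid regressor: a convolutional feature block
   (Conv1d + batch norm + ELU), an LSTM long-dependency encoder
   (+ dropout + ELU), and a **position-aware time-weighted self-attention**
   (PTW-SA) core in which a learnable positional matrix \(P\) is added to
   the hidden states, \(Q = H'W_Q,\; K = H'W_K,\; V = H'W_V\), each key row
   is rescaled by a learnable time weight \(w_i\)
   (\(K'_{i\cdot} = w_i K_{i\cdot}\)), and
   \(O = \mathrm{softmax}(QK'^T/\sqrt{d})\,V\) feeds a fully connected
   head. Forward and backward passes are implemented from scratch
   (RcppArmadillo kernels, Adam optimizer, finite-difference-verified
   gradients).
4. **Analysis utilities**: cross-sow Pearson correlation matrices and
   per-sow average activity correlation (AACC), STL decomposition to
   isolate the pre-farrowing trend from the diurnal cycle, per-day
   box-plot statistics, interval-wise MAE/RMSE/R² reports, and a
   return-on-investment calculator for deployment economics.
5. **A synthetic-cohort generator** that emulates the pre-farrowing
   activity regime (stable baseline, diurnal rhythm, 15 h → 2 h activity
   ramp, final-day dispersion burst, per-sow heterogeneity), so the entire
   pipeline is testable without farm video.

## Worked example

```r
library(farrowcast)

# simulate a 20-sow cohort and run the full pipeline on it
res <- run_pipeline(run_config(seed = 1), out_dir = "run1")

res$metrics
#> # A tibble: 2 × 6
#>   method            n   mae  rmse    r2 mae_reduction_pct
#>   <chr>         <int> <dbl> <dbl> <dbl>             <dbl>
#> 1 claptnet        868  103.  126. 0.837              61.9
#> 2 mean_baseline   868  271.  313. 0                  NA

as.data.frame(res$interval_report)[, c("interval", "n", "mae", "rmse", "r2")]
#>   interval   n       mae      rmse          r2
#> 1  30-24 h 292 423.75902 449.86907 -17.2326288
#> 2  24-18 h 288 106.83579 125.47114  -0.4579671
#> 3  18-12 h 288 118.06117 136.05486  -0.7143052
#> 4   12-6 h 288 140.55179 160.48343  -1.3851760
#> 5    6-0 h 288  51.61502  61.07934   0.6544995
```

Reading the output: on the four held-out sows, the model predicts remaining
time to onset with a mean absolute error of ~103 minutes over the final
18 h (a 62% improvement over always predicting the mean label), and the
interval report reproduces the characteristic pattern of continuous
farrowing prediction — useless 30–24 h out (activity has not changed yet, so
R² is strongly negative), increasingly accurate as onset approaches, best in
the final 6 h. `autoplot(res$model)` shows the training history,
`autoplot(res$interval_report)` the per-interval metrics, and
`plot_activity_cohort(res$cohort)` the simulated activity curves.

The same stages are available as a thin command-line wrapper:
`Rscript inst/cli/farrowcast.R pipeline --config cfg.yaml --out rundir`
(subcommands: `simulate`, `window`, `train`, `predict`, `report`, `roi`,
`pipeline`, `show-config`).

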