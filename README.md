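# statewarp

Noise-correlation analysis of pairwise first-spike latencies under
repeated sensory stimulation, for electrophysiologists and computational
neuroscientists studying millisecond-scale spike-timing codes.

When two neurons' first-spike latencies are plotted against each other
over the trials of one stimulus condition on which both spiked, responses
often fall into isolated clusters, and within a cluster the latencies
co-vary. `statewarp` asks whether that covariation is explained by
stimulus-response adaptation or by a shared per-trial excitability
("cortical state"), and what it implies for encoding capacity. The core
model is a linear single factor on each zero-centred cluster,

    s_i = lambda_i * eta + sigma_i,   i in {0, 1},

with `eta ~ N(0, 1)` the shared state, `lambda_i` the ms-per-state-unit
gain and `sigma_i` the residual sd. A cluster whose first principal
component lies at an angle `theta != 45` degrees (with
`theta45 = min(theta, 90 - theta)` folding out the neuron ordering) has a
latency *difference* that is warped by state; the spread of decodable
differences is compared across three regimes — the whole response
distribution (RDR 1), the stationary cluster (RDR 2), and conditioned on
state via `sigma_diff = sqrt(sigma0^2 + sigma1^2)` (RDR 3).

The pipeline: two-stage cluster extraction (a DBSCAN epsilon sweep with
isolation testing and flat 4-sigma expansion, then a three-round
bootstrap-ellipse refinement with 10,000 resamples); bootstrap estimation
of the principal-component angle with empirical 95% CIs; a stationarity
criteria battery with first-order differencing (rescaled by 1/sqrt(2))
and automated Box-Jenkins ARIMA detrending; factor fitting and RDR
summaries; per-trial state prediction and cross-cluster state
correlations. A synthetic-session generator reproduces the statistical
structure the analysis assumes (shared latent state, saturating
adaptation, unreliable 0/1 spiking, multi-cluster distributions) and
drives the surrogate controls: pair shuffling (derangement), matched
independent Gaussians, 45-degree replacement, and a distractor-cluster
construction.

## Worked example

```r
library(statewarp)
cfg <- read_config(system.file("extdata", "demo_session.yaml",
                               package = "statewarp"))
out <- run_pipeline(config = cfg, seed = 5,
                    settings = pipeline_settings(n_boot = 2000))
out$manifest[c("n_distributions", "n_stage1", "n_stage2",
               "n_stationary", "n_state_edges")]
#> $n_distributions  12
#> $n_stage1        199
#> $n_stage2         10
#> $n_stationary      7
#> $n_state_edges     4

cl <- out$cluster_results[[1]]
cl$correlation
#> r = 0.4447 (r2 = 0.1977), p = 0.000851, n = 53
cl$angle
#> theta = 34.30 deg (theta45 = 34.30), 95% CI [19.75, 48.20], 2000 bootstrap samples
cl$rdr
#> RDR1 10.06  RDR2 1.47  RDR3 1.43 ms
cl$factor_model
#> Single-factor model: lambda = (1.115, 0.759) ms/state,
#> sigma = (1.011, 1.011) ms, sigma_diff = 1.430 ms
head(out$state_correlations, 2)
#>          a        b n_common         r            p
#> 1 1|2|C2@1 3|4|C2@1       21 0.4674559 3.262142e-02
#> 2 1|2|C2@4 3|4|C2@4       35 0.6156075 8.278467e-05
```

Reading this: of 12 pairwise response distributions, 10 produced a unique
Stage 2 cluster. The shown cluster is stationary, correlated
(p = 0.00085) with angle 34 degrees; its within-cluster difference spread
(RDR 2, 1.47 ms) is far below the whole-distribution spread (RDR 1,
10.06 ms, inflated by the second latency cluster), and state conditioning
tightens it slightly further (RDR 3, 1.43 ms — the cluster sits near 45
degrees, where state carries little difference information). The state
correlations table links clusters sharing no neuron: their predicted
per-trial states correlate positively, as expected when one session-wide
state drives all pairs.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/statewarp.R run --config inst/extdata/demo_session.yaml \
        --seed 5 --out demo-out
```

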