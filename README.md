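# glifcolumn

Differentiable simulation and gradient-based training of cortical-column
spiking networks in R.

`glifcolumn` is for computational neuroscientists who want a desk-scale,
fully inspectable implementation of the modern "build it from biology, then
fit it to physiology" workflow for primary visual cortex models: construct a
cylindrical column of generalized leaky integrate-and-fire point neurons
with after-spike currents (GLIF3) from cell-type densities, laminar depth
ranges and connectivity statistics; simulate it at 1 ms resolution with
double-alpha synaptic kinetics; and train its recurrent and background
synaptic weights against physiological target statistics by
backpropagation through time with a surrogate spike derivative and a
sign-preserving multiplicative optimizer.

## The model in brief

Membrane dynamics per neuron (normalized so reset is 0 and threshold 1,
`alpha = e^{-dt/tau_m}`):

    v[n+1] = alpha v[n] + (1 - alpha) R i[n] - S[n]
    S[n]   = 1{refrac = 0} H(v[n] - 1)

with two after-spike currents that decay exponentially and increment at
spike steps, an absolute refractory counter, and a soft reset.  Synaptic
currents are double-alpha kernels
`A[(t/tau_f)e^{1-t/tau_f} + lambda (t/tau_s)e^{1-t/tau_s}]` realized as
linear state recursions; an optional shared alpha basis compresses the
per-neuron PSC state to `2 n_basis` values.

Construction composes a distance-dependent Gaussian wiring rule with an
orientation-dependent centroid displacement, like-to-like modulation of
excitatory pairs, and in-degree (target-size) modulation; weights follow
the log-normal quotient rule so the population PSP distribution exactly
matches its target log-normal; thalamic synapse counts are Yule-Simon;
background drive is calibrated to spontaneous-rate targets.

Training minimizes

    L = L_core + 0.1 L_peri + L_volt + L_w

with quantile-Huber rank matching of firing-rate distributions,
crowd-surrogate orientation/direction-selectivity matching, multi-scale
Fano-factor synchrony matching, a voltage regularizer and a Wasserstein-1
weight-distribution regularizer, using Exponentiated Adam — Adam moments
applied as multiplicative updates to positive weight magnitudes, so Dale's
law is preserved by construction.

A post-hoc analysis suite covers vector-sum OSI/DSI, preferred directions,
response sparsity, participation ratio, oracle correlations,
Kolmogorov-Smirnov similarity scores, like-to-like weight statistics,
outgoing-weight cohorts, and silencing perturbations.

## Worked example

```r
library(glifcolumn)

## build a ~300-neuron, four-type column through the full construction
## path, including background calibration to spontaneous-rate targets
net <- make_toy_network(300, seed = 7)
net
#> column network: 300 neurons (4 types), 3028 recurrent / 7773 LGN / 1200 background edges
#>   column radius 400 um (core 200 um), 80 LGN units, 100 background units

## simulate 1 s of spontaneous activity
set.seed(1)
out <- run_network(net, spont_lgn_spikes(net, 1000),
                   background_spikes(net, 1000), 1000)
tapply(rowSums(out$spikes), net$neurons$type, mean)
#>   L4_Exc       PV      SST      VIP
#> 2.950000 7.866667 3.133333 4.333333
```

The spontaneous rates land on the calibration targets (3, 8, 4, 5 Hz for
L4_Exc, PV, SST, VIP): the background calibration searches one weight scale
per cell model until each model's isolated rate matches.

```r
## drive it with a drifting grating through the surrogate LGN
mv  <- drifting_grating(C = 0.8, theta = 90, f_t = 2, f_s = 0.04,
                        duration = 500, field = net$config$lgn$field)
lgn <- bernoulli_spikes(surrogate_lgn_rates(mv, net$lgn_units))
evoked <- run_network(net, lgn, background_spikes(net, 500), 500)

## train two updates against synthetic physiological targets
tg  <- make_targets(unique(net$neurons$type), seed = 5)
res <- train_network(net, tg, train_config(epochs = 1, updates_per_epoch = 2),
                     seed = 3)
res$losses[, c("update", "total", "rate", "osi_dsi", "volt", "mean_rate")]
```

Each row reports the per-update loss components; `rate` is the
quantile-Huber rank-matching term, `osi_dsi` the selectivity term, and
`mean_rate` the network mean firing rate used by the runaway guard.
Trained weights keep their signs (Dale's law) and LGN weights are frozen —
both are asserted by the test suite after every optimizer step.

An executable command-line wrapper is installed at
`system.file("cli/glifcolumn", package = "glifcolumn")` with
`fixtures / build / simulate / train / analyze / perturb` subcommands.

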