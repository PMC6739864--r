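# frnldecode

Linear decodability of stimulus orientation through the firing rate
nonlinearity (FRNL) of V1 simple cells.

## The problem

V1 simple-cell membrane potentials are driven by oriented Gabor receptive
fields, so they carry orientation information — but they are jointly
modulated by nuisance parameters of the stimulus (phase, spatial period,
contrast). Under phase variability the response manifolds of different
orientations interleave, and a linear read-out of orientation from
membrane potentials fails entirely: a population can *encode* a feature
without that feature being *linearly decodable*. The firing rate
nonlinearity of the cells,

    r(u) = Φ · ⌊u − u_th⌋₊^κ ,

rectifies the low half of response space away. That loses total
information, but sparsifies the code and untangles it: linear decodability
of orientation from firing rates peaks at an intermediate firing threshold
a few mV above the mean membrane potential, while an optimal Bayesian
decoder (total information) only ever loses from thresholding. The
package is for computational neuroscientists who want to simulate this
trade-off, locate optimal thresholds and robust-performance regimes as a
function of cellular parameters, and test measured intracellular
thresholds against them.

What it provides:

* analytic Gabor / pixel / difference-of-Gaussians population responses to
  sine gratings (`make_population()`, `mean_response()`), with
  noise and correlation models (`noise_model()`, `sample_membrane_potentials()`);
* labelled stimulus banks with nuisance-parameter distributions
  (`bank_spec()`, `build_bank()`);
* a multinomial logistic decoder trained by Barzilai–Borwein gradient
  descent (`train_linear_decoder()`) and an optimal Bayesian decoder with
  nuisance marginalisation in the log domain (`optimal_posterior()`,
  `ilc_posterior()`);
* threshold sweeps, parameter scans, robust regimes, nuisance-feature
  decoding and heterogeneous-population experiments (`threshold_sweep()`,
  `parameter_scan()`, `robust_regime()`, `decode_nuisance()`,
  `heterogeneous_experiment()`);
* a synthetic intracellular-recording generator with ground truth
  (`synth_trace()`) and the analysis pipeline for real-style traces:
  spike removal, cycle-overlay parameter extraction, FRNL estimation and
  a threshold-optimality permutation test (`remove_spikes()`,
  `extract_cell_params()`, `estimate_frnl()`, `optimality_test()`).

## Worked example

A reduced model (120 cells, 5 orientation classes, phase nuisance) swept
over firing thresholds:

```r
library(frnldecode)
set.seed(1)
pop <- make_population(N = 120)           # Gabor population, uDC −60, uAC 12 mV
nm  <- noise_model(sigma = 3)             # 3 mV membrane-potential noise
bank <- build_bank(pop, bank_spec(K = 5, Mtheta = 4, Mphi = 20,
                                  Mrep = 3, Mrep_test = 6), nm)
sw <- threshold_sweep(pop, nm, bank, thresholds = seq(-70, -46, by = 2),
                      which = "both", n_eval_optimal = 600)
sw
#> <sweep_result> 13 thresholds (both); linear optimum at -56.00 mV (normalised 0.333)
round(sw$table[c(4, 6, 8, 10), c("threshold", "fc_linear", "fc_opt",
                                 "sparseness", "fc_predicted")], 3)
#>    threshold fc_linear fc_opt sparseness fc_predicted
#> 4        -64     0.265  0.997      0.115        0.291
#> 6        -60     0.523  0.977      0.500        0.588
#> 8        -56     0.618  0.870      0.886        0.793
#> 10       -52     0.447  0.525      0.990        0.522
cor(sw$table$fc_linear, sw$table$fc_predicted)
#> [1] 0.996
```

Reading the output: as the threshold rises, the optimal decoder's fraction
correct (`fc_opt`, a proxy for total information) falls monotonically,
while sparseness rises; their product structure
`(fc_opt − chance)·sparseness + chance` (`fc_predicted`) tracks the actual
linear decoder (`fc_linear`), which peaks at −56 mV, i.e. a few mV above
the −60 mV mean potential — total information is already being discarded
there, but what remains is linearly readable. At the full model
(N = 500, K = 10) the same sweep peaks at −57 mV, membrane-potential
decoding under variable phase is at the 10% chance level, and fixed-phase
decoding reaches ~87%.

The intracellular side:

```r
set.seed(8)
cell  <- cell_params(uDC = -60, uAC = 12, sigma = 3, uth = -45)
trace <- synth_trace(cell, n_trials = 10)     # 2 Hz drifting-grating trials
gen   <- remove_spikes(trace)                 # generator potential + spike times
extract_cell_params(gen)[c("uDC", "uAC", "sigma")]  # ≈ −60, 12, 3
estimate_frnl(gen)$threshold                  # ≈ −45
recorded_cells()                              # four reference simple cells
```

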