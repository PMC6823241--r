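# msadapt

Recurrent-network modeling of the monoaminergic neurotransmitter and
stress-hormone systems, for computational screening of chronic
antidepressant drug and hormone combinations.

## The problem

Chronic SSRIs relieve depression in only a minority of patients, and
augmentation with a second drug is largely trial-and-error.  One
candidate explanation is *degeneracy*: the brain has many ways to
neuroadapt to a chronic drug — many joint settings of the receptor and
transporter efficacies that restore key firing rates toward baseline —
and only some of those adapted states also raise the monoamines
(serotonin 5HT, norepinephrine NE, dopamine DA) and lower cortisol
(CORT) into a therapeutic range.  msadapt is for computational
neurobiologists and quantitative pharmacologists who want to build,
train, and interrogate such a model: enumerate the adapted states,
screen drug/hormone combinations by the monoamine profiles of their
adapted populations, and probe which adaptable components matter.

## The model

A recurrent network of sigmoidal units — one unit per brain region,
transmitter, hormone, receptor, transporter, or enzyme.  Unit activity
is x = σ(net) = 1/(1+e^(−net)) of the summed weighted input; the
network's response to a clamped 0/1 input pattern is its steady state
after 100 synchronous updates.  Connections carry a fixed sign and a
trainable magnitude in [0, 10] (floor 1 for the *canonical* class; an
integer structure matrix declares canonical ±2 / structure ±1 /
non-structure 0 classes).  Training is steady-state recurrent
back-propagation: settle, relax the adjoint system
y = f′(net)(e + Wᵀy), update magnitudes by −η·sign·(−y xᵀ) with
per-class learning rates (1 / 1 / 0.10), and clip to bounds; targets
are truth-table rows whose desired outputs are quantized to
{0.30, 0.40, 0.50, 0.60, 0.70} around the 0.50 baseline.

Neuroadaptation to a chronic input (drug units held at 1) is modeled
as discrete ±0.50 adjustments of ten transmitter-system-component
(TSC) weights — autoreceptors, transporters, glucocorticoid and CRF1
receptors — up to six total steps.  A configuration is **adapted**
when the summed |deviation from baseline| of DR, LC, VTA, and PVN
falls below the unadjusted (initial) error, and **therapeutic** when
5HT ≥ 0.70 and CORT ≤ 0.70.  On top of this the package provides
combination screening against reference vectors (baseline
[0.50 0.50 0.50], therapeutic [0.70 0.70 0.70], excess
[0.80 0.80 0.80]), FRIWA single-weight sensitivity sweeps with
resistant/sensitive classification, cross-network Pearson correlation
screening, and bounded temporal-logic checking of leads-to
propositions over adjustment trajectories.

## A worked example

The built-in demo model is a minimal serotonin/HPA circuit (12 units,
five training patterns: Baseline, SSRI, Dexamethasone, Stress,
Adrenalectomy).

```r
library(msadapt)
demo <- build_demo_model()
net <- initialize_network(demo$structure, seed = 1)
net <- train_network(net, demo$truth_table, ms_training_config(seed = 1))
net
#> <ms_network> 12 units (4 input, 3 hidden, 4 output, 1 bias); weight matrix 7 x 12
#>   connections: 5 canonical, 8 structure, 71 non-structure; 0 pruned

round(settle(net, c(SSRI = 1))$activities[c("DR", "5HT", "CORT")], 3)
#>   DR  5HT CORT
#>  0.4  0.6  0.7
```

The trained network reproduces the quantized targets: acute SSRI
moderately suppresses the dorsal raphe (0.40), moderately raises
serotonin (0.60), and maximally raises cortisol (0.70); the final
training RMS over all targeted outputs is 2.8e-4.  Enumerating every
TSC-strength configuration within six adjustment steps under chronic
SSRI:

```r
cfg <- enumerate_configurations(net, demo$tscs, max_degree = 6)
rec <- evaluate_configurations(net, cfg, "SSRI",
                               regions = demo$adapt_regions)
sum(rec$adapted); nrow(rec)
#> [1] 137
#> [1] 295
```

137 of 295 configurations lower the regional deviation below the
initial error of 0.2755 — many distinct ways to adapt, each with its
own serotonin and cortisol levels (the degeneracy at the heart of the
model).  Screening a combination and checking a temporal proposition:

```r
screen_combination(net, c("SSRI", "Dexamethasone"), demo$tscs,
                   max_degree = 3, regions = demo$adapt_regions)
#> <ms_screen> SSRI+Dexamethasone: fht 0.698 (n = 30)

ts <- build_transition_system(net, demo$tscs, "SSRI", budget = 4)
suite <- run_proposition_suite(list(ts))
suite[suite$form == "strong", c("tsc", "direction", "verdict")]
#>          tsc       direction verdict
#> 3  DR_5HT1AR desensitization    TRUE
#> 7   5HT_5HTT desensitization   FALSE
#> 11    AG_GCR desensitization   FALSE
#> 1  DR_5HT1AR   sensitization   FALSE
#> 5   5HT_5HTT   sensitization   FALSE
#> 9     AG_GCR   sensitization   FALSE
```

(The one TRUE row is vacuous: that autoreceptor weight sits too close
to zero for three downward steps to be reachable.)

Full-scale work — the 102-unit synthetic fixture, million-cycle
training, pruning, and the complete analysis battery — runs through
the command-line script:

```sh
Rscript inst/scripts/msadapt synth --seed 1 --out fixtures/
Rscript inst/scripts/msadapt pipeline --fixture demo --max-degree 3 --out run/
```

Every run writes a JSON manifest (command, flags, seeds, version) next
to its outputs.  See the vignette
(`vignettes/monoamine-stress-model.Rmd`) for the model's assumptions,
parameter meanings, and design decisions.

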