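---
title: "Modeling neuroadaptation to chronic antidepressants with msadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neuroadaptation to chronic antidepressants with msadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msadapt)
```

## The model

msadapt implements a recurrent-network model of the monoaminergic
neurotransmitter systems (serotonin/5HT from the dorsal raphe, DR;
norepinephrine/NE from the locus coeruleus, LC; dopamine/DA from the
ventral tegmental area, VTA) and the hypothalamic–pituitary–adrenal
(HPA) stress axis (PVN, pituitary, adrenal gland, cortisol/CORT).
Every biological entity — a brain region, transmitter, hormone,
receptor, transporter, or enzyme — is one sigmoidal unit; every
directed influence is one signed connection weight.  A unit's activity
is the logistic function $\sigma(net) = 1/(1+e^{-net})$ of its summed
weighted input, so activities live in $(0,1)$ with $0.50$ the
"spontaneous" level of an unconnected unit.  The network's response to
an input pattern (drugs, hormones, or manipulations clamped to 0/1) is
its steady state after 100 synchronous updates.

Connections come in three classes, declared by an integer *structure
matrix*: **canonical** weights (entries $\pm 2$) are the key
monoamine–stress interactions, **structure** weights ($\pm 1$) other
empirically established interactions, and **non-structure** weights
(0) free connections that training may or may not exploit.  At full
scale the model has 102 units (40 inputs, 23 outputs, 38 hidden, one
constant bias sender), a $61 \times 102$ weight matrix (6222 weights:
23 canonical, 305 structure, 5894 non-structure).

Training targets are a *truth table*: input patterns paired with
desired steady-state outputs quantized to five levels, 0.30 (maximal
decrease) through 0.70 (maximal increase) around the 0.50 baseline,
with blanks where no finding constrains an output.

## Fixed signs, trainable magnitudes

Weight magnitudes are bounded in $[0,10]$, with a floor of 1 for
canonical weights so they always exert an influence.  Reconciling a
non-negative magnitude bound with inhibitory connections requires a
representational choice: each connection carries a **fixed sign**
(the declared valence for canonical/structure connections; drawn once,
$\pm 1$ equiprobably, for non-structure connections) and a trainable
**non-negative magnitude**.  The effective weight is their product.
Initial magnitudes are uniform on $[1,2]$ for canonical and $[0,1)$
for all other connections — ranges chosen so every class starts inside
its bounds with room to move in both directions.

A bookkeeping subtlety: 40 input units plus a 102-unit total implies
62 non-input units, yet the weight matrix has 61 rows.  The package
resolves this with a constant bias unit that sends but never receives:
40 + 23 + 38 + 1 = 102 columns and 23 + 38 = 61 receiving rows.

## Training

`train_network()` performs steady-state gradient descent in the style
of recurrent back-propagation: each cycle draws one pattern uniformly
at random, settles the network (100 iterations), relaxes the adjoint
error-propagation system $y = f'(net)\,(e + W^\top y)$ on the same
schedule, and updates magnitudes by $\Delta m_{ij} = -\eta_{class}
\cdot s_{ij} \,\partial E/\partial w_{ij}$ with
$\partial E/\partial w_{ij} = -y_i x_j$, clipping to the class bounds.
The error functional is the summed squared deviation over *targeted*
outputs only; blank truth-table cells contribute nothing.  Learning
rates are 1 for canonical and structure weights and 0.10 for
non-structure weights, disadvantaging connections with no empirical
support.  The adjoint relaxation shares the forward settle's 100
iterations and reports its final update size as a convergence
diagnostic; the test suite verifies the gradient against central
finite differences at relative tolerance $10^{-4}$ on randomized small
networks.

Checkpoint RMS error is recorded every `cycles/100` cycles.  The
full-scale schedule is $10^6$ cycles; the demo model (below) trains
well at the default $2 \times 10^4$ (well under a minute on one core).

## Pruning

`weight_sensitivity()` scores each non-structure connection by the
change in table-wide RMS error when that connection alone is lesioned
to magnitude 0.  The signed change is recorded (a lesion can help);
ranking uses its absolute value.  `select_cutoff()` picks the cutoff
that generalizes best: train on single-manipulation patterns, prune,
retrain on singles, and score on the held-out combination patterns,
averaging over seeds; candidate cutoffs default to the deciles of the
observed sensitivity distribution.  `prune_and_retrain()` then prunes
at the cutoff (strict inequality, so ties at the cutoff survive),
freezes the mask, and retrains on the full table.  Canonical and
structure connections are never pruned.  The lesion statistic is this
package's concrete operationalization of sensitivity-based pruning:
it is deterministic given the trained network, directly testable, and
needs no tuning parameters beyond the cutoff itself.

## Neuroadaptation as configuration enumeration

Ten connection weights represent transmitter-system components (TSCs)
known to adapt under chronic drug exposure: the autoreceptors on DR,
LC, and VTA (5HT1AR, AR2, D2R), the three monoamine transporters
(5HTT, NET, DAT), the glucocorticoid receptors on PVN, pituitary, and
adrenal, and the pituitary CRF1 receptor.  Chronic administration is
simulated by clamping drug inputs at 1; neuroadaptation by discrete,
unsupervised adjustments of TSC magnitudes in $\pm 0.50$ steps within
$[0,10]$, up to a total of six adjustments (the *degree*, counted as
the L1 norm of the offset vector across all ten TSCs).

`enumerate_configurations()` generates exactly the offset vectors with
degree $\le d$ whose magnitudes stay in bounds.  Because any such
vector is reachable by adjusting each TSC monotonically, direct
lattice generation equals the breadth-first closure over single-step
moves; the suite property-tests this equivalence, and in the
no-clipping regime the count matches the closed form $\sum_k 2^k
\binom{10}{k}\binom{d}{k}$ (221 at $d = 2$; 134,245 at $d = 6$).

Each configuration is settled under the chronic input and scored by
its **adaptation error**: the summed absolute deviation of the key
region units (DR, LC, VTA, PVN) from their no-drug baselines.  A
configuration is **adapted** when this error is strictly below the
**initial error** of the unadjusted network under the same input
(computed once and cached), and **therapeutic** when 5HT $\ge 0.70$
and CORT $\le 0.70$ (inclusive thresholds; optional NE/DA floors).
The 0.70 serotonin floor doubles the acute-SSRI increase of 0.10 over
baseline; the CORT ceiling reflects the decrease from the acute level.
Histograms of adapted levels use left-closed bins of width 0.03
anchored at 0 (the anchor is this package's choice; only the width is
inherited).

## Screening, FRIWA, correlations, temporal logic

`screen_combination()` evaluates a drug/hormone pair or triple over
several independently trained networks (three by default, mirroring
inter-individual variability), pools adapted configurations by
concatenation, and averages the monoamine levels into a vector
[5HT NE DA].  `rank_combinations()` orders vectors with any component
above 0.80 by Euclidean distance from the excess reference
[0.80 0.80 0.80], and all others (plus a baseline row) by distance
from the therapeutic reference [0.70 0.70 0.70] — Euclidean because
only "vector distance" is specified; ties break by name for
determinism.  Averages use adapted configurations only: adaptation is
the precondition for a chronic steady state to be observable at all.

`friwa_sweep()` (full-range individual-weight adjustment) starts from
every adapted-and-therapeutic configuration and sweeps one TSC at a
time across $[0,10]$ in 0.50 steps relative to its start value
(20 candidates per TSC for an on-grid interior start), freezing the
other nine.  Candidates partition into *excluded* (no longer adapted),
*resistant* (adapted, still therapeutic), and *sensitive* (adapted,
no longer therapeutic).  Class means per TSC exclude each record's own
swept TSC, whose value was manipulated rather than adapted; the same
exclusion applies to the pairwise Pearson correlations (45 pairs at
full scale), which are "reported" only when significant at
$\alpha = 0.05$ with a consistent sign in every network.  Pearson is
used because no statistic is specified and the TSC magnitudes are
continuous-valued grid variables; no multiple-testing correction is
applied beyond the cross-network consistency filter, which is the
reference protocol's own guard.

`build_transition_system()` and `check_leads_to()` treat adjustment
*trajectories* rather than endpoints: states are configurations,
moves single $\pm 0.50$ adjustments, and the leads-to proposition
$a \mapsto c$ holds when, along every maximal move sequence from the
origin, each position satisfying $a$ is followed (then or later) by
one satisfying $c$.  Semantics are finite-trace with an explicit move
budget of 6: revisits consume budget, so the checker memoizes
(configuration, moves-remaining) pairs; the suite verifies it against
exhaustive path enumeration on small systems.  "Sensitized by at least
three steps" is read as a net offset of $\ge +3$ (and $\le -3$ for
desensitization): offsets, not move histories, determine the network's
state.  The built-in suite checks, for each TSC and direction, the
strong form `TSC_sens_gt_3 |-> fht_high /\ cort_low` and the weakened
form that also accepts losing the adjustment, and reports per-network
verdicts plus a consistency flag.

## The fixtures: demo and synthetic full scale

`build_demo_model()` is a deterministic, hand-sized serotonin/HPA
circuit: DR→5HT(+), 5HT→5HT1AR(+), 5HT1AR→DR(−), 5HTT→5HT(−),
SSRI→5HTT(−), Stress→DR(+), Stress→AG(+), AG→CORT(+), CORT→GCR(+),
GCR→AG(−), Dexamethasone→GCR(+), Adrenalectomy→AG(−), 5HT→AG(+), with
a five-row truth table (Baseline, SSRI, Dexamethasone, Stress,
Adrenalectomy) and three adjustable TSCs (5HT1AR→DR, 5HTT→5HT,
GCR→AG).  The edge list is a concrete completion of the simplified
schematic it realizes, chosen so each truth-table row is causally
reachable (Adrenalectomy must inhibit AG for CORT to fall to 0.30).
Because the demo has neither LC, VTA, nor PVN, its adaptation error is
taken over its two region units, DR and AG.

`generate_synthetic_fullscale()` emulates the *dimensions* of the
complete model — every count above, exactly — without transcribing
the literature-derived connection list and truth-table content, which
this package deliberately does not reproduce.  Structure connections
are placed at random (valence $\pm 1$ equiprobable) outside the 23
fixed canonical slots, seeded so that every output unit is reachable
from some input through declared connections (checked by graph
reachability at generation time).  The synthetic truth table has a
baseline row, one single row per input with 4–8 random quantized
targets, and 25 combination rows whose targets sum the constituent
singles' deviations from 0.50, saturate at the 0.30/0.70 extremes,
and re-quantize to the 5-level grid — giving the table the
single/combination generalization structure the pruning procedure
needs.  Identical seeds yield byte-identical files.

What the synthetic fixture does *not* emulate: real connection
placement, real target assignments, and any biological coherence
between them.  Tests passing on it demonstrate dimensional and
procedural fidelity — the machinery computes the right quantities on
inputs of the right shape — not that this package's trained synthetic
networks reproduce the reference model's biology.

## Numerical and scale choices

- Sigmoid: the standard logistic with unit slope; only "sigmoidal in
  (0,1) with value 0.50 at 0" is constrained, and the logistic is the
  field's default.
- Updates are synchronous from the previous iteration's activities;
  settles start from 0.50 for non-clamped units and are bitwise
  deterministic.
- Grid comparisons use a $10^{-9}$ tolerance so accumulated 0.5-step
  arithmetic never drops a boundary configuration.
- Enumeration de-duplicates by offset vector; with all TSCs at least
  $d \cdot 0.5$ from both bounds the count equals the closed form,
  and clipping only ever shrinks it.
- The degree-7 enumeration is omitted by design everywhere, matching
  the reference protocol's bound of six.
- Problem sizes in the test suite: the demo model trains at
  $2 \times 10^4$ cycles (seconds); property tests use networks of
  $\le 12$ units, enumerations to degree 6 only for counting,
  transition systems with 1–3 TSCs and budgets $\le 6$.  These sizes
  keep the whole suite to a few minutes while exercising every code
  path; full-scale training ($10^6$ cycles on the 102-unit network)
  runs for hours and is reserved for real use via the CLI.

## Known limitations

- The synthetic full-scale fixture supports shape- and
  procedure-level validation only (see above); quantitative anchors
  that depend on the literature-derived structure matrix and truth
  table (final full-scale training error, the exact pruned fraction)
  are not asserted against it.
- Combinations are binary input activations; there is no
  pharmacokinetics, dosing, or receptor-affinity modeling.
- Adaptation is the discrete, unsupervised grid process; no
  continuous or gradient-based adaptation dynamics are provided.
- The leads-to fragment is the only temporal operator; there is no
  general LTL (no U/X, no infinite traces, no automata).
- Whether non-structure connections were sign-constrained in the
  reference implementation is unstated; fixing their random signs is
  this package's choice, and its main consequence is that training
  cannot flip an unhelpful non-structure valence, only silence it.

## A worked session

```{r demo-train, eval = FALSE}
demo <- build_demo_model()
net <- initialize_network(demo$structure, seed = 1)
net <- train_network(net, demo$truth_table, ms_training_config(seed = 1))
settle(net, c(SSRI = 1))$activities[["5HT"]]        # ~0.60
settle(net, c(Dexamethasone = 1))$activities[["CORT"]]  # ~0.30

cfg <- enumerate_configurations(net, demo$tscs, max_degree = 6)
rec <- evaluate_configurations(net, cfg, "SSRI",
                               regions = demo$adapt_regions)
table(adapted = rec$adapted)
```

The same workflow scales to the full synthetic fixture through the
`msadapt` command-line script (`inst/scripts/msadapt`): `demo`,
`synth`, `train`, `prune`, `adapt`, `screen`, `friwa`, `ltl`, and
`pipeline` subcommands, each writing delimited tables and a JSON
manifest that records the command, flags, seeds, and package version
for reproducibility.
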