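# gcmyc

Agent-based simulation of **permissive positive selection** in germinal
centers (GCs), with the in-silico cytometry and model-selection machinery
needed to interrogate it.

## The problem

GC B cells cycle between a dark zone (DZ), where centroblasts divide and
hypermutate their B-cell receptor, and a light zone (LZ), where
centrocytes capture antigen and compete for limited T follicular helper
(TFH) signals. Positively selected LZ cells switch on cMyc and progress
through a chain of subpopulations — newly selected (**early**),
plasmablast precursors (**prePB**), **lateCD23int** and **lateCD23lo**
cells en route to the DZ, and cMyc+ **DZ** entrants. Selection is
*permissive*: most newly selected cells carry low-affinity receptors and
are protected from apoptosis, yet DZ entrants end up with higher affinity
because high-affinity cells proliferate preferentially inside the LZ.

`gcmyc` implements this system as a stochastic agent-based model. Each
B-cell agent carries zone, cell-cycle phase with timers, a shape-space
position (affinity `exp(-d^2/gamma^2)` to an optimum on a 4-D integer
lattice), captured antigen, integrated TFH signal, a cMyc subpopulation
state with an MFI-like level, EdU/BrdU/CTV/pH3 labels, and a division
allowance. Selected cells make a fixed 90%:10% recycle:output fate
decision. The cMyc+ subpopulation chain is a configurable transition
topology; `model_zero()` is the working model
(`NONE → EARLY → {PREPB | LATE_INT → LATE_LO → DZ_CMYC → NONE}`), and
candidate topologies are ranked against census time courses by residual
sum of squares and the corrected Akaike information criterion,

```
AICc = n log(RSS/n) + 2k + 2k(k+1)/(n-k-1).
```

## A worked example

```r
library(gcmyc)

cfg <- gc_config(founders = 80)
tc  <- simulate_gc(cfg, model_zero(), seed = 1, replicates = 4, days = 7)

day7 <- dplyr::filter(aggregate_timecourse(tc), time_h == 168)
round(100 * day7$mean / day7$mean[day7$population == "cmyc"], 1)
#> early 3.4, prepb 2.6, late_int 40.8, late_lo 16.8, dz 36.4 (% of cMyc+)
```

At day 7 the simulated cMyc+ compartment is dominated by the lateCD23int
subpopulation (~41%), the DZ subpopulation follows (~36%), and the newly
selected and prePB subpopulations are rare (~3%) — the observed census
structure. The fate-decision counter over the same run shows the fixed
recycle:output split:

```r
ev <- attr(tc, "events")[[1]]
100 * ev$n_recycle / (ev$n_recycle + ev$n_output)
#> 89.1  (n = 1546 decisions; 90% within binomial noise)
```

The in-silico dual-pulse experiment (1 h EdU, then 1 h BrdU, on a
steady-state cycling population) and its derived estimators:

```r
x <- simulate_cycling(3000, hours = 8, seed = 1)
time_to_tetraploid(x)   # hours for the early-S cohort median to reach 4n
#> 3.6
s_phase_duration(dual_label_counts(x$cells, interval = 1))
```

Division tracking and the pooled unmutated-clone fraction:

```r
ctv <- simulate_gc(ctv_transfer_config(), model_zero(), seed = 2,
                   replicates = 4, days = 70/24, keep_state = TRUE)
ctv_composition(dplyr::bind_rows(attr(ctv, "cells")))

unmutated_fraction(gc_fixtures()$clone_table)
#> 8.641975   (14 of 162 sequenced clones; prints as 8.6%)
```

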