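---
title: "The gcmyc model: permissive selection and cMyc+ subpopulation dynamics in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gcmyc model: permissive selection and cMyc+ subpopulation dynamics in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmyc)
```

## The biological problem

Germinal centers (GCs) improve antibody affinity by cycling B cells between a
dark zone (DZ), where centroblasts divide and hypermutate their B-cell
receptor (BCR), and a light zone (LZ), where centrocytes capture antigen and
compete for T follicular helper (TFH) cell help. Positive selection marks LZ
cells with the transcription factor cMyc. Reporter-mouse cytometry resolves
the cMyc+ compartment into five subpopulations — `EARLY` (newly selected),
`PREPB` (plasmablast precursors), `LATE_INT` and `LATE_LO` (CD23
intermediate/low cells en route to the DZ), and `DZ_CMYC` (recent DZ
entrants still cMyc+). The puzzle this model addresses is *permissive*
selection: newly selected cells are predominantly of low affinity and are
protected from apoptosis, yet the affinity of DZ entrants is higher than
that of newly selected cells, because high-affinity cells proliferate
preferentially inside the LZ between selection and DZ re-entry.

`gcmyc` implements this picture as an agent-based model plus the in-silico
instruments used to interrogate it (EdU/BrdU dual pulse labeling, DNA
content, phospho-histone H3, CellTrace division tracking), and a
model-selection harness that ranks alternative subpopulation transition
topologies against census time courses by residual sum of squares (RSS) and
the corrected Akaike information criterion (AICc).

## The agent-based model

Each agent carries a zone (DZ/LZ), a program (centroblast CB, centrocyte
CC, or selected), a cell-cycle phase (G0/G1/S/G2/M) with a per-phase timer,
a shape-space position, captured antigen, integrated T-cell help
("tc signal"), a cMyc subpopulation state with an MFI-like level, label
states, a division counter, and a remaining-divisions allowance. One step
of `gc_step()` applies, in fixed order: cycle progression and division;
hypermutation at DZ division; DZ-to-LZ transit when divisions are
exhausted; antigen capture; rationed TFH contacts; selection; the
subpopulation state machine (fate decisions before timers, at most one
transition per cell per step, ties between cells resolved by random
jitter); apoptosis of unselected centrocytes; label pulses; and cMyc level
decay. The fixed order makes runs bit-for-bit reproducible under a seed.

Key mechanisms and their defaults:

* **Shape space and affinity.** BCRs live on a 4-D integer lattice of
  extent 40; affinity is `exp(-d^2 / gamma^2)` with `gamma = 2.8` lattice
  units, 1 at the optimum. Hypermutation moves one random coordinate by one
  step (clamped at the boundary so ordering is preserved at edges), with
  probability 0.2 per daughter per DZ division. Founders are drawn at
  distance 3–5 from the optimum, so all start below maximal affinity. The
  kernel, dimension and mutation kinetics are package choices isolated
  behind the `affinity_model()` interface; only their qualitative behavior
  (smooth, bounded, locally mutable) matters downstream. The high/low
  affinity gate sits at 0.5 of maximal affinity (closed boundary), and the
  scenario constants — a reference association constant of 2e10 1/M and a
  13,000-fold drop for the mutant antigen — let the gate be re-expressed on
  the Ka scale via `k_low()`.
* **Cell cycle.** G1/S/G2/M last 2/4/1.5/0.5 h (8 h total, the upper end of
  the 6–8 h GC cycle), each drawn with ±10% uniform jitter per cell per
  phase to avoid artificial synchrony. DNA content is 2n through G1, rises
  linearly across S, and is 4n in G2/M; pH3 is true exactly during M.
* **Selection.** Centrocytes attempt antigen capture once per step with
  success probability equal to affinity (so the capture *rate* is
  affinity-proportional per unit time at fixed `dt`). TFH help is rationed:
  at most `tfh_capacity` (default 4) contacts per step across the LZ,
  awarded to the highest presented antigen with random tie-breaking; each
  contact adds `antigen` units of signal. A cell is selected when its
  integrated signal reaches the threshold (10) after at least 3 contacts.
  This is *permissive* in the sense that low-affinity cells are selected
  too, only later; and selected cells are never subject to the
  centrocyte-lifetime apoptosis rule (10 h), mirroring the protection of
  cMyc+ cells from cell death.
* **Fate decision.** After the `EARLY` dwell, cells recycle to the DZ
  branch with probability 0.90 or leave for the output branch with
  probability 0.10 — a fixed constant of the model, not a fit target.
  Output cells dwell as `PREPB` for 6 h and then exit; low-affinity output
  cells are recorded as memory-precursor (MBC) output with probability 0.5,
  the rest as plasmablasts.
* **Affinity-dependent LZ proliferation.** cMyc+ LZ cells start a division
  cycle at 0.12/h (high-affinity gate) vs 0.04/h (low), the mechanism that
  enriches affinity between selection and DZ entry.
* **DZ division allowance.** Recycled cells receive 4 divisions plus one
  per affinity quartile above the population median (cap 6). The base of 4
  (rather than a minimal 2) keeps the cMyc+ compartment at a few percent of
  the GC, matching the observed 3–7% — with base 2 the cMyc+ fraction would
  sit near 25%, because the cMyc-negative DZ and centrocyte pools would be
  far too small relative to the cMyc+ chain.

## The subpopulation state machine

`gc_topology()` encodes transition graphs over the cMyc+ states with
event- and timer-triggered edges. The working model (`model_zero()`) is:
selection puts a cell into `EARLY`; after `t_early` (1 h) the 90:10 fate
decision routes it to `LATE_INT` or `PREPB`; `LATE_INT` becomes `LATE_LO`
after `t_split` (12 h); `LATE_LO` differentiates into a DZ centroblast
(`DZ_CMYC`) after `t_latelo` (3 h); cMyc is lost a fixed `t_dzloss` (5 h)
after DZ entry; `PREPB` exits the GC after `t_prepb` (6 h). All five dwell
times are free parameters of the fit. We parameterize per-state dwells (the
total LATE residence is `t_split + t_latelo`), which keeps the generic
engine uniform across alternative topologies. The dwell defaults were
calibrated once, by steady-state occupancy arithmetic against the day-7
census shares (newly selected and prePB cells rare at 3–5% each, lateCD23int
the largest at 37–53%, DZ at 28–39%), before any fitting machinery existed.

The cMyc reporter level is set to 100 at selection and decays exponentially
with a 12-h half-life (so the observed 8-h stimulus-free maintenance holds
with margin); it is multiplied by 0.3 while pH3+ for *reporting only*,
mirroring the mitotic drop of cMyc protein without touching subpopulation
membership. The half-life is a package choice: the data constrain only the
ordering of mean levels across subpopulations and the 8-h maintenance, not
the kinetics.

Four *illustrative* alternative topologies ship with the package
(`topology_alternatives()`): prePB branching later in the chain, direct DZ
entry without LATE states, no late split, and the fate decision at the last
LZ state. They are constructions for exercising the model-selection
harness, not reconstructions of any externally specified variants.

## In-silico cytometry

* **Dual pulse.** EdU for 1 h, then BrdU for 1 h. Any cell that touches S
  during a window (at `dt` resolution) is labeled, permanently, and labels
  are inherited — mirroring thymidine-analog chemistry with perfect
  detection; observation noise belongs to the synthetic-data layer.
  EdU−BrdU+ cells are early-S, EdU+BrdU+ mid/late-S, EdU+BrdU− post-S. The
  S-phase duration estimator is `(n_midlateS / n_postS) * interval`; at
  steady state with sharp 1-h windows it is nearly unbiased (the mid/late-S
  window spans one S-phase duration of entry times, the post-S window one
  interval), with a small downward bias from population growth during the
  windows, documented by the recovery tests (estimates for a true 4-h S
  phase fall in 3–5 h).
* **2n-to-4n kinetics.** `simulate_cycling()` runs a pure steady-state
  cycling population (uniform random position along the cycle) under the
  pulse protocol and tracks the median DNA content of the EdU−BrdU+
  cohort. `time_to_tetraploid()` reports hours from the *end of the BrdU
  window* (the first post-labeling observation, which is how a pulse-chase
  doubling time is read off) until the cohort median first reaches 4n;
  with the default phase durations this is about 3.5 h, within the 4 h
  reported in vivo.
* **Post-S diploid fraction.** Among EdU+BrdU− cells, the percentage with
  DNA content below 3.0 — the 2n/4n gate boundary is a documented package
  convention (real gates are drawn on a dye histogram). Faster G2/M
  (DZ-like) yields a higher diploid fraction than slower G2/M (LZ-like).
* **Division tracking.** `ctv_generation` increments by one per division in
  both daughters, so dye mass `sum(2^-generation)` is conserved exactly.
  `ctv_composition()` bins cMyc+ cells into div4–div6 and div7+ and
  reports subpopulation percentages per compartment;
  `transit_fractions()` turns consecutive compartments into per-boundary
  ratios and differences.

## The division-tracked scenario

`ctv_transfer_config()` emulates the adoptive-transfer experiment behind
the division-compartment analysis: 1,000 stained founders activate
asynchronously over 48 h, carry a heritable cell-cycle speed multiplier
drawn from 0.6–1.6 (heterogeneous proliferative capacity of activated
lineages), and receive a founder division allowance of 4, 5 or 6 with
declining weights (0.68/0.24/0.08 — large clonal bursts are rarer). Under
these conditions the influx of *newly selected* cells declines with
division number while LZ divisions cascade older cMyc+ cells into deeper
compartments, so the expected EARLY share among cMyc+ cells decreases from
div4 to div6 — the division-coupled progression signature. The gradient is
a difference of small percentages estimated from a few hundred cells per
compartment, so tests pool replicates and run under fixed seeds; the
packaged reference table carries the printed in vivo percentages, which the
simulation mirrors qualitatively (monotone decline), not numerically.

## Synthetic data and calibration

The synthetic-data module makes every pipeline stage testable without
external data. `gc_fixtures()` loads three plain-text reference tables
(day-7 census, CTV composition, clone mutation counts); slots that were
not published numerically (the lateCD23lo census count, the prePB CTV
rows) are flagged rather than invented. `gc_calibration()` completes the
census: lateCD23lo from its compartment-share remainder (13.5%), the GC
total from a 5% cMyc+ fraction — both flagged `derived`.
`generate_timecourse()` draws per-mouse counts log-normally (CV 0.3,
consistent with the printed SEMs over 15 mice) around a log-normal pulse
that rises from about day 4, peaks near day 10 and declines to day 21,
scaled so every population passes through its anchor on day 7. All
populations share the pulse shape, so the dataset's compartment shares are
constant at their anchored values — the feature the fit must recover. What
the generator does *not* emulate: mouse-to-mouse kinetic differences,
cytometry spillover and gating error, and the real (unpublished) shape of
each subpopulation's time course; passing fits therefore demonstrate
recovery of compartment structure under idealized observation, not
field-realistic robustness.

`generate_from_simulator()` produces ground-truth datasets from the model
itself (with optional log-normal observation noise and provenance
metadata) for the model- and parameter-recovery experiments.

## Fitting and model selection

`fit_topology()` is a grid search: for each candidate parameter point the
model is simulated (default 20 replicates — scaled down from the 100
display replicates), replicate censuses are averaged, and *both* the
simulation and the data are normalized by the candidate's own simulated
GC-curve maximum — the single-divisor convention is preserved exactly, so
the divisor depends on the candidate under evaluation. The RSS sums
squared differences over populations and observed time points, with linear
interpolation of the simulation to the data times. AICc is the standard
least-squares form `n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `n` the
number of fitted points and `k` the number of grid dimensions;
`rank_models()` sorts candidates by AICc with RSS and name tie-breaks.
Grid points share replicate seeds (common random numbers), making the
argmin deterministic given the seed and less noise-sensitive. A failed
grid point is excluded with a warning rather than aborting the fit.

Design choices worth stating:

* The *fitted populations* are the cMyc+ compartment curves (total plus the
  five subpopulations). The GC-total curve serves as the normalization
  reference rather than entering the RSS: the topology's free parameters
  govern the internal structure of the cMyc+ compartment, while the GC
  total is set by selection throughput, which the timing parameters barely
  move — including it would let its shape noise dominate the objective.
* The packaged fitting example and the acceptance script express the
  synthetic calibration at per-GC scale (`scale = 0.01`): the printed
  census is per spleen, i.e. pooled over the many GCs of a responding
  spleen, while the simulator follows one GC; one percent of the splenic
  compartment per GC aligns the cMyc+ magnitudes.
* Fit problem sizes (documented as the package's own choices): a single-GC
  configuration with 60 founders, TFH capacity 3 and `dt = 0.2` h,
  days 6–7 of the calibration course, a 3x3 grid over `t_early` in
  {0.5, 1, 2} h and `t_split` in {9, 12, 15} h, 20 replicates per point.
* The data trajectory before day ~5 reflects GC coalescence that the
  simulator (which seeds all founders at time zero) does not model, so
  early days carry systematic shape mismatch; the fit window starts at
  day 6.

## Numerical choices and degenerate inputs

Forward stepping uses `dt = 0.1` h (0.2 h in the fitting scenario);
`dt` must not exceed the shortest jittered, speed-scaled phase. The capture
attempt is per step, so `dt` is part of the scenario definition, not a pure
discretization. Event order within a step is fixed; at most one
subpopulation transition fires per cell per step, with event triggers
evaluated before timers. Empty states are no-ops: a zero-day simulation
returns only the initial census; an empty fate queue changes no counters;
`s_phase_duration()` and `post_s_diploid_fraction()` return `NA` with a
warning when their gate is empty (the "undefined" convention of sparse
gates); a zero-founder GC is an error. Dead and exited agents are zeroed in
place and compacted lazily, which keeps the per-step cost linear and the
integer censuses exact.

## Known limitations

* Zones are compartments: no spatial lattice, chemokine fields or FDC
  geometry; transit is timed, not migratory.
* The GC has no late contraction mechanism (antigen consumption, TFH
  waning), so simulated kinetics plateau rather than decline after day 10;
  fits therefore use the rising phase.
* Founders seed once at time zero; ongoing immigration of new clones is
  out of scope, as are antibody feedback and CD40-mediated compensation
  (permissiveness enters only through the threshold and contact rules).
* The affinity kernel and mutation scheme are stand-ins with the right
  qualitative shape; absolute affinities are not mapped to physical Ka
  except through the scenario constants.
* cMyc level kinetics beyond ordering and 8-h maintenance are not
  constrained by data.

## A worked example

```{r example, eval = FALSE}
cfg <- gc_config(founders = 80)
tc <- simulate_gc(cfg, model_zero(), seed = 1, replicates = 4, days = 7)
day7 <- dplyr::filter(aggregate_timecourse(tc), time_h == 168)
shares <- 100 * day7$mean / day7$mean[day7$population == "cmyc"]
autoplot(tc)

# model selection against a synthetic calibration course
data <- generate_timecourse(gc_calibration(), days = 6:7, n_mice = 5,
                            noise_cv = 0.3, seed = 101, scale = 0.01)
grid <- tidyr::expand_grid(t_early = c(0.5, 1, 2), t_split = c(9, 12, 15))
fit <- fit_topology(data, model_zero(), grid,
                    gc_config(founders = 60, tfh_capacity = 3, dt = 0.2),
                    replicates = 20, seed = 1, days = 7,
                    populations = c("cmyc", "early", "prepb", "late_int",
                                    "late_lo", "dz"))
glance(fit)
```

The `cli`-style surface of the package is its function set plus the
TSV/YAML round-trip I/O (`write_timecourse()`, `write_config()`,
`write_topology()`, `validate_topology()`, `write_manifest()`); a shell
entry point would add nothing for an analysis package of this kind.
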