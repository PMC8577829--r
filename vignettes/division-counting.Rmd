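---
title: "Counting cell divisions from fluorescent tag dilution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cell divisions from fluorescent tag dilution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icountr)
```

## The measurement principle

Recombination-induced tag exchange (RITE) division counters tag a stable,
replication-replenished protein — typically the replication-coupled histone
variant H3.1, or the core nucleoporin NUP155 — with an old fluorophore
("red").  An induced recombination event swaps the tag cassette so that all
*newly synthesised* protein carries a new fluorophore ("green").  Because
the tagged protein is only made during S phase and mitosis partitions the
pool symmetrically between daughters, each completed division halves a
cell's old-tag content and tops the pool back up with new tag.  The cell's
green-to-total fluorescence fraction therefore encodes how many times it has
divided since recombination, robustly to cell size, expression level and
imaging gain, because it is a ratio within one cell.

With $C$ the baseline old-to-new intensity ratio (old-tag intensity of an
undivided cell divided by the new-tag intensity of a fully exchanged one),
the green fraction after $n$ completed divisions is

$$R(n) = \frac{2^{n}-1}{C + 2^{n}-1},
\qquad
\hat n(R) = \log_2\!\left(1 + C\,\frac{R}{1-R}\right),$$

which at $C = 1$ reduces to $\hat n = -\ln(1-R)/\ln 2$ and yields the class
boundaries $R = 50\%,\,75\%,\,87.5\%,\,93.75\%$ after 1–4 divisions.  A
transcription-of-record of this model elsewhere displays the algebraically
transposed form $R = 1/(1+C(2^{n}-1))$; that form is inconsistent with its
own inverse and with the increasing thresholds, so this package implements
the inverse-consistent form above.  The two agree at every printed
threshold.

Division classes are the five bins 0–1, 1–2, 2–3, 3–4 and 4+, assigned from
$R$ with half-open intervals $[\mathrm{lower}, \mathrm{upper})$ and the top
class closed at 1.  This convention makes `classify_division_number(R)`
identical to `min(floor(estimate_divisions(R, 1)), 4)`; the exact boundary
values have measure zero in any continuous measurement, so the choice is
immaterial in practice but is fixed for determinism.  Estimation is capped
at the 4+ class because the bin widths shrink geometrically (class $k$ spans
$2^{-(k+1)}$ in $R$), so beyond four divisions ordinary measurement noise
overwhelms the signal.

## Theoretical trajectories

`theoretical_trajectory()` builds the idealised live-imaging reference: red
starts at a pool level of 100 and halves instantaneously at every division;
within each inter-division cycle the currently synthesised tag rises
*linearly* from its post-division value so that the channel sum returns to
100 exactly at the next division instant.  The linear ramp is a modelling
choice: the only constraint available is that the 0→50 first green ramp
averages 25, which a linear ramp satisfies; true S-phase-restricted
synthesis is not temporally resolved by the data this mimics.  An optional
`detection_delay` (hours) postpones the onset of the first green ramp,
reflecting the lag between transcription of the new tag and detectable
fluorescent protein; its magnitude is not established, so the default is 0.

Inter-division intervals are indexed by the number of completed divisions:
interval 0 spans recombination to the first division (red 100, green 0),
interval 1 carries the 0→50 green ramp (mean 25), interval 2 the 25→75 ramp
(mean 50).  Interval means are computed exactly from the piecewise-linear
segments, not from the sample grid.

For the two-switch (three-colour) reporter, a second recombination at
`flp_time` redirects synthesis from green to blue.  From then on green
behaves like red — halving per division, never refilled.  If `flp_time`
falls strictly inside a cycle, the running refill is split at that instant:
green freezes at its current level and blue completes the pool.  The
closed-form `micount_fractions(n_pre, n_post)` corresponds to the case
where the switch falls on a cycle boundary; the trajectory and the closed
form agree exactly there, and the simulator attributes each division's
synthesis to the epoch in which the division completes.

## What the simulator emulates

`simulate_lineages()` grows asynchronous branching lineages and tracks exact
label states:

* **Cell cycles** are drawn per cell, by default lognormal with mean 16 h
  and CV 0.15.  The live-imaging experiments this emulates span 64 h movies
  with roughly four divisions, implying cycles near 16 h, but no cycle-time
  *distribution* is reported for mESCs/NSPCs; the lognormal family and the
  modest CV are a conventional choice for mammalian cell-cycle variability
  and are fully configurable.  These defaults were chosen once and are not
  tuned.
* **Recombination** is instantaneous and fully penetrant at
  `recombination_time`.  A `recombined_fraction < 1` leaves some founder
  clones red-only — the analogue of non-switched cells, which double as the
  brightest-red-only normalization references and are excluded from
  division-count comparisons.
* **Division bookkeeping**: at each division the parent's pool is doubled by
  synthesis of the current tag and split between daughters, either exactly
  in half (`deterministic`) or tag-by-tag binomially from a finite pool
  (`binomial`, probing symmetric-but-stochastic segregation).  A cell's
  stored label is its birth state, when its pool is complete; exited and
  still-cycling cells keep it unchanged, encoding the experimentally
  established stability of the tagged protein in non-dividing cells.  Cells
  are not modelled mid-S-phase.
* **Fate**: each newborn daughter permanently exits the cycle
  (quiescence/differentiation) with probability `exit_prob`, which may be a
  per-generation schedule.
* **Measurement noise** is an invented model — the imaging pipelines this
  stands in for publish no noise model: per channel, a lognormal
  multiplicative factor with mean 1 and configurable CV, plus an additive
  Gaussian background whose drawn value is recorded so that per-cell
  background subtraction mirrors the real analysis.  All parameters surface
  in the configuration.

A green test on this simulator therefore establishes *internal* consistency
— that the analysis chain inverts the generative model it assumes — and
cannot establish the accuracy attainable on real movies or tissue, whose
noise structure (segmentation error, bleed-through, depth-dependent
attenuation) is unavailable.  In particular the published 95.5%
live-imaging accuracy is not reproducible here; its desk-scale counterpart
is the requirement that noiseless recovery be exact.

The cortical model (`simulate_cortical_population()`) is a
discrete-generation branching process with per-generation differentiation
probabilities.  It deliberately does not reimplement the published
MADM-based clonal likelihood (whose equations are in supplementary material
not reproduced here); it provides the same kind of comparison target — a
division-count distribution per compartment — at the level the main
analyses use it.

## Normalization

Fixed-tissue mode reproduces the reference-nucleus pipeline: per-cell
background subtraction (clipping negatives to zero, a choice the source
analysis leaves unstated; fractions must stay in $[0,1]$); red anchored at
0% on the mean of the 10 darkest nuclei in the tissue and at 100% on the
mean of the 10 brightest red-only nuclei; green scaled so the brightest
green value is 100%; then $R = \mathrm{green\%}/(\mathrm{green\%} +
\mathrm{red\%})$.  The darkest set is drawn from *all* nuclei, since the
source prescription does not restrict it; ties break by `cell_id` for
determinism; with fewer than 10 reference nuclei all available (minimum 2)
are used with a warning.

One consequence worth knowing: the 0% anchor is the darkest *observed*
nucleus set, not a true zero.  If the tissue's deepest division number is
$m$, a cell with exactly $m$ divisions normalizes to $R = 1$ and is called
4+.  All classes are still recovered exactly whenever the tissue contains
cells of 4 or more divisions — the regime the method is specified for — and
$R$ converges to the closed form as the darkest references approach the
asymptote ($\mathrm{red} \to 0$), which the end-to-end tests exercise with
deep lineages.

Live mode normalizes each channel by its maximum over one lineage's whole
time series, as in the movie analysis; the per-time-point green fraction is
then computed from those normalized values (both conventions are exposed;
lineage-normalized is the default).

## Inference and evaluation

`classify_dataset()` excludes cells with an undefined fraction (0/0) and
reports their count rather than imputing; $R = 1$ maps to an infinite point
estimate and the 4+ class.  `evaluate_accuracy()` scores an event as
correct when the true completed-division count falls inside the predicted
class interval — class "k–(k+1)" means $k$ completed divisions with the
next pending, and 4+ absorbs any count $\ge 4$.  How cells observed
mid-cycle were scored in the original movie analysis is not stated; this
interval rule is the package's operationalisation.  `calibrate_C()` is
opt-in (default $C = 1$ everywhere, matching the analyses this mirrors) and
uses the median of $(1-R)/R$ over known one-division cells for robustness.
`compare_distributions()` reports total-variation distance plus a
Monte-Carlo chi-square, chosen for small-count robustness; the original
side-by-side histogram comparisons report no test statistic at all, so this
is a package-level choice.

## Numerical and degenerate-input choices

* `green_fraction_after_divisions()` is computed as
  $1/(1 + C/(2^n - 1))$ via `expm1`, stable for large $n$ (returns 1 at
  overflow rather than NaN).
* `estimate_divisions()` rejects $R = 1$ (unbounded) and uses `log1p`.
* Degenerate references (no red-only nuclei, all-zero green, equal dark and
  bright anchors) are errors, not silent output; an all-zero live channel is
  a warning and left at zero.
* All simulation randomness flows through a single integer seed
  (`withr::with_seed`), making trees, tables and pipeline summaries
  byte-reproducible.

## Limitations

No spatial structure, interkinetic migration, image formation, segmentation
or FACS gating is modelled; inputs are per-cell integrated densities.
Newick export carries topology, ids and chronology only — JSON is the
lossless format.  Division classes beyond 4+ are deliberately not resolved.
The cortical branching model is a stand-in comparison target, not a
reimplementation of the published clonal-inference machinery, and the noise
model is a plausible invention, not a fitted one.
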