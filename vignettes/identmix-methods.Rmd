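---
title: "Pattern-guided identification with combinatorial standard mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-guided identification with combinatorial standard mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(identmix)
```

## The problem

A large fraction of the metabolites in common databases share their
molecular mass — as isobars (same nominal or exact mass) or isomers (same
sum formula) — with at least one other compound. Mass spectrometry alone
therefore cannot identify them, and the orthogonal evidence, retention
behaviour, is only as good as the library it is compared against: retention
indices shift between columns of nominally identical coating, retention
times in LC drift by tens of seconds between experiments, and the shifts
are not even parallel across compounds, so elution orders can invert.
A library measured once and trusted forever will eventually misassign
exactly the compounds that matter most — the chemically similar ones.

The remedy implemented here is to re-validate the retention information of
a whole standard panel with every batch, using **combinatorially pooled
standard mixtures**. The panel is distributed over `k` mixtures (default
`k = 4`, labelled A–D) such that every compound is present in **exactly
two** of them. The unordered pair of mixtures a compound occupies — its
*pair-code* — is then a presence/absence fingerprint observable in the data:

* `code_capacity(k)` = `choose(k, 2)` distinct codes exist (6 for k = 4,
  10 for k = 5, 15 for k = 6), so up to that many mutually similar
  compounds can be told apart by pattern alone;
* each single mixture contains only `2/k` of the panel (a 50 % complexity
  reduction at k = 4), easing coelution;
* every compound is measured twice per batch, giving a built-in duplicate.

Identification then works by the **principle of exclusion**: a peak is
assigned to the candidate whose pair-code equals the peak's occurrence
across the `k` runs. A peak present in A and D cannot be a compound coded
B+C, however similar the spectra and retention are.

## Design construction

`assign_codes()` turns a compound list and a typed constraint graph into a
design:

* `DISTINCT` — similar compounds must receive different codes;
* `DISJOINT` — the codes share no mixture, so the pair is never
  co-injected (the safe choice for badly coeluting pairs);
* `OVERLAP_ONE` — the codes share exactly one mixture, so one run shows
  whether the pair still separates when simultaneously present.

The search is plain backtracking, ordered most-constrained-compound-first,
with candidate codes tried in order of current mixture load and ties broken
by a seeded shuffle; unconstrained compounds are placed greedily by load
afterwards. This is deliberately simple: real panels have tens to a few
hundred compounds and constraint cliques no larger than the code capacity,
so the search space is tiny, and the load-balancing tie-break keeps the
per-mixture loads within a spread of 2 without an explicit optimisation
pass. Infeasibility is detected up front: a clique of mutually distinct
compounds larger than `choose(k, 2)` (found via `igraph`), or a `DISJOINT`
constraint with `k < 4`, is rejected with the offending clique or pair
named. The design itself carries no chemistry — solubilities, stock
concentrations and pipetting are bench-side concerns outside this package.

## Retention indices

GC retention is expressed on the retention-index scale via
`compute_ri()`, using van den Dool–Kratz **linear** interpolation between
n-alkane anchors — the appropriate form for temperature-programmed GC (the
logarithmic Kovats form assumes isothermal elution). The bundled default
ladder uses C10, C12, C15, C17, C19, C22, C28, C32, C36, a marker set that
leaves the crowded RI 1800 region free of markers. Beyond the terminal
anchors the terminal segment is continued linearly and the result is
flagged `extrapolated`; late-eluting compounds near the end of the
temperature program are thereby still usable, at reduced trust.
`rt_for_ri()` is the exact piecewise-linear inverse (round trip accurate to
1e-9 relative), used to place RI windows back on the time axis. LC data
skip the index and use raw retention times (`mode = "rt"`).

`shift_report()` quantifies what happens between two setups: per-compound
deltas, a fixed-width histogram (default 5 RI units / 5 s — the scale on
which within-class differences live), and the list of **elution-order
inversions**, i.e. compound pairs whose retention order disagrees between
setups. Inversions are counted by direct pairwise comparison; the test
suite pins this against an independent quadratic oracle.

`ambiguity_risk()` chains library entries whose expected RIs are within a
tolerance of their neighbours (single-linkage along the RI axis). These
groups are where a retention shift of that magnitude can silently swap
identities, and they are the natural input for `DISTINCT` constraints.
Single-linkage is used rather than pairwise cliques because a drifting
window slides along the axis: if A is confusable with B and B with C, all
three belong in one risk set even when A and C are farther apart.

## Spectral similarity

`match_factor()` implements the Stein–Scott weighted cosine on unit-m/z
bins: bin weights `intensity^a * mz^b` with the published defaults
`a = 0.6`, `b = 3`, score `1000 * (Σ w_q w_r)² / (Σ w_q² Σ w_r²)`. The
*reverse* match factor restricts the comparison to bins occupied by the
reference, so impurity peaks in the measured spectrum do not penalise the
score — which is why it is the gate used during identification. The
composite ratio-of-adjacent-peaks term used by some search engines is
deliberately omitted: the pure weighted cosine is hand-computable (the test
oracle recomputes it from first principles) and the exponents and bin width
are exposed for anyone wanting other weightings. Scores from vendor search
engines will therefore agree in rank but not bit-for-bit.

## Identification

`identify_batch()` proceeds per entry:

1. **Candidate peaks**: peaks within `ri_window` of the expected RI
   (default 10 RI units; `rt_window` 30 s in LC mode, matching the
   magnitude of between-experiment LC drift), above `intensity_min_frac`
   of the run's base peak (default 5 % — spiked standards are strong by
   design, so the floor can be high and false positives are excluded at
   the price of occasional not-founds), and, when spectra are present,
   reverse match factor ≥ 650.
2. **Joint resolution**: entries whose candidate sets overlap are resolved
   together (`resolve_isomers()`). An entry needs a *pair* of peaks, one
   in each code mixture, agreeing within `pair_tol` (default 5 RI units —
   the duplicate measurement must agree); pairs closest to the expected RI
   win, ties to the most intense; every peak supports at most one entry.
   This is what swaps an identification from the compound a naive
   nearest-RI match would pick to the compound whose code matches the
   peaks' occurrence.
3. **Exclusion check**: the observed pattern is the entry's assigned
   mixtures plus any mixture holding a *residual* (unassigned) peak inside
   the entry's window. `match_pattern()` yields `confirmed` only on exact
   equality with the code; an unexplained peak in a non-code mixture gives
   `conflict` (a distinct, reportable diagnosis — not a silent
   not-found), full absence gives `not_found`, and identical-code
   competitors give `ambiguous`. An entry whose presence pattern matches
   but whose two peaks disagree by more than `pair_tol` is reported as a
   conflict rather than confirmed: retention agreement across the
   duplicate is precisely the evidence the design buys.
4. **Library update**: confirmed entries get their RI (or RT) replaced by
   the intensity-weighted mean of the two supporting peaks, and the
   returned library carries re-encoded names — ready to identify the
   samples of the same batch with tight windows.

Entries without a pair-code cannot take part in the exclusion logic; they
are matched by retention/spectrum only and flagged `unvalidated` (a fifth
status value — they can never satisfy the confirmed-pattern invariant).
Software-imputed ("gap-filled") peaks are excluded from presence by
default: an imputed value is not evidence of presence for a binary
readout, though `include_gap_filled = TRUE` restores them.

Names encode the identification state machine-readably:
`Fructose_(MeOX)(5TMS)_MP_RI:1862_IDENT:B+C` — compound, derivatisation
state, main-product flag, integer RI, pair-code. Splitting after the second
underscore recovers the compound display identity regardless of which later
segments are present; compound names therefore must not contain
underscores. By-products are tagged `BP`, an extension of the main-product
(`MP`) convention for panels that track more than one derivatisation
product per compound.

## The synthetic generator

`generate_truth()` / `generate_peaklists()` are the test substrate: a
panel of `n_compounds` with expected RIs (isomer clusters tightly spaced
and constrained `DISTINCT`, the rest uniform over the RI range), codes
assigned by the real design machinery, peaks placed at
`Normal(expected RI, noise_sd)` in exactly the code mixtures, converted to
retention times through the default ladder so the peak lists contain only
what an instrument reports. Defaults are fixed once as the simulated study
conditions: `k = 4`, `n = 50`, `noise_sd = 2` RI units (within-batch GC
reproducibility), log-normal intensities (`meanlog = log(1e6)`,
`sdlog = 0.5`) reflecting typical MS response spread, RI range 1100–3400
inside the C10–C36 ladder. Dropout removes a true peak per mixture with
the configured probability; decoys are drawn uniformly over the RI range
(in `clean_decoys` mode re-drawn until ≥ 2·`noise_sd` from every true RI,
so dropout effects and collision effects can be separated).

What the generator emulates: retention noise, missing peaks, spurious
peaks, isomer crowding, intensity spread. What it does not: spectral
fragmentation physics (synthetic spectra are random sparse peak sets),
correlated drift within a run, peak-shape effects, matrix suppression.
Passing tests therefore demonstrate the combinatorial and retention logic,
not chromatography; the wet-lab half of the method lives outside the
package.

The bundled `table2_library()` / `table2_design()` preset is a 13-compound
worked example — four pentoses, four hexoses, five sugar derivatives with
RIs from 1651 to 1996 and codes over A–D — whose hexose block contains a
fully separated `DISJOINT` pair (fructose/mannose, B+C vs A+D) and an
`OVERLAP_ONE` pair (mannose/galactose, A+D vs A+C). Fructose is carried at
its main-product RI (1862); its second derivatisation product is a
documented real-world complication, not part of the zero-noise preset.

## Isobar statistics

The database module works on flat TSV exports (a column-mapping list
adapts any schema), never live APIs. `filter_records()` applies the usual
pre-filters in a fixed audited order — formula present, reaction
associated, organic (formula contains carbon — the pragmatic reading of
"remove inorganics"), mass cap (1500 Da is the conventional metabolome
ceiling), the textual lipid rule (`digits:digits` in the name — cheap,
effective, and with documented false positives like "1:1 complex"),
status and pathway whitelists — and reports per-rule removal counts that
sum back to the input. `isobar_group_sizes()` counts mass sharers at exact
resolution (equality after rounding to 4 decimals, matching stored
database precision) or unit resolution (integer rounding, half away from
zero). `cumulative_isobar_curve()` gives the percentage of compounds with
at least *t* isobaric partners, and `window_density()` the maximum group
size per half-open 5 Da window. Absolute counts from any given database
snapshot are inherently snapshot-dependent; the module is validated on
bundled fixtures (e.g. the five-compound C3H7NO2 cluster at 89.0477 Da)
and on brute-force oracles.

## Numerical choices and edge cases

* RI rendered as nearest integer in encoded names, kept floating-point
  internally.
* Duplicate m/z values within a spectrum are summed on construction;
  peaks are stored sorted.
* `compute_ri` is vectorised and exact at anchors by construction;
  monotonicity follows from the strictly increasing ladder.
* Ties in the assignment search are broken by a seeded shuffle, making
  `assign_codes` and the whole simulation pipeline reproducible from a
  single integer seed.
* Degenerate inputs fail loudly: empty spectra, non-finite retention
  times, ladders with non-monotone anchors, designs whose labels don't
  match the runs.

## Problem sizes

The shipped tests and the reproduction script run the design machinery at
up to 100 compounds, the identification pipeline on batches of 13–50
compounds across 100 seeded simulations, inversion counting at n = 200,
and isobar grouping at n = 200 — sizes chosen to exercise every code path
with comfortably interpretable fixtures. All of them are far below the
package's practical limits; the pipeline is linear in peaks per run except
for the pairwise pieces (inversions, pairwise match matrices), which are
quadratic by definition.

## Known limitations

* Peak picking and deconvolution are out of scope: inputs are peak lists.
* The spectral score will not numerically match vendor search engines
  that add composite terms.
* `conflict` diagnoses an unexplained peak but does not attribute it; in
  dense decoy regimes the conflict rate rises accordingly (the honest
  behaviour for a binary readout with a high evidence bar).
* Confidence is guaranteed only for compounds *in* the mixtures; the
  package flags everything else `unvalidated` rather than extrapolating.
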