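---
title: "Spectral-count differential analysis with DAve and DCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count differential analysis with DAve and DCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcompare)
```

## The quantification model

Label-free spectral counting treats the number of MS/MS spectra assigned
to a protein in a run (SpC) as a relative abundance measure. `spcompare`
works on per-run identification lists — tab-separated exports with one
row per protein carrying its accession, unique-peptide count and SpC —
and makes three modeling commitments:

1. **Identification confidence is a per-run filter.** Proteins must have
   at least `min_unique` unique peptides (default 1) to enter the
   analysis. The filter is applied per run, before alignment, because a
   protein's peptide support is a property of the run that identified it;
   the threshold is configurable for users who prefer filtering after
   alignment (apply it with `min_unique = 0` and post-filter).

2. **Absence of evidence is a zero.** Alignment (`align_lists()`) takes
   the union of accessions across runs and fills non-detections with an
   explicit 0. In spectral counting a missing protein usually *is* a
   low-abundance protein, so the default averaging policy
   (`zeros_included`) counts absences as zeros in the per-strain mean
   aSpC. The alternative reading — that a non-detection is missing data —
   is available as `policy = "detected_only"`; both are tested. Rows that
   are zero in every run (possible when an input list carries an SpC of
   0) are dropped at alignment, since they are indistinguishable from
   never-identified proteins downstream.

3. **Replicates are exchangeable by default.** All runs of a strain
   (2 preparations × 2 technical replicates in the reference design) are
   weighted equally in the flat mean. Because nothing in the design
   dictates a nesting order, `nested = TRUE` offers the
   mean-of-biological-means alternative; the two agree exactly on
   balanced designs under `zeros_included`.

## The differential indices

For averaged counts $X$ and $Y$ of one protein in two conditions:

$$\mathrm{DAve} = \frac{X - Y}{(X + Y)\cdot 0.5}, \qquad
  \mathrm{DCI} = (X + Y)\cdot\frac{X - Y}{2}.$$

DAve is a bounded effect size: it is $\pm 2$ exactly when the protein is
detected in only one condition, 0 when counts are equal, and for positive
pairs $|\mathrm{DAve}| \ge 0.4 \iff \max(X,Y)/\min(X,Y) \ge 1.5$ — an
algebraic identity the test suite verifies on random inputs. DCI weights
the same difference by total abundance, so it scales as $c^2$ when both
counts scale by $c$; it acts as a confidence gate that suppresses calls
on proteins observed with few spectra. Both indices are antisymmetric and
share a sign whenever $X \ne Y$, so the joint two-sided filter

$$\mathrm{DAve} \ge +t_{\mathrm{DAve}} \wedge \mathrm{DCI} \ge
 +t_{\mathrm{DCI}} \quad\text{or}\quad \mathrm{DAve} \le
 -t_{\mathrm{DAve}} \wedge \mathrm{DCI} \le -t_{\mathrm{DCI}}$$

is equivalent to $|\mathrm{DAve}| \ge t_{\mathrm{DAve}} \wedge
|X^2 - Y^2|/2 \ge t_{\mathrm{DCI}}$.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `t_dave` | 0.4 | effect-size threshold; 0.4 ≙ fold change 1.5 |
| `t_dci` | 5 | abundance-weighted confidence threshold, in SpC² units |
| `min_unique` | 1 | unique peptides required per identification |
| `min_runs` | 1 | detections required for Venn presence in a strain |
| `min_score` | 0.4 | interaction-confidence cut for network edges |

Numerical conventions: thresholds are **inclusive** ($\ge$/$\le$ exactly
as written); a protein with $X = Y = 0$ has DAve $= 0/0$ and is flagged
`not_comparable` rather than assigned 0 — it renders white and is
excluded from significance counts; DAve is computed at full precision and
only rounded to 2 decimals in written tables; orientation is fixed with
the first-named sample as $X$, so in reference-vs-mutant comparisons a
positive DAve means down-represented in the mutant. No multiple-testing
correction is applied: the procedure is a deterministic threshold filter,
not a p-value-based test, and its error rates are instead characterized
by simulation (below).

## Display conventions

The differential table marks each protein's DAve in each comparison with
a chromatic code: red for positive values, blue for negative, white for 0
or not-comparable. Intensity $|\mathrm{DAve}|/2$ is mapped to a discrete
four-step ramp over $[t_{\mathrm{DAve}}, 2]$ (quarter-width bins, upper
bounds inclusive); values with $0 < |\mathrm{DAve}| < t_{\mathrm{DAve}}$,
or values failing the joint filter on DCI, take the light shade of their
hue, so the table shows sub-threshold trends without claiming
significance. Printed percentages round to one decimal and drop a
trailing `.0` (`format_percent(48, 447)` is `"10.7%"`,
`format_percent(18, 447)` is `"4%"`).

The Venn partition of per-strain detection sets reports all $2^n - 1$
disjoint regions plus two auditable aggregates relative to the reference
strain (proteins shared with it, proteins absent from it). The `plot()`
method draws a region-count barplot rather than proportional ellipses:
4-set proportional geometry is a layout problem out of scope here, and
the bar form shows every region exactly.

## What the simulator emulates

`generate_ground_truth()` + `simulate_runs()` produce datasets with the
structure the analysis assumes, plus known truth:

- **Design**: 4 strains × 2 biological preparations × 2 technical
  replicates = 16 runs, the reference study layout.
- **Baselines**: per-protein expected SpC drawn lognormal
  (`meanlog = log(10)`, `sdlog = 1`), giving a few-to-hundreds SpC range
  typical of enriched-proteome runs, with 450 proteins by default — the
  scale of the motivating dataset (447 distinct identifications).
- **Planted changes**: a fraction `prop_diff = 0.15` of proteins per
  single mutant receives a fold factor drawn uniformly in (1.5, 4),
  direction randomized 50/50; the double mutant's folds default to the
  product of the single mutants' (a configurable "combined effect" rule,
  chosen to create the partially-overlapping significant sets a double
  deletion produces without asserting any mechanism).
- **Noise**: Poisson counts by default; negative binomial with
  dispersion 0.05 is available because technical SpC replicates are often
  mildly overdispersed.
- **Dropout**: a detection draw with
  $p_{\mathrm{detect}} = 1 - e^{-\mu/3}$ removes low-abundance proteins
  from individual runs, which is what creates the non-trivial Venn
  structure (strain-exclusive regions) in simulated data.
- **Determinism**: seeds are explicit arguments everywhere; identical
  seeds give bit-identical outputs end to end.

What it does **not** emulate: peptide-level identification and FDR
control, shared-peptide ambiguity between homologous proteins,
retention-time structure, run-order drift, and any correlation between a
protein's ubiquitylation state and its detectability. Passing recovery
tests on these simulations therefore shows the pipeline's arithmetic and
filtering behave as specified under the stated stochastic model — not
that the thresholds are optimal for any particular real instrument or
enrichment protocol.

## Operating characteristics

The test suite calibrates the filter on simulated data (problem sizes
chosen to keep the whole suite fast while leaving Monte-Carlo error well
inside the asserted margins): under a pure null (all folds 1, Poisson
λ = 20, 2×2 replicates, 2000 proteins, 20 seeds) the false-positive rate
is ≈ 1.6%, comfortably below the 5% bound asserted; sensitivity is
monotone non-decreasing in fold factor and in abundance on a
{2,3,4} × {20,50,100} grid (200 proteins, 20 seeds per cell); and 3-fold
changes at λ ≥ 20 are recovered with sensitivity ≥ 0.8 (measured ≈ 1.0).
At λ = 20 the DCI gate is nearly always satisfied when the DAve gate is
(DCI ≈ 40·ΔSpC at that abundance), so the null FPR is governed by the
DAve tail; the FPR *decreases* as λ grows because DAve concentrates as
$1/\sqrt{\lambda}$. Conversely, at low baselines (median 10 SpC in the
default generator) threshold-only filtering is noisy — the worked example
in the README shows an FDP around 0.5 there, which is the expected cost
of a fixed-threshold procedure without abundance-dependent calibration,
and the reason the per-protein DCI gate matters.

## Design choices that were genuinely open

- **Averaging absences as zeros** (default) versus detected-only: the
  procedure description averages "the proteins identified" without a
  dropout rule; both readings are implemented and the default is the one
  that keeps the column-sum invariant of the aligned matrix meaningful.
- **Flat versus nested replicate averaging**: no nesting is specified;
  flat is the default, `nested = TRUE` the alternative.
- **DCI threshold on raw aSpC**: the index is applied to raw averaged
  counts, not rescaled or normalized counts; no NSAF-style normalization
  is performed anywhere.
- **Boundary inclusivity**: thresholds compare with ≥/≤, including at
  exactly 0.4/5, and network edges are kept at a confidence of exactly
  0.4.
- **Not-comparable handling**: $X = Y = 0$ yields a flagged
  `not_comparable` status, never DAve = 0, so "unidentified" and
  "unchanged" are distinguishable in every output.

## Known limitations

- Spectral counting saturates for very abundant proteins and undercounts
  short ones; the pipeline inherits these biases from its input.
- The filter provides no formal error-rate guarantee; the simulation
  module quantifies its operating characteristics under stated models,
  which is the strongest claim a fixed-threshold procedure supports.
- Annotation (functional classes, orthologues, interaction flags) and
  network edges are user-supplied tables; the package performs no live
  database queries, by design, for reproducibility.
- The aligner matches accessions exactly; it does not resolve protein
  groups whose representative accession differs between runs.
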