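---
title: "Methods: SDP scoring, candidate retrieval and feedback scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SDP scoring, candidate retrieval and feedback scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpsearch)
```

## The scoring model

`sdpsearch` identifies peptides by matching experimental MS/MS spectra
against theoretical fragment spectra of database peptides. Both sides are
reduced to boolean vectors over m/z bins: a peak at m/z *x* occupies bin
`floor(x / w)`, where the bin width *w* is the fragment tolerance in Da.
The score of a peptide-spectrum match is the boolean dot product — the
number of bins occupied in both vectors. Intensities are carried through
the I/O layer but never scored; duplicate peaks in one bin count once.

The model's assumptions, stated explicitly:

* **Ion series.** Theoretical spectra contain singly protonated b and y
  ions only (`b_i` = prefix residue sum + proton, `y_i` = suffix residue
  sum + water + proton). No a/c/x/z ions, no multiply charged fragments,
  no neutral losses. This is the minimal faithful fragment model of the
  engines this design descends from, and it keeps every score exactly
  reproducible by hand.
* **Binning, not windows.** The fragment tolerance is applied as a bin
  width, not as a ±w window around each theoretical peak. A true peak
  pair w apart can therefore straddle a bin boundary and not match. The
  alternative (neighbour-bin matching) breaks the clean boolean-vector
  formulation, so it was deliberately not implemented.
* **Masses.** Monoisotopic throughout; proton 1.007276 Da, water
  18.010565 Da. Precursor comparison happens in neutral-mass space:
  `query = (precursor_mz − proton) × charge`, with the precursor
  tolerance applied symmetrically in Da.
* **Fixed modifications only.** Every occurrence of a target residue is
  shifted (default: carbamidomethylation of cysteine, +57.021464 Da).
  Variable modifications multiply the candidate space and are a
  non-goal.

## Two scorers, one contract

`score_spectrum_alg1()` is the two-pass reference: binary search yields
the candidate window H in the mass-sorted peptide index, the window is
materialized as a list, every candidate is scored, and the scores are
ranked. `score_spectrum_micsdp()` fuses the two passes: after the same
binary search, candidates are scored one at a time and pushed through a
top-k buffer that never holds more than k + 1 entries, so neither the
candidate list nor the full score vector exists in memory, and one whole
spectrum is a self-contained unit of work that can be dispatched to any
worker.

Because both scorers sort with the same total ordering — score descending,
then absolute precursor mass difference, then lexicographic sequence, with
zero scores discarded — their outputs are identical field for field. The
test suite asserts this identity on hundreds of randomized databases; it
is the package's central structural claim and is testable exactly, with no
tolerance.

The tie-break deserves a note: sequences are unique in the index (identical
peptides from different proteins collapse into one entry carrying all
provenances, semicolon-joined), so the ordering key is total and the
ranking is deterministic. That determinism is what makes the serial/
parallel equivalence below a byte-level property rather than a statistical
one.

## Candidate retrieval

The peptide index is sorted by neutral mass (ties by sequence);
`candidate_window()` finds the maximal half-open run within the precursor
tolerance using `findInterval`, i.e. O(log |T|) comparisons. Tests compare
it against a linear-scan filter on randomized mass lists, including the
empty-window edge cases (tolerance 0, query outside the mass range).

## The feedback scheduler

Chunks of spectra are assigned to workers in proportion to an *effective
weight* built from each worker's performance factor:

* throughput estimated by a small sample probe (work per unit time);
* CPU utilization, mean run-queue length per core, and memory usage
  `(MT − MF − Buffers − Cached)/MT` — on Linux these come from
  `/proc/stat`, `/proc/loadavg` and `/proc/meminfo`; all tests use
  simulated sources behind the same interface.

No canonical formula combines the three load statistics, so the package
uses a monotone, bounded choice made once: the weight is the probe
throughput, and when CPU utilization exceeds 0.9 it is multiplied by the
free-memory fraction and divided by (1 + queue length). Any combination
that shrinks an overloaded worker's share would serve; this one is simple
and dimensionally sensible.

After the initial largest-remainder proportional split (ties on the
fractional part broken by worker order, so rounding is deterministic),
every chunk-completion report triggers the feedback step:

1. each worker's weight is geometrically smoothed toward its observed
   rate, `w ← α·w + (1 − α)·w_obs`, with α = 0.5 by default (α = 1
   freezes the initial estimates);
2. while the projected finish times are imbalanced beyond the threshold
   (default 0.08), unstarted chunks migrate from the worker projected to
   finish last to the one projected to finish first. In-flight chunks are
   never moved, so no spectrum is lost or scored twice.

The balance criterion is `(max − mean)/mean` over per-worker busy totals.
The metric itself was a design choice — the threshold figure is
conventionally quoted without one — and this form is 0 for perfect balance,
dimensionless, and dominated by the single most-loaded worker, which is
what limits wall-clock time.

The simulation in `simulate_schedule()` is event-driven in virtual time:
workers process their FIFO queues concurrently, the earliest completion
fires next, and costs carry lognormal jitter (σ = 0.1 by default) around a
unit base cost. With 300 chunks and three workers at speeds 1 : 1.5 : 2
the granularity of a single chunk is well under the 8% threshold, which is
why feedback scheduling lands a few percent of imbalance; the acceptance
script reports the median over 50 seeded runs.

## Pipeline and queues

The end-to-end search has four phases: (1) load inputs and partition the
spectra into contiguous chunks; (2) build the peptide index — the
precursor-window lookup per spectrum is the "unrefined" search that
precedes fragment scoring; (3) score chunks through the worker pool; (4)
merge and write the report. Chunk transport uses a pair of bounded
circular queues per worker (requests out, responses back), each with
head/tail counters and fixed capacity ≥ 2. Capacity 2 realizes double
buffering: one chunk is scored while the next is already in transit. The
host never lets a worker hold more unacknowledged chunks than the queue
capacity, and if a worker dies its in-flight and queued chunks return to
the pending pool, so conservation (every chunk consumed exactly once)
holds even under injected faults.

The worker pool is an in-process, logical pool driven deterministically
through this queue contract; hardware offload and message-passing
transports are out of scope. The payoff of the in-process design is that
*serial/parallel equivalence is exact*: the merge orders PSMs by spectrum
source position and rank, independent of chunk arrival order, so reports
for 1, 2 and 4 workers are byte-identical, which the tests assert on the
standard fixture.

## Synthetic data: what it does and does not emulate

The fixtures module generates proteomes by uniform residue draw and
spike-in spectra built from a chosen peptide's b/y ladder, with three
controlled corruptions: a fraction of fragments removed, uniform random
noise peaks added in 100–2000 Da, and a uniform precursor mass error.
Charges are drawn from {2, 3}; intensities are uniform in (0, 1] because
scoring ignores them. Defaults for the recovery surface — up to 5 noise
peaks, up to 30% missing fragments, precursor error within the 3 Da
tolerance — describe clean, well-calibrated spectra of confidently
identifiable peptides.

What this deliberately does not emulate: biological amino-acid
frequencies, fragmentation intensity patterns, isotope envelopes,
co-eluting chimeric spectra, or real noise structure. Passing the
spike-in recovery test therefore shows the engine's plumbing and scoring
are correct — that a spectrum genuinely generated by an in-database
peptide is found — not that the score separates true from false matches
on real data. The package intentionally has no hyperscore, E-value or
decoy/FDR machinery, so it should not be used to claim identification
confidence on experimental datasets.

## Numerical choices and degenerate inputs

* SDP scores are exact integers; masses are printed to 5 decimals in the
  TSV report, which round-trips losslessly at that precision.
* `binarize` floors; bin indices are non-negative integers with set
  semantics (strictly increasing sparse encoding).
* Empty inputs are defined, not errors: an empty spectra file produces a
  header-only report; an empty candidate window produces no PSMs; zero
  chunks exhaust the pipeline immediately; all-zero worker loads have
  imbalance 0 by convention.
* Missing `CHARGE` in MGF defaults to 2 (configurable); peptides with
  non-standard residues (B, J, O, U, X, Z) are skipped with a warning
  rather than failing a whole database.
* Problem sizes in the test suite were chosen so the whole suite runs in
  well under a minute on one core: 10,000 random vector pairs and window
  queries for the oracle equivalences, 200 random databases for the
  scorer identity, 200 spiked spectra for recovery, 10,000 chunks for
  queue conservation, 50 seeds for the scheduler. These sizes are large
  enough that a systematic defect in any of the checked properties would
  be detected with overwhelming probability.

## Known limitations

* Bin-edge effects (above) can drop a true fragment match; widening the
  fragment tolerance coarsens rather than shifts the boundary.
* The scheduler's performance-factor combination and the smoothing
  coefficient α are heuristics; they are exercised in simulation, not on
  heterogeneous hardware.
* MGF is the only spectra dialect on the test surface; mzML input and
  pepXML/mzIdentML output are not provided.
* No statistical validation of matches (see above); ranks and scores are
  descriptive.
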