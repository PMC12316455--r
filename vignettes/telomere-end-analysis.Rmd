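---
title: "Telomere terminal-end analysis: models, conventions and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere terminal-end analysis: models, conventions and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloend)
```

## The biological setting

Human and mouse telomeres are 5–15 kb tracts of the duplex repeat
TTAGGG/CCCTAA. The G-rich strand runs 5'→3' toward the chromosome tip and
ends in a 3' single-stranded overhang; the C-rich strand's 5' end *is* the
chromosome terminus, and in cells with functional POT1 it is precisely
processed so that, written 3'→5' toward the terminus, it reads
`CCAATC-5'` (the terminal trinucleotide `ATC-5'`).

END-seq ligates biotinylated adaptors to blunted double-strand DNA ends and
sequences from the ligated end inward, so **the first sequenced base of a
read is the first base of the end**. A natural chromosome terminus is a
one-ended break: it yields exactly one read, on the C-rich strand, starting
at the terminal base. S1-END-seq first digests single-stranded DNA (ssDNA)
with S1 nuclease, converting any internal ssDNA region into a two-ended
break that yields one C-strand *and* one G-strand read. Cells that maintain
telomeres by the recombination-based ALT pathway carry abundant internal
telomeric ssDNA, which is what the package's end-counting model quantifies.

## Read classification

A read is **telomeric** when it contains at least `k = 4` exact consecutive
copies of `TTAGGG` (G-rich) or `CCCTAA` (C-rich) anywhere in the sequenced
orientation; `N` never matches, and no reverse-complement search is done
because END-seq reads carry strand identity directly. Reads containing runs
of both units are counted separately as `AMBIGUOUS` — at 75 bp this needs
48 nt of split signal and is overwhelmingly artifactual — and are excluded
from C/G denominators. Telomeric counts are normalized as reads per million
(RPM) against *all* reads of the library.

```{r}
tally_library(c(strrep("CCCTAA", 12), strrep("TTAGGG", 12),
                strrep("ACGT", 18)))
```

## Terminal-hexamer orientation convention

Because a C-rich read starts at the chromosome's 5'-terminal base, its
**first six bases are the terminal hexamer read inward**; reversing them
gives the conventional `-5'` display. A canonical end therefore appears as
the read prefix `CTAACC…` and is displayed `CCAATC-5'`. Resection of a pure
repeat can only expose one of the **six cyclic rotations** of the hexamer,
so the distribution lives on six categories plus an `OTHER` bin (sequencing
errors, adapter remnants, `N`s). An alternative reading of the same
convention — reverse-complementing the read and taking its last six bases —
yields the same category set; the package fixes the first convention and
never mixes them. The display-only `Rest` grouping pools
`CCCAAT`, `TCCCAA` and `ATCCCA`.

Per-position conservation is reported as standard logo information content,
`bits = 2 − H` with `H` the Shannon entropy of the observed base
frequencies at that position (terminal-most first, `N` skipped). No
small-sample correction is applied: the intended inputs are libraries with
thousands of C-rich reads, where the correction is negligible.

## KL divergence and the canonical-fraction mixture

Distributions are compared with the Kullback–Leibler divergence
`D(P‖Q) = Σ p_i log2(p_i/q_i)` over the **six permutation categories only**
(`OTHER` dropped and renormalized — phase randomization cannot produce
`OTHER`, so including it would let sequencing artifacts dominate the
comparison). Conventions, each recorded in output metadata:

* **Direction** `P` = observed sample, `Q` = reference/in-silico control
  (the conventional sample-vs-model direction).
* **Base 2** (bits), matching the logo units; the significance bands are
  applied in the same base, so internal consistency is what matters.
* **Pseudocount** `epsilon = 1e-9` added to every cell before
  renormalization, keeping empty reference cells finite while perturbing
  divergences by far less than any decision boundary.
* **Dot categories**: `< 0.125` nonsignificant, then one dot per 0.125-wide
  band up to `≥ 0.375` = three dots; boundary values go to the higher
  category (a deterministic tie-break the band definition leaves open).

The canonical-end fraction is estimated against the in-silico mixture
family: a fraction `p` of ends perfectly canonical, the rest uniform over
the six rotations, giving canonical frequency `p + (1−p)/6`. The estimate
is the argmin of `D(observed ‖ mixture(p))` over the grid
`p = 0, 0.01, …, 1` (ties to the smallest `p`; the 0.01 step matches the
precision at which such fractions are reported, and the estimator is exact
on noiseless mixtures at every grid point).

```{r}
obs <- mixture_distribution(0.7)   # a POT1-proficient-like distribution
estimate_canonical_fraction(obs)
```

## The ssDNA end-counting model

Each chromosome end contributes one C-readable end; each internal S1 cut
contributes one C-readable and one G-readable end. With `n` internal ssDNA
regions per end the expected C-strand read fraction is

\[ f = \frac{n+1}{2n+1}, \qquad n = \frac{1-f}{2f-1}. \]

Because capture and sequencing losses can only *hide* ends, the inversion
is reported as a **minimum**, `n_min = ⌈n⌉` (ceiling, not rounding). The
model assumes equal capture efficiency of C- and G-readable ends; `f ≤ 0.5`
is a model violation (it would require unboundedly many cuts) and is
reported as such rather than inverted. Numerically, the ceiling is taken
after subtracting `1e-9` so that model-exact fractions `f = (n+1)/(2n+1)`
invert to exactly `n` despite floating-point rounding.

```{r}
min_ssdna_regions(0.55)
```

ALT status is called from `f` with configurable thresholds defaulting to
the boundaries of the empirically observed ranges: `f ≤ 0.58` ALT-positive,
`f ≥ 0.98` ALT-negative, otherwise indeterminate.

## Variant telomeric repeats

VTR frequency is the fraction of *repeat units* deviating from the
canonical hexamer among complete units tiled within the first 30 nt of each
telomeric read. Per read, the tiling phase (offset 0–5) is chosen to
maximize exact canonical matches, so a terminal phase shift does not flag
every unit; partial units at the window edge are discarded for a
determinate denominator, units containing `N` leave both numerator and
denominator, and reads shorter than the window are skipped with a count.
The window (30 nt) restricts the scan to the terminal region that short
reads can interrogate reliably. Real-data VTR frequencies depend on
denominator and phase conventions that published summary figures do not pin
down, so cross-study comparisons of absolute VTR percentages should be made
with the same convention throughout.

## The synthetic-library simulator

`simulate_library()` generates END-seq and S1-END-seq libraries from a
parametric telomere model, with a ground-truth sidecar (per-telomere tract
length, terminal phase, cut positions; emitted read counts) so every
analysis stage has a recovery oracle. Defaults emulate an untreated
telomerase-positive END-seq library; each choice and its rationale:

* `telomere_length = c(5000, 15000)` bp, uniform — the span of typical
  human telomere lengths.
* `read_length = 75` — the single-end read length of the emulated
  protocol.
* `p_canonical = 0.7`, remainder uniform over the six rotations — the
  canonical-end fraction of POT1-proficient cells; uniform rotation is the
  same randomization model used by the mixture family (and models POT1
  depletion / 5'→3' exonuclease resection when `p_canonical` is lowered).
  A geometric-resection alternative was considered and rejected: observed
  randomized samples match the uniform model.
* `cuts_per_telomere` (fixed or Poisson) — internal ssDNA regions (S1
  mode) or nuclease-induced DSBs (END-seq mode). Cut positions are uniform
  over the tract interior at least `min_fragment` from both boundaries.
  `mode` is metadata only: blunt DSBs are sequenced two-endedly by either
  protocol, so the cut law alone distinguishes libraries.
* `min_fragment = 36` bp — library-prep size selection; shorter fragments
  yield no reads. Cuts within one `min_fragment` of each other drop one
  C-read *and* one G-read, so the C-strand fraction stays within a small
  bias (upward, toward fewer inferred cuts) of `(n+1)/(2n+1)`.
* `vtr_rate = 0.02` — per-unit variant substitution, the order of
  magnitude observed in terminal repeats; variants are whole-unit
  substitutions at the read's own repeat phase.
* `background_fraction = 0.5` — uniform-random non-telomeric reads. Real
  END-seq libraries are far more dilute (telomeric reads are an RPM-scale
  fraction), but background only exercises the classifier's specificity,
  so simulating deeper dilution would cost runtime without changing any
  tested quantity.
* `error_rate` (default 0) — uniform per-base substitutions; recovery
  tests run error-free so closed-form expectations are exact, and the
  error model exists to probe robustness.
* Qualities are constant Q40: the pipeline deliberately never filters on
  quality, so simulated qualities only need to round-trip.

All randomness derives from `seed`; a config reproduces its library byte
for byte, and reads are emitted in shuffled order with the caller's RNG
state restored.

What the simulator does **not** model: subtelomeric sequence (every stage
operates within 75 bp of an end), C-circles and other extrachromosomal
structures, R-loops/G-quadruplexes (their read-level footprint is captured
abstractly as internal cuts), ligation bias, adapter read-through, indels,
and quality-dependent errors. Passing recovery tests therefore demonstrate
correctness of the analysis logic under the stated generative model, not
robustness to every artifact of real libraries.

## Problem sizes and determinism of the test suite

The packaged tests run the estimators at the scales they were designed
for: canonical-fraction recovery on libraries of 50,000 C-rich reads,
ALT separation on 20,000 telomeres, VTR recovery on ~28,000 scanned units,
and classifier/brute-force agreement on 10,000 random 75-mers. All
stochastic tests fix seeds, and tolerances are pre-registered statistical
bounds (3 binomial standard errors, or the stated recovery bands of ±0.05
for the canonical fraction and ±0.005 for the VTR rate), not post-hoc
margins.

## Known limitations

* The end-counting inversion is a lower bound and collapses at `f ≤ 0.5`;
  it cannot estimate ssDNA tract *lengths*, and it cannot distinguish
  chromosomal ssDNA from C-circle contributions.
* KL dot categories on real data can depend on whether the divergence is
  computed over all six permutations (as here) or over display groupings,
  and on the log base; the package fixes one internally consistent
  convention and records it in output metadata.
* The classifier is exact-match by design; degenerate telomeric motifs are
  the VTR scanner's job, not fuzzy classification.
* Paired-end input, BAM/SAM, adapter trimming and deduplication are out of
  scope; inputs are assumed preprocessed.
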