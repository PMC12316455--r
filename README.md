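# teloend

Read-level analysis of telomere termini in END-seq and S1-END-seq
libraries, for researchers studying telomere end protection and
alternative lengthening of telomeres (ALT).

END-seq sequences blunted DNA double-strand ends so that the first
sequenced base of a read is the first base of the end. Natural chromosome
termini are one-ended breaks that yield only C-rich-strand telomeric reads
(`CCCTAA` repeats) starting exactly at the chromosome 5' terminus;
S1-END-seq additionally converts internal single-stranded DNA (ssDNA) into
two-ended breaks, adding matched G-rich (`TTAGGG`) reads. From single-end
FASTQ input, the package:

* **classifies reads** as G-rich / C-rich / ambiguous / non-telomeric by
  exact consecutive-repeat scanning (≥ *k* = 4 units by default), with
  reads-per-million (RPM) tallies;
* **quantifies the 5'-terminal hexamer** of C-rich reads over the six
  cyclic permutations of the repeat (canonical terminus `CCAATC-5'`, i.e.
  read prefix `CTAACC…`), plus per-position information content in bits;
* **compares distributions by KL divergence** (bits, sample‖reference,
  pseudocount 1e-9) with the dot significance bands
  (`< 0.125` ns; then one, two, three dots per 0.125 band), and estimates
  the **canonical-end fraction** `p` by grid matching against in-silico
  mixtures in which a fraction `p` of ends is canonical and the rest
  uniform over the six rotational phases;
* **inverts the C-strand read fraction** `f = c/(c+g)` of an S1-END-seq
  library through the end-counting model `f = (n+1)/(2n+1)` into a
  *minimum* number `n_min = ⌈(1−f)/(2f−1)⌉` of internal ssDNA regions per
  chromosome end, and calls ALT status (`f ≤ 0.58` positive, `f ≥ 0.98`
  negative);
* **scans variant telomeric repeats (VTRs)**: the fraction of non-canonical
  repeat units among phase-optimized complete units within the first 30 nt
  of telomeric reads;
* **simulates** END-seq / S1-END-seq libraries from a parametric telomere
  model with a ground-truth sidecar, so every stage is testable without
  sequencing data.

## Worked example

Simulate an ALT-like S1-END-seq library (5,000 chromosome ends, three
internal ssDNA cuts per telomere) and run the full pipeline:

```r
library(teloend)
cfg <- simulation_config(n_telomeres = 5000, mode = "s1",
                         cuts_per_telomere = 3, seed = 7)
sim <- simulate_library(cfg)
report <- run_pipeline(sim$reads)
print(report)
```

```
== teloend pipeline report ==
Strand counts (69520 reads)
  G-rich:             14870  (213895.282 RPM)
  C-rich:             19875  (285888.953 RPM)
  ambiguous:              0
  non-telomeric:      34775
  C-strand fraction (C/(C+G)): 0.5720
Terminal-hexamer distribution (19875 C-rich reads)
  CCAATC-5':     6276  ( 31.58%)
  CAATCC-5':     2764  ( 13.91%)
  AATCCC-5':     2652  ( 13.34%)
  ATCCCA-5':     2645  ( 13.31%)
  TCCCAA-5':     2673  ( 13.45%)
  CCCAAT-5':     2756  ( 13.87%)
  OTHER -5':      109  (  0.55%)
  Rest (CCCAAT+TCCCAA+ATCCCA): 40.62%
Canonical-end fraction estimate: p_hat = 0.18 (KL at minimum = 0.0001815 bits, grid step 0.01)
C-strand read fraction f = 0.5720
Model inversion n = (1 - f)/(2f - 1) = 2.9710
Minimum internal ssDNA regions per chromosome end: 3
ALT call: ALT_positive 
VTR scan (first 30 nt): 2827/144159 variant units (1.961%); 0 reads skipped
```

Reading the numbers: three cuts per telomere produce four C-readable and
three G-readable ends, so the C-strand fraction sits near 4/7 ≈ 0.571; the
inversion recovers the generating cut count (minimum 3 ssDNA regions) and
calls the library ALT-positive. Only one C-read in four starts at a
natural terminus, so the canonical hexamer frequency is diluted from the
generating 75% to ≈ 31.6% (hence the low whole-library `p_hat`; on an
END-seq library without cuts, `p_hat` recovers the generating canonical
fraction directly). The VTR scan recovers the simulated 2% per-unit
variant rate.

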