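---
title: "Models and methods behind fragmentoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fragmentoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmentoscope)
```

This vignette explains the models implemented in fragmentoscope, the
assumptions behind them, the numerical choices that were genuinely open,
and what the synthetic-data generator does and does not emulate. Everything
quantitative stated here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is quoted from external data.

## The fragmentomics model

Plasma cfDNA is the debris of regulated cell death: DNA is degraded down to
whatever was protected from nucleases. The package works entirely from the
resulting fragment intervals — stranded, 0-based, half-open coordinates on
a contig, the BED convention used throughout. Three observable signatures
follow from the protection model:

1. **Length structure.** Chromatosomes (core particle + linker histone)
   protect ~167 bp, core particles ~144 bp. Below the chromatosome length,
   nuclease access to the exposed minor groove every helical turn produces
   a ladder of sub-peaks at ~10.4 bp spacing.
2. **Endpoint structure.** Cut positions are sequence-biased, so base and
   dinucleotide composition deviates from background around fragment
   termini; weak (AA/AT/TA/TT) and strong (CC/CG/GC/GG) dinucleotides
   alternate with ~10 bp phase inside nucleosome-protected spans.
3. **Coverage structure.** Positions inside protected spans are crossed by
   many fragments but contain few fragment endpoints. The window
   protection score (WPS) turns this into a per-position statistic.

A second, orthogonal model concerns **library preparation**. A duplex
template is represented by its two strand intervals (`top_start, top_end,
bottom_start, bottom_end`); offsets between strand ends encode 5′/3′
overhangs of 0–6 nt. Native-end (single-stranded ligation) preparation
emits each strand unchanged. End-polishing fills in 5′ overhangs and chews
back 3′ overhangs; at each duplex end the surviving coordinate is the 5′
terminus of the strand that carries it, so the blunted molecule is always
`[top_start, bottom_end)`. Two consequences are exact, coordinate-level
facts in this representation and are asserted as such in the tests:

* 5′ termini are identical between the two prep modes (both preserve
  `top_start` for the plus strand and `bottom_end` for the minus strand);
  only 3′ termini differ, and only when overhangs are present.
* For blunt-only templates the two preps produce identical intervals.

## The window protection score

At position *p* with window width *W* (even), the window is
`[p − W/2, p + W/2)`. A fragment `[s, e)` in the selected length bin
contributes −1 if `s` or `e − 1` lies in the window, +1 if `s < p − W/2`
and `e > p + W/2`, else 0. The endpoint rule takes precedence when both
apply. Defaults follow the two standard regimes: 120 bp window with a
120–180 bp bin for nucleosome-scale protection, and a 16 bp window with a
35–80 bp bin for transcription-factor footprints. (A 35 bp short-fraction
window is a documented alternative — both conventions circulate; the
16 bp default matches the footprint-scale figure convention, and the
parameter is exposed.)

Window anchoring is a genuine convention choice: nothing pins where an
even window sits relative to *p*. We fix `[p − W/2, p + W/2)` and verify
the implementation against a brute-force per-position evaluation of the
same rule (exact equality on randomized instances), so the convention is
testable rather than implicit.

Post-processing follows the standard pipeline: median adjustment to zero
over non-overlapping 1000 bp segments (anchored at the track start; the
final partial segment is adjusted the same way), then Savitzky–Golay
smoothing (21 bp window, order 2). The filter coefficients are the exact
least-squares ones (via `signal::sgolay`); edge handling is mirror
padding, chosen so the filter stays a linear operator of the observed
track without inventing data. Order-2 smoothing reproduces any quadratic
exactly; the tests check this, the impulse response against an
independently solved least-squares system, and linearity.

`wps_periodicity()` reports the mean spacing between local maxima of an
averaged profile; a maximum must strictly dominate every neighbour within
±20 bp *and* have its full neighbourhood available — peaks too close to
the profile ends cannot be certified and are dropped, which avoids
spurious boundary maxima on truncated oscillations.

## Periodicity estimation in length spectra

`sawtooth_periodicity()` works on `log1p(count/mean(count))` over a closed
length range (default 90–160 bp). The mean-scaling makes the estimate
exactly invariant under rescaling all counts; `log1p` compresses the
dynamic range so ladder rungs and valleys contribute comparably. A 21 bp
centered moving average removes the nucleosomal envelope (the same
smoothing scale used elsewhere in the package) without attenuating ~10 bp
structure. The first autocorrelation maximum at lag ≥ 6 is refined by
quadratic interpolation through the peak and its neighbours, giving sub-bp
resolution — necessary because the true period (10.4 bp) is not an
integer. With integer-rounded ladder rungs (alternating 10 and 11 bp
steps), the estimator typically lands near 10.1–10.5 bp; the acceptance
band of ±0.4 bp reflects that discretization, not estimator noise.

## End and dinucleotide profiles

`termini_composition()` computes strand-resolved base proportions from
offset −2 to +34 across each terminus (offset 0 = the terminal base; the
3′ profile uses the same 5′→3′ offset axis). Proportions are normalized by
dividing each channel by its **modal** proportion across offsets and
log2-transforming. "Mode" of a continuous proportion needs a definition:
we use the most frequent value after rounding to 3 decimals, which acts as
a robust background divisor. Positions with N are excluded from counts,
never imputed. Fragments whose flanks leave the contig are skipped and
counted (attribute `n_skipped`); it is an error if none remain.

Dinucleotide profiles classify dimers as weak/strong/mixed; the classes
partition every offset. The midpoint profile anchors at
`start + floor(L/2)` (for odd lengths, one base toward the 5′ side) and
counts the dimer starting at every offset exactly once per fragment, so
overlapping per-end context windows cannot double-count. The termini
profile uses an inward-positive axis (−10 outside … 0 at the terminal base
… +9 inside); the dimer at offset *k* is the base at *k* plus its inward
neighbour, read 5′→3′ along the fragment's strand. That convention is
chosen deliberately: the weak and strong classes are closed under reverse
complement, so for end-polished libraries carrying both strands of each
blunted duplex the 5′ and 3′ profiles are *exactly* equal — the blunting
rule forces it coordinate by coordinate — while native-end libraries with
asymmetric overhangs break the symmetry. The default strand filter is
`"+"` (the forward-read orientation filter used with aligned data); the
exact symmetry is demonstrated with `strands = "both"`.

"Median filter" normalization is implemented as division of each channel
by its median across the whole window, not a running median: the purpose
is to center profiles at 1, and a running median would erase the
oscillation being measured. It is idempotent after one application.

## The synthetic-data generator

The generator's defaults are the study conditions the analyses are
verified under:

| parameter | default | meaning |
|---|---|---|
| `nucleosome_spacing` | 180 bp | repeat length of phased arrays |
| `chromatosome_len` | 167 bp | chromatosome protection |
| `core_len` | 144 bp | core-particle protection |
| `cut_period` | 10.4 bp | sub-nucleosomal ladder period |
| `subnucleosomal_weight` | 0.15 | ladder-truncation probability |
| `length_jitter_sd` | 3 bp | chromatosome length spread |
| `overhang_probs` | blunt 0.4 / 5′ 0.3 / 3′ 0.3, lengths uniform 1–6 | per-end overhang model |
| `footprint_len_range` | 35–80 bp | factor-protected lengths |
| `coupling_efficiency` | 0.99 | per-cycle oligo synthesis success |
| `dinuc_amplitude` | 0.3 | weak/strong placement bias under dyads |

Choices worth explaining:

* **Overhang model.** No empirical overhang distribution is available —
  only the observation that 5′ and 3′ termini differ — so the default is a
  symmetric, per-end-independent mixture. Overhangs *extend* one strand
  outward from the duplex core. A consequence verified by exact
  convolution in the ledger analysis and visible in the tests: the modal
  *strand* length sits at 168 bp, one above the 167 bp core mode, because
  extensions are one-sided. The package reports whatever mode the
  histogram has; tests assert the core mode exactly and the strand mode
  within 2 bp.
* **Ladder truncations** are one-sided cuts of the chromatosome span
  (`round(167 − k·10.4)`, k = 1..8, cut side uniform), with no extra
  length jitter — rungs are discrete.
* **Array dyad dispersion.** In the factor-locus generator, nucleosome
  dyads are phased at `site ± (90 + m·180)`, m = 0..5, with per-template
  Gaussian jitter (sd 5 bp) — the same dispersion used for the cfDNA dyad
  grid. Dispersion matters: with dyads fixed at identical coordinates in
  every molecule, the averaged WPS becomes a flat-topped plateau per
  nucleosome and the Savitzky–Golay filter overshoots at plateau corners,
  manufacturing twin spurious maxima; phasing is a distribution across
  molecules, not a fixed coordinate.
* **Purification constants** (truncation retention: desalt 1, HPLC 0.35,
  PAGE 0.12) are calibration constants chosen only to reproduce the
  qualitative purity ordering desalt < HPLC < PAGE; they are exposed, not
  claimed as measured. The optional bead-cleanup bias (logistic recovery,
  midpoint 33 nt, scale 3 nt) is off by default.
* **Resampling.** Templates falling outside the contig are redrawn with a
  hard cap of 100·n attempts, so infeasible configurations fail loudly.

All generators are reproducible bit-for-bit given `seed`.

**What the generator does not emulate:** sequencing errors, adapter
dimers, PCR duplicates, GC-amplification bias, sequence-specific ligation
bias, mappability, and real genomic base composition (backgrounds are
i.i.d. uniform). Passing tests therefore demonstrate correctness of the
*computations* under the protection/prep model, not robustness to every
artifact of real libraries.

## Problem sizes and tolerances

The verification suite runs at desk scale, chosen so the whole suite
completes in well under a minute of compute per module: length-spectrum
and mode checks use 10⁵ templates on a 1 Mb contig; WPS oracle equality
uses 100 randomized instances of 5–50 fragments; the locus analyses use
100–200 sites × 400–500 fragments; oligo models use 10⁴–10⁵ reads per
length. Stochastic assertions use fixed seeds and tolerances derived from
the constructions themselves (binomial standard errors for fractions,
±0.4 bp for the discretized ladder period, ±10 bp for the 180 bp repeat).

## Known limitations

* `raw_wps()` scores one contig region at a time; genome-wide scoring is
  a loop the caller owns.
* Truncated oligo reads are matched to oligos by id, not by alignment;
  cross-mapping ambiguity in real pools is out of scope.
* The 83 bp sub-peak and one-sided degradation hypotheses are biological
  interpretations; the package computes the profiles but asserts nothing
  about their cause.
* Region averaging assumes all regions fit inside scored bounds and
  errors otherwise (no silent clipping anywhere in the package).
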