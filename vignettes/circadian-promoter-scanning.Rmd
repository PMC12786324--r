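---
title: "Circadian cis-regulatory motif scanning: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian cis-regulatory motif scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circamotif)
```

## The problem

Insect circadian clocks drive rhythmic transcription through a small set of
well-characterized cis-regulatory elements: CLOCK/CYCLE activators bind E-boxes
(canonical core `CACGTG`, degenerate form `CANNTG`), the DBP/VRILLE–PDP1
output loop acts through D-boxes (`TTATG[TC]AA`) and PDP1 cores
(`ATTTAT`/`ATAAAT`), cAMP input arrives through CREs (`TGACGTCA`), and short
PER-associated repeats (`CATAC`/`GTATG`) recur in clock-gene promoters.
Whether a gene of interest — here, the honey-bee melatonin receptor *AmMTR* —
is plausibly clock-regulated can be screened in silico by scanning its
promoter for these elements and asking whether they are more frequent than a
background model predicts.

`circamotif` implements that screen as a reusable, fully testable pipeline:

1. **extraction** of a TSS-anchored upstream window from genomic FASTA;
2. **PWM scanning** with min–max relative-score thresholding;
3. **consensus scanning** of exact/degenerate IUPAC cores;
4. **enrichment testing** against Markov-background resampling;
5. a **synthetic-promoter generator** with planted sites and a truth table,
   so that every stage has a ground truth without genome downloads.

## Coordinate conventions

All reported positions are TSS-relative with negative values upstream. A
window of length $L$ covers exactly $-L \dots -1$; the base at $-1$ is
immediately 5′ of the TSS and the TSS base itself is excluded. Internally,
0-based index $i$ and relative position $r$ satisfy $r = i - L$. Genomic
input coordinates are 1-based inclusive (NCBI citation style), so a + strand
window is the genomic interval $[\mathrm{tss} - L, \mathrm{tss} - 1]$; for a
− strand gene the window is the reverse complement of
$[\mathrm{tss} + 1, \mathrm{tss} + L]$, so the output always reads 5′→3′
toward the TSS. One consequence worth stating: whether a published "−3 kb
promoter" includes the TSS base is often ambiguous; we fix the TSS-excluded
convention, so an off-by-one against other tools is possible at the window
edge.

Hits are always reported on the + strand of the extracted window:
`rel_start` is the TSS-relative position of the hit's 5′-most base on the
+ strand, and `matched` is the + strand substring even for − strand hits.

## PWM scoring model

A position frequency matrix (counts $c_{bj}$, column totals $N_j$) becomes a
log-odds weight matrix under a background distribution $\pi$ with a
pseudocount $\kappa$ distributed by the background:

$$ f_{bj} = \frac{c_{bj} + \kappa\,\pi_b}{N_j + \kappa}, \qquad
   w_{bj} = \log_2 \frac{f_{bj}}{\pi_b}. $$

A window scores $s = \sum_j w_{b(j),j}$, and is reported when its **relative
score**

$$ \tilde s = \frac{s - s_{\min}}{s_{\max} - s_{\min}} \ge \tau $$

where $s_{\min}, s_{\max}$ are the sums of per-column weight minima/maxima.
Defaults: $\kappa = 0.8$, uniform $\pi$, $\tau = 0.85$ inclusive, both
strands. Rationale for the unstated constants: $\kappa = 0.8$ spread by the
background is common PFM practice (it is TRANSFAC/MOODS lineage), the uniform
background is the neutral default (the promoter's own composition can be
supplied via `score_params()`), and the min–max relative score is invariant
to the log base, so base 2 is purely conventional. The threshold comparison
is inclusive ($\ge$), and degenerate matrices with $s_{\min} = s_{\max}$ are
rejected at build time. Windows containing `N` are skipped. Overlapping hits
of one motif are all reported by default; `scan_config(prune_overlaps =
TRUE)` enables greedy pruning (best relative score, ties 5′-most then +
strand) for users who want non-redundant site lists.

Per-site p-values are deliberately out of scope: the relative-score
threshold is the sole PWM filter, and significance is assessed at the
family-count level by the enrichment module instead.

## Consensus scanning

`compile_pattern()` turns an IUPAC string into a position-wise allowed-base
matcher; `N` in a *pattern* allows any of A/C/G/T, while `N` in the
*sequence* matches nothing (conservative on masked bases). The default
strand mode is `plus_only`, reproducing the convention of listing positions
on the + strand; this is less restrictive than it looks because the Pdp1 and
PER-repeat alternative pairs are mutual reverse complements (the families
are orientation-closed), the canonical E-box and CRE are palindromic, and
`CANNTG` is reverse-complement-closed as a set. Both-strand scanning is an
explicit option.

Every `CACGTG` is also a `CANNTG`, so degenerate E-box hits that coincide
with a canonical hit are dropped by default (`dedup_degenerate_ebox`),
keeping the two families disjoint in reports. On random sequence `CANNTG`
matches once per ~256 windows, so raw degenerate counts in a 3 kb window are
expected near 11 per strand; published degenerate-E-box site lists are
typically much shorter, implying additional unstated filters (conservation,
clustering, factor context). We implement the stated patterns and
conventions only, and therefore treat published *total* consensus counts as
non-reproducible; the planted-site fixtures, where truth is known, are the
package's accuracy benchmark instead.

## Enrichment test

For each family the observed count in the query window is compared with
counts in $n$ background sequences of the same length (default $n = 999$),
giving the one-sided empirical p-value

$$ p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{1 + n}, $$

the add-one permutation form, which can never be zero. Corrections across
the families actually tested (all configured consensus families plus one per
supplied PWM) use Benjamini–Hochberg by default, or Bonferroni. Depletion is
available by flipping the tail. Defaults $n = 999$ and $\alpha = 0.05$ are
the permutation-testing conventions; all are overridable in
`enrichment_config()`.

The background is a zero- or first-order Markov model. Because a genuine
set of genome-wide promoters requires a download, the default fits the model
to the query promoter itself (`markov_shuffle` — a mononucleotide or
dinucleotide shuffle null); a user FASTA of real promoters can be supplied
either to fit the model or, with `background_mode = "promoter_set"`, to
draw count nulls from directly. Fitting uses add-pseudocount smoothing
(default 1) with `N` bases excluded, so all probabilities are strictly
positive.

Two properties define "working" here, and both are tested: **calibration**
(on null promoters drawn from the fitted model, the rejection rate at
$\alpha = 0.05$ over 200 replicates lies inside the exact binomial 95% band
— note that with a discrete count statistic the empirical p is conservative
through ties, so the rate sits near the band's lower edge) and **power**
(five planted Pdp1 cores against a null mean of
$2 \times 2995 / 4^6 \approx 1.46$ are detected at $\alpha = 0.05$ in well
over 80% of replicates).

## The synthetic generator

`simulate_promoter()` emulates exactly what the analysis assumes about real
promoters: a Markov background (order 0 or 1) optionally **purged** of all
six families' cores (offending windows locally resampled until clean), with
exact cores planted at specified TSS-relative positions and a truth table
recording family, position, strand and site sequence. Degenerate E-box
plants use `CAGTTG` — a `CANNTG` word that is not `CACGTG` — so the
canonical and degenerate families stay disjoint in fixtures and family-level
recall is unambiguous.

Planting can create new cores at plant/background junctions (a `CANNTG`
straddling a junction is expected ~0.5 times per 12-site fixture), so with
`ensure_clean = TRUE` (default) the generator redraws the purged background
within the seeded stream until a consensus scan of the planted window
returns exactly the truth table. Generation is a pure function of
(seed, parameters); a capped number of redraws (50) guards against
pathological layouts. The bundled `ammtr_site_layout()` encodes the
positions reported for the *AmMTR* promoter — Pdp1 at −820/−357/−102,
degenerate E-boxes at −2762/−1580/−1383, a canonical E-box at −1334, a CRE
at −93, and D-boxes at −2701/−2498/−457/−132 — as a 12-site reference
layout for recovery tests.

What the generator does **not** emulate: real base composition and
isochores, repeat structure, conservation, nucleosome context, indel noise
on sites, or weak/partial motif instances. Passing recovery tests on these
fixtures demonstrates that the coordinate chain, matchers and statistics are
correct — not that the biological predictions on real promoters are
complete or specific.

## Numerical and degenerate-input choices

* PWM scanning is vectorized per column; windows containing `N` score `NA`
  and are skipped rather than penalized.
* `s_{\min} = s_{\max}` (all-constant columns) is a build error, not an NaN
  at scan time.
* Empirical p-values use sample moments for `null_mean`/`null_sd` purely as
  descriptive output; inference never touches a normal approximation.
* Tie-breaks in hit ordering are fixed (position, then family, then +
  before −) so that pipeline outputs are byte-identical across runs with the
  same configuration and seed.
* Seeded routines snapshot and restore the caller's RNG state, so library
  calls do not perturb user scripts.

## Problem sizes used in the test suite

Scan correctness is checked against an exhaustive per-window oracle on 100
random PFM/sequence instances (widths ≤ 5, lengths ≤ 200); scoring bounds by
full enumeration of all $4^w$ words (w ≤ 5); calibration and power on 200
replicates of 3 kb promoters with 999 resamples each; density sanity checks
on 500–1000 replicates of 3 kb backgrounds against closed-form expectations.
These sizes give stable pass/fail behavior at desk scale while keeping the
full suite comfortably fast.

## Worked example

```{r example}
fx <- simulate_promoter(seed = 1, tss_genomic = 5949179,
                        assembly_label = "synthetic")
hits <- scan_consensus(fx$region)
summary(hits)

enr <- test_enrichment(fx$region,
                       config = enrichment_config(n_samples = 999, seed = 2))
enr
```

The planted D-box (4 sites vs a null mean near 0.1) and Pdp1 (3 vs a null
mean near 1) families behave exactly as the construction dictates;
PER-repeat, never planted, stays at its null.

## Known limitations

* The consensus totals of any specific published promoter scan are not
  reproduction targets: they depend on unstated matrix versions and filters
  (see above). The package reproduces conventions and positions, and its
  accuracy claims are made on fixtures with known truth.
* `plus_only` counting halves the search space for families that are not
  orientation-closed (D-box); use `strands = "both"` when orientation
  should not matter biologically.
* The Markov-shuffle null conditions on the query's own composition; with a
  single 3 kb query the fitted model is itself noisy (±1% per base
  frequency), which the calibration test shows is immaterial at this scale.
* No mismatch-tolerant consensus matching and no analytic (compound-Poisson)
  count p-values; the resampling path is the only inferential route.
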