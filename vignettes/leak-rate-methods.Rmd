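---
title: "Methods: estimating and modelling stop codon readthrough from ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and modelling stop codon readthrough from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrleak)
```

## The estimation problem

Stop codon readthrough (SCR) leaves a footprint-density signature in
ribosome profiling data: coverage between a transcript's annotated stop
codon and the next in-frame stop codon in its 3'UTR. `scrleak` quantifies
that signature per transcript as a ribosomal leak rate

$$\rho = \frac{\delta_{ext}}{\delta_{CD}},$$

the ratio of cumulative footprint density in a 30-nt window inside the
C-terminal extension to cumulative density in a 30-nt window at the end of
the coding region. Both windows are defined relative to the first nucleotide
of the stop codon:

* $\delta_{CD}$: the 14 nt preceding the stop codon plus the 16 nt
  following it (the 3 stop-codon nucleotides are excluded). Because
  ribosome-protected fragments are 28–29 nt long with the P-site at
  fragment position 13, this window collects the full density of ribosomes
  decoding the final codons.
* $\delta_{ext}$: downstream offsets +29..+58, counted from the first
  nucleotide after the stop codon. Starting the window 29 nt downstream
  keeps footprints that merely dangle past a terminating ribosome out of
  the extension signal; only ribosomes that actually translated past the
  stop can deposit density there.

Density is full-footprint **coverage** (each fragment increments every
position it spans), not P-site-collapsed counts. The window construction
already absorbs footprint geometry, and coverage is the quantity that can
be read directly off an alignment pileup. This is a deliberate choice:
with P-site counting the windows would need different offsets.

### Selection filters

A transcript becomes an SCR candidate only when

1. footprints cover at least 90% of the *extended region* (the interval
   from the nucleotide after the annotated stop to the nucleotide before
   the next in-frame stop), with at least 2 supporting reads;
2. $\rho > 0.005$ (strictly; a transcript at exactly 0.005 is rejected);
3. the next in-frame stop lies at least 18 nt downstream — closer second
   stops distort the local density (a ribosome covers ~30 nt) and make the
   estimate unreliable;
4. a next in-frame stop exists at all (otherwise the extension is
   undefined).

"At least 2 reads" is read as two distinct footprints overlapping the
extended region in total; a stricter per-position variant is available via
`scr_config(per_position = TRUE)`. The per-region reading is the default
because the 90%-coverage clause is stated separately and would be largely
redundant under the per-position reading.

Events are then stratified by rate: TS1 ($\rho > 3\times10^{-4}$) and TS2
($\rho > 20\times10^{-4}$); TS2 is a subset of TS1 by construction.
Transcripts with no extension signal at all ($\delta_{ext} = 0$) form the
control pool TS0 used as the reference for all context statistics. Note
that the TS1 threshold sits *below* the candidate threshold of 0.005; the
two are independent dials (`scr_config(ts1 =, ts2 =, rho_min =)`) and we do
not attempt to reconcile them — with the default candidate filter active,
every passing event is also in TS2.

## Context statistics

The stop codon context (SCC) is the 70-nt window: 49 nt upstream, the stop
codon, 18 nt downstream. Positions are labelled −49..−1 and +1..+18; the
three stop-codon slots are constant within a per-codon analysis and carry
no label. For a transcript set against the TS0 reference:

* **Positional divergence** $D(r) = \sum_i p_i(r)\log(p_i(r)/p^*_i(r))$ in
  nats. Natural logarithms throughout; the base only rescales and all
  comparisons are internal.
* **Pairwise divergence** $D(r,s) = \sum_{ij} p_{ij}\log(p_{ij}/p_i p_j)$,
  the mutual information of the nucleotides at two positions, computed for
  all $\binom{67}{2} = 2211$ unordered non-stop position pairs. Empirical
  joint frequencies keep this finite without smoothing (a zero joint cell
  contributes zero).
* **Fisher exact tests** of GC vs AU counts (set vs reference) per
  position, two-sided, raw p-values by default (`p_adjust_method = "BH"`
  enables Benjamini–Hochberg). A table with an all-zero margin returns
  p = 1 by convention.
* **GC3 profiles**: fraction of transcripts with G or C at each codon's
  third position, aligned at the CDS start or end; the stop codon is not
  part of the profile.

**Zero-frequency handling.** $D(r)$ on raw frequencies is infinite whenever
the reference lacks a nucleotide the set contains. `scc_divergence()`
therefore adds a Jeffreys pseudocount of ½ per nucleotide per position
before normalising (disable with `pseudocount = 0`). The pairwise
divergence needs no pseudocount and uses none.

## The leak-rate model

The model is linear in the nucleotide identities at selected context
positions, $y = a_0 + \sum_i b_i x_i$, with each nucleotide encoded by a
bipolar pair: A→{1,1}, C→{−1,1}, U→{1,−1}, G→{−1,−1}. A model on $k$
positions has $N = 2k + 1$ coefficients (intercept included).

Coefficients are the minimum-norm least-squares solution computed from the
SVD of the (transposed) design: singular values below $10^{-10}$ times the
largest are truncated to zero (standard pseudoinverse practice), which
makes rank-deficient designs — duplicated positions, more coefficients than
training sequences — well defined: among all least-squares solutions the
one with the smallest Euclidean norm is returned. The all-zero response
yields the all-zero coefficient vector.

**Position selection.** The $k$ positions with the largest $D(r)$ are
selected; ties break toward the position closer to the stop codon (smaller
absolute label), and the selection is reported 5'→3'. Three canonical
position sets support model comparison (`model_variants()`):

* `flank12` — six positions on each side of the stop codon, the classical
  short-context model;
* `contig29` — 29 positions contiguous to the stop. How these split
  between the two sides is not canonical; the default is 15 upstream + 14
  downstream (upstream-weighted, since the analysis window offers 49 nt
  upstream but only 18 downstream), configurable via `contig29_split`;
* `topk` — the top-k divergence-ranked positions, with k defaulting to
  18 (UGA), 13 (UAA), 25 (UAG).

Only single positions enter the default model. An interaction encoding for
position *pairs* would be a natural extension (the pairwise divergence
identifies candidate pairs), but there is no canonical pair code to commit
to, so the shipped model stays with single positions.

**Evaluation.** Classification is by sign: a false positive is a no-SCR
context with strictly positive predicted rate; a false negative an SCR
context with strictly negative predicted rate. A prediction of exactly
zero means "no readthrough predicted" and is counted as neither error.
Models are always fitted per stop codon, never pooled: the stop codon
itself is constant within a model and carries no information, and the
context patterns associated with readthrough differ between codons.

## The synthetic-data generator

`simulate_transcripts()` + `simulate_reads()` emulate exactly the
statistical structure the estimator assumes:

* transcripts with 5'UTR/CDS/3'UTR structure; the CDS is drawn codon-wise
  with in-frame stop codons rejected, so a valid ORF is guaranteed by
  construction rather than post-hoc repair;
* an annotated stop codon of chosen identity and an in-frame second stop
  at a controllable distance (codons between the two stops are stop-free,
  so the distance is exact);
* footprint 5' starts drawn per nucleotide position as Poisson counts:
  mean `cds_density` in the coding region, `true_rho * cds_density` in the
  extension, zero past the second stop; lengths from a 28/29-nt mixture;
* optional planted context biases in high-rate transcripts: a bias with
  excess $e$ raises a nucleotide's frequency at one SCC position from its
  base value $p$ to exactly $p + e$ (non-target bases are replaced with
  probability $e/(1-p)$), which gives tests an analytically known shift.
  If planting would create a premature in-frame stop, the unforced bases
  of the affected codon are resampled.

Two distributional consequences matter for interpreting tests:

* **ORF conditioning.** Codon-wise stop rejection tilts in-frame CDS
  composition slightly away from the raw base frequencies (with uniform
  bases, T at codon position 1 drops to 13/61). Composition checks against
  the raw base frequencies are only valid at i.i.d. 3'UTR positions; CDS
  positions are checked against the 61-codon conditional distribution.
* **Window-edge bias.** The generator produces flat *start-rate* profiles,
  so coverage tapers linearly over the 28–29 nt after starts cease. The 16
  downstream positions of the $\delta_{CD}$ window sit in that taper:
  with mixture mean length $\bar L = 28.5$, the expected window sums are
  $E[\delta_{CD}] \approx (30\bar L - 136)\,c$ and
  $E[\delta_{ext}] = 30\bar L \rho c$, so
  $E[\hat\rho]/\rho \approx 855/(719 + 136\rho)$ — an upward bias of
  17–19% across $\rho \in [0.01, 0.1]$. This is a property of the
  estimator on taper-free profiles, not a defect of either piece: on real
  data the termination peak fills that part of the window. The recovery
  tests assert agreement within 20%, which this bias fits; sample sizes
  (250–2500 transcripts per rate, density 50, chunked to bound memory)
  are chosen so Monte-Carlo noise cannot move the mean across that band.

What the generator does **not** emulate: the termination-peak and
codon-level dwell-time structure of real profiles (the profile is flat
within each region — the window sums only see totals), sequencing error,
multimapping, splice isoforms, reads in genome coordinates, and any
correlation between expression level and context. Passing tests therefore
demonstrate correctness of the estimation machinery under its own model
assumptions, not robustness to alignment artefacts or biological
confounders.

### The model-comparison benchmark

`simulate_scc_benchmark()` builds a readthrough-prediction benchmark with
planted ground truth: readthrough contexts carry nucleotide biases at four
stop-flanking positions and eight distal ones, their rates follow the
corresponding linear model (negative intercept, so unbiased contexts imply
no readthrough), and rates are kept positive by rejection — observed
readthrough events have positive measured rates. Defaults: 60 training
pairs, 300 held-out readthrough contexts plus 50 readthrough-free contexts
for evaluation, excess 0.5, effect sizes 0.017 (proximal) / 0.012 (distal),
intercept −0.155, rate noise 0.005.

The design is deliberate. A least-squares model trained only on
positive-rate sequences regresses toward the positive training mean, so a
model blind to part of the signal (the flank-only variant misses the
distal half) fails in two visible ways only when the training set is small
enough that coefficient noise is material — M = 60 matches the scale of
the experimental training sets that motivated short-context models — and
the planted rates are almost surely positive, so truncation does not
attenuate the fit. In that regime the divergence-selected model, which
recovers the planted positions from the data, is on average at least as
good on *both* error fractions, while the flank-only model misclassifies
readthrough-free contexts wholesale and the 29-position model pays for its
parameter count. This reproduces the qualitative ordering the estimator is
meant to exhibit, with all quantities recomputed at run time.

## Numerical and interface conventions

* Coordinates are 1-based inclusive in memory (R convention) and 0-based
  half-open in every file format (annotation TSV, footprint TSV, bedGraph
  profiles); readers and writers convert at the boundary.
* U and T are interchangeable on input; sequences are normalised to
  uppercase A/C/G/T internally, and stop codons are reported with RNA
  labels (UAA/UAG/UGA).
* All randomness flows through explicit seeds; identical configurations
  reproduce identical transcripts, reads, truth tables and pipeline
  manifests.
* Degenerate inputs are defined, not fatal: a transcript with no
  downstream stop is excluded from candidacy (not an error), an event with
  $\delta_{CD} = 0$ has an undefined rate and is rejected, an empty read
  table yields an all-zero profile and a warning from the pipeline, and a
  context with insufficient flank is skipped with a `NA`.

## Limitations

* The leak-rate estimator inherits the window-edge bias discussed above;
  on real data its magnitude depends on the termination-peak shape, which
  the package does not model.
* Divergence ranking with few contexts (tens) is noisy; position selection
  should be trusted only with hundreds of contexts per set.
* The linear model predicts a signed score whose sign is the readthrough
  call; predicted magnitudes are not calibrated rates.
* No regularised variants (ridge/lasso) and no cross-validated choice of
  k are provided; k defaults follow the per-codon values quoted above.
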