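# scrleak

Detection and sequence-context modelling of **stop codon readthrough (SCR)**
from ribosome profiling data, in transcript coordinates.

During translation termination, ribosomes occasionally misread a stop codon:
a near-cognate tRNA outcompetes the release factor, translation continues
into the 3'UTR, and a C-terminally extended protein is produced. In Ribo-seq
data this leaves a diagnostic signature — footprint density between the
annotated stop codon and the next in-frame stop codon. `scrleak` implements
a complete analysis of that signature:

1. **Density profiles.** Per-nucleotide footprint coverage per transcript
   (`build_density_profile()`), with the P-site at footprint position 13 and
   the A-site one codon downstream.
2. **Leak-rate estimation.** The ribosomal leak rate of a transcript is

   ρ = δ_ext / δ_CD

   where δ_CD is the cumulative density over the 30-nt window at the end of
   the coding region (14 nt before the stop codon + 16 nt after it, stop
   codon excluded) and δ_ext the cumulative density over the 30-nt window
   spanning downstream offsets +29..+58. The gap between the windows keeps
   footprints of terminating ribosomes out of the extension signal.
   Candidate events must have ≥90% footprint coverage of the extended
   region with ≥2 reads, ρ > 0.005, and a next in-frame stop ≥18 nt away
   (`detect_scr()`). Events are stratified into rate sets: TS1 (ρ > 3×10⁻⁴),
   TS2 (ρ > 20×10⁻⁴, a subset of TS1), with transcripts lacking extension
   signal forming the control pool TS0.
3. **Context statistics.** For the 70-nt stop codon context (SCC: 49 nt
   upstream, stop, 18 nt downstream): per-position nucleotide frequencies,
   positional Kullback–Leibler divergence D(r) = Σᵢ pᵢ(r) log(pᵢ(r)/p*ᵢ(r))
   against the TS0 reference, pairwise divergence D(r,s) (the mutual
   information of the 2211 non-stop position pairs), two-sided Fisher exact
   tests of GC-vs-AU usage, GC3 profiles along the CDS, and leak-rate
   histograms stratified by the stop-adjacent nucleotides.
4. **Leak-rate model.** A linear model y = a₀ + Σᵢ bᵢ xᵢ on the nucleotides
   at selected context positions, each encoded by a bipolar pair
   (A→{1,1}, C→{−1,1}, U→{1,−1}, G→{−1,−1}). Coefficients are estimated by
   minimum-norm least squares via SVD pseudoinverse (`leak_model()`, an S3
   modelling class with `coef`/`predict`/`summary`/`residuals`/`simulate`
   methods). Position sets for model comparison (`model_variants()`): the
   6+6 stop-flanking positions, 29 positions contiguous to the stop, or the
   top-k positions ranked by divergence (k = 18/13/25 for UGA/UAA/UAG).
   `evaluate_leak_model()` scores false positives (no-SCR context, positive
   predicted rate) and false negatives (SCR context, negative predicted
   rate).
5. **Synthetic data with ground truth.** `simulate_transcripts()` /
   `simulate_reads()` generate transcripts (5'UTR/CDS/3'UTR, chosen stop
   codon, controllable second-stop distance, guaranteed-ORF CDS) and
   Poisson-distributed footprints at a coding-region density and ρ-times
   that density in the extension; `simulate_regression_set()` and
   `simulate_scc_benchmark()` generate training sets with planted
   coefficients and context biases.

## Worked example

```r
library(scrleak)

cfg <- sim_config(seed = 42, n_transcripts = 400, cds_density = 10,
                  true_rho = c(0, 0.03), second_stop_distance = 90,
                  utr3_length_range = c(150, 200),
                  planted_bias = data.frame(position = c(-12L, 1L),
                                            nucleotide = c("A", "G"),
                                            excess = c(0.35, 0.35)))
sim    <- simulate_transcripts(cfg)
reads  <- simulate_reads(sim$transcripts, sim$truth, cfg)
events <- detect_scr(sim$transcripts, reads)
as.data.frame(events)[1:2, c("transcript_id", "delta_cd", "delta_ext",
                             "rho", "set_label")]
#>   transcript_id delta_cd delta_ext        rho set_label
#> 1       TX00001     7215         0 0.00000000       TS0
#> 2       TX00002     7202       330 0.04582061       TS2
```

Half of the transcripts were simulated with a true leak rate of 0.03 and
biased contexts; the estimator recovers rates of the right magnitude
(δ_ext ≈ 330 footprint-nucleotides over δ_CD ≈ 7200 gives ρ̂ ≈ 0.046) and the
unbiased half lands in the TS0 control pool. The divergence profile of the
high-rate set against the controls ranks the planted positions first:

```r
ctx <- extract_scc(sim$transcripts$sequence, sim$transcripts$stop_start)
div <- scc_divergence(ctx[events$set_label == "TS2"],
                      ctx[events$set_label == "TS0"])
head(div$per_position[order(-div$per_position$D), c("label", "D", "fisher_p")], 3)
#>  label          D     fisher_p
#>    -12 0.27946232 3.136701e-08
#>      1 0.26530995 8.823547e-05
#>    -35 0.04627393 1.607949e-01
```

Divergence at the planted positions (−12 upstream, +1 downstream of the
stop) stands an order of magnitude above the sampling-noise floor of the
unplanted ones. A leak-rate model on the six most informative positions:

```r
fit <- leak_model(ctx[events$set_label == "TS2"],
                  events$rho[events$set_label == "TS2"],
                  positions = select_positions(div$per_position, 6),
                  stop_codon = "UGA")
fit
#> Linear leak-rate model (UGA)
#>   6 positions, 13 coefficients, M = 200 training contexts, rank 13
#>   positions: -39 -35 -33 -12 +1 +15
#>   intercept a0 = 0.0348, residual sd = 0.01034
round(predict(fit, ctx[1:4]), 4)
#> 0.0347 0.0332 0.0355 0.0354
```

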