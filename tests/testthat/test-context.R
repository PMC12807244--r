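test_that("context extraction is a 70-nt slice around the stop codon", {
  tx <- make_transcript(utr5 = strrep("G", 60), cds = strrep("GCT", 30),
                        stop = "TGA", utr3 = strrep("C", 40))
  ctx <- extract_scc(tx$sequence, tx$stop_start)
  expect_equal(nchar(ctx), 70)
  # slice equals the hand-indexed substring
  expect_equal(ctx, substr(tx$sequence, tx$stop_start - 49, tx$stop_start + 20))
  # the stop codon sits at window indices 50..52
  expect_equal(substr(ctx, 50, 52), "TGA")

  # too-short upstream flank (48 nt available) -> skip signal
  short <- make_transcript(utr5 = "", cds = strrep("GCT", 16),
                           utr3 = strrep("C", 40))
  expect_true(is.na(extract_scc(short$sequence, short$stop_start)))
  # too-short downstream flank
  short3 <- make_transcript(utr5 = strrep("G", 60), cds = strrep("GCT", 30),
                            utr3 = strrep("C", 10))
  expect_true(is.na(extract_scc(short3$sequence, short3$stop_start)))
})

test_that("position labels map to window indices and back", {
  expect_equal(scc_label_to_index(c(-49, -1, 1, 18)), c(1, 49, 53, 70))
  expect_equal(scc_index_to_label(c(1, 49, 53, 70)), c(-49, -1, 1, 18))
  expect_true(all(is.na(scc_index_to_label(50:52))))  # stop slots unlabelled
  expect_length(scc_position_labels(), 67)
  expect_error(scc_label_to_index(0), "invalid")
})

test_that("position frequencies are column-stochastic counts", {
  expect_true(all(position_frequencies(c(strrep("A", 70)))["A", ] == 1))
  two <- c(paste0("A", strrep("C", 69)), paste0("G", strrep("C", 69)))
  p <- position_frequencies(two)
  expect_equal(unname(p[, 1]), c(0.5, 0, 0.5, 0))  # A,C,G,T at position 1
  expect_equal(colSums(p), rep(1, 70), ignore_attr = TRUE)

  set.seed(11)
  big <- uniform_contexts(2000)
  p <- position_frequencies(big)
  se3 <- 3 * sqrt(0.25 * 0.75 / 2000)
  expect_true(all(abs(p[, -(50:52)] - 0.25) < se3 + 0.01))
  expect_error(position_frequencies(NA_character_), "no contexts")
})

test_that("KL divergence matches closed forms and a brute-force oracle", {
  u <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  # identical distributions diverge by zero
  expect_equal(kl_divergence_profile(u, u), rep(0, 3))
  # degenerate vs uniform: D = ln 4
  p <- matrix(c(1, 0, 0, 0), 4, 3)
  expect_equal(kl_divergence_profile(p, u), rep(log(4), 3))
  # random columns against the term-by-term oracle
  set.seed(3)
  for (i in 1:10) {
    a <- prop.table(runif(4) + 0.01)
    b <- prop.table(runif(4) + 0.01)
    expect_equal(unname(kl_divergence_profile(cbind(a), cbind(b))[1]),
                 kl_oracle(a, b))
  }
  expect_error(kl_divergence_profile(u * 2, u), "column-stochastic")
})

test_that("pairwise divergence is the mutual information of position pairs", {
  # 67 non-stop positions -> choose(67, 2) = 2211 pairs
  set.seed(5)
  ctx <- uniform_contexts(40)
  pd <- pairwise_divergence(ctx)
  expect_equal(nrow(pd), 2211)
  expect_true(all(pd$D >= -1e-12))

  # perfectly coupled pair with exactly uniform marginals: D = ln 4
  bases <- rep(c("A", "C", "G", "T"), each = 100)
  coupled <- vapply(bases, function(b) {
    x <- rep("A", 70); x[50:52] <- c("T", "G", "A")
    x[1] <- b; x[70] <- b
    paste(x, collapse = "")
  }, character(1))
  pd <- pairwise_divergence(coupled, positions = c(1L, 70L))
  expect_equal(pd$D, log(4), tolerance = 1e-12)
  expect_equal(pd$r, -49)
  expect_equal(pd$s, 18)

  # matches the entropy-decomposition oracle on arbitrary joints
  set.seed(9)
  ctx <- uniform_contexts(120)
  pd <- pairwise_divergence(ctx, positions = c(2L, 10L, 60L))
  m <- do.call(rbind, strsplit(ctx, ""))
  for (k in seq_len(nrow(pd))) {
    joint <- table(m[, pd$index_r[k]], m[, pd$index_s[k]]) / length(ctx)
    expect_equal(pd$D[k], mi_oracle(joint), tolerance = 1e-12)
  }

  # independence limit: large i.i.d. set gives near-zero divergence
  set.seed(13)
  pd <- pairwise_divergence(uniform_contexts(3000), positions = c(5L, 40L))
  expect_lt(pd$D, 0.01)
})

test_that("Fisher GC-vs-AU test agrees with hypergeometric enumeration", {
  mk_counts <- function(gc, au) {
    m <- matrix(0, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
    m["G", 1] <- gc; m["A", 1] <- au
    m
  }
  # identical proportions -> p = 1
  expect_equal(fisher_gc_au(mk_counts(50, 50), mk_counts(500, 500)), 1)
  expect_equal(fisher_gc_au(mk_counts(5, 5), mk_counts(5, 5)), 1)
  # all-zero margin -> p = 1 by convention
  expect_equal(fisher_gc_au(mk_counts(0, 0), mk_counts(0, 0)), 1)
  # extreme association matches the enumeration oracle
  p <- fisher_gc_au(mk_counts(10, 0), mk_counts(0, 10))
  expect_equal(p, fisher_oracle(matrix(c(10, 0, 0, 10), 2)), tolerance = 1e-9)
  # moderate tables too
  set.seed(21)
  for (i in 1:5) {
    a <- sample(0:20, 4)
    p <- fisher_gc_au(mk_counts(a[1], a[2]), mk_counts(a[3], a[4]))
    expect_equal(p, fisher_oracle(matrix(c(a[1], a[2], a[3], a[4]), 2)),
                 tolerance = 1e-7)
  }
})

test_that("GC3 profile counts wobble-position G/C per codon index", {
  # all codons end in G or C -> 1.0 everywhere
  tx <- make_transcript(cds = paste0("ATG", strrep("GCC", 20)))
  g <- gc3_profile(tx, "start", n_codons = 10)
  expect_true(all(g$gc3[-1] == 1))  # codon 1 is ATG (third base G) = 1 too
  expect_true(all(g$gc3 >= 0 & g$gc3 <= 1))

  # constructed 5-codon CDS with known third bases: G,T,C,A,G
  tx5 <- make_transcript(cds = "ATGGCTGCCGCAGCG", utr3 = strrep("C", 80))
  g5 <- gc3_profile(tx5, "start", n_codons = 5)
  expect_equal(g5$gc3, c(1, 0, 1, 0, 1))
  # end-aligned view reverses the codon order
  e5 <- gc3_profile(tx5, "end", n_codons = 5)
  expect_equal(e5$gc3, rev(g5$gc3))
  expect_equal(e5$codon, -(1:5))

  # i.i.d. uniform CDS: GC3 near the 50% uniform-usage expectation
  set.seed(31)
  cfg <- sim_config(seed = 31, n_transcripts = 150, true_rho = 0,
                    stop_codon = "UAA")
  sim <- simulate_transcripts(cfg)
  g <- gc3_profile(sim$transcripts, "end", n_codons = 20)
  expect_true(all(abs(g$gc3 - 0.5) < 3 * sqrt(0.25 / g$n) + 0.02))
})

test_that("adjacent-nucleotide stratification conserves event counts", {
  set.seed(41)
  cfg <- sim_config(seed = 41, n_transcripts = 40, cds_density = 10,
                    true_rho = 0.05, second_stop_distance = 90,
                    utr3_length_range = c(150, 200))
  sim <- simulate_transcripts(cfg)
  reads <- simulate_reads(sim$transcripts, sim$truth, cfg)
  ev <- detect_scr(sim$transcripts, reads)
  strat <- stratify_by_adjacent(ev, sim$transcripts)
  # each side partitions all rated events across nucleotides and bins
  for (side in c("-1", "+1")) {
    expect_equal(sum(strat$count[strat$side == side]), sum(!is.na(ev$rho)))
  }

  # a side with a constant nucleotide leaves the other histograms empty
  tx <- make_transcript(utr3 = paste0("G", strrep("A", 20), "TAA",
                                      strrep("C", 70)))
  ev1 <- data.frame(transcript_id = tx$id, stop_codon = tx$stop_codon,
                    rho = 0.02)
  s <- stratify_by_adjacent(ev1, tx)
  dn <- s[s$side == "+1", ]
  expect_equal(sum(dn$count[dn$nucleotide == "G"]), 1)
  expect_equal(sum(dn$count[dn$nucleotide != "G"]), 0)
})
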