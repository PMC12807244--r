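test_that("config invariants are enforced", {
  expect_error(sim_config(base_composition = c(A = 0.5, C = 0.5, G = 0.1,
                                               T = -0.1)), "base_composition")
  expect_error(sim_config(second_stop_distance = 20), "multiple of 3")
  expect_error(sim_config(true_rho = -0.1))
  expect_error(sim_config(planted_bias = data.frame(position = 30L,
                                                    nucleotide = "A",
                                                    excess = 0.2)), "invalid")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("generated transcripts satisfy the requested geometry", {
  cfg <- sim_config(seed = 5, n_transcripts = 30, stop_codon = "UAA",
                    second_stop_distance = 0)
  sim <- simulate_transcripts(cfg)
  tx <- sim$transcripts
  validate_transcripts(tx)
  # every CDS ends with the requested stop codon
  expect_true(all(substr(tx$sequence, tx$stop_start, tx$stop_start + 2)
                  == "TAA"))
  # distance 0: the codon right after the annotated stop is itself a stop
  d <- mapply(find_next_inframe_stop, tx$sequence, tx$stop_start)
  expect_true(all(d == 0))

  # requested positive distance is honoured exactly, and no premature
  # in-frame stop exists inside the CDS
  cfg2 <- sim_config(seed = 6, n_transcripts = 30, stop_codon = "UGA",
                     second_stop_distance = 129,
                     utr3_length_range = c(150, 250))
  tx2 <- simulate_transcripts(cfg2)$transcripts
  d2 <- mapply(find_next_inframe_stop, tx2$sequence, tx2$stop_start)
  expect_true(all(d2 == 129))
  for (i in seq_len(nrow(tx2))) {
    starts <- seq(tx2$cds_start[i], tx2$stop_start[i] - 3, by = 3)
    codons <- substring(tx2$sequence[i], starts, starts + 2)
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }

  # mixed stop codons draw from all three
  cfg3 <- sim_config(seed = 7, n_transcripts = 60, stop_codon = "mixed")
  expect_setequal(unique(simulate_transcripts(cfg3)$transcripts$stop_codon),
                  c("UAA", "UAG", "UGA"))
})

test_that("identical seeds reproduce transcripts, reads and truth", {
  cfg <- sim_config(seed = 9, n_transcripts = 10)
  a <- simulate_transcripts(cfg)
  b <- simulate_transcripts(cfg)
  expect_identical(a, b)
  expect_identical(simulate_reads(a$transcripts, a$truth, cfg),
                   simulate_reads(b$transcripts, b$truth, cfg))
})

test_that("planted bias shifts the context frequency by the stated excess", {
  # plant downstream of an immediately adjacent second stop, where the 3'UTR
  # sequence is i.i.d. from the base composition, so the expected frequency
  # is exactly base + excess
  bias <- data.frame(position = 10L, nucleotide = "A", excess = 0.25)
  cfg <- sim_config(seed = 15, n_transcripts = 1000, true_rho = 0.05,
                    second_stop_distance = 0, planted_bias = bias)
  sim <- simulate_transcripts(cfg)
  expect_true(all(sim$truth$biased))
  ctx <- extract_scc(sim$transcripts$sequence, sim$transcripts$stop_start)
  p <- position_frequencies(ctx)
  idx <- scc_label_to_index(10)
  se3 <- 3 * sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(p["A", idx] - 0.50), se3)  # 0.25 base + 0.25 excess
  # unplanted i.i.d. positions (past the second stop) keep the composition
  other <- scc_label_to_index(c(7, 14, 17))
  expect_true(all(abs(p[, other] - 0.25) < 3 * sqrt(0.25 * 0.75 / 1000)))
  # low-rate transcripts are left unplanted
  cfg0 <- sim_config(seed = 15, n_transcripts = 400, true_rho = 1e-4,
                     second_stop_distance = 0, planted_bias = bias)
  sim0 <- simulate_transcripts(cfg0)
  expect_false(any(sim0$truth$biased))
  ctx0 <- extract_scc(sim0$transcripts$sequence, sim0$transcripts$stop_start)
  p0 <- position_frequencies(ctx0)
  expect_lt(abs(p0["A", idx] - 0.25), 3 * sqrt(0.25 * 0.75 / 400) + 0.01)
})

test_that("CDS composition follows the stop-free codon model", {
  # codon-wise rejection of the three stop codons tilts in-frame CDS
  # composition away from the raw base frequencies; the oracle enumerates
  # the 61 retained codons
  codons <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                              b2 = c("A", "C", "G", "T"),
                              b3 = c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  keep <- !(codons %in% c("TAA", "TAG", "TGA"))
  expected <- sapply(1:3, function(k) {
    prop.table(table(factor(substr(codons[keep], k, k),
                            levels = c("A", "C", "G", "T"))))
  })
  cfg <- sim_config(seed = 25, n_transcripts = 800, true_rho = 0)
  sim <- simulate_transcripts(cfg)
  ctx <- extract_scc(sim$transcripts$sequence, sim$transcripts$stop_start)
  p <- position_frequencies(ctx)
  se3 <- 3 * sqrt(0.25 * 0.75 / 800)
  for (lab in c(-48, -47, -46, -12, -2, -1)) {
    codon_pos <- lab %% 3 + 1  # -48, -45, ... start a codon
    expect_true(all(abs(p[, scc_label_to_index(lab)] -
                          expected[, codon_pos]) < se3 + 0.01),
                info = paste("position", lab))
  }
})

test_that("read geometry and Poisson coverage match the generative model", {
  cfg <- sim_config(seed = 17, n_transcripts = 1, cds_length_range = c(300, 300),
                    utr3_length_range = c(200, 200), cds_density = 5,
                    true_rho = 0, second_stop_distance = 90)
  sim <- simulate_transcripts(cfg)
  L <- nchar(sim$transcripts$sequence)

  # rho = 0: no read starts between the stops
  reads <- simulate_reads(sim$transcripts, sim$truth, cfg)
  s1 <- sim$transcripts$stop_start
  expect_false(any(reads$start > s1 + 2 & reads$start <= s1 + 2 + 90))
  # every footprint lies inside the transcript, lengths from the mixture
  expect_true(all(reads$start >= 1 & reads$start + reads$length - 1 <= L))
  expect_true(all(reads$length %in% c(28, 29)))

  # total CDS starts over replicates: Poisson with mean density * (len+3)
  totals <- vapply(1:200, function(s) {
    nrow(simulate_reads(sim$transcripts, sim$truth, cfg, seed = 5000 + s))
  }, numeric(1))
  mu <- 5 * 303
  expect_lt(abs(mean(totals) - mu), 3 * sqrt(mu / 200) + 3)
})

test_that("the estimator recovers planted leak rates within 20%", {
  # mid-range rate at moderate depth; the window-edge taper of the coverage
  # profile biases rho_hat upward by a known ~18%, inside the band
  cfg <- sim_config(seed = 19, n_transcripts = 250, cds_density = 20,
                    true_rho = 0.05, second_stop_distance = 90,
                    cds_length_range = c(120, 180),
                    utr3_length_range = c(150, 200))
  sim <- simulate_transcripts(cfg)
  reads <- simulate_reads(sim$transcripts, sim$truth, cfg)
  ev <- detect_scr(sim$transcripts, reads)
  expect_lt(abs(mean(ev$rho, na.rm = TRUE) - 0.05), 0.2 * 0.05)
})

test_that("regression-set generation validates dimensions", {
  expect_error(simulate_regression_set(10, c(-1, 1), rep(0, 4)),
               "length")
  d <- simulate_regression_set(25, c(-1, 1), c(0.01, 1:4 / 100), seed = 2)
  expect_length(d$contexts, 25)
  expect_true(all(nchar(d$contexts) == 70))
})

test_that("benchmark sets are reproducible and carry planted signal", {
  b1 <- simulate_scc_benchmark(seed = 3, n_train = 30, n_test_pos = 20,
                               n_control = 100)
  b2 <- simulate_scc_benchmark(seed = 3, n_train = 30, n_test_pos = 20,
                               n_control = 100)
  expect_identical(b1, b2)
  expect_true(all(b1$train$rates > 0))
  expect_equal(length(b1$test_neg), 50)
  # planted positions show elevated divergence against the control pool
  b <- simulate_scc_benchmark(seed = 4)
  div <- scc_divergence(b$train$contexts, b$control)
  planted <- div$per_position$label %in% b$bias$position
  expect_gt(min(div$per_position$D[planted]),
            max(div$per_position$D[!planted & !is.na(div$per_position$label)]))
})
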