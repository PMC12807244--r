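#' Simulation configuration
#'
#' Parameters of the synthetic transcript / footprint generator. The
#' generator emulates the data regime the detection stage assumes:
#' transcripts with 5'UTR / CDS / 3'UTR structure, an annotated stop codon
#' of chosen identity, an in-frame second stop codon at a controllable
#' distance, Poisson-distributed footprint 5' starts (28-29 nt fragments)
#' at a coding-region density and at `true_rho` times that density in the
#' extension between the two stops, and optional per-position nucleotide
#' biases planted in the stop-codon contexts of high-rate transcripts.
#'
#' @param seed integer RNG seed recorded in the config; the generator
#'   functions use it (identical configs give identical data).
#' @param n_transcripts number of transcripts to generate.
#' @param cds_length_range nt range of the coding sequence (start codon
#'   included, stop codon excluded); lengths are rounded to multiples of 3.
#' @param utr5_length_range,utr3_length_range nt ranges of the UTRs.
#' @param stop_codon `"UGA"`, `"UAA"`, `"UAG"`, or `"mixed"` (uniform draw
#'   per transcript).
#' @param base_composition named probabilities of A, C, G, U/T (sums to 1).
#' @param cds_density mean footprint 5'-start count per nt in the coding
#'   region.
#' @param true_rho ground-truth leak rate; a scalar or a vector recycled
#'   over transcripts (typically 0-0.2).
#' @param second_stop_distance nt from the first nucleotide after the
#'   annotated stop to the first nucleotide of the second stop (a multiple
#'   of 3), or `"random"` for a per-transcript draw.
#' @param footprint_lengths named numeric vector of footprint-length mixture
#'   weights (names are lengths; default equal parts 28 and 29 nt).
#' @param planted_bias `NULL`, or a data.frame with columns `position`
#'   (context label, negative upstream / positive downstream of the stop),
#'   `nucleotide`, and `excess` -- the increase in that nucleotide's
#'   frequency over `base_composition` at that position, applied to
#'   high-rate transcripts.
#' @param bias_rho_min transcripts with `true_rho >= bias_rho_min` receive
#'   the planted biases.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_transcripts = 100L,
                       cds_length_range = c(150L, 300L),
                       utr5_length_range = c(10L, 50L),
                       utr3_length_range = c(150L, 250L),
                       stop_codon = "UGA",
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       cds_density = 10, true_rho = 0.05,
                       second_stop_distance = "random",
                       footprint_lengths = c(`28` = 0.5, `29` = 0.5),
                       planted_bias = NULL, bias_rho_min = 20e-4) {
  names(base_composition) <- normalize_seq(names(base_composition))
  base_composition <- base_composition[NUCLEOTIDES]
  if (anyNA(base_composition) || any(base_composition < 0) ||
      abs(sum(base_composition) - 1) > 1e-9) {
    stop("base_composition must be nonnegative A/C/G/U probabilities summing to 1")
  }
  stopifnot(cds_density >= 0, all(true_rho >= 0),
            stop_codon %in% c(STOP_CODONS_RNA, "mixed"))
  if (is.numeric(second_stop_distance)) {
    if (second_stop_distance < 0 || second_stop_distance %% 3 != 0) {
      stop("second_stop_distance must be a nonnegative multiple of 3")
    }
  } else if (!identical(second_stop_distance, "random")) {
    stop("second_stop_distance must be numeric or \"random\"")
  }
  if (!is.null(planted_bias)) {
    stopifnot(is.data.frame(planted_bias),
              all(c("position", "nucleotide", "excess") %in%
                    names(planted_bias)))
    scc_label_to_index(planted_bias$position)  # validates window membership
    planted_bias$nucleotide <- normalize_seq(planted_bias$nucleotide)
    stopifnot(all(planted_bias$nucleotide %in% NUCLEOTIDES),
              all(planted_bias$excess >= 0),
              all(planted_bias$excess <=
                    1 - base_composition[planted_bias$nucleotide] + 1e-12))
  }
  stopifnot(all(footprint_lengths >= 0), sum(footprint_lengths) > 0,
            !is.null(names(footprint_lengths)))
  structure(list(
    seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
    cds_length_range = as.integer(cds_length_range),
    utr5_length_range = as.integer(utr5_length_range),
    utr3_length_range = as.integer(utr3_length_range),
    stop_codon = stop_codon, base_composition = base_composition,
    cds_density = cds_density, true_rho = true_rho,
    second_stop_distance = second_stop_distance,
    footprint_lengths = footprint_lengths,
    planted_bias = planted_bias, bias_rho_min = bias_rho_min),
    class = "sim_config")
}

# n random bases from the configured composition
random_bases <- function(n, comp) {
  sample(NUCLEOTIDES, n, replace = TRUE, prob = comp)
}

# n/3 codons with no in-frame stop, as one string
random_orf_codons <- function(n_codons, comp) {
  if (n_codons == 0L) return("")
  draw <- function(k) {
    m <- matrix(random_bases(3L * k, comp), nrow = 3L)
    apply(m, 2, paste, collapse = "")
  }
  codons <- draw(n_codons)
  repeat {
    bad <- which(is_stop_codon(codons))
    if (length(bad) == 0L) break
    codons[bad] <- draw(length(bad))
  }
  paste(codons, collapse = "")
}

#' Generate synthetic transcripts with known ground truth
#'
#' Builds `n_transcripts` transcripts according to a [sim_config()]: the CDS
#' is drawn codon-wise with in-frame stops rejected (a valid ORF by
#' construction), the annotated stop codon has the requested identity, the
#' 3'UTR carries a second in-frame stop at the configured distance (codons
#' before it are stop-free), and context biases are planted in transcripts
#' whose true leak rate reaches `bias_rho_min`. A planted bias with excess
#' `e` raises the nucleotide's frequency at that position from its base
#' value `p` to `p + e` (non-target bases are replaced with probability
#' `e / (1 - p)`).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `transcripts` (data.frame: `id`, `sequence`,
#'   `cds_start`, `stop_start`, `stop_codon`; 1-based coordinates) and
#'   `truth` (data.frame: `id`, `rho`, `second_stop_distance`, `biased`).
#' @export
simulate_transcripts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_transcripts
  comp <- config$base_composition
  rho <- rep_len(config$true_rho, n)

  pick <- function(range) {
    if (range[1] == range[2]) range[1] else
      sample(seq.int(range[1], range[2]), 1L)
  }
  ids <- sprintf("TX%05d", seq_len(n))
  sequence <- character(n)
  cds_start <- integer(n)
  stop_start <- integer(n)
  stop_lab <- character(n)
  d_out <- integer(n)
  biased <- rho >= config$bias_rho_min & !is.null(config$planted_bias)

  for (i in seq_len(n)) {
    utr5 <- pick(config$utr5_length_range)
    cds_len <- pick(config$cds_length_range)
    cds_len <- max(3L, (cds_len %/% 3L) * 3L)
    utr3 <- pick(config$utr3_length_range)
    stop_lab[i] <- if (config$stop_codon == "mixed") {
      sample(STOP_CODONS_RNA, 1L)
    } else config$stop_codon

    d <- config$second_stop_distance
    if (identical(d, "random")) {
      dmax <- utr3 - 33L
      if (dmax < 18L) stop("utr3_length_range too short for a second stop")
      d <- 3L * sample(seq.int(6L, dmax %/% 3L), 1L)
    }
    d <- as.integer(d)
    if (d + 3L > utr3) {
      stop(sprintf("second_stop_distance %d does not fit in a %d-nt 3'UTR",
                   d, utr3))
    }
    d_out[i] <- d

    cds <- paste0("ATG", random_orf_codons(cds_len %/% 3L - 1L, comp))
    second_stop <- sample(STOP_CODONS_DNA, 1L)
    utr3_seq <- paste0(random_orf_codons(d %/% 3L, comp), second_stop,
                       paste(random_bases(utr3 - d - 3L, comp),
                             collapse = ""))
    seq_i <- paste0(paste(random_bases(utr5, comp), collapse = ""),
                    cds, codon_to_dna(stop_lab[i]), utr3_seq)
    cds_start[i] <- utr5 + 1L
    stop_start[i] <- utr5 + cds_len + 1L

    if (biased[i]) {
      seq_i <- plant_context_bias(seq_i, stop_start[i], d,
                                  config$planted_bias, comp)
    }
    sequence[i] <- seq_i
  }
  list(
    transcripts = data.frame(id = ids, sequence = sequence,
                             cds_start = cds_start, stop_start = stop_start,
                             stop_codon = stop_lab, stringsAsFactors = FALSE),
    truth = data.frame(id = ids, rho = rho, second_stop_distance = d_out,
                       biased = biased, stringsAsFactors = FALSE))
}

# apply planted per-position biases to one transcript's context and repair
# any accidental in-frame stop codons this creates in the CDS or extension
plant_context_bias <- function(seq_i, stop_start, d, bias, comp) {
  bases <- seq_chars(seq_i)
  idx <- scc_label_to_index(bias$position)
  pos_tx <- stop_start - 50L + idx  # window index 1 -> stop_start - 49
  forced <- integer(0)
  for (b in seq_len(nrow(bias))) {
    p <- pos_tx[b]
    if (p < 1L || p > length(bases)) next
    # keep the second stop codon intact
    if (p >= stop_start + 3L + d && p <= stop_start + 5L + d) next
    nt <- bias$nucleotide[b]
    p_repl <- bias$excess[b] / (1 - comp[[nt]])
    if (bases[p] != nt && stats::runif(1) < p_repl) bases[p] <- nt
    if (bases[p] == nt) forced <- c(forced, p)
  }
  # repair in-frame stops introduced upstream of the annotated stop or
  # inside the extension, resampling only non-forced bases; only codons
  # touching the context window can be affected
  check_starts <- c(seq.int(stop_start - 51L, stop_start - 3L, by = 3L),
                    if (d >= 3L) seq.int(stop_start + 3L, stop_start + d,
                                         by = 3L))
  check_starts <- check_starts[check_starts >= 1L]
  for (cs in check_starts) {
    guard <- 0L
    while (is_stop_codon(paste(bases[cs:(cs + 2L)], collapse = ""))) {
      free <- setdiff(cs:(cs + 2L), forced)
      if (length(free) == 0L) {
        stop("planted biases force a premature in-frame stop codon")
      }
      bases[free] <- random_bases(length(free), comp)
      guard <- guard + 1L
      if (guard > 1000L) stop("failed to repair planted stop codon")
    }
  }
  paste(bases, collapse = "")
}

#' Generate footprint reads for simulated transcripts
#'
#' Draws a Poisson number of footprint 5' starts at every transcript
#' position: mean `cds_density` within the coding region (stop codon
#' included), `rho * cds_density` in the extension between the annotated and
#' the second stop, and 0 elsewhere. Footprint lengths are drawn from the
#' configured mixture; footprints that would overrun the transcript end are
#' dropped.
#'
#' @param transcripts,truth as returned by [simulate_transcripts()].
#' @param config the [sim_config()] used to generate them.
#' @param seed RNG seed (default derived from `config$seed`).
#' @return data.frame with columns `transcript_id`, `start` (1-based),
#'   `length`.
#' @export
simulate_reads <- function(transcripts, truth, config,
                           seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  lens <- as.integer(names(config$footprint_lengths))
  wts <- config$footprint_lengths / sum(config$footprint_lengths)
  out <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    L <- nchar(tx$sequence)
    rate <- numeric(L)
    rate[tx$cds_start:(tx$stop_start + 2L)] <- config$cds_density
    d <- truth$second_stop_distance[i]
    if (d > 0L) {
      rate[(tx$stop_start + 3L):(tx$stop_start + 2L + d)] <-
        truth$rho[i] * config$cds_density
    }
    counts <- stats::rpois(L, rate)
    starts <- rep.int(seq_len(L), counts)
    if (length(starts) == 0L) next
    rl <- if (length(lens) == 1L) rep.int(lens, length(starts)) else
      sample(lens, length(starts), replace = TRUE, prob = wts)
    keep <- starts + rl - 1L <= L
    out[[i]] <- data.frame(transcript_id = tx$id, start = starts[keep],
                           length = rl[keep], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      length = integer(0)))
  }
  do.call(rbind, out)
}

#' Random stop-codon contexts
#'
#' Draws 70-nt context sequences i.i.d. from a base composition, with the
#' given stop codon at the stop slot.
#'
#' @param n number of contexts.
#' @param stop_codon `"UGA"`, `"UAA"` or `"UAG"`.
#' @param base_composition named A/C/G/U probabilities.
#' @return character vector of 70-nt sequences (DNA alphabet).
#' @export
random_contexts <- function(n, stop_codon = "UGA",
                            base_composition = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25)) {
  names(base_composition) <- normalize_seq(names(base_composition))
  comp <- base_composition[NUCLEOTIDES]
  m <- matrix(random_bases(n * SCC_LEN, comp), nrow = n)
  m[, SCC_STOP_IDX] <- matrix(rep(seq_chars(codon_to_dna(stop_codon)),
                                  each = n), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Generate a regression training set with known coefficients
#'
#' Draws `n` random contexts and computes their rates from the linear model
#' `y = w . v` (bipolar encoding at the given positions) plus Gaussian
#' noise -- a ground-truth training set for validating the fit.
#'
#' @param n number of context/rate pairs.
#' @param positions selected position labels.
#' @param true_w coefficient vector of length `2 * length(positions) + 1`
#'   (intercept first).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed RNG seed.
#' @param stop_codon,base_composition passed to [random_contexts()].
#' @return list with `contexts`, `rates`, and `truth` (list: `w`,
#'   `positions`, `noise_sd`).
#' @export
simulate_regression_set <- function(n, positions, true_w, noise_sd = 0,
                                    seed = 1L, stop_codon = "UGA",
                                    base_composition = c(A = 0.25, C = 0.25,
                                                         G = 0.25, T = 0.25)) {
  if (length(true_w) != 2L * length(positions) + 1L) {
    stop("true_w must have length 2 * length(positions) + 1")
  }
  set.seed(seed)
  contexts <- random_contexts(n, stop_codon, base_composition)
  V <- vapply(contexts, encode_context, positions = positions,
              numeric(length(true_w)), USE.NAMES = FALSE)
  rates <- as.numeric(crossprod(V, true_w)) +
    stats::rnorm(n, 0, noise_sd)
  list(contexts = contexts, rates = rates,
       truth = list(w = true_w, positions = positions, noise_sd = noise_sd))
}

#' Synthetic context benchmark with planted distal signal
#'
#' Builds a readthrough-prediction benchmark emulating the model-comparison
#' experiment: readthrough contexts carry planted nucleotide biases at a
#' mix of proximal and distal positions, and their leak rates follow a
#' linear model aligned with those biases (intercept negative, so
#' unbiased contexts predict no readthrough); non-readthrough contexts are
#' unbiased. Rates are kept strictly positive by rejection, mirroring the
#' fact that observed readthrough events have positive measured rates.
#'
#' @param n_train number of training (context, rate) pairs.
#' @param n_test_pos held-out readthrough contexts for evaluation.
#' @param n_neg non-readthrough contexts in the test set.
#' @param n_control unbiased contexts forming the divergence reference pool.
#' @param seed RNG seed.
#' @param stop_codon stop codon of the benchmark.
#' @param bias data.frame (`position`, `nucleotide`, `excess`) of planted
#'   biases; the default plants signal at the four stop-flanking positions
#'   (-2..-1, +1..+2) and at eight distal positions (-47, -40, -31, -21,
#'   -16, -12, +9, +15), the distal share carrying about half the rate
#'   variance -- the regime in which a flank-only model misses readthrough
#'   determinants.
#' @param a0 true intercept (negative).
#' @param b_scale per-position coefficient scale: the coefficient pair of a
#'   planted position is `b_scale` times the planted nucleotide's code. A
#'   numeric `b` column in `bias` overrides it per position.
#' @param noise_sd rate noise standard deviation.
#' @return list with `train` (contexts, rates), `test_pos`, `test_neg`,
#'   `control`, `bias`, `true_w` description.
#' @export
simulate_scc_benchmark <- function(n_train = 60L, n_test_pos = 300L,
                                   n_neg = 50L, n_control = 500L, seed = 1L,
                                   stop_codon = "UGA",
                                   bias = data.frame(
                                     position = c(-2L, -1L, 1L, 2L,
                                                  -40L, -21L, -12L, 9L,
                                                  -31L, -16L, 15L, -47L),
                                     nucleotide = c("A", "G", "G", "C",
                                                    "C", "G", "A", "C",
                                                    "G", "C", "G", "A"),
                                     excess = 0.5,
                                     b = c(rep(0.017, 4), rep(0.012, 8))),
                                   a0 = -0.155, b_scale = 0.012,
                                   noise_sd = 0.005) {
  set.seed(seed)
  bias$nucleotide <- normalize_seq(bias$nucleotide)
  if (is.null(bias$b)) bias$b <- b_scale
  comp <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  n_pos_total <- n_train + n_test_pos

  plant <- function(ctx) {
    idx <- scc_label_to_index(bias$position)
    for (b in seq_len(nrow(bias))) {
      nt <- bias$nucleotide[b]
      p_repl <- bias$excess[b] / (1 - comp[[nt]])
      hit <- stats::runif(length(ctx)) < p_repl
      substr(ctx[hit], idx[b], idx[b]) <- nt
    }
    ctx
  }
  rate_of <- function(ctx) {
    contrib <- a0
    idx <- scc_label_to_index(bias$position)
    for (b in seq_len(nrow(bias))) {
      code_b <- NUC_CODE[bias$nucleotide[b], ]
      obs <- substring(ctx, idx[b], idx[b])
      contrib <- contrib +
        bias$b[b] * (NUC_CODE[obs, 1] * code_b[1] + NUC_CODE[obs, 2] * code_b[2])
    }
    contrib + stats::rnorm(length(ctx), 0, noise_sd)
  }

  pos_ctx <- character(0)
  pos_rate <- numeric(0)
  guard <- 0L
  while (length(pos_ctx) < n_pos_total) {
    ctx <- plant(random_contexts(2L * n_pos_total, stop_codon, comp))
    y <- rate_of(ctx)
    keep <- y > 0
    pos_ctx <- c(pos_ctx, ctx[keep])
    pos_rate <- c(pos_rate, y[keep])
    guard <- guard + 1L
    if (guard > 100L) stop("benchmark rejection sampling failed to converge")
  }
  pos_ctx <- pos_ctx[seq_len(n_pos_total)]
  pos_rate <- pos_rate[seq_len(n_pos_total)]

  list(
    train = list(contexts = pos_ctx[seq_len(n_train)],
                 rates = pos_rate[seq_len(n_train)]),
    test_pos = pos_ctx[n_train + seq_len(n_test_pos)],
    test_neg = random_contexts(n_neg, stop_codon, comp),
    control = random_contexts(n_control, stop_codon, comp),
    bias = bias,
    truth = list(a0 = a0, b_scale = b_scale, noise_sd = noise_sd))
}
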