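#' Extract the 70-nt stop-codon context
#'
#' The stop-codon context (SCC) spans 49 nt upstream of the stop codon, the
#' 3 stop-codon nt, and 18 nt downstream -- 70 nt in total. Transcripts
#' lacking either flank are skipped (`NA`), not errors.
#'
#' @param sequence transcript sequence(s); normalised to A/C/G/T.
#' @param stop_start 1-based position(s) of the first stop-codon nucleotide.
#' @return character vector of 70-nt context strings, `NA` where a flank is
#'   too short.
#' @examples
#' extract_scc(strrep("A", 100), 50)
#' @export
extract_scc <- function(sequence, stop_start) {
  s <- normalize_seq(sequence)
  stop_start <- as.integer(stop_start)
  from <- stop_start - SCC_UP
  to <- stop_start + 2L + SCC_DOWN
  ok <- from >= 1L & to <= nchar(s)
  out <- rep(NA_character_, length(s))
  out[ok] <- substr(s[ok], from[ok], to[ok])
  out
}

# contexts (equal-length strings) -> n x W character matrix
context_matrix <- function(contexts) {
  contexts <- contexts[!is.na(contexts)]
  if (length(contexts) == 0L) stop("no contexts supplied")
  w <- unique(nchar(contexts))
  if (length(w) != 1L) stop("contexts differ in length")
  m <- matrix(unlist(strsplit(normalize_seq(contexts), "", fixed = TRUE)),
              nrow = length(contexts), ncol = w, byrow = TRUE)
  bad <- !(m %in% NUCLEOTIDES)
  if (any(bad)) stop("non-ACGU/T symbol in context sequences")
  m
}

#' Per-position nucleotide counts and frequencies
#'
#' `scc_counts()` tabulates nucleotide occurrences per context position;
#' `position_frequencies()` normalises each column to sum to 1.
#'
#' @param contexts character vector of equal-length context sequences
#'   (`NA` entries dropped).
#' @param pseudocount value added to every cell of the count table before
#'   normalising (0 disables; 0.5 is the Jeffreys choice used by the
#'   divergence functions).
#' @return a 4 x width numeric matrix with rows A, C, G, T (U and T are
#'   equivalent on input); `position_frequencies()` columns each sum to 1.
#' @export
scc_counts <- function(contexts) {
  m <- context_matrix(contexts)
  out <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(factor(m[, j], levels = NUCLEOTIDES), nbins = 4L)
  }, integer(4))
  rownames(out) <- NUCLEOTIDES
  out
}

#' @rdname scc_counts
#' @export
position_frequencies <- function(contexts, pseudocount = 0) {
  cn <- scc_counts(contexts) + pseudocount
  sweep(cn, 2, colSums(cn), "/")
}

#' Positional Kullback-Leibler divergence
#'
#' For each position r, `D(r) = sum_i p_i(r) * log(p_i(r) / p*_i(r))` in
#' nats, where `p` is the nucleotide usage of the analysed set and `p*` that
#' of the reference set at the same position. Terms with `p_i(r) = 0`
#' contribute zero; a zero reference frequency against a nonzero set
#' frequency yields `Inf`, which is what the pseudocount in
#' [scc_divergence()] prevents.
#'
#' @param p_set,p_ref column-stochastic 4 x width frequency tables (as from
#'   [position_frequencies()]) of equal width.
#' @return numeric vector of per-position divergences (nats), one per column.
#' @export
kl_divergence_profile <- function(p_set, p_ref) {
  stopifnot(is.matrix(p_set), is.matrix(p_ref),
            all(dim(p_set) == dim(p_ref)))
  if (max(abs(colSums(p_set) - 1)) > 1e-6 ||
      max(abs(colSums(p_ref) - 1)) > 1e-6) {
    stop("frequency tables must be column-stochastic")
  }
  term <- ifelse(p_set > 0, p_set * log(p_set / p_ref), 0)
  colSums(term)
}

#' Pairwise positional divergence (mutual information)
#'
#' For positions r and s, `D(r, s) = sum_ij p_ij log(p_ij / (p_i p_j))` --
#' the mutual information (nats) between the nucleotides at the two
#' positions across the context set. It is computed for every unordered
#' pair of non-stop positions (67 positions in the 70-nt window give 2211
#' pairs). Empirical joint frequencies keep the estimate finite without any
#' pseudocount.
#'
#' @param contexts character vector of 70-nt context sequences.
#' @param positions integer vector of window indices to pair up; defaults to
#'   all non-stop positions.
#' @return data.frame with columns `r`, `s` (position labels, `r` 5' of
#'   `s`), `index_r`, `index_s` (window indices) and `D` (nats).
#' @export
pairwise_divergence <- function(contexts, positions = NULL) {
  m <- context_matrix(contexts)
  if (nrow(m) < 2L) stop("need at least 2 contexts")
  if (is.null(positions)) {
    positions <- setdiff(seq_len(ncol(m)), SCC_STOP_IDX)
  }
  codes <- matrix(match(m, NUCLEOTIDES), nrow = nrow(m))
  n <- nrow(m)
  np <- length(positions)
  pairs <- utils::combn(np, 2L)
  D <- numeric(ncol(pairs))
  marg <- lapply(positions, function(j) tabulate(codes[, j], nbins = 4L) / n)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    joint <- tabulate((codes[, positions[a]] - 1L) * 4L + codes[, positions[b]],
                      nbins = 16L) / n
    # joint is laid out with the second position varying fastest
    pm <- as.vector(outer(marg[[b]], marg[[a]]))
    nz <- joint > 0
    D[k] <- sum(joint[nz] * log(joint[nz] / pm[nz]))
  }
  ir <- positions[pairs[1L, ]]
  is <- positions[pairs[2L, ]]
  data.frame(r = scc_index_to_label(ir), s = scc_index_to_label(is),
             index_r = ir, index_s = is, D = D)
}

#' Fisher exact test of GC versus AU usage per position
#'
#' At each position, the 2x2 table of (G+C, A+U) occurrences in the analysed
#' set versus the reference set is tested with a two-sided Fisher exact
#' test. Positions where a margin is all zero return p = 1 by convention.
#'
#' @param counts_set,counts_ref 4 x width count matrices (rows A, C, G, T;
#'   from [scc_counts()]).
#' @return numeric vector of two-sided p-values, one per position.
#' @export
fisher_gc_au <- function(counts_set, counts_ref) {
  stopifnot(all(dim(counts_set) == dim(counts_ref)))
  gc <- c("C", "G")
  au <- c("A", "T")
  vapply(seq_len(ncol(counts_set)), function(j) {
    tab <- matrix(c(sum(counts_set[gc, j]), sum(counts_set[au, j]),
                    sum(counts_ref[gc, j]), sum(counts_ref[au, j])),
                  nrow = 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
}

#' Full divergence profile of a context set against a reference
#'
#' Convenience wrapper combining [position_frequencies()] (with a Jeffreys
#' add-1/2 pseudocount so divergences stay finite), [kl_divergence_profile()],
#' [fisher_gc_au()] and optionally [pairwise_divergence()].
#'
#' @param contexts_set,contexts_ref character vectors of 70-nt contexts
#'   (analysed set and reference/control set).
#' @param pseudocount per-cell pseudocount applied before the single-position
#'   divergence (0 disables).
#' @param pairwise also compute the pairwise divergence table of
#'   `contexts_set` (slower).
#' @param p_adjust_method optional multiple-testing correction for the
#'   Fisher p-values (a `stats::p.adjust` method, e.g. `"BH"`); default
#'   `"none"` reports raw p-values.
#' @return list with elements `per_position` (data.frame: `index`, `label`,
#'   `D`, `fisher_p`), and `pairs` (from [pairwise_divergence()], or `NULL`).
#' @export
scc_divergence <- function(contexts_set, contexts_ref, pseudocount = 0.5,
                           pairwise = FALSE, p_adjust_method = "none") {
  p_set <- position_frequencies(contexts_set, pseudocount)
  p_ref <- position_frequencies(contexts_ref, pseudocount)
  D <- kl_divergence_profile(p_set, p_ref)
  p <- fisher_gc_au(scc_counts(contexts_set), scc_counts(contexts_ref))
  if (p_adjust_method != "none") p <- stats::p.adjust(p, p_adjust_method)
  per_position <- data.frame(index = seq_len(ncol(p_set)),
                             label = scc_index_to_label(seq_len(ncol(p_set))),
                             D = D, fisher_p = p)
  pairs <- if (pairwise) pairwise_divergence(contexts_set) else NULL
  list(per_position = per_position, pairs = pairs)
}

#' GC3 profile along the coding sequence
#'
#' Fraction of transcripts carrying G or C at the third nucleotide of each
#' codon, with codons aligned either at the start of the CDS (codon 1 = the
#' initiator) or at its end (codon -1 = the last coding codon). The stop
#' codon is not part of the profile.
#'
#' @param transcripts transcript table (`id`, `sequence`, `cds_start`,
#'   `stop_start` columns).
#' @param align `"start"` or `"end"`.
#' @param n_codons number of codon positions to report.
#' @return data.frame with columns `codon` (index; negative when aligned at
#'   the end), `gc3` (fraction in \[0, 1\]) and `n` (transcripts contributing
#'   to that index).
#' @export
gc3_profile <- function(transcripts, align = c("start", "end"),
                        n_codons = 30L) {
  align <- match.arg(align)
  n_codons <- as.integer(n_codons)
  seqs <- normalize_seq(transcripts$sequence)
  cds_len <- transcripts$stop_start - transcripts$cds_start  # coding, excl. stop
  stopifnot(all(cds_len %% 3L == 0L), all(cds_len >= 3L))
  n_cod_tx <- cds_len %/% 3L
  gc_hits <- matrix(NA, nrow = nrow(transcripts), ncol = n_codons)
  for (i in seq_len(nrow(transcripts))) {
    k <- min(n_cod_tx[i], n_codons)
    idx <- seq_len(k)
    third <- if (align == "start") {
      transcripts$cds_start[i] + idx * 3L - 1L
    } else {
      transcripts$stop_start[i] - (idx - 1L) * 3L - 1L
    }
    bases <- substring(seqs[i], third, third)
    gc_hits[i, idx] <- bases %in% c("G", "C")
  }
  gc3 <- colMeans(gc_hits, na.rm = TRUE)
  n <- colSums(!is.na(gc_hits))
  codon <- if (align == "start") seq_len(n_codons) else -seq_len(n_codons)
  data.frame(codon = codon, gc3 = gc3, n = n)
}

#' Leak-rate distributions stratified by stop-adjacent nucleotides
#'
#' Bins the leak rates of events by the identity of the nucleotide
#' immediately upstream (-1) and downstream (+1) of the stop codon,
#' separately per stop codon -- the per-nucleotide rate histograms of the
#' adjacent-position analysis.
#'
#' @param events an `scr_events` table (rows with `NA` rates are dropped).
#' @param transcripts the matching transcript table.
#' @param breaks numeric vector of bin breaks for the rates (closed on the
#'   left, right-open; the last bin is catch-all when it ends in `Inf`).
#' @return data.frame with columns `stop_codon`, `side` (`"-1"`/`"+1"`),
#'   `nucleotide` (RNA alphabet), `bin` (label), and `count`.
#' @export
stratify_by_adjacent <- function(events, transcripts,
                                 breaks = c(0, 5e-4, 2e-3, 5e-3, 1e-2,
                                            2e-2, 5e-2, 0.1, Inf)) {
  keep <- !is.na(events$rho)
  ev <- events[keep, , drop = FALSE]
  tx <- transcripts[match(ev$transcript_id, transcripts$id), , drop = FALSE]
  seqs <- normalize_seq(tx$sequence)
  nt_up <- substring(seqs, tx$stop_start - 1L, tx$stop_start - 1L)
  nt_dn <- substring(seqs, tx$stop_start + 3L, tx$stop_start + 3L)
  bin <- cut(ev$rho, breaks = breaks, right = FALSE, include.lowest = TRUE)
  long <- rbind(
    data.frame(stop_codon = ev$stop_codon, side = "-1",
               nucleotide = codon_to_rna(nt_up), bin = bin),
    data.frame(stop_codon = ev$stop_codon, side = "+1",
               nucleotide = codon_to_rna(nt_dn), bin = bin))
  out <- as.data.frame(table(stop_codon = long$stop_codon, side = long$side,
                             nucleotide = factor(long$nucleotide,
                                                 levels = c("A", "C", "G", "U")),
                             bin = long$bin), responseName = "count")
  out
}
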