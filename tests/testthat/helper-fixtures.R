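# fixture builders shared across test files; everything is generated in code

# assemble a transcript data.frame row from explicit parts; `cds` excludes
# the stop codon and must start with ATG for realism (not enforced)
make_transcript <- function(id = "tx1", utr5 = "AAAA", cds = "ATGGCTGCT",
                            stop = "TGA", utr3 = strrep("C", 80)) {
  seq <- paste0(utr5, cds, stop, utr3)
  data.frame(id = id, sequence = seq,
             cds_start = nchar(utr5) + 1L,
             stop_start = nchar(utr5) + nchar(cds) + 1L,
             stop_codon = codon_to_rna(stop),
             stringsAsFactors = FALSE)
}

# independent per-position coverage oracle: count reads overlapping p
coverage_oracle <- function(reads, len) {
  vapply(seq_len(len), function(p) {
    sum(reads$start <= p & reads$start + reads$length - 1L >= p)
  }, numeric(1))
}

# brute-force KL divergence, term by term
kl_oracle <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  s
}

# mutual information of a joint table via the entropy decomposition
# I(X;Y) = H(X) + H(Y) - H(X,Y)
mi_oracle <- function(joint) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  H(rowSums(joint)) + H(colSums(joint)) - H(as.vector(joint))
}

# two-sided Fisher exact p-value by hypergeometric enumeration
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# uniform random 70-nt contexts with a fixed stop codon (local, simple)
uniform_contexts <- function(n, stop = "TGA") {
  sapply(seq_len(n), function(i) {
    x <- sample(c("A", "C", "G", "T"), 70, replace = TRUE)
    x[50:52] <- strsplit(stop, "")[[1]]
    paste(x, collapse = "")
  })
}
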