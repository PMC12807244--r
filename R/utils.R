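#' @keywords internal
"_PACKAGE"

# Stop codons in the two alphabets. All internal sequence handling is in the
# DNA alphabet (A/C/G/T, uppercase); stop codons are reported with the RNA
# labels customary in the translation-termination literature (UAA/UAG/UGA).
STOP_CODONS_DNA <- c("TAA", "TAG", "TGA")
STOP_CODONS_RNA <- c("UAA", "UAG", "UGA")
NUCLEOTIDES <- c("A", "C", "G", "T")

# Stop-codon context geometry: 49 nt upstream, the 3 stop-codon nt, 18 nt
# downstream -- 70 positions, stop codon at indices 50..52 (1-based).
SCC_UP <- 49L
SCC_DOWN <- 18L
SCC_LEN <- 70L
SCC_STOP_IDX <- 50:52

#' Normalise a nucleotide sequence to the internal alphabet
#'
#' Uppercases and converts U to T, so RNA- and DNA-alphabet input (in any
#' case) are treated identically.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over A/C/G/T (other symbols are left as-is and
#'   caught by downstream validation).
#' @examples
#' normalize_seq(c("augcu", "ATGCT"))
#' @export
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Convert between RNA and DNA stop-codon labels
#'
#' @param codon character vector of 3-nt codons in either alphabet.
#' @return `codon_to_rna()` returns U-containing labels (as used in reports);
#'   `codon_to_dna()` returns T-containing codons (as stored in sequences).
#' @examples
#' codon_to_rna("TGA")
#' codon_to_dna("UGA")
#' @export
codon_to_rna <- function(codon) chartr("T", "U", toupper(codon))

#' @rdname codon_to_rna
#' @export
codon_to_dna <- function(codon) normalize_seq(codon)

is_stop_codon <- function(codon) normalize_seq(codon) %in% STOP_CODONS_DNA

#' Map stop-codon context position labels to window indices
#'
#' Context positions are labelled relative to the stop codon: -49..-1
#' upstream, +1..+18 downstream; the three stop-codon slots carry no label
#' (they are constant within a per-codon analysis). Internally the 70-nt
#' window is indexed 1..70 with the stop codon at 50..52.
#'
#' @param label integer vector of position labels (negative upstream,
#'   positive downstream; 0 is invalid).
#' @param index integer vector of window indices in 1..70.
#' @return `scc_label_to_index()` returns window indices; `scc_index_to_label()`
#'   returns labels, with `NA` for the three stop-codon indices.
#' @examples
#' scc_label_to_index(c(-49, -1, 1, 18))
#' scc_index_to_label(c(1, 49, 50, 53, 70))
#' @export
scc_label_to_index <- function(label) {
  label <- as.integer(label)
  bad <- label == 0L | label < -SCC_UP | label > SCC_DOWN
  if (any(bad, na.rm = TRUE)) {
    stop("invalid context position label(s): ",
         paste(label[bad], collapse = ", "))
  }
  ifelse(label < 0L, label + SCC_UP + 1L, label + SCC_UP + 3L)
}

#' @rdname scc_label_to_index
#' @export
scc_index_to_label <- function(index) {
  index <- as.integer(index)
  if (any(index < 1L | index > SCC_LEN, na.rm = TRUE)) {
    stop("context window index out of 1..70")
  }
  out <- ifelse(index < SCC_STOP_IDX[1], index - SCC_UP - 1L,
         ifelse(index > SCC_STOP_IDX[3], index - SCC_UP - 3L, NA_integer_))
  out
}

#' Labels of the non-stop context positions in 5' to 3' order
#'
#' @return integer vector of the 67 informative position labels
#'   (-49..-1, +1..+18).
#' @export
scc_position_labels <- function() {
  c(-(SCC_UP:1), seq_len(SCC_DOWN))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
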