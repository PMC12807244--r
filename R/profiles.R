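#' Build a per-nucleotide ribosome density profile
#'
#' The density profile of a transcript is the total number of ribosome
#' protected footprint fragments covering each nucleotide position: a read
#' with 1-based start `s` and length `l` contributes one count to every
#' position in `[s, s + l - 1]`.
#'
#' @param reads data.frame with columns `start` (1-based 5' end) and
#'   `length` (nt), one row per footprint; rows for other transcripts should
#'   be filtered out beforehand. A `transcript_id` column, if present, must
#'   be constant.
#' @param transcript_length transcript length in nt.
#' @return integer vector of length `transcript_length`; element `p` is the
#'   number of footprints overlapping position `p`.
#' @examples
#' build_density_profile(data.frame(start = 11, length = 28), 100)
#' @export
build_density_profile <- function(reads, transcript_length) {
  transcript_length <- as.integer(transcript_length)
  stopifnot(transcript_length >= 1L)
  if (!is.null(reads$transcript_id) && nrow(reads) > 0 &&
      length(unique(reads$transcript_id)) > 1L) {
    stop("reads span multiple transcripts; profile one transcript at a time")
  }
  counts <- integer(transcript_length)
  if (is.null(reads) || nrow(reads) == 0L) {
    return(counts)
  }
  start <- as.integer(reads$start)
  len <- as.integer(reads$length)
  bad <- which(start < 1L | len < 1L | start + len - 1L > transcript_length)
  if (length(bad) > 0L) {
    stop(sprintf(
      "read %d (start=%d, length=%d) outside transcript of length %d",
      bad[1], start[bad[1]], len[bad[1]], transcript_length))
  }
  # difference-array coverage accumulation
  delta <- integer(transcript_length + 1L)
  add <- tabulate(start, nbins = transcript_length + 1L)
  rem <- tabulate(start + len, nbins = transcript_length + 1L)
  delta <- add - rem
  counts <- cumsum(delta)[seq_len(transcript_length)]
  as.integer(counts)
}

#' Ribosomal P-site and A-site positions of a footprint
#'
#' The P-site of the ribosome sits at the 13th nucleotide of the protected
#' fragment; the A-site -- where stop-codon decoding happens -- is one codon
#' downstream.
#'
#' @param start 1-based transcript position of the footprint 5' end.
#' @param length footprint length in nt (must be at least 13 for the P-site,
#'   16 for the A-site, to lie within the fragment).
#' @return 1-based transcript position of the first nucleotide of the site.
#' @examples
#' psite_position(1, 28)  # 13
#' asite_position(1, 28)  # 16
#' @export
psite_position <- function(start, length) {
  start <- as.integer(start)
  length <- as.integer(length)
  if (any(length < 13L)) {
    stop("footprint shorter than 13 nt has no defined P-site")
  }
  start + 12L
}

#' @rdname psite_position
#' @export
asite_position <- function(start, length) {
  if (any(as.integer(length) < 16L)) {
    stop("footprint shorter than 16 nt has no defined A-site")
  }
  psite_position(start, length) + 3L
}

#' Write a density profile as bedGraph-style TSV
#'
#' Runs of equal coverage are collapsed into intervals; coordinates are
#' written 0-based half-open, matching the bedGraph convention.
#'
#' @param counts integer coverage vector (as from [build_density_profile()]).
#' @param transcript_id transcript identifier for the first column.
#' @param path output file path.
#' @return the output path, invisibly.
#' @export
write_profile_bedgraph <- function(counts, transcript_id, path) {
  r <- rle(as.integer(counts))
  end <- cumsum(r$lengths)
  start0 <- c(0L, end[-length(end)])
  df <- data.frame(transcript_id = transcript_id, start = start0,
                   end = end, count = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
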