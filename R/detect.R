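#' Detection configuration
#'
#' Collects every threshold and window of the readthrough-detection stage.
#' Defaults follow the published analysis: the coding-side window spans the
#' 14 nt preceding the stop codon plus the 16 nt following it (30 positions,
#' the 3 stop-codon nt excluded); the extension window spans downstream
#' offsets +29..+58 (counted from the first nucleotide after the stop
#' codon); candidate events need footprint coverage of at least 90% of the
#' extended region, at least 2 supporting reads, a leak rate above 0.005 and
#' a next in-frame stop at least 18 nt away. Rate-set thresholds are
#' 3e-4 (TS1) and 20e-4 (TS2).
#'
#' @param cd_upstream,cd_downstream nt of the coding-side window before and
#'   after the stop codon.
#' @param ext_from,ext_to downstream offset range of the extension window
#'   (1-based, +1 = first nt after the stop codon), ends inclusive.
#' @param coverage_min minimum covered fraction of the extended region.
#' @param min_reads minimum number of footprints overlapping the extended
#'   region.
#' @param per_position if `TRUE`, a position only counts as covered when its
#'   profile count is at least `min_reads` (stricter reading of the support
#'   rule); default counts a position as covered when any footprint spans it.
#' @param rho_min leak-rate threshold for candidate selection (strict `>`).
#' @param next_stop_min minimum distance (nt) to the next in-frame stop.
#' @param ts1,ts2 leak-rate thresholds of the moderate (TS1) and high (TS2)
#'   rate sets (strict `>`); TS2 membership implies TS1 membership.
#' @return a list of class `"scr_config"`.
#' @export
scr_config <- function(cd_upstream = 14L, cd_downstream = 16L,
                       ext_from = 29L, ext_to = 58L,
                       coverage_min = 0.90, min_reads = 2L,
                       per_position = FALSE,
                       rho_min = 0.005, next_stop_min = 18L,
                       ts1 = 3e-4, ts2 = 20e-4) {
  stopifnot(cd_upstream >= 0, cd_downstream >= 0, ext_from >= 1,
            ext_to >= ext_from, coverage_min >= 0, coverage_min <= 1,
            min_reads >= 0, rho_min >= 0, next_stop_min >= 0,
            ts1 >= 0, ts2 >= ts1)
  structure(list(
    cd_upstream = as.integer(cd_upstream),
    cd_downstream = as.integer(cd_downstream),
    ext_from = as.integer(ext_from), ext_to = as.integer(ext_to),
    coverage_min = coverage_min, min_reads = as.integer(min_reads),
    per_position = isTRUE(per_position),
    rho_min = rho_min, next_stop_min = as.integer(next_stop_min),
    ts1 = ts1, ts2 = ts2), class = "scr_config")
}

#' Window positions used by the leak-rate estimator
#'
#' `delta_cd_window()` returns the transcript positions of the coding-side
#' window (14 nt before the stop codon and 16 nt after it by default; the
#' stop codon itself is excluded). `delta_ext_window()` returns the
#' positions of the extension window (+29..+58 downstream of the stop codon
#' by default). The two windows are disjoint: offsets +17..+28 form a gap
#' that absorbs footprints from terminating ribosomes.
#'
#' @param stop_start 1-based position of the first stop-codon nucleotide.
#' @param config an [scr_config()].
#' @return integer vector of 1-based transcript positions.
#' @examples
#' length(delta_cd_window(100))   # 30
#' length(delta_ext_window(100))  # 30
#' intersect(delta_cd_window(100), delta_ext_window(100))  # empty
#' @export
delta_cd_window <- function(stop_start, config = scr_config()) {
  s <- as.integer(stop_start)
  c(seq.int(s - config$cd_upstream, length.out = config$cd_upstream),
    seq.int(s + 3L, length.out = config$cd_downstream))
}

#' @rdname delta_cd_window
#' @export
delta_ext_window <- function(stop_start, config = scr_config()) {
  s <- as.integer(stop_start)
  seq.int(s + 2L + config$ext_from, s + 2L + config$ext_to)
}

#' Cumulative densities of the leak-rate estimator
#'
#' `compute_delta_cd()` sums the density profile over the coding-side window;
#' `compute_delta_ext()` sums it over the extension window. The leak rate is
#' their ratio, `compute_scr_rate()`.
#'
#' @param counts integer density profile (from [build_density_profile()]).
#' @param stop_start 1-based position of the first stop-codon nucleotide.
#' @param config an [scr_config()].
#' @return cumulative footprint density (a count) over the window.
#' @export
compute_delta_cd <- function(counts, stop_start, config = scr_config()) {
  w <- delta_cd_window(stop_start, config)
  if (min(w) < 1L || max(w) > length(counts)) {
    stop("coding-side window outside transcript bounds")
  }
  sum(counts[w])
}

#' @rdname compute_delta_cd
#' @export
compute_delta_ext <- function(counts, stop_start, config = scr_config()) {
  w <- delta_ext_window(stop_start, config)
  if (min(w) < 1L || max(w) > length(counts)) {
    stop("extension window outside transcript bounds")
  }
  sum(counts[w])
}

#' @param delta_cd,delta_ext cumulative densities of the two windows.
#' @return `compute_scr_rate()` returns `delta_ext / delta_cd`, or `NA` when
#'   `delta_cd` is zero (the rate is then undefined and the event rejected).
#' @rdname compute_delta_cd
#' @export
compute_scr_rate <- function(delta_cd, delta_ext) {
  ifelse(delta_cd > 0, delta_ext / delta_cd, NA_real_)
}

#' Distance to the next in-frame stop codon
#'
#' Scans the transcript downstream of the annotated stop codon, codon by
#' codon in the reading frame, for the next stop codon. The distance is
#' measured from the first nucleotide after the annotated stop codon to the
#' first nucleotide of the next stop, so an immediately adjacent stop codon
#' has distance 0.
#'
#' @param sequence transcript sequence (any alphabet; normalised internally).
#' @param stop_start 1-based position of the first annotated stop-codon nt.
#' @return distance in nt (a nonnegative multiple of 3), or `NA_integer_`
#'   when no downstream in-frame stop exists before the transcript end.
#' @examples
#' find_next_inframe_stop("ATGAAATAAAAATGACC", 7)  # 6
#' @export
find_next_inframe_stop <- function(sequence, stop_start) {
  s <- normalize_seq(sequence)
  n <- nchar(s)
  pos <- as.integer(stop_start) + 3L
  while (pos + 2L <= n) {
    if (is_stop_codon(substr(s, pos, pos + 2L))) {
      return(pos - (as.integer(stop_start) + 3L))
    }
    pos <- pos + 3L
  }
  NA_integer_
}

#' Assign leak-rate set labels
#'
#' Transcripts with no extension signal (`rho` = 0) form the control pool
#' TS0; those with `rho` above the TS2 threshold are labelled TS2, above the
#' TS1 threshold TS1; every TS2 member is by construction also a TS1 member
#' (use `rho > config$ts1` for TS1 membership including TS2). Rates between
#' zero and the TS1 threshold are labelled `"candidate-excluded"`.
#'
#' @param rho numeric vector of leak rates (`NA` allowed).
#' @param config an [scr_config()] holding the `ts1`/`ts2` thresholds.
#' @return character vector of labels among
#'   `"TS0"`, `"TS1"`, `"TS2"`, `"candidate-excluded"`.
#' @export
label_rate_sets <- function(rho, config = scr_config()) {
  ifelse(is.na(rho), "candidate-excluded",
  ifelse(rho == 0, "TS0",
  ifelse(rho > config$ts2, "TS2",
  ifelse(rho > config$ts1, "TS1", "candidate-excluded"))))
}

# filter evaluation for one event; returns list(pass, reasons)
scr_filter_reasons <- function(rho, coverage_fraction, read_count,
                               next_stop_distance, config) {
  reasons <- character(0)
  if (is.na(next_stop_distance)) {
    reasons <- c(reasons, "no-downstream-stop")
  } else if (next_stop_distance < config$next_stop_min) {
    reasons <- c(reasons, "next-stop distance")
  }
  if (is.na(coverage_fraction) || coverage_fraction < config$coverage_min) {
    reasons <- c(reasons, "coverage")
  }
  if (read_count < config$min_reads) {
    reasons <- c(reasons, "read-support")
  }
  if (is.na(rho)) {
    reasons <- c(reasons, "undefined-rate")
  } else if (rho <= config$rho_min) {
    reasons <- c(reasons, "rate")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Detect stop codon readthrough events
#'
#' Runs the full per-transcript estimation: builds the density profile,
#' computes the cumulative densities of the coding-side and extension
#' windows, the leak rate, the next in-frame stop distance and the coverage
#' of the extended region (annotated stop to next in-frame stop), applies
#' the selection filters and assigns rate-set labels.
#'
#' @param transcripts a transcript table (see [read_transcripts()] or
#'   [simulate_transcripts()]): columns `id`, `sequence`, `cds_start`,
#'   `stop_start`, `stop_codon`.
#' @param reads footprint table with columns `transcript_id`, `start`
#'   (1-based), `length`.
#' @param config an [scr_config()].
#' @return data.frame of class `"scr_events"`, one row per transcript, with
#'   columns `transcript_id`, `stop_codon`, `delta_cd`, `delta_ext`, `rho`,
#'   `next_stop_distance`, `coverage_fraction`, `read_count`,
#'   `passes_filters`, `filter_reasons`, `set_label`.
#' @export
detect_scr <- function(transcripts, reads, config = scr_config()) {
  stopifnot(is.data.frame(transcripts), is.data.frame(reads))
  reads_by_tx <- split(reads[c("start", "length")],
                       factor(reads$transcript_id, levels = transcripts$id))
  n <- nrow(transcripts)
  out <- data.frame(
    transcript_id = transcripts$id,
    stop_codon = transcripts$stop_codon,
    delta_cd = NA_real_, delta_ext = NA_real_, rho = NA_real_,
    next_stop_distance = NA_integer_, coverage_fraction = NA_real_,
    read_count = NA_integer_, passes_filters = FALSE,
    filter_reasons = NA_character_, set_label = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tx <- transcripts[i, ]
    len <- nchar(tx$sequence)
    r <- reads_by_tx[[i]]
    counts <- build_density_profile(r, len)
    s1 <- tx$stop_start
    d <- find_next_inframe_stop(tx$sequence, s1)
    out$next_stop_distance[i] <- d

    dcd <- tryCatch(compute_delta_cd(counts, s1, config), error = function(e) NA_real_)
    dext <- tryCatch(compute_delta_ext(counts, s1, config), error = function(e) NA_real_)
    out$delta_cd[i] <- dcd
    out$delta_ext[i] <- dext
    rho <- if (is.na(dcd) || is.na(dext)) NA_real_ else compute_scr_rate(dcd, dext)
    out$rho[i] <- rho

    # extended region: nucleotide after the annotated stop up to the
    # nucleotide before the next in-frame stop
    if (!is.na(d) && d > 0L) {
      region <- seq.int(s1 + 3L, s1 + 2L + d)
      min_depth <- if (config$per_position) config$min_reads else 1L
      out$coverage_fraction[i] <- mean(counts[region] >= min_depth)
      out$read_count[i] <- sum(r$start <= region[length(region)] &
                               r$start + r$length - 1L >= region[1])
    } else {
      out$coverage_fraction[i] <- NA_real_
      out$read_count[i] <- 0L
    }

    f <- scr_filter_reasons(rho, out$coverage_fraction[i], out$read_count[i],
                            d, config)
    out$passes_filters[i] <- f$pass
    out$filter_reasons[i] <- paste(f$reasons, collapse = ";")

    out$set_label[i] <- if (!is.na(rho) && (rho == 0 || dext == 0)) {
      "TS0"
    } else if (!f$pass) {
      "candidate-excluded"
    } else {
      label_rate_sets(rho, config)
    }
  }
  class(out) <- c("scr_events", "data.frame")
  out
}

#' @export
print.scr_events <- function(x, ...) {
  cat(sprintf("SCR event table: %d transcripts, %d passing filters\n",
              nrow(x), sum(x$passes_filters)))
  tab <- table(factor(x$set_label, levels = c("TS0", "TS1", "TS2",
                                              "candidate-excluded")))
  cat("  set labels: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  NextMethod()
}
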