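#' Read transcripts from FASTA plus a CDS annotation table
#'
#' The annotation TSV has columns `transcript_id`, `cds_start`,
#' `stop_codon_start` (both 0-based), and `stop_codon` (RNA or DNA
#' alphabet). Sequences are normalised to uppercase A/C/G/T; every record is
#' validated: the annotation must reference a FASTA sequence, the reading
#' frame from `cds_start` to the stop must be intact (length a multiple of
#' 3), and the sequence at the stop position must match the annotated codon.
#'
#' @param fasta path to the transcript FASTA file.
#' @param annotation path to the annotation TSV.
#' @return transcript data.frame (`id`, `sequence`, `cds_start`,
#'   `stop_start` -- 1-based -- and `stop_codon` as an RNA label).
#' @export
read_transcripts <- function(fasta, annotation) {
  # read without alphabet coercion: RNA (U) and lowercase input are
  # normalised here, not silently dropped
  seqs <- Biostrings::readBStringSet(fasta)
  ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "stop_codon_start", "stop_codon")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  ids <- sub("\\s.*", "", names(seqs))
  missing <- setdiff(ann$transcript_id, ids)
  if (length(missing) > 0L) {
    stop("annotation references sequences absent from the FASTA: ",
         paste(missing, collapse = ", "))
  }
  sequence <- normalize_seq(as.character(seqs[match(ann$transcript_id, ids)]))
  out <- data.frame(id = ann$transcript_id, sequence = sequence,
                    cds_start = as.integer(ann$cds_start) + 1L,
                    stop_start = as.integer(ann$stop_codon_start) + 1L,
                    stop_codon = codon_to_rna(ann$stop_codon),
                    stringsAsFactors = FALSE)
  validate_transcripts(out)
  out
}

#' Validate a transcript table
#'
#' Checks the invariants every downstream stage relies on: the annotated
#' codon is a stop codon, the sequence carries it at `stop_start`, and
#' `stop_start - cds_start` is a multiple of 3.
#'
#' @param transcripts transcript data.frame (1-based coordinates).
#' @return the table, invisibly; stops with the offending transcript named.
#' @export
validate_transcripts <- function(transcripts) {
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    if (!(tx$stop_codon %in% STOP_CODONS_RNA)) {
      stop(sprintf("transcript %s: '%s' is not a stop codon", tx$id,
                   tx$stop_codon))
    }
    found <- substr(tx$sequence, tx$stop_start, tx$stop_start + 2L)
    if (found != codon_to_dna(tx$stop_codon)) {
      stop(sprintf(
        "transcript %s: annotated stop codon %s but sequence has %s at position %d",
        tx$id, tx$stop_codon, codon_to_rna(found), tx$stop_start))
    }
    if ((tx$stop_start - tx$cds_start) %% 3L != 0L) {
      stop(sprintf("transcript %s: stop codon out of frame with cds_start",
                   tx$id))
    }
  }
  invisible(transcripts)
}

#' Write transcripts as FASTA plus annotation TSV
#'
#' Inverse of [read_transcripts()]; coordinates are written 0-based.
#'
#' @param transcripts transcript data.frame.
#' @param fasta,annotation output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_transcripts <- function(transcripts, fasta, annotation) {
  ss <- Biostrings::DNAStringSet(transcripts$sequence)
  names(ss) <- transcripts$id
  Biostrings::writeXStringSet(ss, fasta)
  ann <- data.frame(transcript_id = transcripts$id,
                    cds_start = transcripts$cds_start - 1L,
                    stop_codon_start = transcripts$stop_start - 1L,
                    stop_codon = transcripts$stop_codon)
  utils::write.table(ann, annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, annotation = annotation))
}

#' Read and write footprint tables
#'
#' Footprint TSVs carry `transcript_id`, `start` (0-based 5' end) and
#' `length`; in memory starts are 1-based.
#'
#' @param path TSV path.
#' @param reads in-memory read table (1-based `start`).
#' @return `read_footprints()`: data.frame with 1-based `start`.
#' @export
read_footprints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "start", "length") %in% names(df)))
  df$start <- as.integer(df$start) + 1L
  df$length <- as.integer(df$length)
  df
}

#' @rdname read_footprints
#' @export
write_footprints <- function(reads, path) {
  out <- data.frame(transcript_id = reads$transcript_id,
                    start = reads$start - 1L, length = reads$length)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full readthrough analysis pipeline on synthetic data
#'
#' Orchestrates the stages end to end: simulate transcripts and reads,
#' detect readthrough events, compute the divergence profile of the
#' high-rate set against the control pool, fit the leak-rate model on the
#' divergence-selected positions, and (when enough labelled contexts exist)
#' evaluate false-positive / false-negative fractions. All tables plus a
#' run manifest are written under `out_dir`; reruns with the same config
#' are deterministic.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param detect_config an [scr_config()].
#' @param k number of divergence-selected model positions.
#' @return list with `transcripts`, `truth`, `reads`, `events`,
#'   `divergence`, `model` (possibly `NULL`), and `manifest`.
#' @export
run_scr_pipeline <- function(config, out_dir = NULL,
                             detect_config = scr_config(), k = 18L) {
  sim <- simulate_transcripts(config)
  reads <- simulate_reads(sim$transcripts, sim$truth, config)
  events <- detect_scr(sim$transcripts, reads, detect_config)
  if (nrow(reads) == 0L) {
    warning("empty read table: no events detectable")
  }

  ctx <- extract_scc(sim$transcripts$sequence, sim$transcripts$stop_start)
  set_ctx <- ctx[events$set_label == "TS2" & !is.na(ctx)]
  ref_ctx <- ctx[events$set_label == "TS0" & !is.na(ctx)]
  divergence <- NULL
  model <- NULL
  if (length(set_ctx) >= 2L && length(ref_ctx) >= 2L) {
    divergence <- scc_divergence(set_ctx, ref_ctx)
    pos <- select_positions(divergence$per_position,
                            min(k, sum(!is.na(divergence$per_position$label))))
    train_keep <- events$set_label == "TS2" & !is.na(ctx)
    model <- leak_model(ctx[train_keep], events$rho[train_keep], pos,
                        stop_codon = if (config$stop_codon == "mixed")
                          NA_character_ else config$stop_codon)
  }

  manifest <- list(
    config = unclass(config)[setdiff(names(config), "planted_bias")],
    n_transcripts = nrow(sim$transcripts),
    n_reads = nrow(reads),
    n_pass = sum(events$passes_filters),
    set_counts = as.list(table(events$set_label)),
    model_positions = if (!is.null(model)) model$positions else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_transcripts(sim$transcripts,
                      file.path(out_dir, "transcripts.fa"),
                      file.path(out_dir, "annotation.tsv"))
    write_footprints(reads, file.path(out_dir, "footprints.tsv"))
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(events),
                       file.path(out_dir, "events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(divergence)) {
      utils::write.table(divergence$per_position,
                         file.path(out_dir, "divergence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(model)) {
      coefs <- data.frame(feature = names(coef(model)),
                          coefficient = unname(coef(model)))
      utils::write.table(coefs, file.path(out_dir, "model.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(transcripts = sim$transcripts, truth = sim$truth, reads = reads,
       events = events, divergence = divergence, model = model,
       manifest = manifest)
}
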