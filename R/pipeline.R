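# End-to-end pipeline: query -> curated selection -> protein stage ->
# six-frame stage -> report.

#' Run a curated homology search against a genome
#'
#' Executes the full pipeline: select curated sequences whose entry
#' descriptions match the query; align them (as queries) against the
#' predicted proteins; rank hits by identity x curated coverage and group
#' them per protein; then, when a nucleotide genome is supplied, under
#' 30 Mb and not skipped, extract stop-free reading frames of at least
#' `min_frame_aa` residues from the six-frame translation, align against
#' those, suppress frame hits already explained by a predicted protein
#' (see [filter_sixframe_hits()]) and rank what remains. Zero curated
#' matches is a valid outcome, not an error.
#'
#' @param db a `curated_db`.
#' @param proteome data.frame from [read_proteome_fasta()] (or a FASTA
#'   path).
#' @param genome optional named character vector of contigs (or FASTA
#'   path); `NULL` skips the six-frame stage.
#' @param query a [cb_query] or query string.
#' @param word_mode whole-word matching (used when `query` is a string).
#' @param max_evalue alignment E-value cutoff (default 0.01).
#' @param min_frame_aa minimum reading-frame length in residues (30).
#' @param sixframe_factor redundancy-filter multiplier (1.1).
#' @param engine alignment engine (default [aligner_builtin()]).
#' @param skip_sixframe skip the six-frame stage even when a genome is
#'   given.
#' @param genetic_code NCBI genetic code id for translation ("11").
#' @param quiet suppress stage progress messages on stderr.
#' @return an object of class `cb_report`.
#' @export
run_pipeline <- function(db, proteome, genome = NULL, query,
                         word_mode = FALSE, max_evalue = 0.01,
                         min_frame_aa = 30, sixframe_factor = 1.1,
                         engine = aligner_builtin(), skip_sixframe = FALSE,
                         genetic_code = "11", quiet = TRUE) {
  stopifnot(inherits(db, "curated_db"))
  if (is.character(proteome)) proteome <- read_proteome_fasta(proteome)
  if (nrow(proteome) == 0) {
    cb_error("cb_format_error", "proteome is empty")
  }
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome))) {
    genome <- read_genome_fasta(genome)
  }
  query <- if (inherits(query, "cb_query")) query
           else cb_query(query, word_mode)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[curated-blast] ", fmt), ...))
  }

  t0 <- proc.time()[["elapsed"]]
  matched <- select_curated(db, query)
  say("query \"%s\": %d curated sequence(s) matched (%.2fs)", query$text,
      length(matched), proc.time()[["elapsed"]] - t0)

  prot_descriptions <- setNames(proteome$description, proteome$protein_id)
  protein_hits <- empty_hits()
  protein_groups <- list()
  if (length(matched)) {
    targets <- data.frame(target_id = proteome$protein_id,
                          target_kind = "protein",
                          sequence = proteome$sequence,
                          stringsAsFactors = FALSE)
    t0 <- proc.time()[["elapsed"]]
    protein_hits <- align_all(matched, targets, max_evalue, engine)
    protein_groups <- rank_protein_hits(protein_hits, prot_descriptions)
    say("protein stage: %d hit(s) to %d protein(s) (%.2fs)",
        nrow(protein_hits), length(protein_groups),
        proc.time()[["elapsed"]] - t0)
  }

  frame_stage <- list(run = FALSE, reason = "")
  frame_groups <- list()
  frames <- NULL
  frame_hits_kept <- empty_hits()
  if (is.null(genome)) {
    frame_stage$reason <- "no nucleotide genome supplied"
  } else if (skip_sixframe) {
    frame_stage$reason <- "six-frame stage skipped on request"
  } else if (!check_sixframe_eligible(genome)) {
    frame_stage$reason <- "genome is 30 Mb or larger; six-frame search skipped"
  } else if (length(matched) == 0) {
    frame_stage$reason <- "no curated sequences matched the query"
  } else {
    frame_stage$run <- TRUE
    t0 <- proc.time()[["elapsed"]]
    frames <- extract_reading_frames(genome, min_aa = min_frame_aa,
                                     genetic_code = genetic_code)
    say("six-frame stage: %d reading frame(s) >= %d aa (%.2fs)",
        nrow(frames), min_frame_aa, proc.time()[["elapsed"]] - t0)
    if (nrow(frames)) {
      ftargets <- data.frame(target_id = frames$frame_id,
                             target_kind = "frame",
                             sequence = frames$aa_sequence,
                             stringsAsFactors = FALSE)
      t0 <- proc.time()[["elapsed"]]
      frame_hits <- align_all(matched, ftargets, max_evalue, engine)
      frame_hits_kept <- filter_sixframe_hits(frame_hits, protein_hits,
                                              sixframe_factor)
      frame_groups <- rank_frame_hits(frame_hits_kept, frames)
      say("six-frame stage: %d hit(s), %d kept after redundancy filter (%.2fs)",
          nrow(frame_hits), nrow(frame_hits_kept),
          proc.time()[["elapsed"]] - t0)
    }
  }

  report <- list(
    query = list(text = query$text, word_mode = query$word_mode,
                 has_wildcard = query$has_wildcard),
    options = list(max_evalue = max_evalue, min_frame_aa = min_frame_aa,
                   sixframe_factor = sixframe_factor,
                   genetic_code = genetic_code),
    n_curated_matched = length(matched),
    matched_seq_ids = vapply(matched, `[[`, "", "seq_id"),
    matched_descriptions = curated_description_map(matched),
    protein_groups = protein_groups,
    frame_stage = frame_stage,
    frame_groups = frame_groups,
    metadata = list(
      engine = attr(engine, "engine_name", exact = TRUE) %||% "custom",
      db_digest = unname(seq_digest(paste(db$sequences$seq_id,
                                          collapse = ""))),
      proteome_digest = unname(seq_digest(paste(proteome$sequence,
                                                collapse = ""))),
      genome_digest = if (is.null(genome)) "" else
        unname(seq_digest(paste(genome, collapse = ""))),
      n_proteins = nrow(proteome),
      n_frames = if (is.null(frames)) 0L else nrow(frames))
  )
  class(report) <- "cb_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seq_id -> "desc1 | desc2" over the matching entries
curated_description_map <- function(matched) {
  if (!length(matched)) return(setNames(character(0), character(0)))
  setNames(
    vapply(matched, function(m)
      paste(unique(m$entries$description), collapse = " | "), ""),
    vapply(matched, `[[`, "", "seq_id"))
}

#' @export
print.cb_report <- function(x, max_groups = 10, ...) {
  cat(sprintf("Curated homology search report for query \"%s\"%s\n", x$query$text,
              if (x$query$word_mode) " [whole words]" else ""))
  cat(sprintf("  %d curated sequence(s) matched\n", x$n_curated_matched))
  cat(sprintf("\nHits to predicted proteins (%d):\n",
              length(x$protein_groups)))
  for (g in head(x$protein_groups, max_groups)) print(g)
  if (length(x$protein_groups) > max_groups) {
    cat(sprintf("  ... %d more group(s)\n",
                length(x$protein_groups) - max_groups))
  }
  if (x$frame_stage$run) {
    cat(sprintf("\nHits to the six-frame translation (%d frame(s)):\n",
                length(x$frame_groups)))
    for (g in head(x$frame_groups, max_groups)) print(g)
  } else {
    cat(sprintf("\nSix-frame stage not run: %s\n", x$frame_stage$reason))
  }
  invisible(x)
}
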