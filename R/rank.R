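# Ranking and grouping of hits, and the six-frame redundancy filter.

sort_hits <- function(hits) {
  hits[order(-hits$score, hits$curated_seq_id, hits$target_id), ,
       drop = FALSE]
}

make_groups <- function(hits, descriptions = NULL, truncate = TRUE) {
  if (nrow(hits) == 0) return(list())
  hits <- sort_hits(hits)
  ids <- unique(hits$target_id) # already ordered by descending best score
  lapply(ids, function(id) {
    h <- hits[hits$target_id == id, , drop = FALSE]
    rownames(h) <- NULL
    n <- nrow(h)
    n_shown <- if (truncate && n >= 4) 3L else n
    g <- list(
      target_id = id,
      target_kind = h$target_kind[1],
      description = if (!is.null(descriptions) && id %in% names(descriptions))
        unname(descriptions[id]) else "",
      hits = h,
      best_score = h$score[1],
      shown_hits = h[seq_len(n_shown), , drop = FALSE],
      n_hidden = n - n_shown)
    class(g) <- "cb_group"
    g
  })
}

#' Rank and group hits to predicted proteins
#'
#' Hits are sorted by descending `score` (identity fraction times
#' curated-coverage fraction; deliberately not the bit score, which would
#' favour homologs of longer proteins) and grouped by predicted protein.
#' Groups are ordered by their best score; within a group hits are in
#' descending score order, with ties broken by (curated_seq_id,
#' target_id) so output is reproducible. When a protein has four or more
#' hits only the top three are marked shown; the rest are counted in
#' `n_hidden` (display bookkeeping only -- no hit is dropped).
#'
#' @param hits hits data.frame with `target_kind == "protein"`.
#' @param descriptions optional named character vector protein_id ->
#'   description, echoed into each group.
#' @return list of `cb_group` objects.
#' @export
rank_protein_hits <- function(hits, descriptions = NULL) {
  if (nrow(hits) && any(hits$target_kind != "protein")) {
    cb_error("cb_format_error", "rank_protein_hits expects protein hits")
  }
  make_groups(hits, descriptions, truncate = TRUE)
}

#' Rank reading-frame hits
#'
#' As [rank_protein_hits()] but for hits to six-frame reading frames,
#' which are shown without truncation; the group description carries the
#' frame's coordinates.
#'
#' @param hits (filtered) frame hits.
#' @param frames data.frame from [extract_reading_frames()], used to
#'   label groups with `contig:start-end(strand)`.
#' @return list of `cb_group` objects.
#' @export
rank_frame_hits <- function(hits, frames = NULL) {
  descriptions <- NULL
  if (!is.null(frames) && nrow(frames)) {
    descriptions <- setNames(
      sprintf("%s:%d-%d(%s) frame %d", frames$contig_id, frames$nt_start,
              frames$nt_end, frames$strand, frames$frame),
      frames$frame_id)
  }
  make_groups(hits, descriptions, truncate = FALSE)
}

#' Six-frame redundancy filter
#'
#' Hits to the six-frame translation that were already expected given the
#' predicted proteins are suppressed, in two steps. Step 1: a frame hit
#' for a curated sequence is provisionally kept only when its score is
#' noticeably better than that curated sequence's best score against any
#' predicted protein -- strictly greater than `factor` (default 1.1)
#' times the best protein score, taken as 0 when the curated sequence has
#' no protein hit at all (the missing-gene case). Step 2: if the
#' best-scoring hit of a reading frame was not provisionally kept, every
#' hit for that frame is discarded; otherwise exactly the provisionally
#' kept hits of that frame survive.
#'
#' @param frame_hits hits with `target_kind == "frame"`.
#' @param protein_hits hits with `target_kind == "protein"` from the same
#'   run.
#' @param factor the "noticeably better" multiplier (default 1.1).
#' @return the surviving subset of `frame_hits`.
#' @export
filter_sixframe_hits <- function(frame_hits, protein_hits, factor = 1.1) {
  if (nrow(frame_hits) == 0) return(frame_hits)
  best_protein <- if (nrow(protein_hits))
    tapply(protein_hits$score, protein_hits$curated_seq_id, max)
  else numeric(0)
  bp <- best_protein[frame_hits$curated_seq_id]
  bp[is.na(bp)] <- 0
  provisional <- frame_hits$score > factor * as.numeric(bp)

  keep <- rep(FALSE, nrow(frame_hits))
  for (fid in unique(frame_hits$target_id)) {
    sel <- frame_hits$target_id == fid
    h <- frame_hits[sel, , drop = FALSE]
    # the frame's best hit, ties resolved like the ranking order
    best_idx <- order(-h$score, h$curated_seq_id, h$target_id)[1]
    if (provisional[sel][best_idx]) {
      keep[sel] <- provisional[sel]
    }
  }
  out <- frame_hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cb_group <- function(x, ...) {
  cat(sprintf("%s%s  (best score %.3f%s)\n", x$target_id,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              x$best_score,
              if (x$n_hidden > 0) sprintf(", %d more hit%s hidden",
                                          x$n_hidden,
                                          if (x$n_hidden > 1) "s" else "")
              else ""))
  h <- x$shown_hits
  for (i in seq_len(nrow(h))) {
    cat(sprintf("    %s: %d%% id., %d%% cov (E = %.2g)\n",
                h$curated_seq_id[i], round(100 * h$identity_frac[i]),
                round(100 * h$coverage_frac[i]), h$evalue[i]))
  }
  invisible(x)
}
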