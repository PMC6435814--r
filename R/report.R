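# Report writers: flat TSV, lossless JSON (with reader), simple HTML.

#' Flatten a report to one row per (group, hit)
#'
#' Columns: `stage` (`protein`/`sixframe`), `target_id`, `target_kind`,
#' `coords` (frame coordinates; empty for proteins), `target_description`,
#' `curated_seq_id`, `curated_descriptions`, `identity_pct`,
#' `coverage_pct`, `evalue`, `score`, `hidden` (hits past the top three
#' of a protein with four or more hits). Percentages carry full
#' precision; the HTML view rounds them.
#'
#' @param report a `cb_report`.
#' @return data.frame (zero rows for an empty report).
#' @export
report_to_table <- function(report) {
  stopifnot(inherits(report, "cb_report"))
  rows <- list()
  flat <- function(groups, stage) {
    for (g in groups) {
      h <- g$hits
      if (nrow(h) == 0) next
      hidden <- seq_len(nrow(h)) > (nrow(h) - g$n_hidden)
      rows[[length(rows) + 1L]] <<- data.frame(
        stage = stage,
        target_id = g$target_id,
        target_kind = g$target_kind,
        coords = if (stage == "sixframe") g$description else "",
        target_description = if (stage == "protein") g$description else "",
        curated_seq_id = h$curated_seq_id,
        curated_descriptions =
          unname(report$matched_descriptions[h$curated_seq_id]),
        identity_pct = 100 * h$identity_frac,
        coverage_pct = 100 * h$coverage_frac,
        evalue = h$evalue,
        score = h$score,
        hidden = hidden,
        stringsAsFactors = FALSE)
    }
  }
  flat(report$protein_groups, "protein")
  flat(report$frame_groups, "sixframe")
  if (!length(rows)) {
    return(data.frame(stage = character(), target_id = character(),
                      target_kind = character(), coords = character(),
                      target_description = character(),
                      curated_seq_id = character(),
                      curated_descriptions = character(),
                      identity_pct = numeric(), coverage_pct = numeric(),
                      evalue = numeric(), score = numeric(),
                      hidden = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a search report
#'
#' `tsv` writes the flat table from [report_to_table()]; `json` writes a
#' lossless dump readable by [read_report_json()]; `html` writes a
#' grouped, human-readable page with the top-three truncation and
#' "N more hits" counts, percentages rounded to integers as
#' "NN% id., NN% cov".
#'
#' @param report a `cb_report`.
#' @param path output file.
#' @param format one of `"tsv"`, `"json"`, `"html"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json", "html")) {
  format <- match.arg(format)
  switch(format,
    tsv = write.table(report_to_table(report), path, sep = "\t",
                      quote = FALSE, row.names = FALSE),
    json = {
      obj <- unclass(report)
      obj$matched_seq_ids <- as.list(obj$matched_seq_ids)
      obj$matched_descriptions <- as.list(obj$matched_descriptions)
      obj$protein_groups <- lapply(obj$protein_groups, group_to_list)
      obj$frame_groups <- lapply(obj$frame_groups, group_to_list)
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
    },
    html = writeLines(report_to_html(report), path))
  invisible(path)
}

group_to_list <- function(g) {
  list(target_id = g$target_id, target_kind = g$target_kind,
       description = g$description, hits = g$hits,
       best_score = g$best_score, n_shown = nrow(g$shown_hits),
       n_hidden = g$n_hidden)
}

hits_from_json <- function(h) {
  int_cols <- c("curated_start", "curated_end", "target_start", "target_end")
  cols <- lapply(names(h), function(nm) {
    v <- unlist(h[[nm]], use.names = FALSE)
    if (nm %in% int_cols) as.integer(v)
    else if (nm %in% c("curated_seq_id", "target_id", "target_kind"))
      as.character(v)
    else as.numeric(v)
  })
  names(cols) <- names(h)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

list_to_group <- function(x) {
  hits <- hits_from_json(x$hits)
  g <- list(target_id = x$target_id, target_kind = x$target_kind,
            description = x$description, hits = hits,
            best_score = as.numeric(x$best_score),
            shown_hits = hits[seq_len(x$n_shown), , drop = FALSE],
            n_hidden = as.integer(x$n_hidden))
  class(g) <- "cb_group"
  g
}

#' Read a JSON report back
#'
#' @param path file written by [write_report()] with `format = "json"`.
#' @return the reconstructed `cb_report`.
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(v) if (length(v)) as.character(unlist(v)) else character(0)
  rep <- list(
    query = list(text = x$query$text,
                 word_mode = isTRUE(x$query$word_mode),
                 has_wildcard = isTRUE(x$query$has_wildcard)),
    options = list(max_evalue = as.numeric(x$options$max_evalue),
                   min_frame_aa = as.numeric(x$options$min_frame_aa),
                   sixframe_factor = as.numeric(x$options$sixframe_factor),
                   genetic_code = as.character(x$options$genetic_code)),
    n_curated_matched = as.integer(x$n_curated_matched),
    matched_seq_ids = chr(x$matched_seq_ids),
    matched_descriptions = setNames(chr(x$matched_descriptions),
                                    names(x$matched_descriptions)),
    protein_groups = lapply(x$protein_groups, list_to_group),
    frame_stage = list(run = isTRUE(x$frame_stage$run),
                       reason = as.character(x$frame_stage$reason)),
    frame_groups = lapply(x$frame_groups, list_to_group),
    metadata = list(engine = as.character(x$metadata$engine),
                    db_digest = as.character(x$metadata$db_digest),
                    proteome_digest = as.character(x$metadata$proteome_digest),
                    genome_digest = as.character(x$metadata$genome_digest),
                    n_proteins = as.integer(x$metadata$n_proteins),
                    n_frames = as.integer(x$metadata$n_frames)))
  class(rep) <- "cb_report"
  rep
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

report_to_html <- function(report) {
  fmt_hit <- function(h, i) {
    sprintf("<li>%s (%s): %d%% id., %d%% cov (E = %.2g)</li>",
            html_escape(h$curated_seq_id[i]),
            html_escape(unname(
              report$matched_descriptions[h$curated_seq_id[i]])),
            round(100 * h$identity_frac[i]),
            round(100 * h$coverage_frac[i]), h$evalue[i])
  }
  fmt_group <- function(g) {
    head_txt <- sprintf("<h3>%s %s</h3>", html_escape(g$target_id),
                        html_escape(g$description))
    items <- vapply(seq_len(nrow(g$shown_hits)),
                    function(i) fmt_hit(g$shown_hits, i), "")
    more <- if (g$n_hidden > 0)
      sprintf("<li><em>%d more hit%s not shown</em></li>", g$n_hidden,
              if (g$n_hidden > 1) "s" else "") else character(0)
    c(head_txt, "<ul>", items, more, "</ul>")
  }
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>Curated homology search: %s</title></head><body>",
            html_escape(report$query$text)),
    sprintf("<h1>Curated homology search results for &quot;%s&quot;%s</h1>",
            html_escape(report$query$text),
            if (report$query$word_mode) " (whole words)" else ""),
    sprintf("<p>%d curated sequence(s) matched the query.</p>",
            report$n_curated_matched),
    sprintf("<h2>Hits to predicted proteins (%d)</h2>",
            length(report$protein_groups)),
    unlist(lapply(report$protein_groups, fmt_group)),
    if (report$frame_stage$run) {
      c(sprintf("<h2>Hits to the six-frame translation (%d)</h2>",
                length(report$frame_groups)),
        unlist(lapply(report$frame_groups, fmt_group)))
    } else {
      sprintf("<h2>Six-frame stage not run</h2><p>%s</p>",
              html_escape(report$frame_stage$reason))
    },
    "</body></html>")
}
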