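# Curated-protein database: ingestion filters, sequence deduplication,
# on-disk format.

CB_SOURCES <- c("BRENDA", "CAZy", "CharProtDB", "EcoCyc", "MetaCyc",
                "REBASE", "SwissProt", "FitnessBrowser", "other")

CB_ENTRY_COLUMNS <- c("entry_id", "source", "description", "organism",
                      "ec_numbers", "publication_ids", "uniprot_id",
                      "entry_type", "is_fragment", "specificity_known",
                      "has_experimental_evidence", "sequence_id")

#' Read a normalized table of curated entries
#'
#' Each curated source (BRENDA, CAZy, CharProtDB, EcoCyc, MetaCyc, REBASE,
#' Swiss-Prot, Fitness Browser) is ingested from a normalized
#' tab-separated table rather than its native distribution format. The
#' table carries one row per curated entry with the columns
#' `entry_id`, `source`, `description`, `organism`, `ec_numbers`
#' (semicolon-joined), `publication_ids` (semicolon-joined), `uniprot_id`,
#' `entry_type`, `is_fragment`, `specificity_known`,
#' `has_experimental_evidence`, and `sequence_id` (a key into the
#' companion protein FASTA). Source-specific judgements (whether a
#' Swiss-Prot entry has experimental evidence, whether a REBASE enzyme's
#' specificity is known, whether a UniProt sequence is a fragment) are
#' supplied as pre-normalized flags, not re-derived.
#'
#' @param path path to a tab-separated entries file with a header row.
#' @return data.frame with one row per entry; flag columns are logical.
#' @export
read_entries_tsv <- function(path) {
  if (!file.exists(path)) {
    cb_error("cb_io_error", sprintf("entries table not found: %s", path))
  }
  df <- read.delim(path, colClasses = "character", na.strings = character(),
                   check.names = FALSE, quote = "")
  missing <- setdiff(CB_ENTRY_COLUMNS, names(df))
  if (length(missing)) {
    cb_error("cb_format_error",
             sprintf("entries table missing columns: %s",
                     paste(missing, collapse = ", ")))
  }
  df <- df[, CB_ENTRY_COLUMNS]
  for (col in c("is_fragment", "specificity_known",
                "has_experimental_evidence")) {
    df[[col]] <- toupper(df[[col]]) %in% c("TRUE", "T", "1", "YES")
  }
  df
}

write_entries_tsv <- function(entries, path) {
  write.table(entries[, CB_ENTRY_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

n_items <- function(x) {
  lengths(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE))
}

#' Apply per-source retention rules to curated entries
#'
#' Each curated source contributes entries under its own retention rule:
#' * BRENDA and MetaCyc: kept only with a UniProt identifier and at least
#'   one publication; sequences flagged as fragments are dropped.
#' * CAZy: kept only when linked to at least one EC number; entries whose
#'   description mentions "frameshift" or "fragment" are dropped.
#' * CharProtDB: entry types `trusted_uniprot` (redundant with Swiss-Prot)
#'   and `trusted_aspgd` are dropped.
#' * REBASE: kept only when the enzyme's sequence specificity is known.
#' * SwissProt: kept only with experimental evidence for the function.
#' * EcoCyc, FitnessBrowser and `other`: no rule; all entries pass (the
#'   fragment flag is not consulted for these sources).
#'
#' Entries missing a field their source's rule needs are dropped and
#' counted in the `n_skipped` attribute of the result. The filter is
#' idempotent and preserves input order.
#'
#' @param entries data.frame of entries as from [read_entries_tsv()].
#' @param source optional single source name; when given, all entries must
#'   carry that source tag.
#' @return the retained rows, with attribute `n_skipped`.
#' @export
apply_source_filters <- function(entries, source = NULL) {
  if (nrow(entries) == 0) {
    out <- entries
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  src <- entries$source
  if (!is.null(source)) {
    if (!all(src == source)) {
      cb_error("cb_source_error",
               "entries carry a source tag different from `source`")
    }
  }
  bad <- setdiff(unique(src), CB_SOURCES)
  if (length(bad)) {
    cb_error("cb_source_error",
             sprintf("unknown source tag(s): %s", paste(bad, collapse = ", ")))
  }

  desc_lc <- tolower(entries$description)
  has_uniprot <- !is.na(entries$uniprot_id) & nzchar(entries$uniprot_id)
  has_pub <- n_items(entries$publication_ids) > 0
  has_ec <- n_items(entries$ec_numbers) > 0

  keep <- rep(TRUE, nrow(entries))
  skipped <- rep(FALSE, nrow(entries))

  sel <- src %in% c("BRENDA", "MetaCyc")
  keep[sel] <- has_uniprot[sel] & has_pub[sel] & !entries$is_fragment[sel]

  sel <- src == "CAZy"
  keep[sel] <- has_ec[sel] &
    !grepl("frameshift", desc_lc[sel], fixed = TRUE) &
    !grepl("fragment", desc_lc[sel], fixed = TRUE)

  sel <- src == "CharProtDB"
  keep[sel] <- !(entries$entry_type[sel] %in%
                   c("trusted_uniprot", "trusted_aspgd"))

  sel <- src == "REBASE"
  keep[sel] <- entries$specificity_known[sel]

  sel <- src == "SwissProt"
  keep[sel] <- entries$has_experimental_evidence[sel]

  # rows whose rule-relevant fields are missing (NA) cannot be judged
  na_keep <- is.na(keep)
  if (any(na_keep)) {
    skipped[na_keep] <- TRUE
    keep[na_keep] <- FALSE
    warning(sprintf("%d entr%s dropped: missing field required by source rule",
                    sum(na_keep), if (sum(na_keep) == 1) "y" else "ies"))
  }
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(skipped)
  out
}

# Uppercase, strip one trailing '*'; NA for sequences that are empty or
# contain internal stops / non-letter characters.
normalize_aa <- function(x) {
  x <- toupper(x)
  x <- sub("\\*$", "", x)
  bad <- !nzchar(x) | grepl("[^A-Z]", x)
  x[bad] <- NA_character_
  x
}

#' Build a deduplicated curated-protein database
#'
#' Entries sharing an identical amino-acid sequence (after uppercasing and
#' stripping one trailing stop `*`) collapse onto one distinct sequence:
#' the distinct sequence, not the entry, is the unit that is later
#' aligned. Sequence identifiers are digests of the sequence string, so
#' the build is reproducible and independent of entry order. Entries whose
#' `sequence_id` is absent from the lookup, or whose sequence contains an
#' internal stop or a non-letter character, are dropped and counted in
#' `build_metadata`.
#'
#' @param entries retained entries, as from [apply_source_filters()].
#' @param sequences named character vector mapping `sequence_id` to an
#'   amino-acid string (e.g. from [read_fasta_chr] on the companion FASTA,
#'   with headers reduced to their first token).
#' @return an object of class `curated_db`: a list with elements
#'   `sequences` (data.frame `seq_id`, `sequence`, `length`), `entries`
#'   (the retained entries plus a `seq_id` column), `per_source_counts`
#'   (data.frame `source`, `n_entries`, `n_distinct`) and
#'   `build_metadata`.
#' @export
build_curated_db <- function(entries, sequences) {
  attr(entries, "n_skipped") <- NULL
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  raw <- sequences[match(entries$sequence_id, names(sequences))]
  aa <- normalize_aa(ifelse(is.na(raw), "", raw))
  unresolved <- is.na(match(entries$sequence_id, names(sequences)))
  bad_residue <- !unresolved & is.na(aa)
  drop <- unresolved | bad_residue
  if (any(drop)) {
    warning(sprintf("%d entr%s dropped while building database", sum(drop),
                    if (sum(drop) == 1) "y" else "ies"))
  }
  entries <- entries[!drop, , drop = FALSE]
  aa <- as.character(aa[!drop])

  seq_id <- if (length(aa)) paste0("seq_", seq_digest(aa)) else character(0)
  useq <- !duplicated(seq_id)
  seqs <- data.frame(seq_id = seq_id[useq], sequence = aa[useq],
                     length = nchar(aa[useq]), stringsAsFactors = FALSE)
  seqs <- seqs[order(seqs$seq_id), , drop = FALSE]
  rownames(seqs) <- NULL

  entries$seq_id <- seq_id
  entries <- entries[order(entries$source, entries$entry_id), , drop = FALSE]
  rownames(entries) <- NULL
  if (anyDuplicated(entries[, c("source", "entry_id")])) {
    cb_error("cb_format_error", "duplicate entry_id within a source")
  }

  per_source <- per_source_counts(entries)

  db <- list(
    sequences = seqs,
    entries = entries,
    per_source_counts = per_source,
    build_metadata = list(
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      n_input_entries = length(drop),
      n_dropped_unresolved = sum(unresolved),
      n_dropped_bad_residue = sum(bad_residue)
    )
  )
  class(db) <- "curated_db"
  db
}

per_source_counts <- function(entries) {
  if (nrow(entries) == 0) {
    return(data.frame(source = character(), n_entries = integer(),
                      n_distinct = integer(), stringsAsFactors = FALSE))
  }
  srcs <- sort(unique(entries$source))
  data.frame(
    source = srcs,
    n_entries = vapply(srcs, function(s) sum(entries$source == s), 0L),
    n_distinct = vapply(srcs, function(s)
      length(unique(entries$seq_id[entries$source == s])), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.curated_db <- function(x, ...) {
  cat(sprintf("Curated protein database: %d entries, %d distinct sequences\n",
              nrow(x$entries), nrow(x$sequences)))
  if (nrow(x$per_source_counts)) {
    print(x$per_source_counts, row.names = FALSE)
  }
  invisible(x)
}

#' Save / load a curated database
#'
#' The on-disk form is a directory of plain-text files: `entries.tsv` (the
#' normalized entries with their `seq_id`), `sequences.fasta` (the
#' distinct sequences keyed by `seq_id`), `stats.tsv` (per-source entry
#' and distinct-sequence counts, with a Total row) and `meta.json`
#' (build metadata plus record counts used to detect truncated writes).
#' `load_curated_db(save_curated_db(db, path))` reproduces `db`
#' field-for-field.
#'
#' @param db a `curated_db` object.
#' @param path directory to create (save) or read (load).
#' @return `save_curated_db` returns `path` invisibly; `load_curated_db`
#'   returns the `curated_db`.
#' @export
save_curated_db <- function(db, path) {
  stopifnot(inherits(db, "curated_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ent <- db$entries
  write.table(ent[, c(CB_ENTRY_COLUMNS, "seq_id")],
              file.path(path, "entries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta_chr(setNames(db$sequences$sequence, db$sequences$seq_id),
                  file.path(path, "sequences.fasta"), "AA")
  write_build_stats(db, file.path(path, "stats.tsv"))
  meta <- db$build_metadata
  meta$n_entries <- nrow(db$entries)
  meta$n_sequences <- nrow(db$sequences)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_curated_db
#' @export
load_curated_db <- function(path) {
  files <- file.path(path, c("entries.tsv", "sequences.fasta", "meta.json"))
  if (!dir.exists(path) || !all(file.exists(files))) {
    cb_error("cb_load_error",
             sprintf("not a curated database directory: %s", path))
  }
  meta <- jsonlite::read_json(files[3], simplifyVector = TRUE)
  ent <- read.delim(files[1], colClasses = "character",
                    na.strings = character(), check.names = FALSE,
                    quote = "")
  for (col in c("is_fragment", "specificity_known",
                "has_experimental_evidence")) {
    ent[[col]] <- ent[[col]] == "TRUE"
  }
  seqs <- read_fasta_chr(files[2], "AA")
  if (nrow(ent) != meta$n_entries || length(seqs) != meta$n_sequences) {
    cb_error("cb_load_error",
             sprintf("curated database at %s is corrupt or truncated", path))
  }
  if (!all(ent$seq_id %in% names(seqs))) {
    cb_error("cb_load_error",
             "entries reference sequences missing from sequences.fasta")
  }
  sdf <- data.frame(seq_id = names(seqs), sequence = unname(seqs),
                    length = nchar(unname(seqs)), stringsAsFactors = FALSE)
  sdf <- sdf[order(sdf$seq_id), , drop = FALSE]
  rownames(sdf) <- NULL
  meta$n_entries <- NULL
  meta$n_sequences <- NULL
  db <- list(sequences = sdf, entries = ent,
             per_source_counts = per_source_counts(ent),
             build_metadata = meta)
  class(db) <- "curated_db"
  db
}

#' Write per-source build statistics
#'
#' A small TSV with one row per source (`source`, `n_entries`,
#' `n_distinct`) and a final `Total` row in which `n_distinct` counts
#' sequences distinct across all sources, so the total can be smaller
#' than the column sum when sources share sequences.
#'
#' @param db a `curated_db`.
#' @param path output file.
#' @export
write_build_stats <- function(db, path) {
  tab <- db$per_source_counts
  tab <- rbind(tab, data.frame(source = "Total",
                               n_entries = nrow(db$entries),
                               n_distinct = nrow(db$sequences),
                               stringsAsFactors = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
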