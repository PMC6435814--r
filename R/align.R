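# Alignment of curated sequences (queries) against genome targets
# (predicted proteins or reading frames): built-in Smith-Waterman engine,
# E-values, the pluggable engine contract, and the BLAST-tabular adapter.

# Karlin-Altschul parameters for gapped BLOSUM62, gap open 11 / extend 1
KA_LAMBDA <- 0.267
KA_K <- 0.041

# 26 x 26 substitution matrix over 'A'..'Z' built from BLOSUM62; letters
# BLOSUM62 does not score (J, O, U) fall back to the 'X' column.
blosum62_matrix <- function() {
  if (!is.null(.cb_cache$blosum62)) return(.cb_cache$blosum62)
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  bl <- get("BLOSUM62", envir = environment())
  letters26 <- LETTERS
  m <- matrix(0L, 26, 26, dimnames = list(letters26, letters26))
  avail <- intersect(letters26, rownames(bl))
  for (i in letters26) {
    ii <- if (i %in% avail) i else "X"
    for (j in letters26) {
      jj <- if (j %in% avail) j else "X"
      m[i, j] <- as.integer(bl[ii, jj])
    }
  }
  .cb_cache$blosum62 <- m
  m
}

validate_aa <- function(x, what = "sequence") {
  if (!nzchar(x) || grepl("[^A-Z]", x)) {
    cb_error("cb_alphabet_error",
             sprintf("%s must be a non-empty uppercase A-Z string", what))
  }
  invisible(x)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1; a gap of length L costs 11 + L). Fully deterministic: among
#' equal-scoring optimal alignments the one with the smallest query start,
#' then smallest target start, is reported. Identity is the number of
#' identical columns divided by the number of alignment columns, gap
#' columns included in the denominator. The E-value follows the
#' Karlin-Altschul formula `K * m * n * exp(-lambda * S)` with the gapped
#' BLOSUM62/11/1 constants (lambda 0.267, K 0.041); `search_space`
#' defaults to `nchar(a) * nchar(b)` but callers searching a whole target
#' set pass query length x total target length.
#'
#' @param a query (curated) amino-acid string.
#' @param b target amino-acid string.
#' @param gap_open,gap_ext affine gap parameters.
#' @param search_space product of query length and total target length
#'   used for the E-value.
#' @return `NULL` when no positive-scoring local alignment exists,
#'   otherwise a list with `score` (raw), `bits`, `evalue`, `a_start`,
#'   `a_end`, `b_start`, `b_end` (1-based inclusive), `n_identical`,
#'   `n_columns`, `identity_frac`.
#' @export
builtin_local_align <- function(a, b, gap_open = 11L, gap_ext = 1L,
                                search_space = nchar(a) * nchar(b)) {
  validate_aa(a, "query sequence")
  validate_aa(b, "target sequence")
  res <- cpp_sw_align(a, b, blosum62_matrix(), as.integer(gap_open),
                      as.integer(gap_ext))
  if (!isTRUE(res$found)) return(NULL)
  bits <- (KA_LAMBDA * res$score - log(KA_K)) / log(2)
  list(score = res$score,
       bits = bits,
       evalue = KA_K * search_space * exp(-KA_LAMBDA * res$score),
       a_start = res$qstart, a_end = res$qend,
       b_start = res$tstart, b_end = res$tend,
       n_identical = res$nident, n_columns = res$ncols,
       identity_frac = res$nident / res$ncols)
}

empty_hits <- function() {
  data.frame(curated_seq_id = character(), target_id = character(),
             target_kind = character(), identity_frac = numeric(),
             coverage_frac = numeric(), evalue = numeric(),
             curated_start = integer(), curated_end = integer(),
             target_start = integer(), target_end = integer(),
             raw_score = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' The built-in alignment engine
#'
#' Returns an engine function satisfying the aligner contract used by
#' [align_all()]: `engine(curated, targets, max_evalue)` where `curated`
#' is a list of `list(seq_id, sequence)` and `targets` a data.frame with
#' columns `target_id`, `target_kind`, `sequence`. The engine reports at
#' most one hit per (curated, target) pair -- the best local alignment --
#' and only hits with `evalue <= max_evalue`.
#'
#' @param gap_open,gap_ext affine gap parameters passed to
#'   [builtin_local_align()].
#' @return a function of class `cb_engine`.
#' @export
aligner_builtin <- function(gap_open = 11L, gap_ext = 1L) {
  f <- function(curated, targets, max_evalue) {
    total_target <- sum(nchar(targets$sequence))
    rows <- vector("list", length(curated) * nrow(targets))
    k <- 0L
    for (cu in curated) {
      space <- nchar(cu$sequence) * total_target
      for (t in seq_len(nrow(targets))) {
        aln <- builtin_local_align(cu$sequence, targets$sequence[t],
                                   gap_open, gap_ext,
                                   search_space = space)
        if (is.null(aln) || aln$evalue > max_evalue) next
        cov <- (aln$a_end - aln$a_start + 1) / nchar(cu$sequence)
        k <- k + 1L
        rows[[k]] <- data.frame(
          curated_seq_id = cu$seq_id,
          target_id = targets$target_id[t],
          target_kind = targets$target_kind[t],
          identity_frac = aln$identity_frac,
          coverage_frac = cov,
          evalue = aln$evalue,
          curated_start = aln$a_start, curated_end = aln$a_end,
          target_start = aln$b_start, target_end = aln$b_end,
          raw_score = aln$score,
          score = aln$identity_frac * cov,
          stringsAsFactors = FALSE)
      }
    }
    if (k == 0L) return(empty_hits())
    do.call(rbind, rows[seq_len(k)])
  }
  structure(f, class = c("cb_engine", "function"), engine_name = "builtin")
}

#' Align curated sequences to a target set
#'
#' Runs the engine on every (curated, target) pair and returns one best
#' hit per pair at `evalue <= max_evalue`. The curated sequence is always
#' the query; `coverage_frac` is the fraction of the *curated* sequence
#' spanned by the alignment and `score = identity_frac * coverage_frac`
#' is the ranking key.
#'
#' @param curated list of `list(seq_id, sequence)` (e.g. from
#'   [select_curated()]).
#' @param targets data.frame with columns `target_id`, `target_kind`
#'   (`"protein"` or `"frame"`), `sequence`.
#' @param max_evalue E-value cutoff (default 0.01).
#' @param engine a `cb_engine` (default [aligner_builtin()]).
#' @return hits data.frame (possibly empty) sorted by
#'   (curated_seq_id, target_id).
#' @export
align_all <- function(curated, targets, max_evalue = 0.01,
                      engine = aligner_builtin()) {
  if (length(curated) == 0 || nrow(targets) == 0) return(empty_hits())
  if (anyDuplicated(targets$target_id)) {
    cb_error("cb_format_error", "duplicate target ids")
  }
  hits <- tryCatch(engine(curated, targets, max_evalue),
                   error = function(e) {
                     if (inherits(e, "cb_error")) stop(e)
                     cb_error("cb_engine_error",
                              sprintf("alignment engine failed: %s",
                                      conditionMessage(e)))
                   })
  if (nrow(hits)) {
    keep <- hits$evalue <= max_evalue
    hits <- hits[keep, , drop = FALSE]
    hits <- hits[order(hits$curated_seq_id, hits$target_id), , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Read predicted proteins from FASTA
#'
#' @param path protein FASTA; the first header token is the protein id,
#'   the remainder its description. One trailing `*` is stripped.
#' @return data.frame `protein_id`, `description`, `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  seqs <- read_fasta_chr(path, "AA")
  hd <- split_fasta_headers(names(seqs))
  if (anyDuplicated(hd$id)) {
    cb_error("cb_format_error", "duplicate protein ids in proteome FASTA")
  }
  aa <- sub("\\*$", "", toupper(unname(seqs)))
  if (any(!nzchar(aa))) {
    cb_error("cb_format_error", "empty protein sequence in proteome FASTA")
  }
  data.frame(protein_id = hd$id, description = hd$desc, sequence = aa,
             stringsAsFactors = FALSE)
}

#' Parse BLAST-style tabular alignment output
#'
#' Adapter input for external alignment engines: the common 12-column
#' tabular dialect (`outfmt 6`) with columns query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start, query
#' end, subject start, subject end, E-value, bit score. Queries are the
#' curated sequences; subjects are the targets. Coverage is recomputed
#' from the query coordinates and the curated length, and identity is
#' converted back to a fraction.
#'
#' @param path tabular file.
#' @param curated_lengths named numeric vector, curated seq_id -> length.
#' @param target_kind `"protein"` or `"frame"` for all rows.
#' @return hits data.frame in the same schema as [align_all()]
#'   (`raw_score` holds the bit score).
#' @export
read_blast_tab <- function(path, curated_lengths,
                           target_kind = c("protein", "frame")) {
  target_kind <- match.arg(target_kind)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.delim(path, header = FALSE, col.names = cols,
                    colClasses = c("character", "character", rep("numeric", 10)),
                    quote = "")
  if (nrow(tab) == 0) return(empty_hits())
  unknown <- setdiff(unique(tab$qseqid), names(curated_lengths))
  if (length(unknown)) {
    cb_error("cb_format_error",
             sprintf("tabular rows for unknown curated sequence(s): %s",
                     paste(unknown, collapse = ", ")))
  }
  len <- curated_lengths[tab$qseqid]
  cov <- (tab$qend - tab$qstart + 1) / len
  idf <- tab$pident / 100
  out <- data.frame(
    curated_seq_id = tab$qseqid, target_id = tab$sseqid,
    target_kind = target_kind, identity_frac = idf,
    coverage_frac = unname(cov), evalue = tab$evalue,
    curated_start = as.integer(tab$qstart),
    curated_end = as.integer(tab$qend),
    target_start = as.integer(tab$sstart),
    target_end = as.integer(tab$send),
    raw_score = tab$bitscore, score = idf * unname(cov),
    stringsAsFactors = FALSE)
  # one best hit per (curated, target) pair
  out <- out[order(out$curated_seq_id, out$target_id, -out$score,
                   out$evalue), , drop = FALSE]
  out <- out[!duplicated(out[, c("curated_seq_id", "target_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' External alignment engine adapter
#'
#' Wraps a shell command into the engine contract. The command is run as
#' `cmd <query.faa> <subject.faa> <out.tsv>` (paths substituted for the
#' placeholders `{query}`, `{subject}`, `{out}` if present, otherwise
#' appended) and must write BLAST-style 12-column tabular output; see
#' [read_blast_tab()]. The test suite exercises the built-in engine only.
#'
#' @param cmd command template.
#' @return a function of class `cb_engine`.
#' @export
aligner_external <- function(cmd) {
  f <- function(curated, targets, max_evalue) {
    qf <- tempfile(fileext = ".faa")
    sf <- tempfile(fileext = ".faa")
    of <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(qf, sf, of)))
    write_fasta_chr(setNames(vapply(curated, `[[`, "", "sequence"),
                             vapply(curated, `[[`, "", "seq_id")), qf, "AA")
    write_fasta_chr(setNames(targets$sequence, targets$target_id), sf, "AA")
    full <- if (grepl("{query}", cmd, fixed = TRUE)) {
      gsub("{out}", of, gsub("{subject}", sf,
           gsub("{query}", qf, cmd, fixed = TRUE), fixed = TRUE), fixed = TRUE)
    } else {
      paste(cmd, shQuote(qf), shQuote(sf), shQuote(of))
    }
    status <- system(full)
    if (status != 0 || !file.exists(of)) {
      cb_error("cb_engine_error",
               sprintf("external engine failed (exit %d): %s", status, full))
    }
    lens <- setNames(vapply(curated, function(x) nchar(x$sequence), 0),
                     vapply(curated, `[[`, "", "seq_id"))
    kind <- if (nrow(targets)) targets$target_kind[1] else "protein"
    read_blast_tab(of, lens, kind)
  }
  structure(f, class = c("cb_engine", "function"),
            engine_name = paste0("external:", cmd))
}
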