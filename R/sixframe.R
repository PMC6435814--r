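# Six-frame translation: stop-free stretches of >= 30 aa ("reading
# frames", not ORFs -- no start codon is required).

IUPAC_NT <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
              "V", "H", "D", "B", "N")

# Codon lookup with the conservative ambiguity rule: a codon containing
# ambiguity codes translates to the common amino acid when every
# disambiguation agrees, to 'X' when disambiguations disagree, and to a
# STOP whenever any disambiguation is a stop (so runs cannot be inflated
# across N stretches). Stops are '*'.
codon_table <- function(genetic_code = "11") {
  key <- paste0("codon_table_", genetic_code)
  if (!is.null(.cb_cache[[key]])) return(.cb_cache[[key]])
  gc_tab <- Biostrings::getGeneticCode(genetic_code)
  iupac <- Biostrings::IUPAC_CODE_MAP[IUPAC_NT]
  expand <- strsplit(iupac, "")
  combos <- expand.grid(b1 = IUPAC_NT, b2 = IUPAC_NT, b3 = IUPAC_NT,
                        stringsAsFactors = FALSE)
  codons <- paste0(combos$b1, combos$b2, combos$b3)
  aa <- character(length(codons))
  for (k in seq_along(codons)) {
    opts <- as.vector(outer(
      as.vector(outer(expand[[combos$b1[k]]], expand[[combos$b2[k]]],
                      paste0)),
      expand[[combos$b3[k]]], paste0))
    tr <- unname(gc_tab[opts])
    if (any(tr == "*")) aa[k] <- "*"
    else if (length(unique(tr)) == 1) aa[k] <- tr[1]
    else aa[k] <- "X"
  }
  tab <- setNames(aa, codons)
  .cb_cache[[key]] <- tab
  tab
}

revcomp_chr <- function(x) {
  x <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x)
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         "", USE.NAMES = FALSE)
}

validate_contigs <- function(genome) {
  if (length(genome) == 0) return(invisible(genome))
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    cb_error("cb_format_error", "contigs must have unique names")
  }
  for (i in seq_along(genome)) {
    s <- genome[[i]]
    if (!nzchar(s)) {
      cb_error("cb_format_error",
               sprintf("contig %s is empty", names(genome)[i]))
    }
    if (grepl("[^ACGTMRWSYKVHDBN]", s)) {
      bad <- unique(strsplit(gsub("[ACGTMRWSYKVHDBN]", "", s), "")[[1]])
      cb_error("cb_alphabet_error",
               sprintf("contig %s contains non-IUPAC character(s): %s",
                       names(genome)[i], paste(bad, collapse = "")))
    }
  }
  invisible(genome)
}

#' Is a genome small enough for six-frame search?
#'
#' Six-frame search is offered for genomes under 30 Mb total nucleotide
#' length (it was designed with bacterial and archaeal genomes in mind and
#' ignores splicing). Exactly 30,000,000 nt is already too large.
#'
#' @param genome named character vector of contig sequences.
#' @return logical scalar.
#' @export
check_sixframe_eligible <- function(genome) {
  sum(nchar(genome)) < 30e6
}

#' Extract reading frames from the six-frame translation
#'
#' Translates each contig in all six frames (standard bacterial genetic
#' code by default) and emits every maximal stop-free stretch of at least
#' `min_aa` residues. Stretches are bounded by stop codons and contig
#' ends; trailing partial codons are ignored; no start codon is required.
#' Coordinates are 1-based inclusive on the forward strand, so for a
#' minus-strand frame `nt_start` is the leftmost base of the last codon.
#'
#' @param genome named character vector of contigs (uppercased
#'   automatically), or a path handled by [read_genome_fasta()].
#' @param min_aa minimum stretch length in residues (default 30).
#' @param genetic_code NCBI genetic code id (default "11", bacterial).
#' @return data.frame with columns `frame_id`, `contig_id`, `strand`
#'   (`+`/`-`), `frame` (1-3), `nt_start`, `nt_end`, `aa_length`,
#'   `aa_sequence`, sorted by (contig_id, strand, frame, nt_start).
#' @export
extract_reading_frames <- function(genome, min_aa = 30,
                                   genetic_code = "11") {
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  genome <- toupper(genome)
  validate_contigs(genome)
  tab <- codon_table(genetic_code)

  rows <- list()
  for (cid in sort(names(genome))) {
    L <- nchar(genome[[cid]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genome[[cid]] else revcomp_chr(genome[[cid]])
      for (frame in 1:3) {
        n_codon <- (L - frame + 1L) %/% 3L
        if (n_codon < min_aa) next
        starts <- frame + 3L * (seq_len(n_codon) - 1L)
        aa <- unname(tab[substring(s, starts, starts + 2L)])
        aastr <- paste(aa, collapse = "")
        runs <- gregexpr("[^*]+", aastr)[[1]]
        if (runs[1] == -1) next
        rlen <- attr(runs, "match.length")
        ok <- rlen >= min_aa
        if (!any(ok)) next
        for (k in which(ok)) {
          i1 <- runs[k]
          i2 <- runs[k] + rlen[k] - 1L
          ws_start <- frame + 3L * (i1 - 1L)
          ws_end <- frame + 3L * i2 - 1L
          if (strand == "+") {
            nt_start <- ws_start; nt_end <- ws_end
          } else {
            nt_start <- L - ws_end + 1L; nt_end <- L - ws_start + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            frame_id = sprintf("%s|%s%d|%d", cid, strand, frame, nt_start),
            contig_id = cid, strand = strand, frame = frame,
            nt_start = nt_start, nt_end = nt_end,
            aa_length = rlen[k],
            aa_sequence = substr(aastr, i1, i2),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(frame_id = character(), contig_id = character(),
                      strand = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      aa_length = integer(), aa_sequence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, match(out$strand, c("+", "-")),
                   out$frame, out$nt_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a nucleotide genome FASTA
#'
#' @param path FASTA file of contigs.
#' @return named character vector (names are the first header token).
#' @export
read_genome_fasta <- function(path) {
  seqs <- read_fasta_chr(path, "DNA")
  hd <- split_fasta_headers(names(seqs))
  if (anyDuplicated(hd$id)) {
    cb_error("cb_format_error", "duplicate contig ids in genome FASTA")
  }
  setNames(toupper(unname(seqs)), hd$id)
}

#' Write reading frames to FASTA and a BED-like interval table
#'
#' The FASTA holds the frame peptides with headers
#' `frame_id contig:start-end strand frame`; the TSV has columns
#' `contig_id`, `nt_start`, `nt_end`, `frame_id`, `strand`, `frame`,
#' `aa_length` (1-based inclusive coordinates on the forward strand).
#'
#' @param frames data.frame from [extract_reading_frames()].
#' @param fasta_path,tsv_path output paths (either may be `NULL`).
#' @export
write_reading_frames <- function(frames, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    headers <- sprintf("%s %s:%d-%d %s frame%d", frames$frame_id,
                       frames$contig_id, frames$nt_start, frames$nt_end,
                       frames$strand, frames$frame)
    write_fasta_chr(setNames(frames$aa_sequence, headers), fasta_path, "AA")
  }
  if (!is.null(tsv_path)) {
    write.table(frames[, c("contig_id", "nt_start", "nt_end", "frame_id",
                           "strand", "frame", "aa_length")],
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
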