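# Shared test helpers: tiny in-memory databases, random sequences, and
# independent oracles (Biostrings-based six-frame translation and
# exhaustive local alignment) kept separate from the code paths they
# check.

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_aa <- function(n) paste(sample(AA20_TEST, n, TRUE), collapse = "")

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# minimal well-formed entries table
make_entries <- function(entry_id, source, description,
                         sequence_id = entry_id, ...) {
  n <- length(entry_id)
  base <- data.frame(
    entry_id = entry_id, source = rep_len(source, n),
    description = rep_len(description, n),
    organism = rep_len("Testus testensis", n),
    ec_numbers = rep_len("1.1.1.1", n),
    publication_ids = rep_len("PMID:1", n),
    uniprot_id = rep_len("P00001", n),
    entry_type = rep_len("trusted", n),
    is_fragment = rep_len(FALSE, n),
    specificity_known = rep_len(TRUE, n),
    has_experimental_evidence = rep_len(TRUE, n),
    sequence_id = sequence_id, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- rep_len(over[[nm]], n)
  base
}

# a small curated database: ids d1..dn with given descriptions/sequences
tiny_db <- function(descriptions, sequences = NULL, source = "EcoCyc") {
  n <- length(descriptions)
  if (is.null(sequences)) sequences <- vapply(seq_len(n), function(i)
    rand_aa(60), "")
  ent <- make_entries(sprintf("d%d", seq_len(n)), source, descriptions,
                      sequence_id = sprintf("s%d", seq_len(n)))
  build_curated_db(ent, setNames(sequences, sprintf("s%d", seq_len(n))))
}

# Independent six-frame oracle: translate each frame with Biostrings
# (no initiator-codon special casing), split on stops, filter by length,
# and derive forward-strand coordinates by arithmetic.
sixframe_oracle <- function(genome, min_aa = 30) {
  rows <- list()
  for (cid in sort(names(genome))) {
    L <- nchar(genome[[cid]])
    dna <- Biostrings::DNAString(genome[[cid]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") dna else Biostrings::reverseComplement(dna)
      for (f in 1:3) {
        nc <- (L - f + 1) %/% 3
        if (nc < 1) next
        aa <- as.character(suppressWarnings(Biostrings::translate(
          Biostrings::subseq(s, f, f + 3 * nc - 1),
          if.fuzzy.codon = "solve", no.init.codon = TRUE)))
        m <- gregexpr("[^*]+", aa)[[1]]
        if (m[1] == -1) next
        ml <- attr(m, "match.length")
        for (k in which(ml >= min_aa)) {
          i1 <- m[k]; i2 <- m[k] + ml[k] - 1
          ws <- f + 3 * (i1 - 1); we <- f + 3 * i2 - 1
          if (strand == "+") { a <- ws; b <- we }
          else { a <- L - we + 1; b <- L - ws + 1 }
          rows[[length(rows) + 1]] <- data.frame(
            contig_id = cid, strand = strand, frame = f,
            nt_start = a, nt_end = b,
            aa_sequence = substr(aa, i1, i2), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig_id = character(), strand = character(),
                      frame = integer(), nt_start = integer(),
                      nt_end = integer(), aa_sequence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, match(out$strand, c("+", "-")),
                   out$frame, out$nt_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

frames_comparable <- function(frames) {
  out <- frames[, c("contig_id", "strand", "frame", "nt_start", "nt_end",
                    "aa_sequence")]
  rownames(out) <- NULL
  out
}

# Exhaustive local-alignment score oracle: Biostrings' full
# dynamic-programming aligner under the same scoring scheme.
sw_oracle_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  bl <- get("BLOSUM62", envir = environment())
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = bl, gapOpening = gap_open, gapExtension = gap_ext,
    scoreOnly = TRUE))
}

# Direct transcription of the two-step six-frame redundancy rule,
# independent of the data-frame machinery in the package.
filter_oracle <- function(frame_hits, protein_hits, factor = 1.1) {
  keep <- logical(nrow(frame_hits))
  prov <- logical(nrow(frame_hits))
  for (i in seq_len(nrow(frame_hits))) {
    cu <- frame_hits$curated_seq_id[i]
    best <- 0
    for (j in seq_len(nrow(protein_hits))) {
      if (protein_hits$curated_seq_id[j] == cu &&
          protein_hits$score[j] > best) best <- protein_hits$score[j]
    }
    prov[i] <- frame_hits$score[i] > factor * best
  }
  for (fid in unique(frame_hits$target_id)) {
    idx <- which(frame_hits$target_id == fid)
    ord <- idx[order(-frame_hits$score[idx], frame_hits$curated_seq_id[idx])]
    if (prov[ord[1]]) keep[idx] <- prov[idx]
  }
  frame_hits[keep, , drop = FALSE]
}

# hit-table constructor for ranking/filter tests
make_hits <- function(curated, target, score, kind = "protein") {
  n <- length(curated)
  data.frame(curated_seq_id = curated, target_id = target,
             target_kind = rep(kind, n),
             identity_frac = sqrt(score), coverage_frac = sqrt(score),
             evalue = rep(1e-5, n),
             curated_start = 1L, curated_end = 10L,
             target_start = 1L, target_end = 10L,
             raw_score = 50, score = score, stringsAsFactors = FALSE)
}

# standard planted-genome scenario used by pipeline and acceptance tests
planted_scenario <- function(seed) {
  proteins <- with_test_seed(seed, list(
    fs = rand_aa(400), int = rand_aa(300), ann = rand_aa(250),
    abs = rand_aa(200), decoy = rand_aa(160)))
  plants <- list(
    plant_spec("plant_fs", proteins$fs, "as_frameshifted_orf"),
    plant_spec("plant_int", proteins$int, "as_intact_orf"),
    plant_spec("plant_ann", proteins$ann, "as_predicted_protein"),
    plant_spec("plant_abs", proteins$abs, "absent"))
  gx <- make_genome_with_plants(plants, background_kb = 25, seed = seed)
  ent <- make_entries(
    c("E_fs", "E_int", "E_ann", "E_abs", "E_decoy"), "SwissProt",
    c("histidinol dehydrogenase", "histidinol dehydrogenase homolog 2",
      "histidinol dehydrogenase homolog 3",
      "histidinol dehydrogenase homolog 4", "unrelated permease"),
    sequence_id = c("s_fs", "s_int", "s_ann", "s_abs", "s_decoy"))
  db <- build_curated_db(ent, c(s_fs = proteins$fs, s_int = proteins$int,
                                s_ann = proteins$ann, s_abs = proteins$abs,
                                s_decoy = proteins$decoy))
  list(db = db, gx = gx, proteins = proteins)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# round-trip fixture entries through the normalized TSV reader
read_entries_tsv_from <- function(fx) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  curatedblast:::write_entries_tsv(fx$entries, f)
  read_entries_tsv(f)
}
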