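# Synthetic inputs with planted signal: a curated-database fixture that
# exercises every source retention rule, and genomes with planted genes
# (intact, annotated, frameshifted, absent) for end-to-end tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# description vocabulary; the "fragment"/"frameshift" variants feed the
# CAZy description rule
CB_DESC_POOL <- c(
  "perchlorate reductase subunit alpha",
  "chlorate reductase",
  "nitrate reductase catalytic subunit",
  "histidinol dehydrogenase",
  "beta-galactosidase",
  "endoglucanase",
  "alcohol dehydrogenase 1.1.1.1",
  "aminotransferase class III",
  "DNA methyltransferase M.EcoRI",
  "sugar ABC transporter permease")

# per-source scenario templates: each is applied cyclically and carries
# the expected retention decision plus the rule it exercises
source_scenarios <- function(source) {
  ok <- list(retain = TRUE, why = "passes all rules", tweak = identity)
  switch(source,
    BRENDA = ,
    MetaCyc = list(
      ok,
      list(retain = FALSE, why = "no UniProt identifier",
           tweak = function(e) { e$uniprot_id <- ""; e }),
      list(retain = FALSE, why = "no publication",
           tweak = function(e) { e$publication_ids <- ""; e }),
      list(retain = FALSE, why = "sequence is a fragment",
           tweak = function(e) { e$is_fragment <- TRUE; e })),
    CAZy = list(
      ok,
      list(retain = FALSE, why = "no EC number",
           tweak = function(e) { e$ec_numbers <- ""; e }),
      list(retain = FALSE, why = "description mentions fragment",
           tweak = function(e) {
             e$description <- paste(e$description, "fragment"); e }),
      list(retain = FALSE, why = "description mentions frameshift",
           tweak = function(e) {
             e$description <- paste(e$description, "frameshift"); e })),
    CharProtDB = list(
      ok,
      list(retain = FALSE, why = "entry_type trusted_uniprot",
           tweak = function(e) { e$entry_type <- "trusted_uniprot"; e }),
      list(retain = FALSE, why = "entry_type trusted_aspgd",
           tweak = function(e) { e$entry_type <- "trusted_aspgd"; e })),
    REBASE = list(
      ok,
      list(retain = FALSE, why = "sequence specificity unknown",
           tweak = function(e) { e$specificity_known <- FALSE; e })),
    SwissProt = list(
      ok,
      list(retain = FALSE, why = "no experimental evidence",
           tweak = function(e) { e$has_experimental_evidence <- FALSE; e })),
    # EcoCyc / FitnessBrowser / other: everything passes, including
    # entries flagged as fragments (the flag is not consulted)
    list(ok,
         list(retain = TRUE, why = "fragment flag ignored for this source",
              tweak = function(e) { e$is_fragment <- TRUE; e }))
  )
}

#' Generate a curated-database fixture
#'
#' Emits normalized per-source entry tables plus a protein FASTA in which
#' every source retention rule is exercised (entries missing UniProt ids
#' or publications, fragments, `trusted_uniprot` records, entries without
#' EC numbers, unknown REBASE specificity, Swiss-Prot entries without
#' experimental evidence), together with a manifest of the expected
#' retain/exclude decision for each entry and the expected distinct
#' sequence counts. A `dup_fraction` of the *retained* entries reuse the
#' sequence of an earlier retained entry, so expected distinct counts are
#' below the retained count. Fully deterministic under `seed`.
#'
#' @param sources which sources to include (default all eight).
#' @param n_entries_per_source entries generated per source.
#' @param dup_fraction fraction (in `[0, 1)`) of retained entries sharing
#'   a sequence with an earlier retained entry.
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `entries.tsv`,
#'   `proteins.fasta` and `manifest.tsv` there.
#' @return list with `entries` (data.frame), `sequences` (named character
#'   vector keyed by sequence_id), `manifest` (data.frame `entry_id`,
#'   `source`, `expected_retained`, `reason`, `sequence_id`), and
#'   `expected` (list `n_retained`, `n_distinct`, `per_source`
#'   data.frame).
#' @export
make_curated_fixture <- function(sources = setdiff(CB_SOURCES, "other"),
                                 n_entries_per_source = 6,
                                 dup_fraction = 0.2, seed = 1,
                                 dir = NULL) {
  stopifnot(all(sources %in% CB_SOURCES), n_entries_per_source >= 1,
            dup_fraction >= 0, dup_fraction < 1)
  with_seed(seed, {
    entries <- list()
    manifest <- list()
    for (src in sources) {
      scen <- source_scenarios(src)
      for (i in seq_len(n_entries_per_source)) {
        sc <- scen[[(i - 1) %% length(scen) + 1]]
        e <- list(
          entry_id = sprintf("%s_%03d", src, i),
          source = src,
          description = CB_DESC_POOL[(i - 1) %% length(CB_DESC_POOL) + 1],
          organism = sprintf("Synthetica organism%d", 1 + (i %% 3)),
          ec_numbers = sprintf("%d.%d.%d.%d", 1 + i %% 6, 1 + i %% 9,
                               1 + i %% 12, i),
          publication_ids = sprintf("PMID:%07d", 1000000 + i),
          uniprot_id = sprintf("P%05d", 10000 + i),
          entry_type = "trusted",
          is_fragment = FALSE,
          specificity_known = TRUE,
          has_experimental_evidence = TRUE,
          sequence_id = NA_character_)
        e <- sc$tweak(e)
        entries[[length(entries) + 1]] <- e
        manifest[[length(manifest) + 1]] <- list(
          entry_id = e$entry_id, source = src,
          expected_retained = sc$retain, reason = sc$why)
      }
    }
    entries <- do.call(rbind, lapply(entries, function(e)
      as.data.frame(e, stringsAsFactors = FALSE)))
    manifest <- do.call(rbind, lapply(manifest, function(m)
      as.data.frame(m, stringsAsFactors = FALSE)))

    # assign sequences: retained entries first, so duplicate sharing is
    # among retained entries (what the distinct-sequence count measures)
    n <- nrow(entries)
    retained_idx <- which(manifest$expected_retained)
    n_dup <- floor(dup_fraction * length(retained_idx))
    seqs <- character(n)
    for (k in seq_along(retained_idx)) {
      i <- retained_idx[k]
      if (k > 1 && n_dup > 0 && k > length(retained_idx) - n_dup) {
        # duplicate of a distinct earlier retained sequence
        donor <- retained_idx[k - (length(retained_idx) - n_dup)]
        seqs[i] <- seqs[donor]
      } else {
        seqs[i] <- random_protein(sample(60:120, 1))
      }
    }
    for (i in setdiff(seq_len(n), retained_idx)) {
      seqs[i] <- random_protein(sample(60:120, 1))
    }
    entries$sequence_id <- sprintf("sid_%04d", seq_len(n))
    # shared sequences share a sequence_id, as a real export would
    first_of <- match(seqs, seqs)
    entries$sequence_id <- entries$sequence_id[first_of]
    manifest$sequence_id <- entries$sequence_id

    fasta <- setNames(seqs[!duplicated(entries$sequence_id)],
                      entries$sequence_id[!duplicated(entries$sequence_id)])

    kept <- entries[manifest$expected_retained, , drop = FALSE]
    kept_seq <- seqs[manifest$expected_retained]
    per_source <- data.frame(
      source = sort(unique(kept$source)),
      stringsAsFactors = FALSE)
    per_source$n_entries <- vapply(per_source$source, function(s)
      sum(kept$source == s), 0L)
    per_source$n_distinct <- vapply(per_source$source, function(s)
      length(unique(kept_seq[kept$source == s])), 0L)

    out <- list(
      entries = entries,
      sequences = fasta,
      manifest = manifest,
      expected = list(n_retained = nrow(kept),
                      n_distinct = length(unique(kept_seq)),
                      per_source = per_source))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_entries_tsv(entries, file.path(dir, "entries.tsv"))
      write_fasta_chr(fasta, file.path(dir, "proteins.fasta"), "AA")
      write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    out
  })
}

#' Specify a gene to plant in a synthetic genome
#'
#' Modes: `as_predicted_protein` (gene in the genome *and* its protein in
#' the proteome -- the fully annotated case, which the six-frame
#' redundancy filter should suppress), `as_intact_orf` (gene in the
#' genome but missing from the proteome -- a missed gene),
#' `as_frameshifted_orf` (one nucleotide deleted mid-gene and the protein
#' omitted -- a frameshift error splitting the gene across two reading
#' frames), and `absent` (protein known to the curated database but not
#' present at all).
#'
#' @param name plant identifier.
#' @param protein amino-acid sequence of the (curated) protein.
#' @param mode one of the four modes above.
#' @param mutation_rate per-residue substitution rate in `[0, 1)` applied
#'   to the planted copy (0 = exact).
#' @return a `cb_plant` specification.
#' @export
plant_spec <- function(name, protein,
                       mode = c("as_predicted_protein", "as_intact_orf",
                                "as_frameshifted_orf", "absent"),
                       mutation_rate = 0) {
  mode <- match.arg(mode)
  stopifnot(mutation_rate >= 0, mutation_rate < 1)
  validate_aa(protein, sprintf("plant %s protein", name))
  structure(list(name = name, protein = protein, mode = mode,
                 mutation_rate = mutation_rate), class = "cb_plant")
}

inv_codon_table <- function(genetic_code = "11") {
  key <- paste0("inv_codon_", genetic_code)
  if (!is.null(.cb_cache[[key]])) return(.cb_cache[[key]])
  gc_tab <- Biostrings::getGeneticCode(genetic_code)
  inv <- split(names(gc_tab), unname(gc_tab))
  inv <- inv[names(inv) != "*"]
  .cb_cache[[key]] <- inv
  inv
}

reverse_translate <- function(aa, genetic_code = "11") {
  inv <- inv_codon_table(genetic_code)
  res <- strsplit(aa, "")[[1]]
  if (!all(res %in% names(inv))) {
    cb_error("cb_alphabet_error",
             "protein contains residues with no codon (e.g. X)")
  }
  vapply(res, function(r) {
    opts <- inv[[r]]
    opts[sample.int(length(opts), 1)]
  }, "", USE.NAMES = FALSE)
}

mutate_protein <- function(aa, rate) {
  if (rate <= 0) return(aa)
  res <- strsplit(aa, "")[[1]]
  hit <- runif(length(res)) < rate
  res[hit] <- vapply(res[hit], function(r)
    sample(setdiff(AA20, r), 1), "", USE.NAMES = FALSE)
  paste(res, collapse = "")
}

# Engineer the frameshift junction so the two halves are cleanly
# separated in the six-frame translation: one nucleotide (the first base
# of codon k+1) is deleted, and codons are chosen so that (a) the
# original frame hits a stop immediately after the junction and (b) the
# shifted frame hits a stop two codons upstream of its clean stretch.
# Returns NULL when position k does not admit such codons.
frameshift_codons_at <- function(res, k, codons) {
  n <- length(res)
  if (k < 2 || k > n - 2) return(NULL)
  inv <- inv_codon_table()
  # codon k-1 must end in T
  c_km1 <- inv[[res[k - 1]]]
  c_km1 <- c_km1[substr(c_km1, 3, 3) == "T"]
  # codon k must start with AA, AG or GA (completing stop TAA/TAG/TGA)
  c_k <- inv[[res[k]]]
  c_k <- c_k[substr(c_k, 1, 2) %in% c("AA", "AG", "GA")]
  # codon k+1 must have middle base T and third base A or G
  c_kp1 <- inv[[res[k + 1]]]
  c_kp1 <- c_kp1[substr(c_kp1, 2, 2) == "T" &
                 substr(c_kp1, 3, 3) %in% c("A", "G")]
  if (!length(c_km1) || !length(c_k) || !length(c_kp1)) return(NULL)
  for (p in c_kp1) {
    # stop after junction: (p2, p3, q1); TA -> q1 in {A, G}; TG -> q1 = A
    q1_ok <- if (substr(p, 3, 3) == "A") c("A", "G") else "A"
    c_kp2 <- inv[[res[k + 2]]]
    c_kp2 <- c_kp2[substr(c_kp2, 1, 1) %in% q1_ok]
    if (length(c_kp2)) {
      out <- codons
      out[k - 1] <- c_km1[1]
      out[k] <- c_k[1]
      out[k + 1] <- p
      out[k + 2] <- c_kp2[1]
      return(out)
    }
  }
  NULL
}

#' Build a synthetic genome with planted genes
#'
#' Reverse-translates each planted protein (uniform synonymous codon
#' choice under the seed), optionally mutates it, and inserts it at a
#' random non-overlapping locus on a random strand of an i.i.d.
#' background contig with the requested GC content. For
#' `as_frameshifted_orf` plants one nucleotide is deleted near the middle
#' of the gene, at a junction engineered so the six-frame translation
#' yields one stop-free stretch covering the N-terminal portion and a
#' second covering the C-terminal portion, mirroring what a real
#' frameshift sequencing error does to a gene model. The proteome
#' contains the proteins of `as_predicted_protein` plants plus
#' `n_decoy_proteins` unrelated random proteins.
#'
#' @param plants list of [plant_spec()] objects.
#' @param background_kb background contig length in kb.
#' @param gc_frac background GC content in `(0, 1)`.
#' @param seed integer seed; fixed seed gives identical bytes.
#' @param n_decoy_proteins unrelated proteins added to the proteome.
#' @param genetic_code NCBI genetic code id (must match the six-frame
#'   stage so planted genes are stop-free in frame).
#' @return list with `genome` (named character vector, one contig),
#'   `proteome` (data.frame `protein_id`, `description`, `sequence`) and
#'   `truth` (data.frame `name`, `mode`, `contig_id`, `strand`,
#'   `nt_start`, `nt_end`, `break_residue`, `in_proteome`,
#'   `expected_sixframe` -- `full`, `two_frames`, `suppressed` or
#'   `none`).
#' @export
make_genome_with_plants <- function(plants, background_kb = 30,
                                    gc_frac = 0.5, seed = 1,
                                    n_decoy_proteins = 5,
                                    genetic_code = "11") {
  stopifnot(all(vapply(plants, inherits, TRUE, "cb_plant")))
  with_seed(seed, {
    bg_len <- as.integer(background_kb * 1000)
    inserts <- list()
    truth <- list()
    proteome <- list()

    for (pl in plants) {
      if (pl$mode == "absent") {
        truth[[length(truth) + 1]] <- list(
          name = pl$name, mode = pl$mode, contig_id = "", strand = "",
          nt_start = NA_integer_, nt_end = NA_integer_,
          break_residue = NA_integer_, in_proteome = FALSE,
          expected_sixframe = "none")
        next
      }
      aa <- mutate_protein(pl$protein, pl$mutation_rate)
      codons <- reverse_translate(aa, genetic_code)
      n <- length(codons)
      break_res <- NA_integer_
      if (pl$mode == "as_frameshifted_orf") {
        res <- strsplit(aa, "")[[1]]
        # both halves must clear the 30-aa reading-frame threshold
        lo <- max(2L, 30L)
        hi <- min(n - 2L, n - 31L)
        if (lo > hi) {
          cb_error("cb_fixture_error",
                   sprintf("plant %s too short to frameshift", pl$name))
        }
        mid <- (lo + hi) %/% 2L
        ks <- lo:hi
        ks <- ks[order(abs(ks - mid))]
        done <- FALSE
        for (k in ks) {
          adj <- frameshift_codons_at(res, k, codons)
          if (!is.null(adj)) {
            codons <- adj
            break_res <- k
            done <- TRUE
            break
          }
        }
        if (!done) {
          cb_error("cb_fixture_error",
                   sprintf("no frameshift junction found for plant %s",
                           pl$name))
        }
        gene <- paste(codons, collapse = "")
        # delete the first base of codon k+1
        pos <- 3L * break_res + 1L
        gene <- paste0(substr(gene, 1, pos - 1),
                       substr(gene, pos + 1, nchar(gene)))
      } else {
        gene <- paste(codons, collapse = "")
      }
      inserts[[length(inserts) + 1]] <- list(plant = pl, gene = gene,
                                             break_res = break_res)
      if (pl$mode == "as_predicted_protein") {
        proteome[[length(proteome) + 1]] <- list(
          protein_id = pl$name,
          description = sprintf("predicted protein %s", pl$name),
          sequence = pl$protein)
      }
    }

    total_insert <- sum(vapply(inserts, function(x) nchar(x$gene), 0))
    if (bg_len < 3 * total_insert) {
      cb_error("cb_fixture_error",
               "background too short for the requested plants")
    }

    background <- paste(sample(
      c("A", "T", "G", "C"), bg_len, replace = TRUE,
      prob = c((1 - gc_frac) / 2, (1 - gc_frac) / 2,
               gc_frac / 2, gc_frac / 2)), collapse = "")

    # non-overlapping random loci (insertion, so coordinates accumulate)
    lens <- vapply(inserts, function(x) nchar(x$gene), 0)
    ord <- seq_along(inserts)
    ok <- FALSE
    for (try in 1:200) {
      starts <- sort(sample.int(bg_len - 1L, length(inserts)))
      if (length(starts) < 2 ||
          all(diff(starts) > utils::head(lens[ord], -1) + 60)) {
        ok <- TRUE
        break
      }
    }
    if (!ok && length(inserts)) {
      cb_error("cb_fixture_error", "could not place plants without overlap")
    }

    contig <- background
    offset <- 0L
    for (i in seq_along(inserts)) {
      ins <- inserts[[i]]
      strand <- sample(c("+", "-"), 1)
      g <- if (strand == "+") ins$gene else revcomp_chr(ins$gene)
      at <- starts[i] + offset
      contig <- paste0(substr(contig, 1, at), g,
                       substr(contig, at + 1, nchar(contig)))
      truth[[length(truth) + 1]] <- list(
        name = ins$plant$name, mode = ins$plant$mode,
        contig_id = "contig_1", strand = strand,
        nt_start = at + 1L, nt_end = at + nchar(g),
        break_residue = ins$break_res,
        in_proteome = ins$plant$mode == "as_predicted_protein",
        expected_sixframe = switch(ins$plant$mode,
          as_predicted_protein = "suppressed",
          as_intact_orf = "full",
          as_frameshifted_orf = "two_frames"))
      offset <- offset + nchar(g)
    }

    for (d in seq_len(n_decoy_proteins)) {
      proteome[[length(proteome) + 1]] <- list(
        protein_id = sprintf("decoy_%03d", d),
        description = "hypothetical protein",
        sequence = random_protein(sample(150:350, 1)))
    }

    truth <- do.call(rbind, lapply(truth, function(x)
      as.data.frame(x, stringsAsFactors = FALSE)))
    proteome <- if (length(proteome)) {
      do.call(rbind, lapply(proteome, function(x)
        as.data.frame(x, stringsAsFactors = FALSE)))
    } else {
      data.frame(protein_id = character(), description = character(),
                 sequence = character(), stringsAsFactors = FALSE)
    }

    list(genome = c(contig_1 = contig), proteome = proteome, truth = truth)
  })
}
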