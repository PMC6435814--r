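# Synthetic-data generators: manifest soundness, duplicate bookkeeping,
# determinism, and planted-gene geometry.

test_that("fixture manifest decisions match the ingestion filters exactly", {
  fx <- make_curated_fixture(seed = 301)
  ent <- read_entries_tsv_from(fx)
  kept <- apply_source_filters(ent)
  expect_setequal(kept$entry_id,
                  fx$manifest$entry_id[fx$manifest$expected_retained])
  db <- build_curated_db(kept, fx$sequences)
  expect_equal(nrow(db$entries), fx$expected$n_retained)
  expect_equal(nrow(db$sequences), fx$expected$n_distinct)
  expect_equal(db$per_source_counts$source, fx$expected$per_source$source)
  expect_equal(db$per_source_counts$n_entries,
               fx$expected$per_source$n_entries)
  expect_equal(db$per_source_counts$n_distinct,
               fx$expected$per_source$n_distinct)
})

test_that("dup_fraction controls the distinct-sequence count", {
  # a rule-free source so all entries are retained: 8 entries at 25%
  # duplication leave 6 distinct sequences
  fx <- make_curated_fixture(sources = "EcoCyc", n_entries_per_source = 8,
                             dup_fraction = 0.25, seed = 302)
  expect_equal(fx$expected$n_retained, 8)
  expect_equal(fx$expected$n_distinct, 6)
  db <- build_curated_db(apply_source_filters(read_entries_tsv_from(fx)),
                         fx$sequences)
  expect_equal(nrow(db$sequences), 6)

  none <- make_curated_fixture(sources = "EcoCyc", n_entries_per_source = 8,
                               dup_fraction = 0, seed = 302)
  expect_equal(none$expected$n_distinct, none$expected$n_retained)
})

test_that("fixtures are byte-identical under a fixed seed", {
  a <- make_curated_fixture(seed = 303)
  b <- make_curated_fixture(seed = 303)
  expect_identical(a, b)
  ga <- make_genome_with_plants(list(plant_spec("p", a$sequences[[1]],
                                                "as_intact_orf")),
                                background_kb = 5, seed = 17)
  gb <- make_genome_with_plants(list(plant_spec("p", a$sequences[[1]],
                                                "as_intact_orf")),
                                background_kb = 5, seed = 17)
  expect_identical(ga, gb)
  gc_ <- make_genome_with_plants(list(plant_spec("p", a$sequences[[1]],
                                                 "as_intact_orf")),
                                 background_kb = 5, seed = 18)
  expect_false(identical(ga$genome, gc_$genome))
})

test_that("planted intact genes translate back exactly at the truth locus", {
  set.seed(304)
  prot <- rand_aa(120)
  gx <- make_genome_with_plants(list(plant_spec("p", prot, "as_intact_orf")),
                                background_kb = 5, seed = 305)
  tr <- gx$truth
  expect_equal(tr$mode, "as_intact_orf")
  gene <- substr(gx$genome[[tr$contig_id]], tr$nt_start, tr$nt_end)
  if (tr$strand == "-") gene <- curatedblast:::revcomp_chr(gene)
  tab <- curatedblast:::codon_table("11")
  starts <- seq(1, nchar(gene), 3)
  expect_equal(paste(tab[substring(gene, starts, starts + 2)],
                     collapse = ""), prot)
  expect_false(tr$in_proteome)
  expect_equal(nrow(gx$proteome[gx$proteome$protein_id == "p", ]), 0)
})

test_that("an intact unannotated plant is recovered with >= 95% coverage", {
  set.seed(306)
  prot <- rand_aa(150)
  gx <- make_genome_with_plants(list(plant_spec("p", prot, "as_intact_orf")),
                                background_kb = 6, seed = 307)
  frames <- extract_reading_frames(gx$genome)
  hits <- align_all(list(list(seq_id = "c", sequence = prot)),
                    data.frame(target_id = frames$frame_id,
                               target_kind = "frame",
                               sequence = frames$aa_sequence,
                               stringsAsFactors = FALSE))
  kept <- filter_sixframe_hits(hits, curatedblast:::empty_hits())
  expect_gte(max(kept$coverage_frac), 0.95)
})

test_that("a frameshifted plant leaves two clean stop-free halves", {
  set.seed(308)
  prot <- rand_aa(350)
  gx <- make_genome_with_plants(
    list(plant_spec("p", prot, "as_frameshifted_orf")),
    background_kb = 10, seed = 309)
  tr <- gx$truth
  k <- tr$break_residue
  expect_true(k > 0.25 * 350 && k < 0.75 * 350)
  # the planted region is one nucleotide short of 3 x protein length
  expect_equal(tr$nt_end - tr$nt_start + 1, 3 * 350 - 1)
  frames <- extract_reading_frames(gx$genome)
  # two frames must each contain one half of the protein verbatim
  n_half <- substr(prot, 1, k)
  c_half <- substr(prot, k + 2, 350)
  expect_true(any(grepl(n_half, frames$aa_sequence, fixed = TRUE)))
  expect_true(any(grepl(c_half, frames$aa_sequence, fixed = TRUE)))
  expect_false(any(grepl(prot, frames$aa_sequence, fixed = TRUE)))
})

test_that("absent plants leave no trace in genome or proteome", {
  set.seed(310)
  prot <- rand_aa(100)
  gx <- make_genome_with_plants(
    list(plant_spec("gone", prot, "absent"),
         plant_spec("there", rand_aa(80), "as_predicted_protein")),
    background_kb = 4, seed = 311)
  expect_equal(gx$truth$expected_sixframe[gx$truth$name == "gone"], "none")
  expect_false(grepl(prot, gx$genome[[1]], fixed = TRUE))
  expect_false("gone" %in% gx$proteome$protein_id)
  expect_true("there" %in% gx$proteome$protein_id)
})

test_that("mutation rate diverges the planted copy but not the curated one", {
  set.seed(312)
  prot <- rand_aa(200)
  gx <- make_genome_with_plants(
    list(plant_spec("p", prot, "as_intact_orf", mutation_rate = 0.1)),
    background_kb = 6, seed = 313)
  tr <- gx$truth
  gene <- substr(gx$genome[[1]], tr$nt_start, tr$nt_end)
  if (tr$strand == "-") gene <- curatedblast:::revcomp_chr(gene)
  tab <- curatedblast:::codon_table("11")
  starts <- seq(1, nchar(gene), 3)
  planted <- paste(tab[substring(gene, starts, starts + 2)], collapse = "")
  ndiff <- sum(strsplit(planted, "")[[1]] != strsplit(prot, "")[[1]])
  expect_gt(ndiff, 5)
  expect_lt(ndiff, 50)
})

test_that("fixture writing produces the documented files", {
  dir <- withr::local_tempdir()
  fx <- make_curated_fixture(seed = 314, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("entries.tsv",
                                               "proteins.fasta",
                                               "manifest.tsv")))))
  ent <- read_entries_tsv(file.path(dir, "entries.tsv"))
  expect_equal(nrow(ent), nrow(fx$entries))
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(sum(man$expected_retained), fx$expected$n_retained)
})
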