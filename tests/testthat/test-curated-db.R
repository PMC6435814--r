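# Database ingestion: per-source retention rules, sequence
# deduplication, and the on-disk round trip.

test_that("each source's retention rule keeps and drops the right entries", {
  cases <- list(
    # source, overrides, expected retained
    list("BRENDA", list(uniprot_id = ""), FALSE),
    list("BRENDA", list(publication_ids = ""), FALSE),
    list("BRENDA", list(is_fragment = TRUE), FALSE),
    list("BRENDA", list(), TRUE),
    list("MetaCyc", list(uniprot_id = ""), FALSE),
    list("MetaCyc", list(is_fragment = TRUE), FALSE),
    list("MetaCyc", list(), TRUE),
    list("CAZy", list(ec_numbers = ""), FALSE),
    list("CAZy", list(description = "putative endoglucanase fragment"), FALSE),
    list("CAZy", list(description = "endoglucanase with frameshift"), FALSE),
    list("CAZy", list(description = "endoglucanase"), TRUE),
    list("CharProtDB", list(entry_type = "trusted_uniprot"), FALSE),
    list("CharProtDB", list(entry_type = "trusted_aspgd"), FALSE),
    list("CharProtDB", list(entry_type = "trusted"), TRUE),
    list("REBASE", list(specificity_known = FALSE), FALSE),
    list("REBASE", list(specificity_known = TRUE), TRUE),
    list("SwissProt", list(has_experimental_evidence = FALSE), FALSE),
    list("SwissProt", list(), TRUE),
    # no stated rule: everything passes, even flagged fragments
    list("EcoCyc", list(is_fragment = TRUE, uniprot_id = "",
                        publication_ids = ""), TRUE),
    list("FitnessBrowser", list(is_fragment = TRUE), TRUE),
    list("other", list(is_fragment = TRUE, ec_numbers = ""), TRUE))
  for (cs in cases) {
    args <- c(list(entry_id = "e1", source = cs[[1]]), cs[[2]])
    if (is.null(args$description)) args$description <- "endoglucanase"
    ent <- do.call(make_entries, args)
    out <- apply_source_filters(ent)
    expect_equal(nrow(out) == 1, cs[[3]],
                 label = sprintf("%s with %s", cs[[1]],
                                 paste(names(cs[[2]]), collapse = "/")))
  }
})

test_that("BRENDA entry with publications but no UniProt id is excluded", {
  ent <- make_entries("b1", "BRENDA", "oxidase", uniprot_id = "",
                      publication_ids = "PMID:1;PMID:2")
  expect_equal(nrow(apply_source_filters(ent)), 0)
})

test_that("filtering preserves order, is idempotent, and handles empty input", {
  ent <- rbind(
    make_entries("a1", "CAZy", "endoglucanase"),
    make_entries("a2", "CAZy", "cellulase fragment"),
    make_entries("a3", "EcoCyc", "kinase"),
    make_entries("a4", "REBASE", "methyltransferase",
                 specificity_known = FALSE),
    make_entries("a5", "BRENDA", "dehydrogenase"))
  once <- apply_source_filters(ent)
  expect_equal(once$entry_id, c("a1", "a3", "a5"))
  twice <- apply_source_filters(once)
  expect_equal(twice$entry_id, once$entry_id)
  empty <- apply_source_filters(ent[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("unknown source tags are rejected with a named error", {
  ent <- make_entries("x1", "NotADatabase", "enzyme")
  expect_error(apply_source_filters(ent), class = "cb_source_error")
  expect_error(apply_source_filters(make_entries("x1", "EcoCyc", "enzyme"),
                                    source = "BRENDA"),
               class = "cb_source_error")
})

test_that("identical sequences collapse to one distinct sequence", {
  ent <- make_entries(c("e1", "e2", "e3", "e4"), "EcoCyc",
                      paste("desc", 1:4),
                      sequence_id = c("s1", "s2", "s3", "s4"))
  seqs <- c(s1 = "MKVILAAGGGLLW", s2 = "MNPQRSTVWYACD",
            s3 = "MKVILAAGGGLLW", s4 = "MMMMCCCCDDDDE")
  db <- build_curated_db(ent, seqs)
  expect_equal(nrow(db$sequences), 3)
  expect_equal(nrow(db$entries), 4)
  shared <- db$entries$seq_id[db$entries$entry_id %in% c("e1", "e3")]
  expect_equal(shared[1], shared[2])
  expect_equal(db$per_source_counts$n_entries, 4L)
  expect_equal(db$per_source_counts$n_distinct, 3L)
})

test_that("sequence normalization uppercases and strips one trailing stop", {
  ent <- make_entries(c("e1", "e2"), "EcoCyc", c("d1", "d2"),
                      sequence_id = c("s1", "s2"))
  db <- build_curated_db(ent, c(s1 = "MKV*", s2 = "mkv"))
  expect_equal(nrow(db$sequences), 1)
  expect_equal(db$sequences$sequence, "MKV")
  expect_equal(length(unique(db$entries$seq_id)), 1)
})

test_that("entries with internal stops or unresolvable sequences are dropped", {
  ent <- make_entries(c("e1", "e2", "e3"), "EcoCyc", paste("d", 1:3),
                      sequence_id = c("s1", "s2", "missing"))
  expect_warning(db <- build_curated_db(ent, c(s1 = "MKV", s2 = "MK*V")),
                 "dropped")
  expect_equal(nrow(db$entries), 1)
  expect_equal(db$build_metadata$n_dropped_unresolved, 1)
  expect_equal(db$build_metadata$n_dropped_bad_residue, 1)
})

test_that("empty input yields an empty database with zero counts", {
  ent <- make_entries(character(0), character(0), character(0))
  db <- build_curated_db(ent, c(s1 = "MKV"))
  expect_equal(nrow(db$entries), 0)
  expect_equal(nrow(db$sequences), 0)
  expect_equal(nrow(db$per_source_counts), 0)
})

test_that("distinct sequences never exceed retained entries", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(3:20, 1)
    pool <- replicate(max(2, n %/% 2), rand_aa(30))
    ent <- make_entries(sprintf("e%d", 1:n), "EcoCyc", sprintf("d%d", 1:n),
                        sequence_id = sprintf("s%d", 1:n))
    db <- build_curated_db(ent, setNames(sample(pool, n, TRUE),
                                         sprintf("s%d", 1:n)))
    expect_lte(nrow(db$sequences), nrow(db$entries))
    expect_equal(sum(db$per_source_counts$n_entries), nrow(db$entries))
  }
})

test_that("deduplication is order-independent", {
  set.seed(77)
  seqs <- setNames(c("MKVILA", "MNPQRS", "MKVILA", "MAACDE", "MNPQRS"),
                   sprintf("s%d", 1:5))
  ent <- make_entries(sprintf("e%d", 1:5), "EcoCyc", sprintf("d%d", 1:5),
                      sequence_id = sprintf("s%d", 1:5))
  db1 <- build_curated_db(ent, seqs)
  perm <- sample(5)
  db2 <- build_curated_db(ent[perm, ], seqs)
  expect_equal(db1$sequences, db2$sequences)
  expect_equal(db1$entries, db2$entries)
  expect_equal(db1$per_source_counts, db2$per_source_counts)
})

test_that("database save/load round-trips field-identically", {
  fx <- make_curated_fixture(seed = 5)
  ent <- apply_source_filters(read_entries_tsv_from(fx))
  db <- build_curated_db(ent, fx$sequences)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "db")
  save_curated_db(db, path)
  db2 <- load_curated_db(path)
  expect_equal(db2$entries, db$entries)
  expect_equal(db2$sequences, db$sequences)
  expect_equal(db2$per_source_counts, db$per_source_counts)
  expect_equal(db2$build_metadata, db$build_metadata)
})

test_that("loading a missing or truncated database raises a load error", {
  expect_error(load_curated_db(file.path(tempdir(), "no_such_db")),
               class = "cb_load_error")
  fx <- make_curated_fixture(seed = 6, n_entries_per_source = 2)
  db <- build_curated_db(apply_source_filters(read_entries_tsv_from(fx)),
                         fx$sequences)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "db")
  save_curated_db(db, path)
  # truncate the entries table to simulate a partial write
  lines <- readLines(file.path(path, "entries.tsv"))
  writeLines(lines[1:2], file.path(path, "entries.tsv"))
  expect_error(load_curated_db(path), class = "cb_load_error")
})

test_that("build stats table mirrors per-source counts with a Total row", {
  fx <- make_curated_fixture(seed = 8)
  db <- build_curated_db(apply_source_filters(read_entries_tsv_from(fx)),
                         fx$sequences)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "stats.tsv")
  write_build_stats(db, f)
  tab <- read.delim(f)
  expect_equal(tab$source[nrow(tab)], "Total")
  expect_equal(tab$n_entries[nrow(tab)], nrow(db$entries))
  expect_equal(tab$n_distinct[nrow(tab)], nrow(db$sequences))
  expect_true(all(tab$n_distinct <= tab$n_entries))
})
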