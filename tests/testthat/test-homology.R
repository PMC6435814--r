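# Built-in alignment engine: optimality, identity/coverage/E-value
# definitions, the engine contract, and the tabular adapter.

test_that("self-alignment gives identity 1, full coverage, score 1", {
  set.seed(61)
  for (len in c(3, 25, 120)) {
    a <- if (len == 3) "MKV" else rand_aa(len)
    aln <- builtin_local_align(a, a)
    expect_equal(aln$identity_frac, 1)
    expect_equal(c(aln$a_start, aln$a_end), c(1, len))
    expect_equal(aln$n_columns, len)
    hits <- align_all(list(list(seq_id = "c", sequence = a)),
                      data.frame(target_id = "t", target_kind = "protein",
                                 sequence = a, stringsAsFactors = FALSE))
    expect_equal(nrow(hits), 1)
    expect_equal(hits$identity_frac, 1)
    expect_equal(hits$coverage_frac, 1)
    expect_equal(hits$score, 1)
  }
})

test_that("score is identity times curated coverage", {
  # a target identical to the first half of a 100-residue curated protein:
  # coverage 0.50, identity 1, score 0.50
  set.seed(8)
  cu <- rand_aa(100)
  half <- substr(cu, 1, 50)
  hits <- align_all(list(list(seq_id = "c", sequence = cu)),
                    data.frame(target_id = "t", target_kind = "protein",
                               sequence = half, stringsAsFactors = FALSE))
  expect_equal(hits$coverage_frac, 0.5)
  expect_equal(hits$score, hits$identity_frac * hits$coverage_frac)
  expect_equal(hits$score, 0.5)
  expect_equal(hits$coverage_frac,
               (hits$curated_end - hits$curated_start + 1) / 100)
  # the ranking key for a moderate hit: 43% id x 38% cov = 0.1634
  expect_equal(0.43 * 0.38, 0.1634)
})

test_that("raw scores match an exhaustive dynamic-programming oracle", {
  set.seed(303)
  for (r in 1:60) {
    a <- rand_aa(sample(5:60, 1))
    b <- rand_aa(sample(5:60, 1))
    aln <- builtin_local_align(a, b)
    expect_equal(aln$score, sw_oracle_score(a, b),
                 label = sprintf("pair %d", r))
  }
})

test_that("gap-containing optima are found (including affine gap costs)", {
  # deletion of a block: alignment must bridge it with one affine gap
  a <- "MKVILAAGGGWWLLNPQRSTEE"
  b <- paste0(substr(a, 1, 10), substr(a, 16, 22))
  aln <- builtin_local_align(a, b)
  expect_equal(aln$score, sw_oracle_score(a, b))
  expect_gt(aln$n_columns, nchar(b))
  expect_lt(aln$identity_frac, 1) # gap columns count in the denominator
})

test_that("no positive-scoring pair means no hit", {
  hits <- align_all(list(list(seq_id = "c", sequence = "WWWWWWWWWW")),
                    data.frame(target_id = "t", target_kind = "protein",
                               sequence = "GGGGGGGGGG",
                               stringsAsFactors = FALSE))
  expect_equal(nrow(hits), 0)
})

test_that("hits above the E-value threshold are discarded", {
  set.seed(12)
  cu <- rand_aa(300)
  targets <- data.frame(target_id = sprintf("t%d", 1:20),
                        target_kind = "protein",
                        sequence = replicate(20, rand_aa(250)),
                        stringsAsFactors = FALSE)
  curated <- list(list(seq_id = "c", sequence = cu))
  strict <- align_all(curated, targets, max_evalue = 0.01)
  loose <- align_all(curated, targets, max_evalue = 10)
  # random proteins should not reach E <= 0.01 against this search space
  expect_equal(nrow(strict), 0)
  expect_gt(nrow(loose), 0)
  expect_true(all(loose$evalue <= 10))
  # lowering the threshold never adds hits
  mid <- align_all(curated, targets, max_evalue = 1)
  expect_true(all(paste(mid$curated_seq_id, mid$target_id) %in%
                  paste(loose$curated_seq_id, loose$target_id)))
})

test_that("hit fields satisfy their invariants on random inputs", {
  set.seed(99)
  curated <- lapply(1:3, function(i)
    list(seq_id = sprintf("c%d", i), sequence = rand_aa(80)))
  targets <- data.frame(target_id = sprintf("t%d", 1:5),
                        target_kind = "protein",
                        sequence = c(curated[[1]]$sequence,
                                     replicate(4, rand_aa(90))),
                        stringsAsFactors = FALSE)
  hits <- align_all(curated, targets, max_evalue = 100)
  expect_gt(nrow(hits), 0)
  lens <- setNames(vapply(curated, function(x) nchar(x$sequence), 0),
                   vapply(curated, `[[`, "", "seq_id"))
  expect_true(all(hits$identity_frac > 0 & hits$identity_frac <= 1))
  expect_true(all(hits$coverage_frac > 0 & hits$coverage_frac <= 1))
  expect_true(all(hits$curated_start >= 1))
  expect_true(all(hits$curated_end <= lens[hits$curated_seq_id]))
  expect_true(all(hits$target_start >= 1))
  expect_equal(hits$score, hits$identity_frac * hits$coverage_frac)
  expect_equal(hits$coverage_frac,
               unname((hits$curated_end - hits$curated_start + 1) /
                        lens[hits$curated_seq_id]))
  # one hit per pair at most
  expect_false(anyDuplicated(hits[, c("curated_seq_id", "target_id")]) > 0)
})

test_that("alignment is deterministic across repeated calls", {
  set.seed(15)
  a <- rand_aa(70)
  b <- rand_aa(75)
  r1 <- builtin_local_align(a, b)
  r2 <- builtin_local_align(a, b)
  expect_identical(r1, r2)
})

test_that("invalid residues raise a named error", {
  expect_error(builtin_local_align("MK V", "MKV"),
               class = "cb_alphabet_error")
  expect_error(builtin_local_align("", "MKV"), class = "cb_alphabet_error")
  expect_error(builtin_local_align("MKv", "MKV"),
               class = "cb_alphabet_error")
})

test_that("engine failures surface as engine errors with diagnostics", {
  broken <- structure(function(curated, targets, max_evalue)
    stop("engine exploded"), class = c("cb_engine", "function"))
  expect_error(
    align_all(list(list(seq_id = "c", sequence = "MKVMKV")),
              data.frame(target_id = "t", target_kind = "protein",
                         sequence = "MKVMKV", stringsAsFactors = FALSE),
              engine = broken),
    class = "cb_engine_error")
})

test_that("BLAST-style tabular output maps onto the hit schema", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "hits.tsv")
  writeLines(c(
    "c1\tt1\t90.00\t100\t10\t0\t1\t100\t5\t104\t1e-50\t200",
    "c1\tt1\t80.00\t40\t8\t0\t10\t49\t1\t40\t1e-10\t80",
    "c1\tt2\t43.00\t80\t45\t1\t20\t95\t3\t81\t1e-5\t60"), f)
  hits <- read_blast_tab(f, c(c1 = 200), "protein")
  # best hit per pair only
  expect_equal(nrow(hits), 2)
  t1 <- hits[hits$target_id == "t1", ]
  expect_equal(t1$identity_frac, 0.9)
  expect_equal(t1$coverage_frac, 0.5)
  expect_equal(t1$score, 0.45)
  expect_equal(t1$target_start, 5L)
  t2 <- hits[hits$target_id == "t2", ]
  expect_equal(t2$coverage_frac, (95 - 20 + 1) / 200)
  expect_error(read_blast_tab(f, c(other = 10), "protein"),
               class = "cb_format_error")
})
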