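# curatedblast

Find candidate genes for a capability in a microbial genome without
trusting automated annotations. Given a free-text query,
`curatedblast` first finds **experimentally characterized proteins**
whose curated descriptions match the query, then searches the genome of
interest for proteins similar to them — first among the predicted
proteins, then in the six-frame translation of the nucleotide sequence,
so that genes missed by the gene models (including genes split by
frameshift sequencing errors) are still found.

Hits are ranked by

```
score = identity fraction × coverage fraction of the characterized protein
```

— deliberately not by bit score, which would bias results toward
homologs of longer proteins. A six-frame hit is reported only when its
score is *noticeably better* (strictly > 1.1×) than the same
characterized protein's best score against any predicted protein, and a
reading frame whose best hit is suppressed is dropped entirely; what
survives points at missing or broken gene models.

The package is aimed at microbiologists and genome curators triaging a
genome for a capability ("which genes could reduce perchlorate?",
"is there a histidinol dehydrogenase hiding in a frameshift?") and at
pipeline authors who want the matching, alignment, ranking and
filtering stages as composable R functions.

## What is in the box

| Stage | Functions |
| --- | --- |
| Curated database | `read_entries_tsv`, `apply_source_filters`, `build_curated_db`, `save_curated_db` / `load_curated_db`, `write_build_stats` |
| Query matching | `cb_query`, `description_matches`, `select_curated` |
| Six-frame translation | `extract_reading_frames`, `check_sixframe_eligible`, `write_reading_frames` |
| Alignment | `builtin_local_align` (exact Smith–Waterman, BLOSUM62, affine gaps 11/1, Karlin–Altschul E-values), `align_all`, `aligner_builtin`, `aligner_external`, `read_blast_tab` |
| Ranking & filtering | `rank_protein_hits`, `filter_sixframe_hits`, `rank_frame_hits` |
| Pipeline & reports | `run_pipeline`, `write_report` (TSV/JSON/HTML), `report_to_table`, `read_report_json` |
| Synthetic data | `make_curated_fixture`, `plant_spec`, `make_genome_with_plants` |

The curated database is built from *normalized* per-source tables (one
TSV + FASTA per source) applying each source's retention rule (UniProt
id + publication for BRENDA/MetaCyc, EC number for CAZy, experimental
evidence for Swiss-Prot, known specificity for REBASE, ...); parsing the
native distribution formats of the eight source databases is out of
scope. A command-line interface is installed at
`inst/scripts/curated-blast.R` (search, `build`, and `fixtures`
subcommands).

## A worked example

Build a tiny curated database of three characterized proteins, plant
two of them in a synthetic 20 kb genome — one as a properly annotated
gene, one hidden by a single-nucleotide deletion and absent from the
gene models — and search it:

```r
library(curatedblast)
set.seed(42)
aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
rp <- function(n) paste(sample(aa, n, TRUE), collapse = "")
prot_pcr <- rp(320); prot_fs <- rp(380)

entries <- data.frame(
  entry_id = c("SP001", "SP002", "SP003"), source = "SwissProt",
  description = c("Perchlorate reductase subunit alpha",
                  "Histidinol dehydrogenase", "Chlorite dismutase"),
  organism = "Azospira demo",
  ec_numbers = c("1.97.1.1", "1.1.1.23", "1.13.11.49"),
  publication_ids = "PMID:1", uniprot_id = c("P10001", "P10002", "P10003"),
  entry_type = "", is_fragment = FALSE, specificity_known = TRUE,
  has_experimental_evidence = TRUE,
  sequence_id = c("sq1", "sq2", "sq3"), stringsAsFactors = FALSE)
db <- build_curated_db(apply_source_filters(entries),
                       c(sq1 = prot_pcr, sq2 = prot_fs, sq3 = rp(250)))

gx <- make_genome_with_plants(list(
  plant_spec("PS_0448", prot_pcr, "as_predicted_protein"),
  plant_spec("hidden_hisD", prot_fs, "as_frameshifted_orf")),
  background_kb = 20, seed = 7)

run_pipeline(db, gx$proteome, gx$genome, "perchlorate")
```

```
Curated homology search report for query "perchlorate"
  1 curated sequence(s) matched

Hits to predicted proteins (1):
PS_0448 predicted protein PS_0448  (best score 1.000)
    seq_828907cb1865a67c: 100% id., 100% cov (E = 2.8e-210)

Hits to the six-frame translation (0 frame(s)):
```

The annotated gene is found at 100% identity over 100% of the curated
protein, and the six-frame stage stays silent — the frame containing
the gene scores no better than the predicted protein, so the redundancy
filter suppresses it. The frameshifted gene tells a different story:

```r
run_pipeline(db, gx$proteome, gx$genome, "histidinol dehydrogenase")
```

```
Curated homology search report for query "histidinol dehydrogenase"
  1 curated sequence(s) matched

Hits to predicted proteins (0):

Hits to the six-frame translation (2 frame(s)):
contig_1|+3|15210 contig_1:15210-15986(+) frame 3  (best score 0.524)
    seq_f71e378368109e5a: 100% id., 53% cov (E = 3.3e-130)
contig_1|+1|14632 contig_1:14632-15210(+) frame 1  (best score 0.474)
    seq_f71e378368109e5a: 100% id., 47% cov (E = 8.6e-115)
```

No predicted protein matches, but two adjacent reading frames — in
different frames of the same strand, meeting at the deletion point —
each match one portion of the characterized histidinol dehydrogenase at
100% identity, jointly covering it completely. That two-frame signature
is how a frameshift error (or a missed gene) looks in the report.

Queries support `%` as a wildcard (`chl%reduct` matches "Perchlorate
reductase subunit alpha") and a whole-word mode under which EC numbers
act as single words (`cb_query("1.1.1.1", word_mode = TRUE)`).

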