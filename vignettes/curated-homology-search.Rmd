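---
title: "Finding candidate genes by homology to characterized proteins"
author: "curatedblast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding candidate genes by homology to characterized proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curatedblast)
```

## The problem

Given a microbial genome, a common question is "which genes could provide
capability X?" Automated annotations answer it poorly: they are often
vague, sometimes wrong, and a single predicted function per protein hides
alternatives. `curatedblast` takes a different route. A free-text query
is matched against the *curated descriptions of experimentally
characterized proteins*; the matching proteins — usually from other
organisms — are then aligned against the genome of interest, and the
genome's proteins are ranked as candidates by how well they match a
characterized protein with the activity of interest. For enzymes this
sidesteps substrate-specificity prediction entirely: we never ask what
the candidate does, only what characterized protein it resembles.

A second stage searches the *six-frame translation* of the genome's
nucleotide sequence, so that genes missed by the gene models — whether
never called, or split by a frameshift sequencing error — still surface.

## The curated database

The database unit is the **distinct amino-acid sequence**. Each curated
source contributes *entries* (description, organism, EC numbers,
publications, flags); entries from any source that share an identical
sequence collapse onto one distinct sequence, which is what gets
aligned. Ingestion applies each source's retention rule: BRENDA and
MetaCyc entries need a UniProt identifier and at least one publication
and must not be sequence fragments; CAZy entries need an EC number and
must not mention "fragment" or "frameshift" in their description;
CharProtDB entries of type `trusted_uniprot` (redundant with Swiss-Prot)
or `trusted_aspgd` are dropped; REBASE entries need a known sequence
specificity; Swiss-Prot entries need experimental evidence for their
function. EcoCyc and Fitness Browser entries pass as-is. These
judgements arrive pre-normalized as boolean flags in the input tables:
parsing eight native distribution formats is deliberately out of scope,
since the formats drift while the rules do not.

Sequence identifiers are digests of the normalized sequence string
(uppercased, one trailing `*` stripped, internal stops rejected), so a
database build is reproducible and independent of input order. The
on-disk form is a directory of plain-text files (entries TSV, sequence
FASTA, per-source statistics, JSON metadata with record counts that
detect truncated writes).

## Query semantics

A description matches when it contains the query as a case-insensitive
substring. `%` is the only wildcard and matches any run of characters,
so `chl%reduct` matches "Perchlorate reductase subunit alpha". In
whole-word mode the match must start and end at word boundaries:
`chlorate` then matches "Chlorate reductase" but not "Perchlorate
reductase". We define word characters as letters and digits, plus `.`
and `-` when flanked by letters or digits, so EC numbers such as
`1.1.1.1` behave as single words — the main reason to use word mode.
Two details were genuinely open and are our own choices, documented
here: when wildcards and word mode combine, boundaries are required only
at the two ends of the overall match (the simplest consistent reading),
and characters such as `/` and `+` are word separators. A query
consisting only of `%` is rejected as degenerate.

## Alignment and scoring

Matched curated sequences are the queries; the genome's predicted
proteins (and later its reading frames) are the subjects. The built-in
engine computes the optimal Smith–Waterman local alignment under
BLOSUM62 with affine gaps (open 11, extend 1; a gap of length $L$ costs
$11 + L$), exactly — no seeding or banding heuristics — with a
deterministic tie-break: among equal-scoring optima, smallest query
start, then smallest target start. E-values follow the Karlin–Altschul
formula $E = K m n e^{-\lambda S}$ with the standard gapped
BLOSUM62/11/1 constants ($\lambda = 0.267$, $K = 0.041$) and search
space equal to query length × total target length; hits above
$E = 0.01$ are discarded. Because percent identity has no single
standard definition, we fix one and use it everywhere: identical
columns divided by all alignment columns, gaps included in the
denominator.

Each hit is scored as

$$\text{score} = \text{identity fraction} \times
  \text{coverage fraction of the curated protein},$$

deliberately *not* the bit score: ranking by bit score would
systematically favour homologs of longer proteins, whereas a
high-identity, high-coverage alignment to a short characterized protein
is at least as informative. Coverage is always measured on the curated
(characterized) side — a candidate that matches only one domain of a
characterized multi-domain protein should rank low, whatever fraction
of the *candidate* is covered. One best alignment per (curated, target)
pair is kept; multiple HSPs are not merged.

An external aligner can be plugged in behind the same contract via
BLAST-style 12-column tabular output; all tests run against the
built-in engine.

## The six-frame stage and the redundancy filter

For genomes under 30 Mb (strictly; the stage was designed for bacteria
and archaea and ignores splicing), every maximal stop-free stretch of at
least 30 residues in the six-frame translation becomes a target — no
start codon is required, since the purpose is to catch protein-coding
sequence that the gene models missed, including gene fragments created
by frameshift errors. Translation uses NCBI genetic code 11 by default
(configurable). Ambiguity codes are handled conservatively: a codon
whose disambiguations agree translates normally, disagreement gives
`X`, and any codon that *could* be a stop breaks the stretch — this
prevents runs of `N` from inflating reading frames, at the cost of
splitting a stretch on a rare resolvable ambiguity. Coordinates are
1-based inclusive on the forward strand.

Most six-frame hits merely rediscover annotated genes. The redundancy
filter keeps a frame hit for a curated sequence only when its score is
noticeably better — strictly greater than 1.1× — than that curated
sequence's best score against any predicted protein, taken per distinct
sequence (the aligned unit) and as 0 when there is no protein hit at
all, which is precisely the missing-gene case. If a reading frame's
best hit is discarded, the whole frame is discarded: a frame that is
best explained by an already-annotated gene should not resurface via
its weaker hits. What survives is sorted by best score and reported per
reading frame. In a frameshifted gene, the N- and C-terminal portions
appear as two nearby reading frames with complementary coverage of the
same curated protein — the signature the six-frame stage exists to
expose.

## Synthetic data

The package tests itself on synthetic inputs; no downloads are
involved. `make_curated_fixture()` emits normalized entry tables
exercising every retention rule together with a manifest of expected
decisions and distinct-sequence counts. `make_genome_with_plants()`
reverse-translates chosen proteins (uniform synonymous codon choice
under a seed) and inserts them at random non-overlapping loci on random
strands of an i.i.d. background contig of the requested GC content.
Plant modes mirror the scenarios the tool targets: annotated gene
(protein in the gene models — the six-frame stage must stay silent),
intact unannotated gene, frameshifted gene (one nucleotide deleted
mid-gene, protein omitted from the gene models), and absent.

For frameshifted plants the deletion junction is engineered, via
synonymous codon choice only, so that the original frame hits a stop
immediately after the junction and the shifted frame hits a stop two
codons upstream of its clean stretch. This makes the two reading frames
end cleanly at the break point, so their coverage of the curated
protein is disjoint by construction rather than by luck; the break
position is the admissible position nearest the middle of the protein
(both halves must clear the 30-residue threshold). The background is
i.i.d. nucleotides — adequate for alignment and filtering tests, but it
has no repeats, no codon bias and no operon structure, so passing tests
demonstrate the machinery, not performance on real genomes with
repetitive or biased composition.

## Problem sizes and numerical choices

The test suite verifies six-frame extraction against an independent
translate–split–filter oracle on 100 random genomes of 0.5–10 kb at
30–70% GC, and the alignment engine against an exhaustive
dynamic-programming oracle on 200 random pairs of up to 60 residues;
end-to-end tests use ~25 kb genomes with planted genes of 200–400
residues. These sizes keep the default test run fast while covering
every boundary the algorithms have (stop codons at stretch edges,
frames shorter than the threshold by one codon, scores exactly at the
1.1× boundary, groups of exactly 3 and 4 hits). The redundancy filter
is checked exhaustively against a direct transcription of its two-step
rule over score grids spanning the 1.1× boundary.

Determinism is treated as a feature throughout: identical inputs give
byte-identical reports. This relies on canonical orderings (sequence
digests, lexicographic tie-breaks) rather than input order, and on the
alignment tie-break above.

## Limitations

The built-in engine is exact but quadratic; it is sized for desk-scale
searches (a handful of curated queries against one genome), not for
all-vs-all scans — that is what the external-engine adapter is for. The
E-value model borrows fixed Karlin–Altschul constants rather than
fitting them, which is adequate for a 0.01 cutoff but not for reporting
publication-grade E-values. Remote homology (below roughly 30%
identity) is out of scope: hits that weak are of questionable value for
transferring functional annotations anyway. And the tool can only find
what someone has characterized and curated: a capability provided by a
protein unrelated to any characterized protein with that activity will
not be found, however the query is phrased.
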