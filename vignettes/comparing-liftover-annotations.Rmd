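---
title: "Comparing lifted-over gene annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing lifted-over gene annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftcompare)
```

# The problem

A lift-over tool maps gene annotations from a reference assembly onto a
second assembly of the same or a closely related species, preserving the
feature identifiers. `liftcompare` takes the two assemblies (FASTA) and the
two annotations (GFF3 or GTF) and quantifies what changed: per-transcript
sequence variants and their protein-level consequences, preservation of
gene order, and gene copy-number gain and loss via paralog clustering. The
only compatibility contract is shared feature IDs, so the target annotation
can come from any lift-over tool that preserves them.

Everything below is computed from the inputs alone; no external services,
databases or aligner binaries are involved.

# Input model

Annotations are parsed into a three-level hierarchy: genes, transcript-like
children, and exon/CDS grandchildren. A feature is *transcript-like* when
its parent is a gene, whatever its type string says — real GFF3 uses many
transcript types (mRNA, ncRNA, tRNA, ...), and the analysis only needs the
level, not the label. In GTF input, `gene_id` and `transcript_id`
attributes are promoted to feature IDs; explicit `gene`/`transcript` rows
are optional and spans are inferred from exons when absent. Coordinates are
kept 1-based inclusive throughout, matching the annotation formats, with
conversion confined to the FASTA accessor — this removes the classic
off-by-one trap at the parser boundary.

Spliced sequences are extracted exon-by-exon (sorted by start), then
reverse-complemented as one unit for minus-strand transcripts. CDS
extraction additionally honours the phase of the first CDS segment in
translation order, trimming that many leading bases. A feature that refers
to a sequence absent from its assembly, or that runs past a sequence end,
is a hard error: silently truncating would corrupt every identity number
downstream.

Target-only genes whose ID is `<reference gene>_<n>` are treated as extra
gene copies of that reference gene (the naming convention used by
lift-over copy search; the suffix pattern is configurable). Target-only IDs
that match nothing are reported and excluded from all downstream analyses —
with no reference counterpart there is nothing to compare them to.

# Alignment

Global pairwise alignment is the toolkit's workhorse, so it is implemented
in C++ as a standard three-state Gotoh dynamic program (match/mismatch,
gap-in-a, gap-in-b). A gap run of length $L$ costs
$g_{open} + L \cdot g_{ext}$, the same convention as
`Biostrings::pairwiseAlignment()` (which the test suite uses as an
independent cross-check on scores).

Defaults: nucleotides score match $+1$, mismatch $-1$ (any comparison
involving N, including N/N, scores $-1$ — ambiguity is never rewarded),
gaps $2/1$; proteins use BLOSUM62 with gaps $11/1$. These are the
conventional defaults of the SIMD alignment libraries used in this problem
domain; all are user-configurable because effect counts can shift slightly
with the gap model.

Two numerical choices matter more than the scores themselves:

* **Percent identity** is `matches / alignment columns`. Gap columns count
  against identity. This is the strictest common definition and makes
  identity sensitive to indels, which the variant classification relies
  on.
* **Traceback is deterministic.** Among co-optimal alignments the
  traceback prefers diagonal moves, then gaps in the second sequence, then
  gaps in the first, with a fixed predecessor preference inside each gap
  state. Co-optimal gap placements are exactly the situations that flip a
  variant call (an end-flush deletion reads as a truncation; the same
  deletion shifted inwards reads as an in-frame deletion), so the choice
  is pinned down rather than left to library internals. This preference
  pushes gap runs toward the alignment start, which keeps 5′-terminal
  deletions flush with column 1.

Translation uses the standard genetic code, codon by codon from position 1.
Internal stops are emitted as `*` — they are evidence of a variant, not an
error — a trailing stop is trimmed, and a trailing partial codon is
dropped. No selenocysteine or readthrough handling is attempted.

# Variant classification

Effects are detected on the **CDS alignment**, not the whole-transcript
alignment: the taxonomy is protein-centric, and UTR-only changes should not
masquerade as coding variants. A transcript whose UTR changed but whose CDS
did not therefore reports `identical` with a nucleotide identity below 1;
the output carries both numbers so users can re-bin. The terminal stop
codon is kept in the CDS for the nucleotide alignment (3′-truncation
detection needs it) but trimmed from translations before protein
comparison.

Each maximal gap run in the CDS alignment is classified independently:

* a run in the target touching the first/last alignment column and
  covering the entire start/stop codon (length ≥ 3) is a 5′/3′
  **truncation**;
* any remaining run whose length is not a multiple of 3 is a
  **frameshift**;
* internal runs with length a multiple of 3 are **in-frame deletions**
  (gap in target) or **insertions** (gap in reference).

Point categories come from the sequences and the protein alignment:
**start loss** (target's first codon aligned but not ATG), **stop gain**
(`*` in the translated target strictly before the reference protein's
end), **nonsynonymous** (any protein substitution column), **synonymous**
(nucleotide substitutions with identical proteins).

All detected labels are kept, and the reported effect is the most severe
under the total order

`identical < synonymous < nonsynonymous < inframe_deletion <
inframe_insertion < five_prime_truncation < three_prime_truncation <
start_lost < stop_gained < frameshift`

Only the bottom and top of this order are forced by the reduction itself
(a synonymous variant co-occurring with a frameshift must report
`frameshift`); the middle ranks order categories by expected functional
disruption — truncations remove sequence, start loss likely abolishes
initiation, premature stops and frameshifts destroy the downstream protein
— and the ranking is an argument to `most_severe()` for users who rank
differently. Because a frameshift dominates everything, a compensated
double frameshift still reports `frameshift` while its high protein
identity (reported alongside) reveals that most of the protein is intact.

# Synteny

Shared genes are sorted by chromosome, then start, then gene ID (a
deterministic tie-break for identical starts), and numbered 1..N in each
annotation. Chromosome order is the order of first appearance among that
annotation's genes — file order — independently for each side, since the
two assemblies may name or order chromosomes differently; using list order
rather than string sort avoids the chr10-before-chr2 trap. Unmapped and
extra-copy genes are excluded before ranking, so both ordinal axes are
packed permutations of 1..N.

The dot plot places one point per gene at (reference ordinal, target
ordinal), coloured from green (identity 1) to red (identity at or below a
configurable floor, default 0.5 — points at or past the floor saturate
red), gray for genes without an identity value, with gray separators at
chromosome boundaries. Identity comes from the target annotation's
lift-over identity attribute (`sequence_ID`) when present, otherwise from
realigning the longest isoforms, or is omitted under `--no-align`.

**Off-diagonal points.** Because both axes are packed permutations of the
same N genes, *exactly one* displaced record is impossible in the strict
sense: a bijection of 1..N cannot have a single non-fixed point, and moving
one gene shifts the ordinals of every gene between its old and new
positions by one. Those ±1 shifts are invisible in the plot — the points
stay on their chromosome's diagonal block. `off_diagonal()` therefore
counts the visibly displaced records: genes whose chromosome block index
differs between the annotations, i.e. points outside their own
chromosome's block. Under k cross-chromosome translocations this count is
exactly k. Within-chromosome rearrangements are instead captured by the
edit distance.

The **gene-order edit distance** is the Levenshtein distance between the
two ID sequences (each gene one symbol, computed via R's C-level `adist()`
after encoding genes as single characters). It is computed genome-wide on
the concatenated order by default — "the reference order and the target
order" are single sequences — with a `--per-chromosome` mode that restricts
to genes sharing a chromosome in both annotations. A single translocation
costs 2 (one deletion, one insertion), which is why the worked example's
distance is 2.

# Paralog clustering and copy number

One sequence represents each gene: the translated CDS of its longest
isoform for coding genes, the spliced transcript for noncoding genes
(lengths in amino acids and nucleotides respectively; the two alphabets
are never compared). The longest isoform is the one maximising spliced
length, ties broken by smallest transcript ID.

Two genes are *similar* when their global alignment reaches `min_id`
identity (default 0.9) and coverage is bidirectional at `min_cov` (default
0.9): the shorter sequence must be ≥ `min_cov` of the longer, and inside
the aligned core (between the first and last column where both sequences
have residues) each sequence must contribute ≥ `min_cov` of its residues.
This decomposition — length-ratio bound plus aligned-span bound — is the
alignment-level meaning of "identical across 90% of both of their
lengths".

Clustering is greedy and representative-based: genes are processed in
decreasing sequence length (ties by ID), each joining the first existing
cluster whose representative it matches, else founding a new cluster. With
exact dynamic-programming alignment this is affordable at the scale this
package targets, and it is fully deterministic — processing order and every
tie-break are fixed. The 90/90 criterion is tested against the cluster
representative rather than against all members (single linkage would let
chains of 90%-neighbours bridge families).

Target clusters are derived from reference clusters by removing genes
absent from the target and attaching extra copies to the cluster containing
their source gene — the copy's ID suffix already names its origin, so the
closest-paralog search (highest global-alignment identity between the
copy's target sequence and each member, ties to the smaller gene ID) serves
reporting rather than routing. Clusters that lose every member persist with
a target count of zero, so a run without extra copies still reports
copy-number loss. The summary counts clusters with negative, positive and
zero delta and totals copies lost and gained.

# The fixture generator

`make_reference()` builds the validation world: random intergenic sequence
with embedded genes on both strands across several chromosomes. Coding
genes carry one transcript with 15 nt UTRs and a complete ORF (ATG start,
single stop, no internal stops, 60–120 codons), split into 1–3 exons by
50 nt introns. `apply_mutations()` injects at most one event per gene —
nine single-variant classes plus gene deletion, duplication (with
configurable divergence, default 2% substitutions) and cross-chromosome
translocation — shifting all downstream coordinates consistently and
recording the expected call per gene in a truth table. Both functions are
byte-deterministic given their seed.

Two placement rules guarantee that every expected label is unambiguous:

* internal events sit at codon positions at least 9 nt from the CDS ends
  and inside a single exon (with one codon of contiguous context on each
  side), so indel gap runs cannot slide into a terminus;
* the last two sense codons of every ORF end in C or T while stop codons
  end in A or G, so deleting the stop-codon terminus has a *unique*
  optimal gap placement flush with the alignment end. Without this, a
  chance repeat of the terminal base six positions earlier makes the
  end-flush and shifted-inward placements co-optimal, and the
  diagonal-preferring traceback would read a 3′ truncation as an internal
  in-frame deletion.

What the generator does **not** emulate: repeat content and segmental
duplications (real assemblies' main source of mapping ambiguity),
sequencing error, alternative splicing, overlapping or nested genes, and
lift-over failure modes other than clean deletion. Passing its tests
therefore demonstrates that the *classification logic* is correct on
unambiguous ground truth, not that the upstream mapping step is robust on
repetitive genomes.

Validation problem sizes were chosen to exercise every code path while
keeping the whole suite quick on a laptop: 1,000 random length-≤8 pairs
against a brute-force affine DP oracle (small lengths make exhaustive
verification meaningful; the DP does not change behaviour with length), a
90-gene fixture giving ten independent placements of each effect class,
30-gene/3-chromosome fixtures for 0/1/5 translocations, exhaustive
permutations up to N = 8 for the edit-distance oracle, and six protein
families (2–5 copies, 300 aa, 2% divergence) for cluster recovery.

# Degenerate inputs and edge cases

Aligning two empty sequences is an error; one empty sequence yields an
all-gap alignment. A CDS shorter than one codon cannot be translated and
the transcript falls back to `unmapped`-style missing protein values.
Codons containing ambiguity codes translate to `X`. Annotations failing
structural invariants — duplicate IDs, orphaned children, transcripts
without exons, overlapping CDS segments in one transcript, phases outside
{0,1,2} — are rejected at parse time with the offending feature named.
Empty ID intersection between the annotations aborts the run: the inputs
are not a matching lift-over pair.

# Known limitations

* Alignment is exact DP with quadratic cost; the package targets
  gene-scale sequences (transcripts, CDS, proteins), not chromosome-scale
  alignment.
* The published tool this design follows delegates clustering to a k-mer
  prefiltered heuristic; the greedy-representative clustering here
  implements the same 90/90 contract but can differ on borderline pairs,
  and exact alignment limits it to desk-scale gene sets.
* Effect categories are protein-centric: splice-site disruption,
  regulatory changes and readthrough are out of scope.
* With the default gap parameters, effect *counts* on real data may differ
  slightly from tools using other gap models, since co-optimal alignments
  near run boundaries depend on the penalties; the parameters are exposed
  for exactly this reason.
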