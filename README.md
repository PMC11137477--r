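# liftcompare

Compare a reference genome annotation against the same annotation lifted
onto a second assembly of the same (or a closely related) species.

When genes are mapped between assemblies with a lift-over tool such as
Liftoff or UCSC liftOver, the feature identifiers are preserved, and the
obvious next questions are biological: which transcripts changed sequence,
and do those changes matter for the protein? Is the gene order (synteny)
preserved? Did any gene family gain or lose copies? `liftcompare` answers
all three, for any pair of annotations whose feature IDs match.

## What it computes

**Variants.** Every reference transcript shared with the target is globally
aligned (Needleman–Wunsch with affine gaps, `match +1 / mismatch −1 /
gap open 2 / gap extend 1` for nucleotides, BLOSUM62 `11/1` for proteins)
against its target counterpart. Percent identity is defined strictly as
`matches / alignment columns`, so indels count against identity. For coding
transcripts the CDS and the translated proteins are aligned as well, and
each difference is classified into one of nine effect categories:
synonymous, nonsynonymous, in-frame deletion, in-frame insertion, start
codon loss, 5′ truncation, 3′ truncation, frameshift, and stop codon gain.
A transcript with several variants is reported under its single most severe
effect (a transcript with a synonymous change and a frameshift is reported
as `frameshift`).

**Synteny.** Genes present in both annotations are sorted by chromosome and
start coordinate in each annotation and given ordinal positions 1..N. A dot
plot of (reference ordinal, target ordinal) — coloured green→red by
sequence identity, with gray lines separating the chromosomes — shows
collinearity at a glance, and the Levenshtein edit distance between the two
gene orders quantifies it.

**Clusters.** Reference genes are clustered into paralog families (protein
sequences for coding genes, transcript sequences for noncoding genes;
longest isoform per gene) under the criterion that members are ≥ 90%
identical across ≥ 90% of both of their lengths (both thresholds
adjustable). Target clusters are derived by dropping genes lost from the
target and attaching extra gene copies (IDs like `gene_1`, the lift-over
copy-naming convention) to the cluster of their source gene; per-cluster
copy-number deltas summarise gene gain and loss.

A seedable fixture generator (`make_reference()`, `apply_mutations()`)
builds matched synthetic assembly/annotation pairs with known injected
mutations of every class, so the whole toolkit is testable without any
downloads.

## Worked example

Generate the standard 50-gene fixture (one injected event of every class)
and run all three modules:

```r
library(liftcompare)
fx <- make_standard_fixture(seed = 1)
write_fixture(fx, "fixture")
run_cli(c("all", "-r", "fixture/ref.fa", "-t", "fixture/target.fa",
          "-rg", "fixture/ref.gff3", "-tg", "fixture/target.gff3",
          "-o", "out", "--edit-distance"))
```

which logs

```
49 shared genes, 1 unmapped, 2 extra copies
variants: identical=30 synonymous=1 nonsynonymous=1 inframe_deletion=1
  inframe_insertion=1 five_prime_truncation=1 three_prime_truncation=1
  start_lost=1 stop_gained=1 frameshift=1 unmapped=1
synteny: edit distance 2
clusters: 50 clusters, 1 copies lost, 2 gained
```

Each injected event is recovered: the deleted gene is the one `unmapped`
transcript, the nine single-variant genes appear under their own effect
class, the two duplicated genes produce `copies gained 2`, and the one
translocated gene makes the gene-order edit distance 2 (one deletion plus
one insertion of the moved gene). `out/variants.tsv` holds the
per-transcript calls:

```
transcript_id  gene_id  nt_identity  protein_identity  effect
gene001.t1     gene001  0.997354     1.000000          synonymous
gene004.t1     gene004  0.989583     0.988235          inframe_insertion
gene007.t1     gene007  0.982456     0.990291          three_prime_truncation
gene010.t1     gene010  NA           NA                unmapped
gene013.t1     gene013  1.000000     1.000000          identical
...
```

and `out/synteny.tsv` shows the translocated gene013 as the single
off-the-block-diagonal record (`chr1` ordinal 4 → `chr2` ordinal 33), which
is also the one off-diagonal point in `out/synteny.png`.

The same interface is available from a shell through the installed script:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "liftcompare",
                                       package = "liftcompare"))')" \
  all -r ref.fa -t target.fa -rg ref.gff3 -tg target.gff3 -o out
```

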