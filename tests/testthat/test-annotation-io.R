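minimal_gff3 <- c(
  "##gff-version 3",
  "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
  "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
  "chr1\tx\texon\t1\t100\t.\t+\t.\tParent=t1")

minimal_gtf <- c(
  "chr1\tx\tgene\t1\t100\t.\t+\t.\tgene_id \"g1\";",
  paste0("chr1\tx\ttranscript\t1\t100\t.\t+\t.\t",
         "gene_id \"g1\"; transcript_id \"t1\";"),
  paste0("chr1\tx\texon\t1\t100\t.\t+\t.\t",
         "gene_id \"g1\"; transcript_id \"t1\";"))

test_that("a minimal hierarchy parses from both dialects identically", {
  g3 <- parse_annotation(write_tmp_annot(minimal_gff3))
  expect_equal(nrow(g3$genes), 1L)
  expect_equal(nrow(g3$transcripts), 1L)
  expect_equal(sum(g3$segments$type == "exon"), 1L)
  expect_equal(g3$source_dialect, "GFF3")

  gt <- parse_annotation(write_tmp_annot(minimal_gtf, "gtf"))
  expect_equal(gt$source_dialect, "GTF")
  for (f in c("id", "seqid", "start", "end", "strand"))
    expect_equal(gt$genes[[f]], g3$genes[[f]])
  expect_equal(gt$transcripts$id, g3$transcripts$id)
  expect_equal(gt$segments[c("start", "end", "type")],
               g3$segments[c("start", "end", "type")])
})

test_that("parse errors name the offending line or orphan", {
  bad <- c(minimal_gff3, "chr1\tx\texon\t1\t50\t.\t+")  # 7 fields
  expect_error(parse_annotation(write_tmp_annot(bad)), "line 5")
  orphan <- c(minimal_gff3, "chr1\tx\texon\t1\t50\t.\t+\t.\tParent=ghost")
  expect_error(parse_annotation(write_tmp_annot(orphan)), "ghost")
})

test_that("round trip through both writers preserves the hierarchy", {
  ref <- make_reference(n_genes = 8, n_chroms = 2, coding_fraction = 0.75,
                        seed = 3)
  p <- tempfile(fileext = ".gff3")
  write_annotation(ref$ann, p, "GFF3")
  back <- parse_annotation(p)
  expect_equal(back$genes[c("id", "seqid", "start", "end", "strand")],
               ref$ann$genes[c("id", "seqid", "start", "end", "strand")])
  expect_equal(back$transcripts[c("id", "gene_id", "start", "end")],
               ref$ann$transcripts[c("id", "gene_id", "start", "end")])
  ord <- function(s) s[order(s$transcript_id, s$type, s$start), ]
  expect_equal(ord(back$segments)[c("transcript_id", "type", "start", "end",
                                    "strand", "phase")],
               ord(ref$ann$segments)[c("transcript_id", "type", "start",
                                       "end", "strand", "phase")],
               ignore_attr = TRUE)

  pg <- tempfile(fileext = ".gtf")
  write_annotation(ref$ann, pg, "GTF")
  back2 <- parse_annotation(pg)
  expect_equal(back2$genes$id, ref$ann$genes$id)
  expect_equal(ord(back2$segments)[c("start", "end", "phase")],
               ord(ref$ann$segments)[c("start", "end", "phase")],
               ignore_attr = TRUE)
})

test_that("transcript extraction splices and reverse-complements", {
  asm <- assembly(c(chr1 = "ATGCCCAAA"))
  ann <- structure(list(
    genes = data.frame(id = "g1", seqid = "chr1", start = 1L, end = 9L,
                       strand = "+", stringsAsFactors = FALSE),
    transcripts = data.frame(id = "t1", gene_id = "g1", type = "mRNA",
                             seqid = "chr1", start = 1L, end = 9L,
                             strand = "+", stringsAsFactors = FALSE),
    segments = data.frame(transcript_id = c("t1", "t1"), type = "exon",
                          seqid = "chr1", start = c(1L, 7L), end = c(3L, 9L),
                          strand = "+", phase = NA_integer_,
                          stringsAsFactors = FALSE),
    source_dialect = "GFF3"), class = "annotation")
  expect_equal(extract_transcript_sequence(asm, ann, "t1"), "ATGAAA")

  ann$segments$strand <- "-"
  ann$transcripts$strand <- "-"
  expect_equal(extract_transcript_sequence(asm, ann, "t1"), "TTTCAT")

  # single exon cases
  asm2 <- assembly(c(chr1 = "ATGAAA"))
  ann$segments <- data.frame(transcript_id = "t1", type = "exon",
                             seqid = "chr1", start = 1L, end = 6L,
                             strand = "+", phase = NA_integer_,
                             stringsAsFactors = FALSE)
  expect_equal(extract_transcript_sequence(asm2, ann, "t1"), "ATGAAA")
  ann$segments$strand <- "-"
  expect_equal(extract_transcript_sequence(asm2, ann, "t1"), "TTTCAT")

  ann$segments$end <- 99L
  expect_error(extract_transcript_sequence(asm2, ann, "t1"), "out of bounds")
})

test_that("CDS extraction handles absence and phase trimming", {
  asm <- assembly(c(chr1 = "NATGAAATAA"))
  base <- list(
    genes = data.frame(id = "g1", seqid = "chr1", start = 1L, end = 10L,
                       strand = "+", stringsAsFactors = FALSE),
    transcripts = data.frame(id = "t1", gene_id = "g1", type = "mRNA",
                             seqid = "chr1", start = 1L, end = 10L,
                             strand = "+", stringsAsFactors = FALSE),
    segments = data.frame(transcript_id = "t1", type = "exon",
                          seqid = "chr1", start = 1L, end = 10L,
                          strand = "+", phase = NA_integer_,
                          stringsAsFactors = FALSE),
    source_dialect = "GFF3")
  ann <- structure(base, class = "annotation")
  expect_true(is.na(extract_cds_sequence(asm, ann, "t1")))

  ann$segments <- rbind(ann$segments, data.frame(
    transcript_id = "t1", type = "CDS", seqid = "chr1", start = 1L,
    end = 10L, strand = "+", phase = 1L, stringsAsFactors = FALSE))
  expect_equal(extract_cds_sequence(asm, ann, "t1"), "ATGAAATAA")
})

test_that("minus-strand extraction equals revcomp of plus-strand extraction", {
  ref <- make_reference(n_genes = 10, n_chroms = 2, seed = 5)
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in seq_len(nrow(ref$ann$transcripts))) {
    tid <- ref$ann$transcripts$id[i]
    s <- extract_transcript_sequence(ref$asm, ref$ann, tid)
    flipped <- ref$ann
    sel <- flipped$segments$transcript_id == tid
    flipped$segments$strand[sel] <-
      ifelse(flipped$segments$strand[sel] == "+", "-", "+")
    expect_equal(extract_transcript_sequence(ref$asm, flipped, tid), rc(s))
  }
})

test_that("generated CDS lengths are complete codons that translate cleanly", {
  ref <- make_reference(n_genes = 12, n_chroms = 3, coding_fraction = 1,
                        seed = 9)
  for (tid in ref$ann$transcripts$id) {
    cds <- extract_cds_sequence(ref$asm, ref$ann, tid)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    aa <- translate_cds(cds)
    expect_false(grepl("*", aa, fixed = TRUE))
  }
})

test_that("feature matching applies the ID and copy-suffix rules", {
  mk <- function(gids, tids = paste0(gids, ".t")) {
    lines <- "##gff-version 3"
    for (i in seq_along(gids)) {
      s <- 10 * i
      lines <- c(lines,
        sprintf("chr1\tx\tgene\t%d\t%d\t.\t+\t.\tID=%s", s, s + 5, gids[i]),
        sprintf("chr1\tx\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                s, s + 5, tids[i], gids[i]),
        sprintf("chr1\tx\texon\t%d\t%d\t.\t+\t.\tParent=%s", s, s + 5,
                tids[i]))
    }
    parse_annotation(write_tmp_annot(lines))
  }
  ref <- mk(c("g1", "g2"))
  m <- match_features(ref, mk(c("g1", "g2")))
  expect_setequal(m$shared_gene_ids, c("g1", "g2"))
  expect_length(m$unmapped_gene_ids, 0)

  m <- match_features(ref, mk("g1"))
  expect_equal(m$unmapped_gene_ids, "g2")

  m <- match_features(mk("g1"), mk(c("g1", "g1_1", "weird")))
  expect_equal(m$extra_copies, c(g1_1 = "g1"))
  expect_equal(m$novel_gene_ids, "weird")
})

test_that("longest isoform maximizes spliced length with ID tie-break", {
  lines <- c("##gff-version 3",
    "chr1\tx\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t450\t.\t+\t.\tID=tLong;Parent=g1",
    "chr1\tx\texon\t1\t450\t.\t+\t.\tParent=tLong",
    "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=tShort;Parent=g1",
    "chr1\tx\texon\t1\t300\t.\t+\t.\tParent=tShort",
    "chr1\tx\tgene\t1\t1000\t.\t-\t.\tID=g2",
    "chr1\tx\tmRNA\t1\t300\t.\t-\t.\tID=tB;Parent=g2",
    "chr1\tx\texon\t1\t300\t.\t-\t.\tParent=tB",
    "chr1\tx\tmRNA\t500\t799\t.\t-\t.\tID=tA;Parent=g2",
    "chr1\tx\texon\t500\t799\t.\t-\t.\tParent=tA")
  ann <- parse_annotation(write_tmp_annot(lines))
  expect_equal(longest_isoform(ann, "g1"), "tLong")
  expect_equal(longest_isoform(ann, "g2"), "tA")  # equal lengths, tA < tB
  expect_error(longest_isoform(ann, "nope"), "no transcripts")
})
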