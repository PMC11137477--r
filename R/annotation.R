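#' Read a genome assembly from FASTA
#'
#' @param path path to a (optionally gzip-compressed) multi-record FASTA
#'   file. Sequences are uppercased; record order is preserved.
#' @return An object of class `assembly` wrapping a
#'   [Biostrings::DNAStringSet].
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  # FASTA headers may carry descriptions after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in ", path)
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence record in ", path)
  structure(list(sequences = seqs, sequence_order = names(seqs)),
            class = "assembly")
}

#' Assembly constructor from plain character sequences
#'
#' Mainly used by the fixture generator and by tests.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @return An `assembly`.
#' @export
assembly <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            !anyDuplicated(names(seqs)), all(nchar(seqs) > 0L))
  structure(list(sequences = Biostrings::DNAStringSet(toupper(seqs)),
                 sequence_order = names(seqs)),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("Assembly with", length(x$sequences), "sequence(s), total",
      sum(Biostrings::width(x$sequences)), "bp\n")
  invisible(x)
}

#' Extract a genomic interval from an assembly
#'
#' @param asm an `assembly`.
#' @param seqid sequence name.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`; minus-strand intervals are
#'   reverse-complemented.
#' @return A nucleotide string of length `end - start + 1`.
#' @export
assembly_seq <- function(asm, seqid, start, end, strand = "+") {
  stopifnot(inherits(asm, "assembly"))
  if (!seqid %in% names(asm$sequences))
    stop("sequence '", seqid, "' not present in assembly")
  len <- Biostrings::width(asm$sequences[seqid])
  if (start < 1L || end > len || start > end)
    stop("interval ", start, "-", end, " out of bounds for '", seqid,
         "' (length ", len, ")")
  s <- Biostrings::subseq(asm$sequences[[seqid]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

## ---- annotation parsing ----------------------------------------------------

.first_or_na <- function(x) {
  # CharacterList column -> first element per row, NA when empty
  vapply(as.list(x), function(v) if (length(v)) v[[1L]] else NA_character_,
         character(1))
}

.detect_dialect <- function(path) {
  base <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("gtf")) return("GTF")
  if (ext %in% c("gff", "gff3")) return("GFF3")
  # sniff: GTF attribute columns look like  key "value";
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  lines <- readLines(con, n = 50L)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) && any(grepl("\\w+ +\"[^\"]*\";", lines))) "GTF" else "GFF3"
}

.precheck_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
  bad <- data_idx[nfield != 9L]
  if (length(bad))
    stop("malformed annotation line ", bad[1L], " in ", path,
         " (expected 9 tab-separated fields, found ", nfield[match(bad[1L],
         data_idx)], ")")
  invisible(TRUE)
}

#' Parse a GFF3 or GTF annotation into a gene/transcript/exon/CDS hierarchy
#'
#' Transcript-level features are recognised structurally: any feature whose
#' parent is a gene is transcript-like, regardless of its type string (mRNA,
#' transcript, ncRNA, ...). In GTF input the `gene_id` and `transcript_id`
#' attributes are promoted to feature IDs; explicit `gene`/`transcript` rows
#' are optional and spans are inferred from exons when they are absent.
#'
#' @param path path to a GFF3 or GTF file (optionally gzip-compressed).
#' @param dialect `"auto"` (default; decided by file extension, then by
#'   attribute syntax), `"GFF3"` or `"GTF"`.
#' @return An object of class `annotation` with components `genes`,
#'   `transcripts` and `segments` (exon/CDS) data frames, plus
#'   `source_dialect`. Gene rows keep file order; Liftoff's `sequence_ID`
#'   identity attribute is carried through when present.
#' @export
parse_annotation <- function(path, dialect = c("auto", "GFF3", "GTF")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "auto") dialect <- .detect_dialect(path)
  .precheck_lines(path)
  gr <- rtracklayer::import(path, format = tolower(dialect))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  if (!"phase" %in% names(df)) df$phase <- NA_integer_
  df$phase <- suppressWarnings(as.integer(df$phase))

  if (dialect == "GFF3") {
    if (!"ID" %in% names(df)) df$ID <- NA_character_
    parent <- if ("Parent" %in% names(df)) .first_or_na(df$Parent)
              else rep(NA_character_, nrow(df))
    id <- as.character(df$ID)

    is_top <- is.na(parent)
    is_gene <- is_top & grepl("gene$", df$type)
    gene_ids <- id[is_gene]
    is_tx <- !is.na(parent) & parent %in% gene_ids
    tx_ids <- id[is_tx]
    is_seg <- df$type %in% c("exon", "CDS") & !is.na(parent) &
      parent %in% tx_ids

    orphan <- !is_gene & !is_tx & !is_seg & !is.na(parent) &
      !(parent %in% c(gene_ids, tx_ids))
    if (any(orphan)) {
      who <- ifelse(is.na(id[orphan]), df$type[orphan], id[orphan])
      stop("orphan feature(s) with missing parent in ", path, ": ",
           paste(unique(paste0(who, " (Parent=", parent[orphan], ")")),
                 collapse = ", "))
    }

    genes <- data.frame(id = gene_ids, seqid = df$seqnames[is_gene],
                        start = df$start[is_gene], end = df$end[is_gene],
                        strand = df$strand[is_gene],
                        stringsAsFactors = FALSE)
    if ("sequence_ID" %in% names(df))
      genes$sequence_ID <- suppressWarnings(
        as.numeric(as.character(df$sequence_ID[is_gene])))
    transcripts <- data.frame(id = tx_ids, gene_id = parent[is_tx],
                              type = df$type[is_tx],
                              seqid = df$seqnames[is_tx],
                              start = df$start[is_tx], end = df$end[is_tx],
                              strand = df$strand[is_tx],
                              stringsAsFactors = FALSE)
    segments <- data.frame(transcript_id = parent[is_seg],
                           type = df$type[is_seg],
                           seqid = df$seqnames[is_seg],
                           start = df$start[is_seg], end = df$end[is_seg],
                           strand = df$strand[is_seg],
                           phase = df$phase[is_seg],
                           stringsAsFactors = FALSE)
  } else {
    if (!all(c("gene_id") %in% names(df)))
      stop("GTF input lacks gene_id attributes: ", path)
    if (!"transcript_id" %in% names(df)) df$transcript_id <- NA_character_
    df$gene_id <- as.character(df$gene_id)
    df$transcript_id <- as.character(df$transcript_id)

    seg_rows <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
    if (any(is.na(seg_rows$transcript_id)))
      stop("GTF exon/CDS line without transcript_id in ", path)
    segments <- data.frame(transcript_id = seg_rows$transcript_id,
                           type = seg_rows$type, seqid = seg_rows$seqnames,
                           start = seg_rows$start, end = seg_rows$end,
                           strand = seg_rows$strand, phase = seg_rows$phase,
                           stringsAsFactors = FALSE)

    tx_rows <- df[!df$type %in% c("exon", "CDS", "gene") &
                    !is.na(df$transcript_id), , drop = FALSE]
    if (nrow(tx_rows)) {
      transcripts <- data.frame(id = tx_rows$transcript_id,
                                gene_id = tx_rows$gene_id,
                                type = tx_rows$type, seqid = tx_rows$seqnames,
                                start = tx_rows$start, end = tx_rows$end,
                                strand = tx_rows$strand,
                                stringsAsFactors = FALSE)
    } else {
      # infer transcript spans from their exons
      sp <- split(segments, segments$transcript_id)
      g_of <- df$gene_id[match(names(sp), df$transcript_id)]
      transcripts <- data.frame(
        id = names(sp), gene_id = g_of, type = "transcript",
        seqid = vapply(sp, function(d) d$seqid[1L], character(1)),
        start = vapply(sp, function(d) min(d$start), integer(1)),
        end = vapply(sp, function(d) max(d$end), integer(1)),
        strand = vapply(sp, function(d) d$strand[1L], character(1)),
        stringsAsFactors = FALSE)
      rownames(transcripts) <- NULL
    }

    gene_rows <- df[df$type == "gene", , drop = FALSE]
    if (nrow(gene_rows)) {
      genes <- data.frame(id = gene_rows$gene_id, seqid = gene_rows$seqnames,
                          start = gene_rows$start, end = gene_rows$end,
                          strand = gene_rows$strand, stringsAsFactors = FALSE)
    } else {
      sp <- split(transcripts, transcripts$gene_id)
      sp <- sp[unique(transcripts$gene_id)]  # keep file order
      genes <- data.frame(
        id = names(sp),
        seqid = vapply(sp, function(d) d$seqid[1L], character(1)),
        start = vapply(sp, function(d) min(d$start), integer(1)),
        end = vapply(sp, function(d) max(d$end), integer(1)),
        strand = vapply(sp, function(d) d$strand[1L], character(1)),
        stringsAsFactors = FALSE)
      rownames(genes) <- NULL
    }
  }

  ann <- structure(list(genes = genes, transcripts = transcripts,
                        segments = segments, source_dialect = dialect),
                   class = "annotation")
  validate_annotation(ann)
  ann
}

#' Validate an annotation hierarchy
#'
#' Checks the structural invariants: unique feature IDs, every transcript
#' attached to a known gene and owning at least one exon, exons of a
#' transcript on one sequence and strand, and pairwise non-overlapping CDS
#' intervals per transcript.
#'
#' @param ann an `annotation`.
#' @return `ann`, invisibly; errors describe the violated invariant.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "annotation"))
  if (anyDuplicated(ann$genes$id))
    stop("duplicate gene ids: ",
         paste(unique(ann$genes$id[duplicated(ann$genes$id)]), collapse = ", "))
  if (anyDuplicated(ann$transcripts$id))
    stop("duplicate transcript ids: ",
         paste(unique(ann$transcripts$id[duplicated(ann$transcripts$id)]),
               collapse = ", "))
  bad <- setdiff(ann$transcripts$gene_id, ann$genes$id)
  if (length(bad)) stop("transcripts reference unknown gene(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(ann$segments$transcript_id, ann$transcripts$id)
  if (length(bad)) stop("exon/CDS reference unknown transcript(s): ",
                        paste(bad, collapse = ", "))
  with_exon <- unique(ann$segments$transcript_id[ann$segments$type == "exon"])
  noex <- setdiff(ann$transcripts$id, with_exon)
  if (length(noex)) stop("transcript(s) without exons: ",
                         paste(noex, collapse = ", "))
  if (any(ann$segments$start > ann$segments$end))
    stop("segment with start > end")
  bad_phase <- ann$segments$type == "CDS" & !is.na(ann$segments$phase) &
    !ann$segments$phase %in% 0:2
  if (any(bad_phase)) stop("CDS phase outside {0,1,2}")
  for (tid in unique(ann$segments$transcript_id)) {
    cds <- ann$segments[ann$segments$transcript_id == tid &
                          ann$segments$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 1L) {
      cds <- cds[order(cds$start), ]
      if (any(cds$start[-1L] <= cds$end[-nrow(cds)]))
        stop("overlapping CDS intervals in transcript ", tid)
    }
  }
  invisible(ann)
}

#' @export
print.annotation <- function(x, ...) {
  cat("Annotation (", x$source_dialect, "): ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts, ",
      sum(x$segments$type == "exon"), " exons, ",
      sum(x$segments$type == "CDS"), " CDS segments\n", sep = "")
  invisible(x)
}

## ---- annotation writing ----------------------------------------------------

#' Write an annotation to GFF3 or GTF
#'
#' The writer is deterministic: genes are emitted in stored order, each
#' followed by its transcripts, then exons and CDS segments sorted by start
#' coordinate. Re-parsing the output recovers an identical hierarchy.
#'
#' @param ann an `annotation`.
#' @param path output file path.
#' @param dialect `"GFF3"` or `"GTF"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, dialect = c("GFF3", "GTF")) {
  dialect <- match.arg(dialect)
  validate_annotation(ann)
  lines <- character(0)
  ph <- function(p) ifelse(is.na(p), ".", as.character(p))
  if (dialect == "GFF3") {
    lines <- "##gff-version 3"
    for (i in seq_len(nrow(ann$genes))) {
      g <- ann$genes[i, ]
      attrs <- paste0("ID=", g$id)
      if (!is.null(g$sequence_ID) && !is.na(g$sequence_ID))
        attrs <- paste0(attrs, ";sequence_ID=", format(g$sequence_ID,
                        scientific = FALSE))
      lines <- c(lines, paste(g$seqid, "liftcompare", "gene", g$start, g$end,
                              ".", g$strand, ".", attrs, sep = "\t"))
      txs <- ann$transcripts[ann$transcripts$gene_id == g$id, , drop = FALSE]
      for (j in seq_len(nrow(txs))) {
        t <- txs[j, ]
        lines <- c(lines, paste(t$seqid, "liftcompare", t$type, t$start,
                                t$end, ".", t$strand, ".",
                                paste0("ID=", t$id, ";Parent=", g$id),
                                sep = "\t"))
        segs <- ann$segments[ann$segments$transcript_id == t$id, , drop = FALSE]
        segs <- segs[order(match(segs$type, c("exon", "CDS")), segs$start), ]
        for (k in seq_len(nrow(segs))) {
          s <- segs[k, ]
          lines <- c(lines, paste(s$seqid, "liftcompare", s$type, s$start,
                                  s$end, ".", s$strand, ph(s$phase),
                                  paste0("Parent=", t$id), sep = "\t"))
        }
      }
    }
  } else {
    for (i in seq_len(nrow(ann$genes))) {
      g <- ann$genes[i, ]
      lines <- c(lines, paste(g$seqid, "liftcompare", "gene", g$start, g$end,
                              ".", g$strand, ".",
                              sprintf("gene_id \"%s\";", g$id), sep = "\t"))
      txs <- ann$transcripts[ann$transcripts$gene_id == g$id, , drop = FALSE]
      for (j in seq_len(nrow(txs))) {
        t <- txs[j, ]
        at <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", g$id, t$id)
        lines <- c(lines, paste(t$seqid, "liftcompare", "transcript", t$start,
                                t$end, ".", t$strand, ".", at, sep = "\t"))
        segs <- ann$segments[ann$segments$transcript_id == t$id, , drop = FALSE]
        segs <- segs[order(match(segs$type, c("exon", "CDS")), segs$start), ]
        for (k in seq_len(nrow(segs))) {
          s <- segs[k, ]
          lines <- c(lines, paste(s$seqid, "liftcompare", s$type, s$start,
                                  s$end, ".", s$strand, ph(s$phase), at,
                                  sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- sequence extraction ---------------------------------------------------

.tx_segments <- function(ann, transcript_id, type) {
  if (!transcript_id %in% ann$transcripts$id)
    stop("unknown transcript: ", transcript_id)
  s <- ann$segments[ann$segments$transcript_id == transcript_id &
                      ann$segments$type == type, , drop = FALSE]
  s[order(s$start), , drop = FALSE]
}

#' Extract the spliced sequence of a transcript
#'
#' Exons are sorted by start coordinate, concatenated, and the concatenation
#' is reverse-complemented as one unit when the transcript is on the minus
#' strand, so the result reads 5' to 3'.
#'
#' @param asm an `assembly`.
#' @param ann an `annotation`.
#' @param transcript_id transcript feature ID.
#' @return The spliced nucleotide string.
#' @export
extract_transcript_sequence <- function(asm, ann, transcript_id) {
  ex <- .tx_segments(ann, transcript_id, "exon")
  if (nrow(ex) == 0L) stop("transcript ", transcript_id, " has no exons")
  strand <- ex$strand[1L]
  parts <- vapply(seq_len(nrow(ex)), function(i)
    assembly_seq(asm, ex$seqid[i], ex$start[i], ex$end[i], "+"), character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Extract the coding sequence of a transcript
#'
#' CDS segments are spliced and strand-corrected like exons. When the first
#' CDS segment in translation order carries a phase greater than zero, that
#' many leading bases are trimmed so translation starts on a codon boundary.
#'
#' @inheritParams extract_transcript_sequence
#' @return The CDS nucleotide string, or `NA_character_` for transcripts
#'   with no CDS children.
#' @export
extract_cds_sequence <- function(asm, ann, transcript_id) {
  cds <- .tx_segments(ann, transcript_id, "CDS")
  if (nrow(cds) == 0L) return(NA_character_)
  strand <- cds$strand[1L]
  parts <- vapply(seq_len(nrow(cds)), function(i)
    assembly_seq(asm, cds$seqid[i], cds$start[i], cds$end[i], "+"),
    character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  first <- if (strand == "-") nrow(cds) else 1L  # translation-order first
  p <- cds$phase[first]
  if (!is.na(p) && p > 0L) s <- substring(s, p + 1L)
  s
}

#' Spliced length of every transcript
#' @param ann an `annotation`.
#' @return Named integer vector of exon-length sums, one per transcript.
#' @keywords internal
.spliced_lengths <- function(ann) {
  ex <- ann$segments[ann$segments$type == "exon", , drop = FALSE]
  len <- tapply(ex$end - ex$start + 1L, ex$transcript_id, sum)
  out <- rep(0L, nrow(ann$transcripts))
  names(out) <- ann$transcripts$id
  out[names(len)] <- as.integer(len)
  out
}

#' Longest isoform of a gene
#'
#' The transcript with the largest spliced (exonic) length; ties are broken
#' by the lexicographically smallest transcript ID.
#'
#' @param ann an `annotation`.
#' @param gene_id gene feature ID.
#' @return The transcript ID.
#' @export
longest_isoform <- function(ann, gene_id) {
  txs <- ann$transcripts$id[ann$transcripts$gene_id == gene_id]
  if (length(txs) == 0L) stop("gene ", gene_id, " has no transcripts")
  len <- .spliced_lengths(ann)[txs]
  txs <- txs[order(-len, txs)]
  txs[1L]
}

## ---- feature matching ------------------------------------------------------

#' Match features between a reference and a target annotation by ID
#'
#' Shared IDs are the intersection; reference IDs absent from the target are
#' unmapped. Target-only gene IDs of the form `<reference gene id>_<n>`
#' (Liftoff's extra-copy naming; the suffix pattern is configurable) are
#' recognised as extra copies of that reference gene. Target-only IDs that
#' match nothing are reported in `novel_gene_ids` and excluded from all
#' downstream analyses.
#'
#' @param ref,tgt `annotation` objects.
#' @param copy_suffix_pattern regular expression for the extra-copy suffix,
#'   anchored at the end of the ID.
#' @return An object of class `feature_match` with components
#'   `shared_gene_ids`, `shared_transcript_ids`, `unmapped_gene_ids`,
#'   `unmapped_transcript_ids`, `extra_copies` (named character vector:
#'   copy ID -> source gene ID) and `novel_gene_ids`.
#' @export
match_features <- function(ref, tgt, copy_suffix_pattern = "_[1-9][0-9]*$") {
  stopifnot(inherits(ref, "annotation"), inherits(tgt, "annotation"))
  rg <- ref$genes$id; tg <- tgt$genes$id
  shared <- intersect(rg, tg)
  unmapped <- setdiff(rg, tg)
  tgt_only <- setdiff(tg, rg)
  src <- sub(copy_suffix_pattern, "", tgt_only)
  is_copy <- src != tgt_only & src %in% rg
  extra <- stats::setNames(src[is_copy], tgt_only[is_copy])
  novel <- tgt_only[!is_copy]
  structure(list(
    shared_gene_ids = shared,
    shared_transcript_ids = intersect(ref$transcripts$id, tgt$transcripts$id),
    unmapped_gene_ids = unmapped,
    unmapped_transcript_ids = setdiff(ref$transcripts$id, tgt$transcripts$id),
    extra_copies = extra,
    novel_gene_ids = novel), class = "feature_match")
}

#' @export
print.feature_match <- function(x, ...) {
  cat("Feature match:", length(x$shared_gene_ids), "shared genes,",
      length(x$unmapped_gene_ids), "unmapped,",
      length(x$extra_copies), "extra copies,",
      length(x$novel_gene_ids), "novel target-only\n")
  invisible(x)
}
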