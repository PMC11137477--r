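## Synthetic assembly/annotation pairs with a recorded ground truth of
## injected mutation events. The generator defines the validation conditions
## for the whole toolkit: every event class it can inject is recoverable by
## the corresponding analysis module.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOPS)
# codons whose first two bases make a four-fold degenerate family
.FOURFOLD_PREFIX <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.rand_nt <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Generate a synthetic reference assembly and annotation
#'
#' Genes are embedded in random intergenic sequence across `n_chroms`
#' chromosomes (round-robin), on both strands. Coding genes carry a single
#' transcript with a complete ORF (starts ATG, ends with a stop codon, no
#' internal stops, length a multiple of 3), 15 nt UTRs, and 1-3 exons
#' separated by 50 nt introns; splice sites sit at least 15 nt inside the
#' CDS so that every mutation event has room within one exon. The last
#' sense codon of each ORF ends in C or T, which keeps a deletion of the
#' stop-codon terminus unambiguous in the optimal alignment. Noncoding
#' genes have the same exon structure without CDS features.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chroms number of chromosomes.
#' @param coding_fraction fraction of genes that are protein-coding (the
#'   first `round(n_genes * coding_fraction)` gene IDs).
#' @param seed integer seed; the output is byte-deterministic given it.
#' @return A list with elements `asm` (an `assembly`) and `ann` (an
#'   `annotation`).
#' @export
make_reference <- function(n_genes, n_chroms = 1L, coding_fraction = 1,
                           seed = 1L) {
  stopifnot(n_genes >= 1L, n_chroms >= 1L,
            coding_fraction >= 0, coding_fraction <= 1)
  n_coding <- round(n_genes * coding_fraction)
  withr::with_seed(seed, {
    utr <- 15L; intron_len <- 50L; spacer <- 150L
    loci <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      coding <- i <= n_coding
      n_cod <- sample(60:120, 1L)
      if (coding) {
        # the last two sense codons end in C or T while stop codons end in
        # A or G, so a deletion of the stop-codon terminus has a unique
        # optimal gap placement flush with the alignment end
        body <- c("ATG", sample(.SENSE_CODONS, n_cod - 4L, replace = TRUE),
                  sample(grep("[CT]$", .SENSE_CODONS, value = TRUE), 2L,
                         replace = TRUE),
                  sample(.STOPS, 1L))
        orf <- paste(body, collapse = "")
      } else {
        orf <- .rand_nt(3L * n_cod)
      }
      tx <- paste0(.rand_nt(utr), orf, .rand_nt(utr))
      tx_len <- nchar(tx)
      cds_rng <- if (coding) c(utr + 1L, utr + 3L * n_cod) else NULL

      n_ex <- sample(1:3, 1L)
      lo <- utr + 16L; hi <- utr + 3L * n_cod - 16L
      cuts <- integer(0)
      if (n_ex > 1L) {
        cand <- seq(lo, hi)
        for (k in seq_len(n_ex - 1L)) {
          if (length(cand) == 0L) break
          c0 <- if (length(cand) == 1L) cand else sample(cand, 1L)
          cuts <- c(cuts, c0)
          cand <- cand[abs(cand - c0) >= 25L]
        }
        cuts <- sort(cuts)
      }
      # exon intervals in transcript coordinates
      ex_tx <- cbind(c(1L, cuts + 1L), c(cuts, tx_len))
      # locus = exons with introns interleaved; locus is in transcript
      # orientation (5'->3' of the mRNA)
      locus_parts <- character(0)
      ex_locus <- matrix(0L, nrow(ex_tx), 2L)
      off <- 0L
      for (k in seq_len(nrow(ex_tx))) {
        w <- ex_tx[k, 2L] - ex_tx[k, 1L] + 1L
        ex_locus[k, ] <- c(off + 1L, off + w)
        locus_parts <- c(locus_parts, substr(tx, ex_tx[k, 1L], ex_tx[k, 2L]))
        off <- off + w
        if (k < nrow(ex_tx)) {
          locus_parts <- c(locus_parts,
                           paste0("GT", .rand_nt(intron_len - 4L), "AG"))
          off <- off + intron_len
        }
      }
      locus <- paste(locus_parts, collapse = "")
      # CDS intervals: exon pieces clipped to the CDS transcript range
      cds_locus <- NULL
      if (coding) {
        for (k in seq_len(nrow(ex_tx))) {
          s <- max(ex_tx[k, 1L], cds_rng[1L])
          e <- min(ex_tx[k, 2L], cds_rng[2L])
          if (s <= e) {
            ls <- ex_locus[k, 1L] + (s - ex_tx[k, 1L])
            cds_locus <- rbind(cds_locus, c(ls, ls + (e - s)))
          }
        }
      }
      loci[[i]] <- list(
        id = sprintf("gene%03d", i),
        tx_id = sprintf("gene%03d.t1", i),
        coding = coding,
        strand = sample(c("+", "-"), 1L),
        chrom = sprintf("chr%d", ((i - 1L) %% n_chroms) + 1L),
        seq = locus, ex = ex_locus, cds = cds_locus)
    }

    chrom_names <- sprintf("chr%d", seq_len(n_chroms))
    seqs <- stats::setNames(rep("", n_chroms), chrom_names)
    genes <- transcripts <- segments <- NULL
    for (cn in chrom_names) {
      for (l in loci) {
        if (l$chrom != cn) next
        seqs[cn] <- paste0(seqs[cn], .rand_nt(spacer))
        offset <- nchar(seqs[cn])
        L <- nchar(l$seq)
        gseq <- if (l$strand == "-") .revcomp(l$seq) else l$seq
        seqs[cn] <- paste0(seqs[cn], gseq)
        map <- function(iv) {  # locus interval -> genomic interval
          if (l$strand == "-") cbind(offset + L - iv[, 2L] + 1L,
                                     offset + L - iv[, 1L] + 1L)
          else cbind(offset + iv[, 1L], offset + iv[, 2L])
        }
        genes <- rbind(genes, data.frame(
          id = l$id, seqid = cn, start = offset + 1L, end = offset + L,
          strand = l$strand, stringsAsFactors = FALSE))
        transcripts <- rbind(transcripts, data.frame(
          id = l$tx_id, gene_id = l$id,
          type = if (l$coding) "mRNA" else "transcript",
          seqid = cn, start = offset + 1L, end = offset + L,
          strand = l$strand, stringsAsFactors = FALSE))
        exg <- map(l$ex)
        segments <- rbind(segments, data.frame(
          transcript_id = l$tx_id, type = "exon", seqid = cn,
          start = exg[, 1L], end = exg[, 2L], strand = l$strand,
          phase = NA_integer_, stringsAsFactors = FALSE))
        if (l$coding) {
          # phase in translation order = locus row order
          w <- l$cds[, 2L] - l$cds[, 1L] + 1L
          before <- c(0L, cumsum(w))[seq_along(w)]
          phase <- (3L - before %% 3L) %% 3L
          cg <- map(l$cds)
          segments <- rbind(segments, data.frame(
            transcript_id = l$tx_id, type = "CDS", seqid = cn,
            start = cg[, 1L], end = cg[, 2L], strand = l$strand,
            phase = phase, stringsAsFactors = FALSE))
        }
      }
      seqs[cn] <- paste0(seqs[cn], .rand_nt(spacer))
    }
    cn <- names(seqs)
    segments <- segments[order(match(segments$seqid, cn), segments$start,
                               segments$transcript_id, segments$type), ,
                         drop = FALSE]
    rownames(genes) <- rownames(transcripts) <- rownames(segments) <- NULL
    ann <- structure(list(genes = genes, transcripts = transcripts,
                          segments = segments, source_dialect = "GFF3"),
                     class = "annotation")
    validate_annotation(ann)
    list(asm = assembly(seqs), ann = ann)
  })
}

## ---- mutation machinery ----------------------------------------------------

# genomic position of every CDS base in translation order (1-based offsets)
.cds_genomic_map <- function(ann, transcript_id) {
  cds <- .tx_segments(ann, transcript_id, "CDS")
  if (nrow(cds) == 0L) stop("transcript ", transcript_id, " has no CDS")
  minus <- cds$strand[1L] == "-"
  if (minus) cds <- cds[order(-cds$start), , drop = FALSE]
  unlist(lapply(seq_len(nrow(cds)), function(i)
    if (minus) seq(cds$end[i], cds$start[i]) else seq(cds$start[i], cds$end[i])
  ), use.names = FALSE)
}

# codon indices usable for internal events: >= 9 nt from both CDS ends and
# genomically contiguous together with one codon of context on each side
.internal_codons <- function(gpos, n_codons) {
  cand <- seq(4L, n_codons - 3L)
  keep <- vapply(cand, function(c0) {
    o <- (3L * (c0 - 2L) + 1L):(3L * (c0 + 1L))
    all(abs(diff(gpos[o])) == 1L)
  }, logical(1))
  cand[keep]
}

.substitute_base <- function(seqs, chrom, pos, base) {
  substr(seqs[chrom], pos, pos) <- base
  seqs
}

# shift features on `chrom` for a deletion of [p1, p2]
.shift_deletion <- function(df, chrom, p1, p2) {
  L <- p2 - p1 + 1L
  on <- df$seqid == chrom
  contains <- on & df$start <= p1 & df$end >= p2
  after <- on & df$start > p2
  partial <- on & !contains & !after & df$end >= p1
  if (any(partial))
    stop("internal error: deletion partially overlaps a feature")
  df$end[contains] <- df$end[contains] - L
  df$start[after] <- df$start[after] - L
  df$end[after] <- df$end[after] - L
  df
}

# shift features on `chrom` for an insertion of length L after position p
.shift_insertion <- function(df, chrom, p, L) {
  on <- df$seqid == chrom
  spans <- on & df$start <= p & df$end > p
  after <- on & df$start > p
  df$end[spans] <- df$end[spans] + L
  df$start[after] <- df$start[after] + L
  df$end[after] <- df$end[after] + L
  df
}

.EVENTS <- c("none", "synonymous_snp", "nonsynonymous_snp", "inframe_del",
             "inframe_ins", "start_loss", "five_prime_trunc",
             "three_prime_trunc", "frameshift_indel", "stop_gain_snp",
             "gene_deletion", "gene_duplication", "translocation")

.EXPECTED_EFFECT <- c(
  none = "identical", synonymous_snp = "synonymous",
  nonsynonymous_snp = "nonsynonymous", inframe_del = "inframe_deletion",
  inframe_ins = "inframe_insertion", start_loss = "start_lost",
  five_prime_trunc = "five_prime_truncation",
  three_prime_trunc = "three_prime_truncation",
  frameshift_indel = "frameshift", stop_gain_snp = "stop_gained",
  gene_deletion = "unmapped", gene_duplication = "identical",
  translocation = "identical")

#' Apply mutation events to a reference pair
#'
#' Produces a target assembly/annotation reflecting the requested events,
#' with coordinates of all downstream features shifted consistently, plus a
#' ground-truth table of the expected call per gene. At most one event per
#' gene keeps the truth unambiguous; point and indel events are placed at
#' seeded random codon positions at least 9 nt away from the CDS ends and
#' inside a single exon.
#'
#' @param ref a [make_reference()] result (list with `asm` and `ann`).
#' @param specs data frame with columns `gene_id` and `event` (one of
#'   `r paste(.EVENTS, collapse=", ")`); optional columns `subs_rate`
#'   (duplication divergence, default 0.02) and `dest_chrom`
#'   (translocation destination, default: next chromosome).
#' @param seed integer seed for the random choices within events.
#' @return A list with `asm`, `ann` (the target pair) and `truth`, a data
#'   frame with one row per reference gene: `gene_id`, `event`,
#'   `expected_effect`, `cluster_delta`, `translocated`.
#' @export
apply_mutations <- function(ref, specs = NULL, seed = 1L) {
  asm <- ref$asm; ann <- ref$ann
  if (is.null(specs) || nrow(specs) == 0L)
    specs <- data.frame(gene_id = character(0), event = character(0),
                        stringsAsFactors = FALSE)
  stopifnot(all(specs$event %in% .EVENTS))
  if (anyDuplicated(specs$gene_id))
    stop("at most one event per gene")
  bad <- setdiff(specs$gene_id, ann$genes$id)
  if (length(bad)) stop("unknown gene(s) in specs: ",
                        paste(bad, collapse = ", "))
  if (!"subs_rate" %in% names(specs))
    specs$subs_rate <- rep(NA_real_, nrow(specs))
  if (!"dest_chrom" %in% names(specs))
    specs$dest_chrom <- rep(NA_character_, nrow(specs))

  withr::with_seed(seed, {
    seqs <- stats::setNames(
      as.character(asm$sequences)[asm$sequence_order], asm$sequence_order)
    genes <- ann$genes; txs <- ann$transcripts; segs <- ann$segments
    indels <- list()      # list(chrom, p1, p2) deletions / (chrom, p, ins)
    del_genes <- character(0)
    appends <- list()     # duplications and translocations

    cds_events <- c("synonymous_snp", "nonsynonymous_snp", "inframe_del",
                    "inframe_ins", "start_loss", "five_prime_trunc",
                    "three_prime_trunc", "frameshift_indel", "stop_gain_snp")
    for (i in seq_len(nrow(specs))) {
      gid <- specs$gene_id[i]; ev <- specs$event[i]
      if (ev == "none") next
      grow <- genes[genes$id == gid, ]
      chrom <- grow$seqid; strand <- grow$strand
      if (ev %in% cds_events) {
        tid <- longest_isoform(ann, gid)
        cds <- extract_cds_sequence(asm, ann, tid)
        if (is.na(cds))
          stop("event ", ev, " requires a CDS but gene ", gid,
               " is noncoding")
        gpos <- .cds_genomic_map(ann, tid)
        n_cod <- nchar(cds) %/% 3L
        codon_at <- function(c0) substr(cds, 3L * c0 - 2L, 3L * c0)
        internal <- .internal_codons(gpos, n_cod)
        sub_tx <- function(offset, new_base) {
          b <- if (strand == "-") .COMPLEMENT[[new_base]] else new_base
          seqs <<- .substitute_base(seqs, chrom, gpos[offset], b)
        }
        if (ev == "synonymous_snp") {
          cand <- internal[substr(vapply(internal, codon_at, character(1)),
                                  1L, 2L) %in% .FOURFOLD_PREFIX]
          if (length(cand) == 0L)
            stop("no degenerate site available for synonymous_snp in ", gid)
          c0 <- if (length(cand) == 1L) cand else sample(cand, 1L)
          old <- substr(codon_at(c0), 3L, 3L)
          sub_tx(3L * c0, sample(setdiff(.BASES, old), 1L))
        } else if (ev == "nonsynonymous_snp") {
          done <- FALSE
          for (c0 in sample(internal)) {
            cod <- codon_at(c0)
            for (b in sample(setdiff(.BASES, substr(cod, 1L, 1L)))) {
              new <- paste0(b, substr(cod, 2L, 3L))
              if (!new %in% .STOPS &&
                  translate_cds(paste0(new, "TAA")) !=
                  translate_cds(paste0(cod, "TAA"))) {
                sub_tx(3L * c0 - 2L, b); done <- TRUE; break
              }
            }
            if (done) break
          }
          if (!done) stop("no nonsynonymous site available in ", gid)
        } else if (ev == "stop_gain_snp") {
          c0 <- if (length(internal) == 1L) internal else sample(internal, 1L)
          cod <- codon_at(c0)
          new <- "TAA"
          for (k in 1:3) if (substr(cod, k, k) != substr(new, k, k))
            sub_tx(3L * c0 - 3L + k, substr(new, k, k))
        } else if (ev == "start_loss") {
          if (substr(cds, 1L, 3L) != "ATG")
            stop("gene ", gid, " does not start with ATG")
          sub_tx(3L, "A")  # ATG -> ATA (Met -> Ile)
        } else if (ev == "inframe_del") {
          c0 <- if (length(internal) == 1L) internal else sample(internal, 1L)
          o <- (3L * c0 - 2L):(3L * c0)
          indels <- c(indels, list(list(chrom = chrom,
                                        p1 = min(gpos[o]), p2 = max(gpos[o]))))
        } else if (ev == "frameshift_indel") {
          c0 <- if (length(internal) == 1L) internal else sample(internal, 1L)
          p <- gpos[3L * c0 - 1L]
          indels <- c(indels, list(list(chrom = chrom, p1 = p, p2 = p)))
        } else if (ev == "inframe_ins") {
          c0 <- if (length(internal) == 1L) internal else sample(internal, 1L)
          cod <- sample(.SENSE_CODONS, 1L)
          if (strand == "-") {
            indels <- c(indels, list(list(chrom = chrom,
                                          p = gpos[3L * c0] - 1L,
                                          ins = .revcomp(cod))))
          } else {
            indels <- c(indels, list(list(chrom = chrom, p = gpos[3L * c0],
                                          ins = cod)))
          }
        } else if (ev == "five_prime_trunc") {
          o <- 1:6
          if (!all(abs(diff(gpos[o])) == 1L))
            stop("CDS start of ", gid, " is split by an intron")
          indels <- c(indels, list(list(chrom = chrom,
                                        p1 = min(gpos[o]), p2 = max(gpos[o]))))
        } else if (ev == "three_prime_trunc") {
          o <- (nchar(cds) - 5L):nchar(cds)
          if (!all(abs(diff(gpos[o])) == 1L))
            stop("CDS end of ", gid, " is split by an intron")
          indels <- c(indels, list(list(chrom = chrom,
                                        p1 = min(gpos[o]), p2 = max(gpos[o]))))
        }
      } else if (ev == "gene_deletion") {
        del_genes <- c(del_genes, gid)
      } else if (ev == "gene_duplication") {
        rate <- specs$subs_rate[i]
        appends <- c(appends, list(list(
          kind = "dup", gid = gid,
          rate = if (is.na(rate)) 0.02 else rate,
          dest = chrom)))
      } else if (ev == "translocation") {
        dest <- specs$dest_chrom[i]
        if (is.na(dest)) {
          cn <- names(seqs)
          dest <- cn[(match(chrom, cn) %% length(cn)) + 1L]
        }
        appends <- c(appends, list(list(kind = "move", gid = gid,
                                        dest = dest)))
        del_genes <- c(del_genes, gid)  # features removed from origin
      }
    }

    # apply indels, per chromosome, in decreasing position order
    key <- vapply(indels, function(e)
      if (!is.null(e$ins)) e$p else e$p1, numeric(1))
    for (j in order(-key)) {
      e <- indels[[j]]
      if (is.null(e$ins)) {
        seqs[e$chrom] <- paste0(substr(seqs[e$chrom], 1L, e$p1 - 1L),
                                substring(seqs[e$chrom], e$p2 + 1L))
        genes <- .shift_deletion(genes, e$chrom, e$p1, e$p2)
        txs <- .shift_deletion(txs, e$chrom, e$p1, e$p2)
        segs <- .shift_deletion(segs, e$chrom, e$p1, e$p2)
      } else {
        L <- nchar(e$ins)
        seqs[e$chrom] <- paste0(substr(seqs[e$chrom], 1L, e$p), e$ins,
                                substring(seqs[e$chrom], e$p + 1L))
        genes <- .shift_insertion(genes, e$chrom, e$p, L)
        txs <- .shift_insertion(txs, e$chrom, e$p, L)
        segs <- .shift_insertion(segs, e$chrom, e$p, L)
      }
    }

    # drop deleted and translocated-origin genes (sequence is left in
    # place; only the features go) before re-adding moved loci
    if (length(del_genes)) {
      drop_tx <- txs$id[txs$gene_id %in% del_genes]
      genes <- genes[!genes$id %in% del_genes, , drop = FALSE]
      txs <- txs[!txs$gene_id %in% del_genes, , drop = FALSE]
      segs <- segs[!segs$transcript_id %in% drop_tx, , drop = FALSE]
    }

    # append duplicated / translocated loci at chromosome ends (never
    # shifts existing coordinates); span sequence and relative feature
    # layout come from the untouched reference gene
    for (e in appends) {
      g0 <- ann$genes[ann$genes$id == e$gid, ]
      span <- assembly_seq(asm, g0$seqid, g0$start, g0$end, "+")
      if (e$kind == "dup" && e$rate > 0) {
        nsub <- max(1L, round(e$rate * nchar(span)))
        at <- sample(nchar(span), nsub)
        for (p in at) {
          old <- substr(span, p, p)
          substr(span, p, p) <- sample(setdiff(.BASES, old), 1L)
        }
      }
      offset <- nchar(seqs[e$dest]) + 100L
      seqs[e$dest] <- paste0(seqs[e$dest], .rand_nt(100L), span)
      sfx <- if (e$kind == "dup") "_1" else ""
      shift <- function(x) x - g0$start + offset + 1L
      genes <- rbind(genes, data.frame(
        id = paste0(e$gid, sfx), seqid = e$dest,
        start = shift(g0$start), end = shift(g0$end), strand = g0$strand,
        stringsAsFactors = FALSE))
      t0 <- ann$transcripts[ann$transcripts$gene_id == e$gid, , drop = FALSE]
      for (j in seq_len(nrow(t0))) {
        txs <- rbind(txs, data.frame(
          id = paste0(t0$id[j], sfx), gene_id = paste0(e$gid, sfx),
          type = t0$type[j], seqid = e$dest,
          start = shift(t0$start[j]), end = shift(t0$end[j]),
          strand = t0$strand[j], stringsAsFactors = FALSE))
        s0 <- ann$segments[ann$segments$transcript_id == t0$id[j], ,
                           drop = FALSE]
        segs <- rbind(segs, data.frame(
          transcript_id = paste0(t0$id[j], sfx), type = s0$type,
          seqid = e$dest, start = shift(s0$start), end = shift(s0$end),
          strand = s0$strand, phase = s0$phase, stringsAsFactors = FALSE))
      }
    }

    # coordinate-sort features within the assembly's chromosome order
    cn <- names(seqs)
    genes <- genes[order(match(genes$seqid, cn), genes$start, genes$id), ,
                   drop = FALSE]
    txs <- txs[order(match(txs$seqid, cn), txs$start, txs$id), , drop = FALSE]
    segs <- segs[order(match(segs$seqid, cn), segs$start,
                       segs$transcript_id, segs$type), , drop = FALSE]
    rownames(genes) <- rownames(txs) <- rownames(segs) <- NULL

    tgt_ann <- structure(list(genes = genes, transcripts = txs,
                              segments = segs, source_dialect = "GFF3"),
                         class = "annotation")
    validate_annotation(tgt_ann)

    truth <- data.frame(gene_id = ann$genes$id, event = "none",
                        stringsAsFactors = FALSE)
    truth$event[match(specs$gene_id, truth$gene_id)] <- specs$event
    truth$expected_effect <- unname(.EXPECTED_EFFECT[truth$event])
    truth$cluster_delta <- ifelse(truth$event == "gene_duplication", 1L,
                                  ifelse(truth$event == "gene_deletion",
                                         -1L, 0L))
    truth$translocated <- truth$event == "translocation"

    list(asm = assembly(seqs), ann = tgt_ann, truth = truth)
  })
}

#' The standard 50-gene validation fixture
#'
#' 50 genes (40 coding, 10 noncoding) on 3 chromosomes, with one event of
#' every class the mutation engine supports: the nine coding effect classes
#' on genes 1-9, a gene deletion (gene 10), two divergent gene duplications
#' (genes 11 and 12, 2% substitutions) and one translocation (gene 13).
#'
#' @param seed integer seed.
#' @return A list with `ref`, `tgt` (each `asm` + `ann`) and `truth`.
#' @export
make_standard_fixture <- function(seed = 1L) {
  ref <- make_reference(n_genes = 50L, n_chroms = 3L, coding_fraction = 0.8,
                        seed = seed)
  specs <- data.frame(
    gene_id = sprintf("gene%03d", 1:13),
    event = c("synonymous_snp", "nonsynonymous_snp", "inframe_del",
              "inframe_ins", "start_loss", "five_prime_trunc",
              "three_prime_trunc", "frameshift_indel", "stop_gain_snp",
              "gene_deletion", "gene_duplication", "gene_duplication",
              "translocation"),
    stringsAsFactors = FALSE)
  tgt <- apply_mutations(ref, specs, seed = seed + 1L)
  list(ref = ref, tgt = tgt[c("asm", "ann")], truth = tgt$truth)
}

#' Write a fixture pair to disk
#'
#' Writes `ref.fa`, `ref.gff3`, `target.fa`, `target.gff3` and `truth.tsv`
#' into `dir`.
#'
#' @param fixture a [make_standard_fixture()]-shaped list (`ref`, `tgt`,
#'   `truth`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(fixture$ref$asm$sequences,
                              file.path(dir, "ref.fa"))
  write_annotation(fixture$ref$ann, file.path(dir, "ref.gff3"), "GFF3")
  Biostrings::writeXStringSet(fixture$tgt$asm$sequences,
                              file.path(dir, "target.fa"))
  write_annotation(fixture$tgt$ann, file.path(dir, "target.gff3"), "GFF3")
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Synthetic paralog families for clustering validation
#'
#' Generates protein families: each family has one random founder sequence
#' and `copies - 1` derived copies carrying `divergence` substitutions.
#' Random founders of different families share only chance identity (well
#' under 50%), so the generating families are the ground-truth clustering.
#'
#' @param n_families number of families.
#' @param copies copies per family (recycled across families).
#' @param aa_len founder protein length.
#' @param divergence per-copy substitution fraction.
#' @param seed integer seed.
#' @return A list with `inputs` (a [cluster_inputs()]-shaped data frame)
#'   and `family` (named integer vector: gene ID -> family index).
#' @export
make_gene_families <- function(n_families = 6L, copies = c(2L, 3L, 4L),
                               aa_len = 300L, divergence = 0.02,
                               seed = 1L) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  copies <- rep_len(copies, n_families)
  withr::with_seed(seed, {
    ids <- character(0); seqsv <- character(0); fam <- integer(0)
    for (f in seq_len(n_families)) {
      founder <- paste(sample(aas, aa_len, replace = TRUE), collapse = "")
      for (k in seq_len(copies[f])) {
        s <- founder
        if (k > 1L) {
          nsub <- max(1L, round(divergence * aa_len))
          at <- sample(aa_len, nsub)
          for (p in at) {
            old <- substr(s, p, p)
            substr(s, p, p) <- sample(setdiff(aas, old), 1L)
          }
        }
        ids <- c(ids, sprintf("fam%02d.copy%d", f, k))
        seqsv <- c(seqsv, s)
        fam <- c(fam, f)
      }
    }
    list(inputs = data.frame(gene_id = ids, sequence = seqsv,
                             alphabet = "protein", stringsAsFactors = FALSE),
         family = stats::setNames(fam, ids))
  })
}
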