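#' Variant effect categories in severity order
#'
#' The ordered vocabulary of per-transcript effect labels, least to most
#' severe. Only the relative position of `synonymous` below `frameshift` is
#' dictated by the reduction to a single most-severe effect; the remaining
#' positions order the categories by expected functional disruption and can
#' be replaced by supplying a custom ranking to [most_severe()].
#'
#' @return Character vector of the ten effect labels, least severe first.
#'   `"unmapped"` sits outside the ranking and marks reference transcripts
#'   absent from the target annotation.
#' @export
effect_levels <- function() {
  c("identical", "synonymous", "nonsynonymous", "inframe_deletion",
    "inframe_insertion", "five_prime_truncation", "three_prime_truncation",
    "start_lost", "stop_gained", "frameshift")
}

#' Reduce a set of detected effects to the single most severe
#'
#' @param effects nonempty character vector of effect labels.
#' @param ranking character vector defining the severity order, least severe
#'   first; defaults to [effect_levels()].
#' @return The label with the highest severity rank.
#' @examples
#' most_severe(c("synonymous", "frameshift"))  # "frameshift"
#' @export
most_severe <- function(effects, ranking = effect_levels()) {
  if (length(effects) == 0L) stop("empty effect set")
  r <- match(effects, ranking)
  if (anyNA(r)) stop("unknown effect label(s): ",
                     paste(effects[is.na(r)], collapse = ", "))
  ranking[max(r)]
}

# maximal gap runs of one side of an alignment
.gap_runs <- function(aligned) {
  ch <- strsplit(aligned, "", fixed = TRUE)[[1L]]
  r <- rle(ch == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep])
}

#' Detect variant effects from CDS and protein alignments
#'
#' Classifies the differences between a reference coding sequence and its
#' lifted counterpart. Each rule fires independently and all detected labels
#' are returned; use [most_severe()] to reduce them to one call.
#'
#' Rules, in terms of the nucleotide CDS alignment (`ref` = `a`, `tgt` = `b`)
#' and the protein alignment of their translations:
#' * `identical` - the CDS nucleotide sequences are identical.
#' * `five_prime_truncation` / `three_prime_truncation` - a gap run in the
#'   target touching the first / last alignment column and deleting the
#'   entire reference start / stop codon (length >= 3).
#' * `frameshift` - any remaining (non-truncation) gap run whose length is
#'   not a multiple of 3.
#' * `inframe_deletion` / `inframe_insertion` - an internal gap run in the
#'   target / reference whose length is a multiple of 3.
#' * `start_lost` - the target's first codon is aligned (no terminal gap)
#'   but is not ATG.
#' * `stop_gained` - the translated target carries `"*"` at an alignment
#'   column strictly before the reference protein's last residue.
#' * `nonsynonymous` - at least one substitution column in the protein
#'   alignment; `synonymous` - nucleotide substitutions but identical
#'   proteins.
#'
#' @param ref_cds,tgt_cds the coding sequences (reference and target).
#' @param nt_aln `pairwise_alignment` of `ref_cds` (a) vs `tgt_cds` (b).
#' @param aa_aln `pairwise_alignment` of their translations
#'   ([translate_cds()]), or `NULL` when either translation is empty.
#' @return Character vector of detected effect labels (at least one).
#' @export
detect_effects <- function(ref_cds, tgt_cds, nt_aln, aa_aln) {
  stopifnot(inherits(nt_aln, "pairwise_alignment"))
  if (!identical(gsub("-", "", nt_aln$aligned_a, fixed = TRUE), ref_cds) ||
      !identical(gsub("-", "", nt_aln$aligned_b, fixed = TRUE), tgt_cds))
    stop("nt_aln does not align the given CDS pair")
  if (identical(ref_cds, tgt_cds)) return("identical")

  eff <- character(0)
  cols <- nt_aln$columns
  runs_a <- .gap_runs(nt_aln$aligned_a)  # insertions in target
  runs_b <- .gap_runs(nt_aln$aligned_b)  # deletions from target

  trunc5 <- nrow(runs_b) > 0L & runs_b$start == 1L & runs_b$len >= 3L
  trunc3 <- nrow(runs_b) > 0L & runs_b$end == cols & runs_b$len >= 3L
  if (any(trunc5)) eff <- c(eff, "five_prime_truncation")
  if (any(trunc3)) eff <- c(eff, "three_prime_truncation")

  rest_b <- runs_b[!(trunc5 | trunc3), , drop = FALSE]
  if (any(rest_b$len %% 3L != 0L) || any(runs_a$len %% 3L != 0L))
    eff <- c(eff, "frameshift")
  internal_b <- rest_b[rest_b$start > 1L & rest_b$end < cols, , drop = FALSE]
  if (any(internal_b$len %% 3L == 0L)) eff <- c(eff, "inframe_deletion")
  internal_a <- runs_a[runs_a$start > 1L & runs_a$end < cols, , drop = FALSE]
  if (any(internal_a$len %% 3L == 0L)) eff <- c(eff, "inframe_insertion")

  b1 <- substr(nt_aln$aligned_b, 1L, 1L)
  a1 <- substr(nt_aln$aligned_a, 1L, 1L)
  if (b1 != "-" && a1 != "-" && substr(tgt_cds, 1L, 3L) != "ATG")
    eff <- c(eff, "start_lost")

  ref_aa <- if (nchar(ref_cds) >= 3L) translate_cds(ref_cds) else ""
  tgt_aa <- if (nchar(tgt_cds) >= 3L) translate_cds(tgt_cds) else ""
  if (!is.null(aa_aln)) {
    stopifnot(inherits(aa_aln, "pairwise_alignment"))
    ca <- strsplit(aa_aln$aligned_a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(aa_aln$aligned_b, "", fixed = TRUE)[[1L]]
    ref_pos <- which(ca != "-")
    last_ref_col <- if (length(ref_pos)) max(ref_pos) else 0L
    if (any(cb == "*" & seq_along(cb) < last_ref_col))
      eff <- c(eff, "stop_gained")
    if (any(ca != "-" & cb != "-" & ca != cb))
      eff <- c(eff, "nonsynonymous")
  }
  nt_sub <- {
    xa <- strsplit(nt_aln$aligned_a, "", fixed = TRUE)[[1L]]
    xb <- strsplit(nt_aln$aligned_b, "", fixed = TRUE)[[1L]]
    any(xa != "-" & xb != "-" & xa != xb)
  }
  if (nt_sub && identical(ref_aa, tgt_aa)) eff <- c(eff, "synonymous")

  if (length(eff) == 0L)
    eff <- if (identical(ref_aa, tgt_aa)) "synonymous" else "nonsynonymous"
  unique(eff)
}

#' Compare all reference transcripts against the target annotation
#'
#' For every reference transcript: shared transcripts get a nucleotide
#' identity from a whole-transcript global alignment; coding transcripts
#' additionally get a protein identity and a variant-effect call computed on
#' the CDS alignment (so UTR-only changes keep the label `identical` while
#' showing a nucleotide identity below 1); reference transcripts absent from
#' the target get `unmapped`; noncoding transcripts get a nucleotide
#' identity only.
#'
#' The terminal stop codon is kept in the CDS for the nucleotide alignment
#' (3' truncation detection needs it) but trimmed from the translations
#' before the protein comparison.
#'
#' @param ref_asm,tgt_asm `assembly` objects.
#' @param ref_ann,tgt_ann `annotation` objects.
#' @param match a [match_features()] result.
#' @param nt_sch,aa_sch scoring schemes for the nucleotide and protein
#'   alignments.
#' @param ranking severity order for the most-severe reduction.
#' @return A data frame with one row per reference transcript: columns
#'   `transcript_id`, `gene_id`, `nt_identity`, `protein_identity`, `effect`
#'   and `detected` (comma-joined full set of detected labels).
#' @export
compare_transcripts <- function(ref_asm, tgt_asm, ref_ann, tgt_ann, match,
                                nt_sch = nt_scheme(), aa_sch = aa_scheme(),
                                ranking = effect_levels()) {
  txs <- ref_ann$transcripts
  n <- nrow(txs)
  out <- data.frame(transcript_id = txs$id, gene_id = txs$gene_id,
                    nt_identity = rep(NA_real_, n),
                    protein_identity = rep(NA_real_, n),
                    effect = rep(NA_character_, n),
                    detected = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  shared <- match$shared_transcript_ids
  for (i in seq_len(n)) {
    tid <- txs$id[i]
    if (!tid %in% shared) {
      out$effect[i] <- "unmapped"
      out$detected[i] <- "unmapped"
      next
    }
    ref_tx <- extract_transcript_sequence(ref_asm, ref_ann, tid)
    tgt_tx <- extract_transcript_sequence(tgt_asm, tgt_ann, tid)
    out$nt_identity[i] <- if (identical(ref_tx, tgt_tx)) 1
      else percent_identity(global_align(ref_tx, tgt_tx, nt_sch))

    ref_cds <- extract_cds_sequence(ref_asm, ref_ann, tid)
    if (is.na(ref_cds)) next  # noncoding: identity only
    tgt_cds <- extract_cds_sequence(tgt_asm, tgt_ann, tid)
    if (is.na(tgt_cds)) {
      # coding in reference, no CDS annotated in target
      out$effect[i] <- "unmapped"
      out$detected[i] <- "unmapped"
      next
    }
    if (identical(ref_cds, tgt_cds)) {
      out$protein_identity[i] <- 1
      out$effect[i] <- "identical"
      out$detected[i] <- "identical"
      next
    }
    nt_aln <- global_align(ref_cds, tgt_cds, nt_sch)
    ref_aa <- if (nchar(ref_cds) >= 3L) translate_cds(ref_cds) else ""
    tgt_aa <- if (nchar(tgt_cds) >= 3L) translate_cds(tgt_cds) else ""
    aa_aln <- if (nchar(ref_aa) && nchar(tgt_aa))
      global_align(ref_aa, tgt_aa, aa_sch) else NULL
    eff <- detect_effects(ref_cds, tgt_cds, nt_aln, aa_aln)
    out$effect[i] <- most_severe(eff, ranking)
    out$detected[i] <- paste(sort(eff), collapse = ",")
    out$protein_identity[i] <- if (!is.null(aa_aln))
      percent_identity(aa_aln) else 0
  }
  out
}

#' Tabulate effect calls
#'
#' Counts transcripts per effect class, in severity order, the shape of the
#' summary the variants analysis logs.
#'
#' @param comparisons result of [compare_transcripts()].
#' @return Named integer vector of counts.
#' @export
summarize_effects <- function(comparisons) {
  lv <- c(effect_levels(), "unmapped")
  eff <- comparisons$effect[!is.na(comparisons$effect)]
  table(factor(eff, levels = lv))
}
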