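#' Chromosome order of an annotation
#'
#' Chromosomes are ordered by first appearance among the annotation's gene
#' rows (file order). Each annotation uses its own order, since reference
#' and target naming may differ; this avoids lexicographic traps such as
#' chr10 sorting before chr2.
#'
#' @param ann an `annotation`.
#' @return Character vector of sequence names.
#' @export
chromosome_order <- function(ann) unique(ann$genes$seqid)

#' Ordinal gene positions within one annotation
#'
#' The selected genes are sorted first by chromosome (position of the
#' chromosome in `chrom_order`), then by start coordinate, with ties broken
#' by gene ID, and numbered 1..N in that order.
#'
#' @param ann an `annotation`.
#' @param gene_ids genes to rank (a subset of the annotation's genes).
#' @param chrom_order chromosome ordering; defaults to
#'   [chromosome_order()] of `ann`.
#' @return Named integer vector mapping gene ID to ordinal.
#' @export
ordinal_positions <- function(ann, gene_ids,
                              chrom_order = chromosome_order(ann)) {
  g <- ann$genes[ann$genes$id %in% gene_ids, , drop = FALSE]
  missing <- setdiff(gene_ids, g$id)
  if (length(missing))
    stop("gene(s) not in annotation: ", paste(missing, collapse = ", "))
  ci <- match(g$seqid, chrom_order)
  if (anyNA(ci))
    stop("gene(s) on chromosome(s) missing from chrom_order: ",
         paste(unique(g$seqid[is.na(ci)]), collapse = ", "))
  o <- order(ci, g$start, g$id)
  stats::setNames(seq_along(o), g$id[o])
}

#' Build the synteny table of shared genes
#'
#' One record per gene present in both annotations, giving its ordinal
#' position in each (unmapped and extra-copy genes are excluded before
#' ranking, so ordinals are packed 1..N on both axes).
#'
#' @param ref_ann,tgt_ann `annotation` objects.
#' @param match a [match_features()] result.
#' @param identities optional named numeric vector (gene ID -> sequence
#'   identity in `[0, 1]`); genes absent from it carry `NA`.
#' @return A data frame sorted by reference ordinal with columns `gene_id`,
#'   `ref_chrom`, `ref_ordinal`, `tgt_chrom`, `tgt_ordinal`, `identity`.
#' @export
build_synteny_table <- function(ref_ann, tgt_ann, match, identities = NULL) {
  shared <- match$shared_gene_ids
  if (length(shared) == 0L)
    return(data.frame(gene_id = character(0), ref_chrom = character(0),
                      ref_ordinal = integer(0), tgt_chrom = character(0),
                      tgt_ordinal = integer(0), identity = numeric(0)))
  ro <- ordinal_positions(ref_ann, shared)
  to <- ordinal_positions(tgt_ann, shared)
  ids <- names(sort(ro))
  df <- data.frame(
    gene_id = ids,
    ref_chrom = ref_ann$genes$seqid[match(ids, ref_ann$genes$id)],
    ref_ordinal = unname(ro[ids]),
    tgt_chrom = tgt_ann$genes$seqid[match(ids, tgt_ann$genes$id)],
    tgt_ordinal = unname(to[ids]),
    identity = if (is.null(identities)) NA_real_
               else unname(identities[ids]),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  stopifnot(setequal(df$ref_ordinal, seq_along(ids)),
            setequal(df$tgt_ordinal, seq_along(ids)))
  df
}

#' Genes lying off the chromosome block diagonal
#'
#' In an ordinal dot plot with chromosome separators, a gene sits inside
#' its own chromosome's diagonal block unless it moved to a different
#' chromosome. This returns the records whose chromosome block index
#' differs between the two annotations - the visibly off-diagonal points
#' (small within-chromosome ordinal shifts caused by neighbours moving are
#' not counted).
#'
#' @param records a [build_synteny_table()] result.
#' @param ref_chrom_order,tgt_chrom_order chromosome orders used for the
#'   block indices; default to order of appearance in `records`.
#' @return The off-diagonal subset of `records`.
#' @export
off_diagonal <- function(records,
                         ref_chrom_order =
                           unique(records$ref_chrom[order(records$ref_ordinal)]),
                         tgt_chrom_order =
                           unique(records$tgt_chrom[order(records$tgt_ordinal)])) {
  ri <- match(records$ref_chrom, ref_chrom_order)
  ti <- match(records$tgt_chrom, tgt_chrom_order)
  records[ri != ti, , drop = FALSE]
}

#' Edit distance between two gene orders
#'
#' Levenshtein distance between the two ID sequences, each gene one symbol
#' (substitutions, insertions and deletions cost 1). Both lists must be
#' permutations of the same ID set.
#'
#' @param ref_order,tgt_order character vectors of gene IDs.
#' @return Non-negative integer distance.
#' @export
order_edit_distance <- function(ref_order, tgt_order) {
  if (anyDuplicated(ref_order) || anyDuplicated(tgt_order) ||
      !setequal(ref_order, tgt_order) ||
      length(ref_order) != length(tgt_order))
    stop("gene orders must be permutations of the same ID set")
  n <- length(ref_order)
  if (n == 0L) return(0L)
  # encode each gene as one Unicode character and use C-level adist();
  # codepoints start above ASCII and skip the surrogate range
  code <- seq_len(n) + 0x100L
  code <- code + ifelse(code >= 0xD800L, 0x0800L, 0L)
  enc <- function(ids) intToUtf8(code[match(ids, ref_order)])
  as.integer(utils::adist(enc(ref_order), enc(tgt_order)))
}

#' Render the synteny dot plot
#'
#' One point per shared gene at (reference ordinal, target ordinal). Point
#' colour interpolates green (identity 1) to red (identity at or below
#' `identity_floor`); genes without an identity are drawn gray. Gray lines
#' separate the chromosomes on both axes.
#'
#' @param records a [build_synteny_table()] result (nonempty).
#' @param out_path output image path; the device is chosen from the
#'   extension (`.png`, `.pdf`, `.svg`).
#' @param identity_floor identity mapped to the fully red end of the scale.
#' @param width,height,dpi device settings passed to [ggplot2::ggsave()].
#' @return `out_path`, invisibly.
#' @export
render_dotplot <- function(records, out_path, identity_floor = 0.5,
                           width = 6, height = 6, dpi = 150) {
  if (nrow(records) == 0L) stop("no synteny records to plot")
  d <- records
  d$identity_clamped <- pmax(d$identity, identity_floor)
  ref_b <- cumsum(rle(d$ref_chrom[order(d$ref_ordinal)])$lengths)
  tgt_b <- cumsum(rle(d$tgt_chrom[order(d$tgt_ordinal)])$lengths)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ref_ordinal,
                                       y = .data$tgt_ordinal)) +
    ggplot2::geom_vline(xintercept = ref_b[-length(ref_b)] + 0.5,
                        colour = "gray70", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = tgt_b[-length(tgt_b)] + 0.5,
                        colour = "gray70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$identity_clamped),
                        size = 0.8, na.rm = FALSE) +
    ggplot2::scale_colour_gradient(low = "red", high = "green3",
                                   limits = c(identity_floor, 1),
                                   na.value = "gray50",
                                   name = "identity") +
    ggplot2::labs(x = "ordinal position in reference",
                  y = "ordinal position in target") +
    ggplot2::theme_bw()
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}

#' Gene-level sequence identities via longest-isoform alignment
#'
#' For each shared gene, aligns the spliced sequence of the reference
#' gene's longest isoform against the target's transcript of the same ID
#' and reports percent identity. When the target annotation carries
#' Liftoff's `sequence_ID` attribute those values are used instead of
#' realigning.
#'
#' @param ref_asm,tgt_asm `assembly` objects.
#' @param ref_ann,tgt_ann `annotation` objects.
#' @param match a [match_features()] result.
#' @param nt_sch nucleotide scoring scheme.
#' @param use_attribute use the target's `sequence_ID` attribute when
#'   present instead of aligning.
#' @return Named numeric vector, gene ID -> identity.
#' @export
gene_identities <- function(ref_asm, tgt_asm, ref_ann, tgt_ann, match,
                            nt_sch = nt_scheme(), use_attribute = TRUE) {
  shared <- match$shared_gene_ids
  if (use_attribute && "sequence_ID" %in% names(tgt_ann$genes)) {
    v <- tgt_ann$genes$sequence_ID[match(shared, tgt_ann$genes$id)]
    if (!all(is.na(v))) return(stats::setNames(as.numeric(v), shared))
  }
  out <- stats::setNames(rep(NA_real_, length(shared)), shared)
  for (g in shared) {
    tid <- longest_isoform(ref_ann, g)
    if (!tid %in% match$shared_transcript_ids) next
    a <- extract_transcript_sequence(ref_asm, ref_ann, tid)
    b <- extract_transcript_sequence(tgt_asm, tgt_ann, tid)
    out[g] <- if (identical(a, b)) 1
      else percent_identity(global_align(a, b, nt_sch))
  }
  out
}
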