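#' Per-gene clustering inputs
#'
#' One sequence per gene, taken from its longest isoform: the translated
#' CDS (protein alphabet) for protein-coding genes, the spliced transcript
#' (nucleotide alphabet) for noncoding genes. Mixed-alphabet comparisons
#' are never attempted downstream.
#'
#' @param asm an `assembly`.
#' @param ann an `annotation`.
#' @param gene_ids genes to include; defaults to all genes.
#' @return A data frame with columns `gene_id`, `sequence`, `alphabet`.
#' @export
cluster_inputs <- function(asm, ann, gene_ids = ann$genes$id) {
  n <- length(gene_ids)
  seqs <- character(n); alph <- character(n)
  for (i in seq_len(n)) {
    tid <- longest_isoform(ann, gene_ids[i])
    cds <- extract_cds_sequence(asm, ann, tid)
    if (!is.na(cds) && nchar(cds) >= 3L) {
      seqs[i] <- translate_cds(cds)
      alph[i] <- "protein"
    } else {
      seqs[i] <- extract_transcript_sequence(asm, ann, tid)
      alph[i] <- "nucleotide"
    }
  }
  data.frame(gene_id = gene_ids, sequence = seqs, alphabet = alph,
             stringsAsFactors = FALSE)
}

#' Identity-and-coverage similarity test for a sequence pair
#'
#' Two sequences are similar when, in their global alignment, the fraction
#' of identical columns is at least `min_id` and each sequence is covered
#' over at least `min_cov` of its length. Coverage is tested twice: the
#' shorter sequence must be at least `min_cov` times the longer one, and
#' within the aligned core (between the first and last column where both
#' sequences have residues) each sequence must contribute at least
#' `min_cov` of its residues.
#'
#' @param a,b sequences (character scalars).
#' @param alphabet `"protein"` or `"nucleotide"` - must be the same for
#'   both sequences.
#' @param min_id minimum identity fraction (default 0.9).
#' @param min_cov minimum bidirectional coverage fraction (default 0.9).
#' @param scheme scoring scheme; defaults to [aa_scheme()] or [nt_scheme()]
#'   according to `alphabet`.
#' @return `TRUE` or `FALSE`.
#' @export
pair_similar <- function(a, b, alphabet = c("protein", "nucleotide"),
                         min_id = 0.9, min_cov = 0.9, scheme = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(scheme))
    scheme <- if (alphabet == "protein") aa_scheme() else nt_scheme()
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L || lb == 0L) return(FALSE)
  if (min(la, lb) < min_cov * max(la, lb)) return(FALSE)
  aln <- global_align(a, b, scheme)
  if (percent_identity(aln) < min_id) return(FALSE)
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  both <- which(ca != "-" & cb != "-")
  if (length(both) == 0L) return(FALSE)
  core <- seq(min(both), max(both))
  sum(ca[core] != "-") >= min_cov * la && sum(cb[core] != "-") >= min_cov * lb
}

#' Greedy paralog clustering of reference genes
#'
#' Inputs are processed in decreasing sequence length (ties by gene ID);
#' each gene joins the first existing cluster whose representative passes
#' [pair_similar()] with matching alphabet, otherwise it founds a new
#' cluster with itself as representative. The result is deterministic given
#' the inputs and thresholds, and partitions the input gene set.
#'
#' @param inputs a [cluster_inputs()] data frame.
#' @param min_id,min_cov thresholds passed to [pair_similar()].
#' @param aa_sch,nt_sch scoring schemes for the two alphabets.
#' @return A list of clusters, each a list with `cluster_id`,
#'   `representative`, `members` (character vector) and `alphabet`.
#' @export
cluster_reference <- function(inputs, min_id = 0.9, min_cov = 0.9,
                              aa_sch = aa_scheme(), nt_sch = nt_scheme()) {
  if (nrow(inputs) == 0L) return(list())
  inputs <- inputs[order(-nchar(inputs$sequence), inputs$gene_id), ,
                   drop = FALSE]
  clusters <- list()
  rep_seq <- character(0); rep_alph <- character(0)
  for (i in seq_len(nrow(inputs))) {
    gid <- inputs$gene_id[i]; s <- inputs$sequence[i]
    al <- inputs$alphabet[i]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      if (rep_alph[k] != al) next
      sch <- if (al == "protein") aa_sch else nt_sch
      if (pair_similar(rep_seq[k], s, al, min_id, min_cov, sch)) {
        clusters[[k]]$members <- c(clusters[[k]]$members, gid)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      k <- length(clusters) + 1L
      clusters[[k]] <- list(cluster_id = sprintf("cluster_%04d", k),
                            representative = gid, members = gid,
                            alphabet = al)
      rep_seq[k] <- s; rep_alph[k] <- al
    }
  }
  clusters
}

#' Derive target clusters and per-cluster copy-number change
#'
#' Each reference cluster is carried to the target by removing genes absent
#' from the target annotation and attaching extra gene copies to the
#' cluster containing their source gene (the copy's ID suffix names its
#' origin). For reporting, each attached copy's closest paralog - the
#' reference cluster member with the highest global-alignment identity to
#' the copy's target sequence, ties broken by smaller gene ID - is recorded.
#' Reference clusters that lose every member persist with a target count of
#' zero, so runs without extra copies still report copy-number loss.
#'
#' @param ref_clusters a [cluster_reference()] result.
#' @param match a [match_features()] result.
#' @param ref_inputs cluster inputs for the reference genes (member
#'   sequences for the closest-paralog search).
#' @param tgt_inputs cluster inputs for the extra-copy genes, with
#'   sequences extracted from the target assembly. May be `NULL` when there
#'   are no extra copies.
#' @param aa_sch,nt_sch scoring schemes.
#' @return A data frame with one row per cluster: `cluster_id`,
#'   `ref_count`, `tgt_count`, `delta`, `ref_members`, `tgt_members`
#'   (comma-joined). Attribute `copy_assignments` is a data frame of
#'   (copy_id, source, cluster_id, closest_paralog, identity); attribute
#'   `unassigned_copies` lists extra copies whose source gene is in no
#'   cluster.
#' @export
derive_target_clusters <- function(ref_clusters, match, ref_inputs,
                                   tgt_inputs = NULL,
                                   aa_sch = aa_scheme(), nt_sch = nt_scheme()) {
  shared <- match$shared_gene_ids
  nk <- length(ref_clusters)
  tgt_members <- lapply(ref_clusters, function(cl)
    intersect(cl$members, shared))

  assigns <- data.frame(copy_id = character(0), source = character(0),
                        cluster_id = character(0),
                        closest_paralog = character(0),
                        identity = numeric(0), stringsAsFactors = FALSE)
  unassigned <- character(0)
  copies <- match$extra_copies
  member_of <- stats::setNames(
    rep(seq_len(nk), lengths(lapply(ref_clusters, `[[`, "members"))),
    unlist(lapply(ref_clusters, `[[`, "members")))
  for (cid in names(copies)) {
    src <- copies[[cid]]
    k <- member_of[src]
    if (is.na(k)) { unassigned <- c(unassigned, cid); next }
    k <- as.integer(k)
    cl <- ref_clusters[[k]]
    best_id <- NA_real_; best <- NA_character_
    if (!is.null(tgt_inputs) && cid %in% tgt_inputs$gene_id) {
      cseq <- tgt_inputs$sequence[tgt_inputs$gene_id == cid][1L]
      calph <- tgt_inputs$alphabet[tgt_inputs$gene_id == cid][1L]
      sch <- if (calph == "protein") aa_sch else nt_sch
      for (m in sort(cl$members)) {
        mrow <- ref_inputs[ref_inputs$gene_id == m, , drop = FALSE]
        if (nrow(mrow) == 0L || mrow$alphabet[1L] != calph) next
        pid <- percent_identity(global_align(mrow$sequence[1L], cseq, sch))
        if (is.na(best_id) || pid > best_id) { best_id <- pid; best <- m }
      }
    }
    tgt_members[[k]] <- c(tgt_members[[k]], cid)
    assigns <- rbind(assigns, data.frame(
      copy_id = cid, source = src, cluster_id = cl$cluster_id,
      closest_paralog = best, identity = best_id, stringsAsFactors = FALSE))
  }

  out <- data.frame(
    cluster_id = vapply(ref_clusters, `[[`, character(1), "cluster_id"),
    ref_count = vapply(ref_clusters, function(cl) length(cl$members),
                       integer(1)),
    tgt_count = lengths(tgt_members),
    stringsAsFactors = FALSE)
  out$delta <- out$tgt_count - out$ref_count
  out$ref_members <- vapply(ref_clusters, function(cl)
    paste(cl$members, collapse = ","), character(1))
  out$tgt_members <- vapply(tgt_members, paste, character(1), collapse = ",")
  attr(out, "copy_assignments") <- assigns
  attr(out, "unassigned_copies") <- unassigned
  out
}

#' Copy-number gain/loss summary
#'
#' @param comparisons a [derive_target_clusters()] result.
#' @return A list: counts of clusters with negative, positive and zero
#'   copy-number change, total copies lost and gained, and the cluster size
#'   ranges in each annotation.
#' @export
summarize_copy_number <- function(comparisons) {
  d <- comparisons$delta
  list(
    n_clusters = nrow(comparisons),
    n_loss = sum(d < 0L), n_gain = sum(d > 0L), n_same = sum(d == 0L),
    copies_lost = sum(pmax(0L, -d)), copies_gained = sum(pmax(0L, d)),
    ref_size_range = if (nrow(comparisons)) range(comparisons$ref_count)
                     else c(NA_integer_, NA_integer_),
    tgt_size_range = if (nrow(comparisons)) range(comparisons$tgt_count)
                     else c(NA_integer_, NA_integer_))
}
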