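#' Scoring schemes for global alignment
#'
#' A scoring scheme bundles a symmetric substitution matrix with affine gap
#' penalties. A gap run of length `L` is charged `gap_open + L * gap_extend`,
#' the same convention as [Biostrings::pairwiseAlignment()]. Symbols not in
#' the scheme's alphabet are scored with the worst value in the matrix.
#'
#' @param substitution integer matrix with identical row/column names (the
#'   alphabet); must be symmetric.
#' @param gap_open,gap_extend non-negative integer penalties;
#'   `gap_extend <= gap_open`.
#' @param alphabet one of `"nucleotide"` or `"protein"`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution, gap_open, gap_extend,
                           alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  substitution <- as.matrix(substitution)
  storage.mode(substitution) <- "integer"
  if (is.null(rownames(substitution)) ||
      !identical(rownames(substitution), colnames(substitution)))
    stop("substitution matrix must have identical row and column names")
  if (!isTRUE(all(substitution == t(substitution))))
    stop("substitution matrix must be symmetric")
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (gap_open < 0L || gap_extend < 0L || gap_extend > gap_open)
    stop("need 0 <= gap_extend <= gap_open")
  structure(list(alphabet = alphabet, substitution = substitution,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Default nucleotide scoring scheme
#'
#' Match +1, mismatch -1 (any comparison involving the ambiguity code N also
#' scores -1, including N/N), gap open 2, gap extend 1. All values are
#' user-configurable.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap penalties.
#' @return A `scoring_scheme`.
#' @export
nt_scheme <- function(match = 1L, mismatch = -1L, gap_open = 2L,
                      gap_extend = 1L) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(as.integer(mismatch), 5, 5, dimnames = list(ab, ab))
  diag(m) <- as.integer(match)
  m["N", "N"] <- as.integer(mismatch)  # N never counts as a scored match
  scoring_scheme(m, gap_open, gap_extend, "nucleotide")
}

#' Default protein scoring scheme
#'
#' BLOSUM62 with gap open 11 and gap extend 1, the conventional defaults of
#' the alignment libraries this package mirrors.
#'
#' @param matrix_name name of a substitution matrix dataset shipped with
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM80"`).
#' @param gap_open,gap_extend affine gap penalties.
#' @return A `scoring_scheme`.
#' @export
aa_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11L,
                      gap_extend = 1L) {
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  scoring_scheme(get(matrix_name, envir = e), gap_open, gap_extend, "protein")
}

#' Global pairwise alignment
#'
#' Optimal global (Needleman-Wunsch) alignment with affine gap penalties.
#' Among co-optimal alignments the traceback is deterministic: diagonal moves
#' are preferred over gaps in `b`, which are preferred over gaps in `a`, so
#' repeated runs are bit-identical and downstream variant-effect calls are
#' reproducible.
#'
#' @param a,b character scalars (the two sequences). One of them may be
#'   empty, in which case the result is an all-gap alignment; both empty is
#'   an error.
#' @param scheme a [scoring_scheme()].
#' @return An object of class `pairwise_alignment`: a list with elements
#'   `aligned_a`, `aligned_b` (equal-length gapped strings), `score`,
#'   `matches` (identical non-gap columns) and `columns`.
#' @examples
#' aln <- global_align("ACGTACGT", "ACGAAGT", nt_scheme())
#' percent_identity(aln)
#' @export
global_align <- function(a, b, scheme = nt_scheme()) {
  stopifnot(is.character(a), length(a) == 1L, !is.na(a),
            is.character(b), length(b) == 1L, !is.na(b),
            inherits(scheme, "scoring_scheme"))
  if (nchar(a) == 0L && nchar(b) == 0L)
    stop("cannot align two empty sequences")
  res <- .nw_align_cpp(a, b, scheme$substitution,
                       rownames(scheme$substitution),
                       scheme$gap_open, scheme$gap_extend)
  structure(res, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment: score", x$score, "-", x$matches, "matches over",
      x$columns, "columns\n")
  w <- 60L
  for (i in seq(1L, x$columns, by = w)) {
    j <- min(i + w - 1L, x$columns)
    cat(substr(x$aligned_a, i, j), "\n", substr(x$aligned_b, i, j), "\n\n",
        sep = "")
  }
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' Identical non-gap columns divided by the total number of alignment
#' columns, so gap columns count against identity.
#'
#' @param aln a `pairwise_alignment`.
#' @return A fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$columns == 0L) stop("alignment has zero columns")
  aln$matches / aln$columns
}

#' Translate a coding sequence
#'
#' Translation uses the standard genetic code, codon by codon from position
#' 1. Internal stop codons are emitted as `"*"` (they are evidence of a
#' variant, not an error); a trailing stop codon is trimmed; a trailing
#' partial codon is dropped. Codons containing ambiguity codes translate to
#' `"X"`.
#'
#' @param cds nucleotide string, length at least 3.
#' @param code named character vector mapping codons to amino acids; defaults
#'   to the standard code ([Biostrings::GENETIC_CODE]).
#' @return The protein string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' translate_cds("ATGTAAAAA")  # "M*K"
#' @export
translate_cds <- function(cds, code = Biostrings::GENETIC_CODE) {
  stopifnot(is.character(cds), length(cds) == 1L, !is.na(cds))
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (aa[n] == "*") aa <- aa[-n]
  paste(aa, collapse = "")
}
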