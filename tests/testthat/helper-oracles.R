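# Independent reference implementations used as oracles. These are written
# as plainly as possible (no optimisation, no shared code with the package)
# so that agreement with the package is meaningful.

# Plain O(n*m*3) affine-gap global alignment DP, score only.
# A gap run of length L costs gap_open + L * gap_extend.
oracle_affine_score <- function(a, b, scheme) {
  sub <- scheme$substitution
  go <- scheme$gap_open; ge <- scheme$gap_extend
  worst <- min(sub)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  s_of <- function(x, y) {
    if (x %in% rownames(sub) && y %in% colnames(sub)) sub[x, y] else worst
  }
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + i * ge)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + j * ge)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s_of(av[i], bv[j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                           Y[i, j + 1] - go - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                           Y[i + 1, j] - ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Plain Levenshtein DP over symbol vectors.
oracle_levenshtein <- function(x, y) {
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  d[n + 1, m + 1]
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Write a tiny annotation from a character vector of GFF3/GTF lines.
write_tmp_annot <- function(lines, ext = "gff3") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}
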