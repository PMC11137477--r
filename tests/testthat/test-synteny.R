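mk_ann <- function(df) {
  # df: gene_id, seqid, start (simple single-exon genes)
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- s + 9
    lines <- c(lines,
      sprintf("%s\tx\tgene\t%d\t%d\t.\t+\t.\tID=%s", df$seqid[i], s, e,
              df$gene_id[i]),
      sprintf("%s\tx\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t;Parent=%s", df$seqid[i],
              s, e, df$gene_id[i], df$gene_id[i]),
      sprintf("%s\tx\texon\t%d\t%d\t.\t+\t.\tParent=%s.t", df$seqid[i], s, e,
              df$gene_id[i]))
  }
  parse_annotation(write_tmp_annot(lines))
}

test_that("ordinals sort by chromosome list order, start, then gene id", {
  ann <- mk_ann(data.frame(gene_id = c("a", "b", "c"), seqid = "chr1",
                           start = c(100L, 500L, 900L),
                           stringsAsFactors = FALSE))
  o <- ordinal_positions(ann, c("a", "b", "c"))
  expect_equal(o, c(a = 1L, b = 2L, c = 3L))

  # chromosome order is list order, not lexicographic: chr2 before chr10
  ann2 <- mk_ann(data.frame(gene_id = c("a", "b"), seqid = c("chr2", "chr10"),
                            start = c(100L, 100L), stringsAsFactors = FALSE))
  o <- ordinal_positions(ann2, c("a", "b"), c("chr2", "chr10"))
  expect_equal(o[["a"]], 1L)
  o <- ordinal_positions(ann2, c("a", "b"), c("chr10", "chr2"))
  expect_equal(o[["b"]], 1L)
  expect_error(ordinal_positions(ann2, c("a", "b"), "chr2"), "chrom_order")

  # tie at identical start broken by gene id
  ann3 <- mk_ann(data.frame(gene_id = c("zz", "aa"), seqid = "chr1",
                            start = c(100L, 100L), stringsAsFactors = FALSE))
  o <- ordinal_positions(ann3, c("zz", "aa"))
  expect_equal(o, c(aa = 1L, zz = 2L))
})

test_that("synteny table packs ordinals over shared genes only", {
  ref <- mk_ann(data.frame(gene_id = paste0("g", 1:5), seqid = "chr1",
                           start = seq(100L, 900L, 200L),
                           stringsAsFactors = FALSE))
  m <- match_features(ref, ref)
  syn <- build_synteny_table(ref, ref, m)
  expect_equal(syn$ref_ordinal, syn$tgt_ordinal)

  # swap genes 2 and 3 in the target's coordinate order
  tgt <- mk_ann(data.frame(gene_id = paste0("g", c(1, 3, 2, 4, 5)),
                           seqid = "chr1", start = seq(100L, 900L, 200L),
                           stringsAsFactors = FALSE))
  syn <- build_synteny_table(ref, tgt, match_features(ref, tgt))
  expect_equal(sum(syn$ref_ordinal != syn$tgt_ordinal), 2L)

  # missing gene: ordinals re-packed 1..4 on both axes
  tgt2 <- mk_ann(data.frame(gene_id = paste0("g", c(1, 2, 3, 5)),
                            seqid = "chr1", start = seq(100L, 700L, 200L),
                            stringsAsFactors = FALSE))
  syn <- build_synteny_table(ref, tgt2, match_features(ref, tgt2))
  expect_equal(nrow(syn), 4L)
  expect_setequal(syn$ref_ordinal, 1:4)
  expect_setequal(syn$tgt_ordinal, 1:4)
})

test_that("order edit distance matches the Levenshtein oracle", {
  expect_equal(order_edit_distance(c("g1", "g2", "g3"),
                                   c("g1", "g2", "g3")), 0L)
  expect_equal(order_edit_distance(c("g1", "g2", "g3"),
                                   c("g1", "g3", "g2")), 2L)
  expect_equal(order_edit_distance(c("g1", "g2", "g3"),
                                   c("g3", "g2", "g1")), 2L)
  expect_error(order_edit_distance(c("g1", "g2"), c("g1", "g1")),
               "permutations")
  expect_error(order_edit_distance(c("g1", "g2"), c("g1", "g3")),
               "permutations")

  set.seed(5)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    ids <- paste0("gene", seq_len(n))
    x <- sample(ids); y <- sample(ids)
    expect_equal(order_edit_distance(x, y), oracle_levenshtein(x, y))
    expect_equal(order_edit_distance(y, x), order_edit_distance(x, y))
    expect_lte(order_edit_distance(x, y), 2L * n)
  }
})

test_that("translocated genes are the off-diagonal records", {
  ref <- make_reference(n_genes = 24, n_chroms = 3, coding_fraction = 0.5,
                        seed = 8)
  for (k in c(0L, 1L, 5L)) {
    specs <- if (k > 0)
      data.frame(gene_id = sprintf("gene%03d", seq_len(k)),
                 event = "translocation", stringsAsFactors = FALSE)
      else NULL
    tgt <- apply_mutations(ref, specs, seed = 9)
    m <- match_features(ref$ann, tgt$ann)
    syn <- build_synteny_table(ref$ann, tgt$ann, m)
    expect_equal(nrow(off_diagonal(syn)), k)
    if (k == 0L)
      expect_equal(order_edit_distance(
        syn$gene_id[order(syn$ref_ordinal)],
        syn$gene_id[order(syn$tgt_ordinal)]), 0L)
  }
})

test_that("the dot plot renders to an image file", {
  ref <- mk_ann(data.frame(gene_id = paste0("g", 1:5), seqid = "chr1",
                           start = seq(100L, 900L, 200L),
                           stringsAsFactors = FALSE))
  m <- match_features(ref, ref)
  syn <- build_synteny_table(ref, ref, m,
                             identities = c(g1 = 1, g2 = 0.95, g3 = 0.5,
                                            g4 = NA, g5 = 1))
  out <- tempfile(fileext = ".png")
  render_dotplot(syn, out)
  expect_true(file.exists(out) && file.size(out) > 0)
  expect_error(render_dotplot(syn[0, ], tempfile(fileext = ".png")),
               "no synteny records")
})
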