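test_that("pair similarity enforces identity and bidirectional coverage", {
  set.seed(2)
  s <- rand_seq(100, AA20)
  expect_true(pair_similar(s, s, "protein"))
  expect_true(pair_similar(s, s, "protein", min_id = 1, min_cov = 1))

  # length-ratio bound: 80 < 0.9 * 100
  expect_false(pair_similar(s, substr(s, 1, 80), "protein"))

  # 8 substitutions in a 100-mer: 92% identity
  s2 <- s
  at <- sample(100, 8)
  for (p in at) {
    substr(s2, p, p) <- sample(setdiff(AA20, substr(s2, p, p)), 1)
  }
  expect_true(pair_similar(s, s2, "protein", min_id = 0.9))
  expect_false(pair_similar(s, s2, "protein", min_id = 0.95))
})

test_that("greedy clustering is a deterministic partition", {
  s <- rand_seq(120, AA20)
  inputs <- data.frame(gene_id = c("a", "b", "c"), sequence = s,
                       alphabet = "protein", stringsAsFactors = FALSE)
  cl <- cluster_reference(inputs)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, c("a", "b", "c"))

  set.seed(3)
  inputs2 <- data.frame(gene_id = c("x", "y"),
                        sequence = c(rand_seq(100, AA20), rand_seq(100, AA20)),
                        alphabet = "protein", stringsAsFactors = FALSE)
  expect_length(cluster_reference(inputs2), 2L)
  expect_length(cluster_reference(inputs2[0, ]), 0L)

  # nucleotide and protein sequences never cluster together
  mixed <- data.frame(gene_id = c("p", "n"), sequence = c(s, rand_seq(120)),
                      alphabet = c("protein", "nucleotide"),
                      stringsAsFactors = FALSE)
  expect_length(cluster_reference(mixed), 2L)
})

test_that("synthetic families are recovered exactly and every gene is placed once", {
  fam <- make_gene_families(n_families = 5, copies = c(2, 3, 4), aa_len = 200,
                            divergence = 0.02, seed = 7)
  cl <- cluster_reference(fam$inputs)
  expect_equal(length(cl), 5L)
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(all_members, fam$inputs$gene_id)
  expect_equal(anyDuplicated(all_members), 0L)
  for (c0 in cl) {
    fams <- unique(fam$family[c0$members])
    expect_length(fams, 1L)
    expect_setequal(c0$members, names(fam$family)[fam$family == fams])
  }
})

test_that("raising min_id never merges clusters", {
  fam <- make_gene_families(n_families = 3, copies = 4, aa_len = 150,
                            divergence = 0.06, seed = 11)
  counts <- vapply(c(0.80, 0.90, 0.95),
                   function(t) length(cluster_reference(fam$inputs,
                                                        min_id = t)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("target clusters track losses, copy attachment and closest paralogs", {
  set.seed(15)
  pa <- rand_seq(150, AA20)
  pb <- pa
  for (p in sample(150, 8))  # 95% identical paralog
    substr(pb, p, p) <- sample(setdiff(AA20, substr(pb, p, p)), 1)
  ref_in <- data.frame(gene_id = c("gA", "gB", "gC"),
                       sequence = c(pa, pb, rand_seq(150, AA20)),
                       alphabet = "protein", stringsAsFactors = FALSE)
  cl <- cluster_reference(ref_in)
  expect_length(cl, 2L)

  # loss: target lacks gB, no extra copies
  m <- structure(list(shared_gene_ids = c("gA", "gC"),
                      extra_copies = character(0)), class = "feature_match")
  cmp <- derive_target_clusters(cl, m, ref_in)
  ab <- cmp[grepl("gA", cmp$ref_members), ]
  expect_equal(ab$ref_count, 2L)
  expect_equal(ab$tgt_count, 1L)
  expect_equal(ab$delta, -1L)

  # gain: extra copy gA_1, closest to gA (99% identical) vs gB (~95%)
  copy <- pa
  substr(copy, 5, 5) <- "W"
  tgt_in <- data.frame(gene_id = "gA_1", sequence = copy,
                       alphabet = "protein", stringsAsFactors = FALSE)
  m2 <- structure(list(shared_gene_ids = c("gA", "gB", "gC"),
                       extra_copies = c(gA_1 = "gA")),
                  class = "feature_match")
  cmp2 <- derive_target_clusters(cl, m2, ref_in, tgt_in)
  ab2 <- cmp2[grepl("gA", cmp2$ref_members), ]
  expect_equal(ab2$delta, 1L)
  expect_true(grepl("gA_1", ab2$tgt_members))
  asg <- attr(cmp2, "copy_assignments")
  expect_equal(asg$closest_paralog, "gA")

  # a cluster losing every member persists with target count 0
  m3 <- structure(list(shared_gene_ids = c("gA", "gB"),
                       extra_copies = character(0)), class = "feature_match")
  cmp3 <- derive_target_clusters(cl, m3, ref_in)
  expect_equal(cmp3$tgt_count[grepl("gC", cmp3$ref_members)], 0L)

  # extra copy with unknown source is reported, not fatal
  m4 <- structure(list(shared_gene_ids = c("gA", "gB", "gC"),
                       extra_copies = c(gZ_1 = "gZ")),
                  class = "feature_match")
  cmp4 <- derive_target_clusters(cl, m4, ref_in)
  expect_equal(attr(cmp4, "unassigned_copies"), "gZ_1")
})

test_that("conservation: target counts sum to shared clustered genes plus copies", {
  fx <- make_standard_fixture(seed = 2)
  m <- match_features(fx$ref$ann, fx$tgt$ann)
  ri <- cluster_inputs(fx$ref$asm, fx$ref$ann)
  cl <- cluster_reference(ri)
  ti <- cluster_inputs(fx$tgt$asm, fx$tgt$ann, names(m$extra_copies))
  cmp <- derive_target_clusters(cl, m, ri, ti)
  clustered <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(clustered, fx$ref$ann$genes$id)  # partition property
  expect_equal(sum(cmp$tgt_count),
               length(intersect(m$shared_gene_ids, clustered)) +
                 nrow(attr(cmp, "copy_assignments")))
})

test_that("copy-number summary arithmetic", {
  cmp <- data.frame(cluster_id = c("c1", "c2", "c3"),
                    ref_count = c(3L, 4L, 1L), tgt_count = c(2L, 2L, 4L),
                    delta = c(-1L, -2L, 3L),
                    ref_members = "", tgt_members = "",
                    stringsAsFactors = FALSE)
  s <- summarize_copy_number(cmp)
  expect_equal(s$n_loss, 2L)
  expect_equal(s$n_gain, 1L)
  expect_equal(s$copies_lost, 3L)
  expect_equal(s$copies_gained, 3L)

  cmp$tgt_count <- cmp$ref_count; cmp$delta <- 0L
  s <- summarize_copy_number(cmp)
  expect_equal(s$copies_lost + s$copies_gained, 0L)
  expect_equal(s$n_same, 3L)
})
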