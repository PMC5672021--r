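# Center-star alignment, conserved-block filtering, outlier removal,
# variability statistics.

test_that("identical sequences align without gaps", {
  s <- plastome:::random_dna(200)
  aln <- multiple_align(c(a = s, b = s, c = s), mode = "coding")
  expect_true(all(aln == s))
  expect_equal(length(unique(nchar(aln))), 1)
})

test_that("a clean deletion yields a single contiguous gap run", {
  set.seed(8)
  s <- plastome:::random_dna(200)
  del <- paste0(substr(s, 1, 90), substr(s, 101, 200))
  aln <- multiple_align(c(a = s, b = del), mode = "noncoding")
  expect_equal(nchar(aln[["a"]]), 200)
  gaps <- gregexpr("-+", aln[["b"]])[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 10)
  expect_equal(ungap(aln[["b"]]), del)
})

test_that("center-star cost is within 2x of the exact 3-sequence optimum", {
  set.seed(17)
  for (z in 1:6) {
    s1 <- plastome:::random_dna(15)
    s2 <- mutate_sequence(plastome:::random_dna(15), 0.2)
    s3 <- plastome:::random_dna(12)
    aln <- multiple_align(c(a = s1, b = s2, c = s3), mode = "noncoding")
    opt <- exact_sp3(s1, s2, s3)
    expect_lte(sp_cost(aln), 2 * opt)
    # every row ungaps back to its input
    expect_equal(ungap(aln[["a"]]), s1)
    expect_equal(ungap(aln[["b"]]), s2)
    expect_equal(ungap(aln[["c"]]), s3)
  }
})

test_that("block filter keeps identical alignments whole", {
  s <- plastome:::random_dna(80)
  bf <- block_filter(c(a = s, b = s, c = s))
  expect_equal(bf$mask$start, 0)
  expect_equal(bf$mask$end, 80)
  expect_equal(unname(bf$alignment), rep(s, 3))
})

test_that("block filter removes a gappy insert and keeps flanks", {
  set.seed(23)
  left <- plastome:::random_dna(15)
  right <- plastome:::random_dna(15)
  ins <- strrep("A", 12)
  a <- paste0(left, ins, right)
  b <- paste0(left, strrep("-", 12), right)
  bf <- block_filter(c(a = a, b = b, c = b))
  # hand application of the rule: the 12 gap columns are non-conserved,
  # run length 12 > 8 -> rejected; both 15-column flanks survive
  expect_equal(nrow(bf$mask), 2)
  expect_equal(bf$mask$start, c(0, 27))
  expect_equal(bf$mask$end, c(15, 42))
  expect_equal(unname(bf$alignment[["a"]]), paste0(left, right))
})

test_that("block filter returns an empty mask when nothing is conserved", {
  aln <- c(a = strrep("A", 20), b = strrep("C", 20), c = strrep("G", 20))
  bf <- block_filter(aln)
  expect_equal(nrow(bf$mask), 0)
  expect_equal(nchar(bf$alignment[["a"]]), 0)
})

test_that("block filter is idempotent", {
  set.seed(31)
  for (z in 1:5) {
    base <- plastome:::random_dna(120)
    rows <- c(a = base,
              b = mutate_sequence(base, 0.1),
              c = mutate_sequence(base, 0.4),
              d = mutate_sequence(base, 0.1))
    bf1 <- block_filter(rows)
    if (!nchar(bf1$alignment[[1]])) next
    bf2 <- block_filter(bf1$alignment)
    expect_identical(bf2$alignment, bf1$alignment)
  }
})

test_that("outlier removal is sensitive to planted non-homologs only", {
  set.seed(57)
  hits <- 0; n_rep <- 20
  for (z in seq_len(n_rep)) {
    base <- plastome:::random_dna(250)
    rows <- vapply(1:5, function(i) mutate_sequence(base, 0.08),
                   character(1))
    names(rows) <- paste0("t", 1:5)
    rows["bad"] <- plastome:::random_dna(250)
    aln <- multiple_align(rows, mode = "noncoding")
    res <- remove_outlier_rows(aln)
    if (identical(res$removed$id, "bad")) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("uniform divergence is not mistaken for outlierness", {
  set.seed(71)
  for (z in 1:10) {
    base <- plastome:::random_dna(300)
    rows <- vapply(1:6, function(i) mutate_sequence(base, 0.3),
                   character(1))
    names(rows) <- paste0("t", 1:6)
    res <- remove_outlier_rows(rows)  # already equal length, gap-free
    expect_equal(nrow(res$removed), 0)
  }
  # identical rows: nothing removed; < 3 rows: passthrough with warning
  expect_equal(nrow(remove_outlier_rows(
    c(a = "ACGT", b = "ACGT", c = "ACGT"))$removed), 0)
  expect_warning(remove_outlier_rows(c(a = "ACGT", b = "ACGT")),
                 "passthrough")
})

test_that("variable sites ignore gaps and N and percent rounds half-up", {
  expect_equal(variable_site_stats(c(a = "ACGT", b = "ACGT"))$variable, 0)
  st <- variable_site_stats(c(a = "ACGT", b = "ACGA"))
  expect_equal(st$variable, 1)
  expect_equal(st$percent, 25.0)
  expect_equal(variable_site_stats(c(a = "A-N", b = "-TN"))$variable, 0)
  # monotonicity: adding a row never decreases the count
  set.seed(83)
  for (z in 1:10) {
    base <- plastome:::random_dna(60)
    rows <- c(a = base, b = mutate_sequence(base, 0.1))
    v2 <- variable_site_stats(rows)$variable
    rows["c"] <- mutate_sequence(base, 0.2)
    expect_gte(variable_site_stats(rows)$variable, v2)
  }
})

test_that("edited and filtered pathways produce consistent alignments", {
  set.seed(5)
  base <- plastome:::random_dna(300)
  seqs <- vapply(1:5, function(i) mutate_sequence(base, 0.05), character(1))
  names(seqs) <- paste0("t", 1:5)
  ed <- align_region(seqs, pathway = "edited", mode = "noncoding")
  fl <- align_region(seqs, pathway = "filtered", mode = "noncoding")
  expect_true(length(ed) == 5 && length(fl) == 5)
  expect_lte(nchar(fl[[1]]), nchar(ed[[1]]))   # filtering only removes
  # a curated alignment short-circuits the edited pathway
  cur <- c(t1 = "AAA-", t2 = "AAAT")
  expect_identical(align_region(seqs[1:2], pathway = "edited",
                                curated = cur), cur)
})
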