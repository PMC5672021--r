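# Fragmentation into coding/non-coding regions, similarity grouping,
# partition schemes.

test_that("the 50 bp region floor is inclusive", {
  # hand-built model: genes separated by 49, 50 and 120 bp spacers
  mk <- function(name, len, comp) plastome:::make_spacer(name, len, comp)
  set.seed(1)
  els <- list(
    mk("LSC_s0", 120, "LSC"),
    plastome:::make_gene("gA", "CDS", 300, "+", "LSC"),
    mk("LSC_s1", 49, "LSC"),
    plastome:::make_gene("gB", "CDS", 300, "+", "LSC"),
    mk("LSC_s2", 50, "LSC"),
    plastome:::make_gene("gC", "CDS", 300, "+", "LSC"),
    mk("LSC_s3", 2000, "LSC"),
    mk("IR_s0", 100, "IR"),
    plastome:::make_gene("rrnX", "rRNA", 1200, "+", "IR"),
    mk("IR_s1", 100, "IR"),
    mk("SSC_s0", 120, "SSC"),
    plastome:::make_gene("gS", "CDS", 400, "+", "SSC"),
    mk("SSC_s1", 700, "SSC"))
  model <- plastome:::fix_boundaries(list(id = "toy", elements = els))
  g <- instantiate_genome(model)
  lay <- find_inverted_repeats(g, min_len = 1000)
  regs <- fragment_genome(layout = lay, min_len = 50)
  nms <- vapply(regs, `[[`, character(1), "region_name")
  lens <- nchar(vapply(regs, `[[`, character(1), "seq"))
  expect_false(any(grepl("gA-gB", nms)))          # 49 bp spacer dropped
  expect_true(any(grepl("gB-gC", nms)))           # 50 bp spacer retained
  expect_equal(lens[grepl("gB-gC", nms)], 50)
  # every coding gene outside IRb appears exactly once (the IR gene
  # keeps its copy tag since it exists in both IR copies)
  expect_equal(sum(nms %in% c("gA", "gB", "gC", "gS", "rrnX.1")), 5)
})

test_that("fragment counts follow from the template by construction", {
  tpl <- build_template("reduced", seed = 14)
  lay <- find_inverted_repeats(tpl$genome, min_len = 1000)
  regs <- fragment_genome(layout = lay, min_len = 50)
  roles <- vapply(regs, `[[`, character(1), "role")
  tab <- tpl$template
  in_scope <- tab$type == "gene"          # IRb copies are excluded already
  expect_equal(sum(roles == "coding"), sum(in_scope))
  # non-coding = introns + retained spacers; at least every intron present
  nms <- vapply(regs, `[[`, character(1), "region_name")
  expect_true(all(c("rps16_intron", "atpF_intron", "trnG-UCC_intron",
                    "ndhA_intron") %in% nms))
  expect_true(any(grepl("^ndhB.*_intron", nms)))  # IR copy keeps its tag
  expect_true(all(c("ycf3_intron1", "ycf3_intron2",
                    "clpP_intron1", "clpP_intron2") %in% nms))
})

test_that("no genome position is emitted twice (disjointness audit)", {
  sim <- small_sim()
  lays <- small_layouts()
  for (id in c("sp01", "OG1")) {
    regs <- fragment_genome(layout = lays[[id]], min_len = 50)
    segs <- do.call(rbind, lapply(regs, `[[`, "segments"))
    segs <- segs[order(segs$start), ]
    expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
  }
})

test_that("global similarity matches hand-derived alignments", {
  expect_equal(global_similarity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(global_similarity("AAAA", "TTTT"), 0.0)
  expect_equal(global_similarity("ACGTACGT", "ACGTTCGT"), 7 / 8)
})

test_that("similarity grouping honors threshold, uniqueness, determinism", {
  set.seed(40)
  base <- list(r1 = plastome:::random_dna(300),
               r2 = plastome:::random_dna(400),
               r3 = plastome:::random_dna(250))
  mk_region <- function(gid, nm, seq, role = "noncoding")
    list(genome_id = gid, region_name = nm, role = role, seq = seq,
         start = 0, end = nchar(seq), strand = "+")
  pool <- list()
  for (gid in c("ref", "tx1", "tx2")) {
    for (nm in names(base)) {
      s <- base[[nm]]
      if (gid != "ref") s <- mutate_sequence(s, 0.05)
      pool[[length(pool) + 1]] <- mk_region(gid, nm, s)
    }
  }
  # plant one diverged-beyond-threshold region in tx2
  pool[[length(pool) + 1]] <- mk_region("tx2", "junk",
                                        plastome:::random_dna(300))
  res <- group_by_similarity(pool, "ref", threshold = 0.65)
  expect_equal(length(res$groups), 3)
  for (nm in names(base)) {
    expect_setequal(names(res$groups[[nm]]$members), c("ref", "tx1", "tx2"))
    expect_true(all(res$groups[[nm]]$similarity >= 0.65))
  }
  expect_true("junk" %in% res$unassigned$region_name)
  # determinism
  res2 <- group_by_similarity(pool, "ref", threshold = 0.65)
  expect_identical(lapply(res$groups, `[[`, "similarity"),
                   lapply(res2$groups, `[[`, "similarity"))
  expect_error(group_by_similarity(pool, "missing"), "configuration")
})

test_that("grouping recovers generator homology for well-separated regions", {
  sim <- cached("hom_sim", simulate_plastome_set(
    n_ingroup = 4, n_outgroup = 1, profile = "reduced", seed = 19,
    scenario = "none"))
  lays <- lapply(sim$genomes, find_inverted_repeats, min_len = 1000)
  regions <- unlist(lapply(lays, function(l)
    fragment_genome(layout = l, min_len = 50)), recursive = FALSE)
  res <- group_by_similarity(regions, "sp01", threshold = 0.65)
  # at the simulated divergence every homolog stays well above threshold,
  # so every group of a locus present in all taxa must be complete
  coding <- Filter(function(g) g$role == "coding", res$groups)
  for (g in coding)
    expect_setequal(names(g$members), names(sim$genomes))
})

test_that("scheme statistics are additive and match Table-style layout", {
  a1 <- c(x = "ACGT", y = "ACGA", z = "ACGT")   # 1 variable site
  a2 <- c(x = "AAAATT", y = "AAcATT", z = "AAAATT")
  a2 <- toupper(a2)                              # 1 variable site
  a3 <- c(x = "GGGG", y = "GGGG", z = "GGGG")    # 0 variable
  sch <- build_schemes(list(g1 = a1), list(n1 = a2), list(n2 = a3))
  expect_equal(nrow(sch), 5)
  comb <- sch[sch$scheme == "coding+noncoding_edited", ]
  expect_equal(comb$alignment_length,
               sch$alignment_length[sch$scheme == "coding"] +
                 sch$alignment_length[sch$scheme == "noncoding_edited"])
  expect_equal(comb$variable_sites, 1 + 1)
  expect_equal(sch$pct_variation[sch$scheme == "coding"],
               round(100 * 1 / 4, 1))
  expect_error(build_schemes(list(), list(n1 = a2), list(n2 = a3)), "empty")
})
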