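# Quadripartite detection, junction context, structural summaries.

test_that("detection recovers planted IR boundaries exactly across seeds", {
  for (seed in 1:5) {
    tpl <- build_template("reduced", seed = seed)
    truth <- plastome:::model_layout(tpl$model)
    lay <- find_inverted_repeats(tpl$genome, min_len = 1000)
    expect_equal(unname(lay$lengths["lsc"]), unname(truth["lsc"]))
    expect_equal(unname(lay$lengths["ira"]), unname(truth["ir"]))
    expect_equal(unname(lay$lengths["ssc"]), unname(truth["ssc"]))
    expect_equal(sum(lay$lengths), tpl$genome$length)   # exact tiling
    expect_equal(lay$ir_identity, 1.0)
  }
})

test_that("canonical layout is invariant to rotation and strand flip", {
  tpl <- build_template("reduced", seed = 6)
  g <- tpl$genome
  ref <- find_inverted_repeats(g, min_len = 1000)
  for (off in c(123, 7777, 20000)) {
    lay <- find_inverted_repeats(rotate_genome(g, off), min_len = 1000)
    expect_equal(lay$lengths, ref$lengths)
    expect_identical(lay$genome$sequence, ref$genome$sequence)
  }
  lay_rc <- find_inverted_repeats(revcomp_genome(g), min_len = 1000)
  expect_equal(lay_rc$lengths, ref$lengths)
  expect_identical(lay_rc$genome$sequence, ref$genome$sequence)
})

test_that("genomes without a qualifying repeat are reported as such", {
  set.seed(4)
  g <- new_genome("norep", plastome:::random_dna(6000))
  expect_error(find_inverted_repeats(g, min_len = 1000),
               "structure-not-found")
})

test_that("detection agrees with Biostrings palindrome search on small genomes", {
  # independent oracle: findPalindromes finds the longest inverted-repeat
  # arm pair with unrestricted loop length
  for (seed in 1:4) {
    g <- planted_ir_genome(lsc = 1800, arm = 400 + 37 * seed, ssc = 900,
                           seed = seed)
    lay <- find_inverted_repeats(g, min_len = 100)
    pal <- Biostrings::findPalindromes(
      Biostrings::DNAString(g$sequence), min.armlength = 100,
      max.looplength = g$length, min.looplength = 50)
    expect_equal(unname(lay$lengths["ira"]),
                 max(Biostrings::palindromeArmLength(pal)))
  }
})

test_that("junction context reports signed distances and overlaps", {
  # genome with one gene ending exactly at the LSC/IRa junction and one
  # gene crossing the SSC/IRb junction by 200 bp
  g0 <- planted_ir_genome(lsc = 2000, arm = 1200, ssc = 1500, seed = 2)
  feats <- list(
    new_feature("endsAtJ", "CDS",
                data.frame(start = 1900, end = 2000, strand = "+")),
    new_feature("crossesJ", "CDS",
                data.frame(start = 4400, end = 4900, strand = "+")),
    new_feature("lscGene", "CDS",
                data.frame(start = 100, end = 700, strand = "+")))
  g <- new_genome("jx", g0$sequence, feats)
  lay <- find_inverted_repeats(g, min_len = 1000)
  # planted layout (already canonical): LSC [0,2000) IRa [2000,3200)
  # SSC [3200,4700) IRb [4700,5900)
  expect_equal(unname(lay$lengths),
               unname(c(lsc = 2000, ira = 1200, ssc = 1500, irb = 1200)))
  jc <- junction_context(layout = lay)
  at_j <- jc[jc$junction == "LSC-IRa" & jc$feature == "endsAtJ", ]
  expect_equal(at_j$distance[at_j$side == "left"], 0)
  cross <- jc[jc$junction == "SSC-IRb" & jc$feature == "crossesJ", ]
  expect_equal(sort(cross$distance), c(-300, -200))  # 300 in SSC, 200 in IRb
})

test_that("GC, counts and pseudogene lists are summarized correctly", {
  expect_equal(genome_summary(new_genome("x", "ATGC"))$gc, 50.0)
  # GC with round-half-up at one decimal
  s <- paste0(strrep("G", 381), strrep("A", 619))
  expect_equal(genome_summary(new_genome("y", s))$gc, 38.1)
  s2 <- paste0(strrep("G", 125), strrep("A", 875))  # 12.5 rounds up
  expect_equal(genome_summary(new_genome("z", s2))$gc, 12.5)

  tpl <- build_template("reduced", seed = 10)
  m <- apply_pseudogenization(tpl$model, "rbcL")
  m <- apply_pseudogenization(m, "matK")
  g <- instantiate_genome(m)
  lay <- find_inverted_repeats(g, min_len = 1000)
  sm <- genome_summary(layout = lay)
  tab <- table(vapply(tpl$genome$features, `[[`, character(1), "kind"))
  expect_equal(sm$cds, unname(tab["CDS"]) - 2)
  expect_equal(sort(sm$pseudogenes), c("matK", "rbcL"))
  expect_equal(sm$trna, unname(tab["tRNA"]))
  expect_equal(sm$rrna, unname(tab["rRNA"]))
  # both gene-count conventions are reported
  expect_true(sm$genes_with_copies > sm$genes_unique)
})

test_that("cross-species table flags IR expansion clades and failures", {
  sim <- small_sim()
  tab <- cross_species_structure_table(sim$genomes)
  expect_equal(nrow(tab), length(sim$genomes))
  ing <- tab[grepl("^sp", tab$id), ]
  og <- tab[grepl("^OG", tab$id), ]
  expect_true(all(ing$ssc < og$ssc))     # planted expansion shrank SSC
  expect_true(all(ing$ir > og$ir))
  # identical genomes give identical rows apart from the id
  g <- sim$genomes[[1]]
  g2 <- g; g2$id <- "copy"
  tab2 <- cross_species_structure_table(list(g, g2))
  expect_equal(tab2[1, -1], tab2[2, -1], ignore_attr = TRUE)
  # a non-quadripartite genome is flagged, the rest proceeds
  set.seed(1)
  bad <- new_genome("bad", plastome:::random_dna(5000))
  tab3 <- cross_species_structure_table(list(g, bad), min_len = 1000)
  expect_equal(tab3$status, c("ok", "no_quadripartite"))
})
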