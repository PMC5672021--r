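# JC69 distances, neighbor joining, Kendall-Colijn comparison, marker
# ranking and candidate selection.

rand_rooted <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr
}

test_that("JC69 distances invert the closed-form divergence", {
  s <- strrep("A", 10000)
  m <- paste0(strrep("C", 937), strrep("A", 9063))  # p = 0.0937
  d <- jc69_distances(c(x = s, y = m))
  expect_equal(d["x", "y"], -0.75 * log(1 - 4 * 0.0937 / 3))
  expect_equal(round(d["x", "y"], 3), 0.1)
  expect_true(all(diag(d) == 0))
  # identical rows -> zero; saturation -> error naming the pair
  expect_true(all(jc69_distances(c(a = s, b = s)) == 0))
  sat <- paste0(strrep("C", 7500), strrep("A", 2500))
  expect_error(jc69_distances(c(x = s, y = sat)), "saturation.*x / y")
  # gap/N sites are excluded pairwise
  d2 <- jc69_distances(c(x = "ACGT--", y = "ACGTNN"))
  expect_equal(unname(d2["x", "y"]), 0)
})

test_that("neighbor joining exactly recovers additive metrics", {
  # quartet ((a:1,b:2):1,(c:3,d:4)) -> additive distance matrix
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 3
  D["a", "c"] <- D["c", "a"] <- 5
  D["a", "d"] <- D["d", "a"] <- 6
  D["b", "c"] <- D["c", "b"] <- 6
  D["b", "d"] <- D["d", "b"] <- 7
  D["c", "d"] <- D["d", "c"] <- 7
  tr <- neighbor_joining(D)
  expect_equal(attr(tr, "clamped"), 0)
  # recovered tree reproduces the full metric
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), rownames(D)],
               D)
  # ab|cd split present
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
  # 3-taxon ultrametric: pendant lengths are exact
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$edge.length), c(1, 1, 3))
})

test_that("KC vectors match the brute-force MRCA-depth oracle (n <= 6)", {
  for (seed in 1:12) {
    n <- 4 + seed %% 3
    tr <- rand_rooted(n, seed)
    expect_equal(unname(kc_vector(tr, lambda = 0)), oracle_kc0(tr))
  }
})

test_that("KC distance reproduces hand-computed cases", {
  t1 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  t2 <- ape::read.tree(text = "(((a:1,c:1):1,b:1):1,d:1);")
  expect_equal(kc_distance(t1, t1, 0), 0)
  expect_equal(kc_distance(t1, t1, 1), 0)
  # caterpillar swap: only the (a,b) and (a,c) entries differ by 1 each
  expect_equal(kc_distance(t1, t2, 0), sqrt(2))
  # same topology, one pendant branch changed by delta at lambda = 1
  t3 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1.75);")
  expect_equal(kc_distance(t1, t3, 1), 0.75)
  # tip-set mismatch names the symmetric difference
  t4 <- ape::read.tree(text = "((a:1,b:1):1,e:1);")
  expect_error(kc_distance(t1, t4, 0), "d, e")
})

test_that("KC distance satisfies metric axioms on random rooted trees", {
  set.seed(13)
  trees <- lapply(1:12, function(i) rand_rooted(3 + i %% 6, i * 7))
  for (z in 1:40) {
    i <- sample(length(trees), 1)
    n <- length(trees[[i]]$tip.label)
    cand <- which(vapply(trees, function(t_)
      length(t_$tip.label) == n, logical(1)))
    j <- sample(cand, 1); k <- sample(cand, 1)
    ti <- trees[[i]]; tj <- trees[[j]]; tk <- trees[[k]]
    for (lam in c(0, 0.5, 1)) {
      dij <- kc_distance(ti, tj, lam)
      expect_gte(dij, 0)
      expect_equal(dij, kc_distance(tj, ti, lam))          # symmetry
      expect_lte(dij, kc_distance(ti, tk, lam) +
                   kc_distance(tk, tj, lam) + 1e-9)        # triangle
    }
    # identity of indiscernibles at lambda 0 (topology only)
    same <- isTRUE(all.equal(ti, tj, use.edge.length = FALSE,
                             use.tip.label = TRUE))
    expect_equal(kc_distance(ti, tj, 0) == 0, same)
  }
})

test_that("rooting and pruning isolates a monophyletic ingroup", {
  tr <- ape::read.tree(
    text = "(((s1:1,s2:1):1,(s3:1,s4:1):1):2,(o1:1,o2:3):1);")
  pr <- root_and_prune(tr, c("o1", "o2"))
  expect_setequal(pr$tip.label, c("s1", "s2", "s3", "s4"))
  expect_true(ape::is.rooted(pr))
  # pruning twice is a no-op
  pr2 <- root_and_prune(pr, character(0))
  expect_equal(ape::write.tree(pr2), ape::write.tree(pr))
  # non-monophyletic ingroup errors with the intruder named
  bad <- ape::read.tree(text = "(((s1:1,o1:1):1,s2:1):1,o2:1);")
  expect_error(root_and_prune(bad, c("o1", "o2")), "intruding taxa: o[12]")
  expect_error(root_and_prune(tr, "nope"), "absent")
})

test_that("bootstrap supports are deterministic and high on clean signal", {
  set.seed(3)
  base <- plastome:::random_dna(2000)
  tree <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,e:2);")
  tree$edge.length <- tree$edge.length * 0.05
  sim <- plastome:::sim_seqs_on_tree(base, tree)
  b1 <- bootstrap_support(sim, n_reps = 50, seed = 9)
  b2 <- bootstrap_support(sim, n_reps = 50, seed = 9)
  expect_identical(b1$node.label, b2$node.label)
  expect_true(all(b1$node.label[-1] >= 90))  # root "support" excluded
  expect_warning(bootstrap_support(c(a = "AAAA", b = "AAAA", c = "AAAA"),
                                   n_reps = 5), "degenerate")
})

test_that("marker ranking standardizes to [0,1] and orders correctly", {
  set.seed(41)
  ref <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  alt <- ape::read.tree(text = "(((a:1,c:1):1,b:1):1,d:1);")
  mk_aln <- function(p) {
    base <- plastome:::random_dna(400)
    rows <- vapply(1:4, function(i) mutate_sequence(base, p), character(1))
    stats::setNames(rows, letters[1:4])
  }
  alns <- list(fast = mk_aln(0.15), slow = mk_aln(0.01), mid = mk_aln(0.05))
  trees <- list(fast = ref, slow = alt, mid = ref)
  sc <- rank_markers(alns, trees, ref)
  expect_true(all(sc$std_variation >= 0 & sc$std_variation <= 1))
  expect_true(all(sc$std_topology %in% c(0, 1)))
  # topology identical to the reference standardizes to 1
  expect_equal(sc$std_topology[sc$region == "fast"], 1)
  expect_equal(sc$std_topology[sc$region == "slow"], 0)
  expect_equal(sc$rank, seq_len(3))
  expect_equal(sc$region[1], "fast")
  # permutation invariance of the scores
  sc2 <- rank_markers(alns[c(2, 3, 1)], trees, ref)
  expect_equal(sc2[order(sc2$region), -which(names(sc2) == "rank")],
               sc[order(sc$region), -which(names(sc) == "rank")],
               ignore_attr = TRUE)
  # degenerate standardization warns and scores 1
  same <- list(x = alns$fast, y = alns$fast)
  expect_warning(sd <- rank_markers(same, list(x = ref, y = ref), ref),
                 "degenerate")
  expect_true(all(sd$composite == 1))
  expect_error(rank_markers(alns[1], trees[1], ref), ">= 2 regions")
})

test_that("marker candidates are filtered by length and breakpoints", {
  mk_group <- function(nm, role, len, start = 0) {
    members <- lapply(c(r = "r", a = "a", b = "b"), function(i)
      list(genome_id = i, region_name = nm, role = role,
           seq = strrep("A", len), start = start, end = start + len))
    list(region_name = nm, role = role, members = members)
  }
  groups <- list(
    good = mk_group("good", "noncoding", 800, start = 5000),
    short = mk_group("short", "noncoding", 450),
    long = mk_group("long", "noncoding", 1200),
    broken = mk_group("broken", "noncoding", 700, start = 100),
    coding = mk_group("coding1", "coding", 800))
  bp <- data.frame(start = 150, end = 300)
  res <- select_marker_candidates(groups, breakpoints = bp,
                                  reference_id = "r")
  expect_equal(res$kept, "good")
  expect_equal(res$excluded$reason[res$excluded$region == "short"], "length")
  expect_equal(res$excluded$reason[res$excluded$region == "long"], "length")
  expect_equal(res$excluded$reason[res$excluded$region == "broken"],
               "breakpoint")
  # boundary values are inclusive
  res2 <- select_marker_candidates(list(e = mk_group("e", "noncoding", 500),
                                        f = mk_group("f", "noncoding", 1100)),
                                   reference_id = "r")
  expect_setequal(res2$kept, c("e", "f"))
})
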