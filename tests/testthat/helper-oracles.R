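# Independent oracles used by several test files. Each recomputes the
# quantity by a route unrelated to the package implementation.

# brute-force Kendall-Colijn topological vector: root-to-tip node paths
# via ape::nodepath; MRCA depth = common-prefix length - 1
oracle_kc0 <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  root <- n + 1L
  paths <- lapply(match(tips, tree$tip.label), function(t_)
    ape::nodepath(tree, from = root, to = t_))
  pairs <- utils::combn(seq_len(n), 2)
  pv <- vapply(seq_len(ncol(pairs)), function(c_) {
    p1 <- paths[[pairs[1, c_]]]; p2 <- paths[[pairs[2, c_]]]
    m <- min(length(p1), length(p2))
    sum(cumprod(p1[seq_len(m)] == p2[seq_len(m)])) - 1
  }, numeric(1))
  c(pv, rep(1, n))
}

# sum-of-pairs cost of an MSA under the unit metric
# (match 0, mismatch 1, gap-vs-char 1, gap-gap 0)
sp_cost <- function(aln) {
  M <- do.call(rbind, strsplit(unname(aln), ""))
  n <- nrow(M); cost <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    a <- M[i, ]; b <- M[j, ]
    both <- a != "-" & b != "-"
    cost <- cost + sum(a[both] != b[both]) + sum(xor(a == "-", b == "-"))
  }
  cost
}

# exact minimum sum-of-pairs cost for three sequences (3D DP)
exact_sp3 <- function(s1, s2, s3) {
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]
  v3 <- strsplit(s3, "")[[1]]
  n1 <- length(v1); n2 <- length(v2); n3 <- length(v3)
  INF <- 1e9
  D <- array(INF, dim = c(n1 + 1, n2 + 1, n3 + 1))
  D[1, 1, 1] <- 0
  pc <- function(x, y) if (x == y) 0 else 1
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    cur <- D[i + 1, j + 1, k + 1]
    if (cur >= INF) next
    a <- if (i < n1) v1[i + 1] else NA
    b <- if (j < n2) v2[j + 1] else NA
    c_ <- if (k < n3) v3[k + 1] else NA
    step <- function(di, dj, dk, cost) {
      t <- cur + cost
      if (t < D[i + di + 1, j + dj + 1, k + dk + 1])
        D[i + di + 1, j + dj + 1, k + dk + 1] <<- t
    }
    if (i < n1 && j < n2 && k < n3)
      step(1, 1, 1, pc(a, b) + pc(a, c_) + pc(b, c_))
    if (i < n1 && j < n2) step(1, 1, 0, pc(a, b) + 2)
    if (i < n1 && k < n3) step(1, 0, 1, pc(a, c_) + 2)
    if (j < n2 && k < n3) step(0, 1, 1, pc(b, c_) + 2)
    if (i < n1) step(1, 0, 0, 2)
    if (j < n2) step(0, 1, 0, 2)
    if (k < n3) step(0, 0, 1, 2)
  }
  D[n1 + 1, n2 + 1, n3 + 1]
}

# block count of a signed permutation by direct run enumeration
oracle_block_count <- function(ref_syms, tgt_syms, tgt_signs) {
  pos <- match(tgt_syms, ref_syms)
  n <- length(pos)
  if (n == 1) return(1L)
  breaks <- vapply(2:n, function(i) {
    fwd <- pos[i] == pos[i - 1] + 1 && tgt_signs[i] == 1 &&
      tgt_signs[i - 1] == 1
    rev_ <- pos[i] == pos[i - 1] - 1 && tgt_signs[i] == -1 &&
      tgt_signs[i - 1] == -1
    !(fwd || rev_)
  }, logical(1))
  sum(breaks) + 1L
}
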