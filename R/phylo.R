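# Distance-based tree inference, Kendall-Colijn tree comparison and
# standardized marker ranking. Trees are ape "phylo" objects; tree
# inference itself is deliberately simple (NJ on JC69 distances) with a
# hook to ingest externally computed newick trees - the comparison and
# ranking metrics are the point, not the inference.

#' JC69-corrected pairwise distances from an alignment
#'
#' p is the mismatch fraction over pairwise non-gap, non-N sites;
#' d = -(3/4) * ln(1 - (4/3) p). Saturated pairs (p >= 3/4) raise an
#' error naming the pair rather than returning infinity.
#'
#' @param aln named character vector of gapped rows, or a character
#'   matrix with one row per taxon (>= 2).
#' @return a symmetric distance matrix with zero diagonal.
#' @export
jc69_distances <- function(aln) {
  M <- as_aln_matrix(aln)
  n <- nrow(M)
  stopifnot(n >= 2)
  ok <- M %in% c("A", "C", "G", "T")
  dim(ok) <- dim(M)
  taxa <- rownames(M)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    sh <- ok[i, ] & ok[j, ]
    if (!any(sh)) stop("jc69: no comparable sites for pair ",
                       taxa[i], " / ", taxa[j])
    p <- mean(M[i, sh] != M[j, sh])
    if (p >= 0.75)
      stop(sprintf("jc69 saturation (p = %.3f) for pair %s / %s",
                   p, taxa[i], taxa[j]))
    D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (standard Q-criterion, via ape); negative
#' branch lengths are clamped to zero and the clamped deficit reported as
#' an attribute.
#'
#' @param dm symmetric distance matrix with taxon dimnames.
#' @return an unrooted "phylo" tree; attribute "clamped" gives the total
#'   negative branch length removed.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(nrow(dm) >= 3, all(is.finite(dm)))
  tr <- ape::nj(stats::as.dist(dm))
  neg <- tr$edge.length < 0
  deficit <- -sum(tr$edge.length[neg])
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- deficit
  tr
}

#' NJ tree with bootstrap support from column resampling
#'
#' Columns are resampled with replacement `n_reps` times; support for each
#' internal bipartition of the point-estimate tree is the percentage of
#' replicate NJ trees containing it.
#'
#' @param aln named character vector of gapped rows.
#' @param n_reps bootstrap replicates (default 100).
#' @param seed RNG seed (determinism: same seed, same supports).
#' @return the point-estimate "phylo" with `node.label` set to supports.
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1) {
  M <- as_aln_matrix(aln)
  w <- ncol(M)
  vs <- variable_site_stats(M)
  if (vs$variable == 0)
    warning("bootstrap_support: no variable sites; tree is degenerate")
  point <- neighbor_joining(jc69_distances(M))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(w, w, replace = TRUE)
    reps[[r]] <- tryCatch(neighbor_joining(jc69_distances(
      M[, cols, drop = FALSE])), error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(point, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  point$node.label <- round(100 * cnt / length(reps), 1)
  point
}

#' Root a tree on an outgroup and prune to the ingroup
#'
#' Errors (naming the intruding taxa) if the ingroup is not monophyletic
#' in the rooted tree.
#'
#' @param tree a "phylo".
#' @param outgroup_taxa character vector of outgroup tip labels.
#' @return the rooted ingroup "phylo".
#' @export
root_and_prune <- function(tree, outgroup_taxa) {
  if (!length(outgroup_taxa)) {
    if (!ape::is.rooted(tree)) stop("no outgroup given and tree unrooted")
    return(tree)                      # already the rooted ingroup tree
  }
  missing_og <- setdiff(outgroup_taxa, tree$tip.label)
  if (length(missing_og))
    stop("outgroup taxa absent from tree: ",
         paste(missing_og, collapse = ", "))
  ingroup <- setdiff(tree$tip.label, outgroup_taxa)
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_taxa, resolve.root = TRUE),
    error = function(e)   # non-monophyletic outgroup: root on one taxon
      ape::root(tree, outgroup = outgroup_taxa[1], resolve.root = TRUE))
  if (!ape::is.monophyletic(rooted, ingroup)) {
    mr <- ape::getMRCA(rooted, ingroup)
    clade_tips <- ape::extract.clade(rooted, mr)$tip.label
    stop("ingroup not monophyletic; intruding taxa: ",
         paste(setdiff(clade_tips, ingroup), collapse = ", "))
  }
  pruned <- ape::drop.tip(rooted, outgroup_taxa)
  pruned
}

#' Kendall-Colijn vector of a rooted tree
#'
#' For every tip pair (in sorted label order) the entry is
#' (1 - lambda) * (edge count root->MRCA) + lambda * (path length
#' root->MRCA); for every tip, (1 - lambda) * 1 + lambda * pendant branch
#' length. lambda = 0 gives the purely topological vector, lambda = 1 the
#' branch-length vector.
#'
#' @param tree rooted "phylo" with unique tip labels.
#' @param lambda blending parameter in [0, 1].
#' @return named numeric vector of length C(n,2) + n.
#' @export
kc_vector <- function(tree, lambda = 0) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (!ape::is.rooted(tree)) stop("kc_vector: tree must be rooted")
  tips <- sort(tree$tip.label)
  n <- length(tips)
  idx <- match(tips, tree$tip.label)
  # node depths from the root, in edges and in branch length
  nn <- ape::Nnode(tree) + n
  root <- n + 1L
  depth_e <- rep(NA_real_, nn); depth_l <- rep(NA_real_, nn)
  depth_e[root] <- 0; depth_l[root] <- 0
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    depth_e[ch] <- depth_e[p] + 1
    depth_l[ch] <- depth_l[p] + eo$edge.length[k]
  }
  mr <- ape::mrca(tree)
  pair_names <- utils::combn(tips, 2, paste, collapse = "|")
  pairs <- utils::combn(seq_len(n), 2)
  pv <- vapply(seq_len(ncol(pairs)), function(c_) {
    a <- idx[pairs[1, c_]]; b <- idx[pairs[2, c_]]
    m <- mr[a, b]
    (1 - lambda) * depth_e[m] + lambda * depth_l[m]
  }, numeric(1))
  # pendant entries
  pend_l <- tree$edge.length[match(idx, tree$edge[, 2])]
  tv <- (1 - lambda) * 1 + lambda * pend_l
  stats::setNames(c(pv, tv), c(pair_names, tips))
}

#' Kendall-Colijn distance between two rooted trees
#'
#' Euclidean norm of the difference of the two lambda-blended vectors.
#' The tip sets must be identical; a mismatch reports the symmetric
#' difference.
#'
#' @param t1,t2 rooted "phylo" trees on the same tips.
#' @param lambda blending parameter (0 = topology, 1 = branch lengths).
#' @return nonnegative numeric distance.
#' @export
kc_distance <- function(t1, t2, lambda = 0) {
  d <- union(setdiff(t1$tip.label, t2$tip.label),
             setdiff(t2$tip.label, t1$tip.label))
  if (length(d))
    stop("tip-set mismatch: ", paste(sort(d), collapse = ", "))
  v1 <- kc_vector(t1, lambda); v2 <- kc_vector(t2, lambda)
  sqrt(sum((v1 - v2[names(v1)])^2))
}

#' Rank candidate marker regions against a reference tree
#'
#' Per region: percent variation of its alignment, and KC distances
#' (lambda = 0 and lambda = 1) between its tree and the reference tree,
#' all on the pruned ingroup. Metrics are standardized to [0, 1] so that 1
#' is best: variation as (v - min)/(max - min), distances as
#' 1 - (d - min)/(max - min) (a topologically identical tree scores 1).
#' The composite is the (configurable-weight) mean; regions are ranked by
#' descending composite.
#'
#' @param region_alns named list of ingroup alignments, one per region.
#' @param region_trees named list of rooted ingroup "phylo" trees.
#' @param reference_tree rooted ingroup "phylo" (the best-scheme tree).
#' @param weights length-3 weights for (variation, topology, branch
#'   lengths).
#' @return data.frame of class "marker_scores", ranked.
#' @export
rank_markers <- function(region_alns, region_trees, reference_tree,
                         weights = c(1, 1, 1)) {
  regions <- names(region_alns)
  if (length(regions) < 2)
    stop("rank_markers: need >= 2 regions for standardization")
  stopifnot(setequal(regions, names(region_trees)))
  stats_ <- lapply(region_alns, variable_site_stats)
  lens <- vapply(region_alns, function(a) nchar(a[[1]]), numeric(1))
  raw_len <- lapply(region_alns, function(a) nchar(vapply(a, ungap,
                                                          character(1))))
  pct <- vapply(stats_, `[[`, numeric(1), "percent")
  d0 <- vapply(regions, function(r)
    kc_distance(region_trees[[r]], reference_tree, lambda = 0), numeric(1))
  d1 <- vapply(regions, function(r)
    kc_distance(region_trees[[r]], reference_tree, lambda = 1), numeric(1))
  degenerate <- FALSE
  std_up <- function(x) {
    if (max(x) == min(x)) {
      degenerate <<- TRUE
      return(rep(1, length(x)))
    }
    (x - min(x)) / (max(x) - min(x))
  }
  std_down <- function(x) {
    if (max(x) == min(x)) {
      degenerate <<- TRUE
      return(rep(1, length(x)))
    }
    1 - (x - min(x)) / (max(x) - min(x))
  }
  sv <- std_up(pct); s0 <- std_down(d0); s1 <- std_down(d1)
  if (degenerate)
    warning("degenerate standardization: metric(s) constant across ",
            "regions; affected scores set to 1")
  w <- weights / sum(weights)
  composite <- w[1] * sv + w[2] * s0 + w[3] * s1
  out <- data.frame(
    region = regions,
    alignment_length = unname(lens),
    min_seq_length = vapply(raw_len, min, numeric(1)),
    max_seq_length = vapply(raw_len, max, numeric(1)),
    pct_variation = unname(pct),
    kc_topology = unname(d0), kc_branch_length = unname(d1),
    std_variation = unname(sv), std_topology = unname(s0),
    std_branch_length = unname(s1), composite = unname(composite))
  out <- out[order(-out$composite, out$region), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("marker_scores", "data.frame")
  out
}

#' Filter non-coding regions to PCR-amplifiable, breakpoint-free candidates
#'
#' Keeps non-coding region groups whose median unaligned member length
#' lies in [min_len, max_len] and whose reference-genome source interval
#' overlaps no detected rearrangement breakpoint region ("recombination
#' free" operationalized as breakpoint-overlap-free). Excluded regions are
#' reported with reasons.
#'
#' @param groups named list of region groups (see [group_by_similarity()]).
#' @param breakpoints data.frame of breakpoint intervals (start, end) in
#'   reference canonical coordinates, e.g. pooled [breakpoint_regions()]
#'   output; NULL = no breakpoint exclusion.
#' @param reference_id genome id whose member supplies the source interval.
#' @param min_len,max_len amplicon length window in bp.
#' @return list with `kept` (group names) and `excluded` (data.frame with
#'   reasons).
#' @export
select_marker_candidates <- function(groups, breakpoints = NULL,
                                     reference_id, min_len = 500,
                                     max_len = 1100) {
  kept <- character(0)
  exc <- list()
  for (g in groups) {
    if (g$role != "noncoding") next
    lens <- vapply(g$members, function(m) nchar(m$seq), numeric(1))
    med <- stats::median(lens)
    if (med < min_len || med > max_len) {
      exc[[length(exc) + 1]] <- data.frame(region = g$region_name,
                                           reason = "length",
                                           median_length = med)
      next
    }
    if (!is.null(breakpoints) && nrow(breakpoints) > 0 &&
        reference_id %in% names(g$members)) {
      src <- g$members[[reference_id]]
      hit <- any(breakpoints$start < src$end & breakpoints$end > src$start)
      if (hit) {
        exc[[length(exc) + 1]] <- data.frame(region = g$region_name,
                                             reason = "breakpoint",
                                             median_length = med)
        next
      }
    }
    kept <- c(kept, g$region_name)
  }
  excluded <- if (length(exc)) do.call(rbind, exc)
  else data.frame(region = character(0), reason = character(0),
                  median_length = numeric(0))
  list(kept = kept, excluded = excluded)
}
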