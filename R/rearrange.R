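# Signed gene-order extraction and rearrangement detection.
#
# The unit of comparison is the annotated locus: gene-order maps are robust
# to spacer divergence, and published plastome rearrangement figures are
# gene-order maps. No minimal rearrangement scenario is computed; blocks
# are maximal order- and sign-consistent runs over the shared locus set.

#' Signed gene order of a canonical genome
#'
#' Loci are sorted by canonical start coordinate; strand is encoded as the
#' sign. IR duplicates keep compartment-aware copy tags (IRa vs IRb) so
#' that copies match their positional counterparts across genomes.
#'
#' @param genome canonical "plastome_genome" (NULL = take from layout).
#' @param layout a "quadripartite_layout".
#' @return data.frame of class "gene_order" with columns symbol, name,
#'   sign, compartment, start, end.
#' @export
gene_order <- function(genome = NULL, layout) {
  if (is.null(genome)) genome <- layout$genome
  n <- genome$length
  feats <- genome$features
  if (!length(feats)) stop("gene_order: genome has no features")
  start <- vapply(feats, feature_start, numeric(1))
  ord <- order(start)
  feats <- feats[ord]; start <- start[ord]
  ext <- t(vapply(feats, feature_extent, numeric(2), n = n))
  comp <- vapply(start, function(p) compartment_of(layout, p), character(1))
  nms <- vapply(feats, `[[`, character(1), "name")
  sgn <- ifelse(vapply(feats, function(f) f$segments$strand[1],
                       character(1)) == "+", 1L, -1L)
  symbol <- order_symbols(nms, comp)
  out <- data.frame(symbol = symbol, name = nms, sign = sgn,
                    compartment = comp, start = start, end = ext[, 2])
  class(out) <- c("gene_order", "data.frame")
  attr(out, "genome_id") <- genome$id
  out
}

# compartment-aware symbols for duplicated locus names, in listed order
order_symbols <- function(nms, comp) {
  tag <- character(length(nms))
  for (nm in unique(nms[duplicated(nms)])) {
    idx <- which(nms == nm)
    cts <- comp[idx]
    if (anyDuplicated(cts)) {
      for (ct in unique(cts)) {
        sub <- idx[cts == ct]
        tag[sub] <- paste0(ct, seq_along(sub))
      }
    } else tag[idx] <- cts
  }
  ifelse(nzchar(tag), paste0(nms, ".", tag), nms)
}

# gene order of the same genome read in the opposite canonical frame:
# row order reverses, signs negate, IRa and IRb swap identity, and
# positional copy tags are re-derived in the new reading order
flip_order <- function(go) {
  out <- go[rev(seq_len(nrow(go))), ]
  out$sign <- -out$sign
  out$compartment <- c(LSC = "LSC", SSC = "SSC", IRa = "IRb",
                       IRb = "IRa")[out$compartment]
  # restore the canonical rotation of the flipped frame (LSC first), so
  # the result equals the gene order the genome would have had if it had
  # canonicalized in the opposite orientation
  lsc <- which(out$compartment == "LSC")
  if (length(lsc) && lsc[1] > 1) {
    n <- nrow(out)
    out <- out[c(lsc[1]:n, 1:(lsc[1] - 1)), ]
  }
  out$symbol <- order_symbols(out$name, out$compartment)
  rownames(out) <- NULL
  out
}

#' Decompose two gene orders into synteny blocks
#'
#' Both orders are restricted to their shared loci; maximal runs that are
#' order- and sign-consistent (collinear) or reversed-and-sign-flipped
#' (inverted) are reported. A collinear block whose target-side neighbors
#' are not its reference-side neighbors is flagged displaced
#' (translocation).
#'
#' @param ref,target "gene_order" objects.
#' @return data.frame with one row per block: orientation ("collinear" /
#'   "inverted"), displaced, n_loci, ref/target index ranges and the locus
#'   symbols.
#' @export
detect_blocks <- function(ref, target) {
  shared <- intersect(ref$symbol, target$symbol)
  if (length(shared) < 2)
    stop("insufficient-homology: fewer than 2 shared loci")
  # a whole-genome strand flip is presentational, not a rearrangement:
  # compare against whichever target frame decomposes into fewer blocks
  # (ties keep the given frame); the flipped frame swaps IRa/IRb identity
  target_flip <- flip_order(target)
  shared_flip <- intersect(ref$symbol, target_flip$symbol)
  r <- ref[ref$symbol %in% shared, ]
  t_fwd <- target[target$symbol %in% shared, ]
  out_fwd <- decompose_blocks(r, t_fwd)
  out_rev <- NULL
  if (length(shared_flip) >= 2) {
    r2 <- ref[ref$symbol %in% shared_flip, ]
    t_rev <- target_flip[target_flip$symbol %in% shared_flip, ]
    out_rev <- decompose_blocks(r2, t_rev)
  }
  if (!is.null(out_rev) && nrow(out_rev) < nrow(out_fwd)) {
    out <- out_rev; t_ <- t_rev; r <- r2; shared <- shared_flip
    flipped <- TRUE
  } else {
    out <- out_fwd; t_ <- t_fwd; flipped <- FALSE
  }
  attr(out, "shared") <- shared
  attr(out, "target_order") <- t_
  attr(out, "ref_order") <- r
  attr(out, "target_flipped") <- flipped
  out
}

decompose_blocks <- function(r, t_) {
  rpos <- stats::setNames(seq_len(nrow(r)), r$symbol)
  rsgn <- stats::setNames(r$sign, r$symbol)
  p <- unname(rpos[t_$symbol])           # ref position of each target locus
  srel <- t_$sign * unname(rsgn[t_$symbol])  # +1 same strand, -1 flipped
  m <- length(p)
  brk <- c(TRUE, vapply(2:m, function(i) {
    fwd <- p[i] == p[i - 1] + 1 && srel[i] == 1 && srel[i - 1] == 1
    rev_ <- p[i] == p[i - 1] - 1 && srel[i] == -1 && srel[i - 1] == -1
    !(fwd || rev_)
  }, logical(1)))
  bid <- cumsum(brk)
  blocks <- lapply(split(seq_len(m), bid), function(idx) {
    orient <- if (length(idx) == 1) {
      if (srel[idx] == -1) "inverted" else "collinear"
    } else if (p[idx[2]] > p[idx[1]]) "collinear" else "inverted"
    data.frame(orientation = orient, n_loci = length(idx),
               tgt_from = idx[1], tgt_to = idx[length(idx)],
               ref_from = min(p[idx]), ref_to = max(p[idx]),
               symbols = paste(t_$symbol[idx], collapse = ","))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  # displaced (translocation): a collinear block whose position changed
  # relative to its flanking blocks - neither target-side neighbor block
  # occupies the circularly adjacent reference range on the matching side
  nb <- nrow(out)
  out$displaced <- FALSE
  if (nb > 1) {
    succ <- function(x) x %% m + 1     # circular successor in ref positions
    for (b in seq_len(nb)) {
      if (out$orientation[b] != "collinear") next
      prv <- out[if (b == 1) nb else b - 1, ]
      nxt <- out[if (b == nb) 1 else b + 1, ]
      ok_prev <- succ(prv$ref_to) == out$ref_from[b]
      ok_next <- succ(out$ref_to[b]) == nxt$ref_from
      out$displaced[b] <- !(ok_prev || ok_next)
    }
  }
  out
}

# signed circular adjacency set of a gene order (canonical form: each
# adjacency (a,b) is stored together with its reading-direction mirror)
signed_adjacencies <- function(go, shared = NULL) {
  if (!is.null(shared)) go <- go[go$symbol %in% shared, ]
  sym <- go$symbol; sgn <- go$sign
  m <- length(sym)
  a <- paste0(ifelse(sgn == 1, "", "-"), sym)
  nxt <- c(2:m, 1)
  fwd <- paste(a, a[nxt], sep = "|")
  neg <- ifelse(sgn == 1, paste0("-", sym), sym)
  bwd <- paste(neg[nxt], neg, sep = "|")
  list(fwd = fwd, closure = union(fwd, bwd))
}

#' Orientation-aware circular breakpoint count
#'
#' Counts adjacent signed pairs in `target` (including the circular wrap
#' pair) that are absent from `ref`'s signed adjacency set (either reading
#' direction).
#'
#' @param ref,target "gene_order" objects.
#' @return integer breakpoint count.
#' @export
breakpoint_count <- function(ref, target) {
  shared <- intersect(ref$symbol, target$symbol)
  if (length(shared) < 2)
    stop("insufficient-homology: fewer than 2 shared loci")
  count_one <- function(t_, sh) {
    ra <- signed_adjacencies(ref, sh)
    ta <- signed_adjacencies(t_, sh)
    sum(!(ta$fwd %in% ra$closure))
  }
  n_fwd <- count_one(target, shared)
  # a presentational whole-genome strand flip must not count as
  # breakpoints: use the frame with fewer
  tf <- flip_order(target)
  shared_flip <- intersect(ref$symbol, tf$symbol)
  if (length(shared_flip) >= 2)
    min(n_fwd, count_one(tf, shared_flip)) else n_fwd
}

#' Rearrangement summary of a genome set against a reference
#'
#' Per genome: synteny-block count, inversion count, translocation count,
#' breakpoint count, and whether every rearranged block has both endpoints
#' in non-coding sequence (a checkable flag, not an assumption).
#'
#' @param orders named list of "gene_order" objects (canonical genomes).
#' @param ref_id name of the reference entry.
#' @return data.frame, one row per non-reference genome.
#' @export
rearrangement_matrix <- function(orders, ref_id) {
  stopifnot(ref_id %in% names(orders))
  ref <- orders[[ref_id]]
  rows <- lapply(setdiff(names(orders), ref_id), function(id) {
    b <- detect_blocks(ref, orders[[id]])
    t_ <- attr(b, "target_order")
    rearr <- b$orientation == "inverted" | b$displaced
    noncoding <- if (!any(rearr)) NA else
      all(vapply(which(rearr), function(i)
        block_endpoints_noncoding(b, i, t_), logical(1)))
    data.frame(id = id, n_blocks = nrow(b),
               n_inversions = sum(b$orientation == "inverted"),
               n_translocations = sum(b$displaced),
               n_breakpoints = breakpoint_count(ref, orders[[id]]),
               endpoints_noncoding = noncoding)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# endpoints of block i fall in spacers if the block-edge loci do not abut
# or overlap their target-order neighbors
block_endpoints_noncoding <- function(blocks, i, t_) {
  m <- nrow(t_)
  gap_ok <- function(a, b) {           # a precedes b in target coordinates
    if (is.na(a) || is.na(b)) return(TRUE)
    t_$start[b] > t_$end[a]
  }
  lo <- blocks$tgt_from[i]; hi <- blocks$tgt_to[i]
  gap_ok(if (lo > 1) lo - 1 else NA, lo) && gap_ok(hi, if (hi < m) hi + 1 else NA)
}

#' Breakpoint regions of a target genome relative to a reference
#'
#' Returns the inter-locus intervals (in target canonical coordinates)
#' around each breakpoint adjacency; used to flag candidate markers that
#' overlap rearrangement endpoints.
#'
#' @param ref,target "gene_order" objects.
#' @return data.frame with columns start, end (0-based half-open).
#' @export
breakpoint_regions <- function(ref, target) {
  shared <- intersect(ref$symbol, target$symbol)
  ra <- signed_adjacencies(ref, shared)
  t_ <- target[target$symbol %in% shared, ]
  ta <- signed_adjacencies(t_, NULL)
  bad <- which(!(ta$fwd %in% ra$closure))
  if (!length(bad)) return(data.frame(start = numeric(0), end = numeric(0)))
  m <- nrow(t_)
  out <- lapply(bad, function(i) {
    j <- if (i == m) 1L else i + 1L
    data.frame(start = t_$end[i], end = t_$start[j])
  })
  do.call(rbind, out)
}
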