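# Quadripartite structure detection and structural summaries.
#
# The inverted-repeat pair is located by exact k-mer seeding between the
# sequence and its reverse complement: a window pair (i, j) whose k-mers are
# reverse complements satisfies i + j = const along an inverted-repeat
# "anti-diagonal", so candidate repeats appear as contiguous runs of hits on
# one anti-diagonal. Runs are then verified and (in mismatch-tolerant mode)
# extended by direct comparison. Everything is circular: k-mers are taken
# from the doubled sequence and coordinates reported modulo genome length.

#' Detect the quadripartite LSC/IRa/SSC/IRb layout of a plastome
#'
#' Finds the maximal pair of disjoint intervals whose sequences are reverse
#' complements of each other (allowing up to `max_mismatch_frac` mismatches
#' when extending beyond the exact core), then canonicalizes the genome:
#' the longer single-copy interval (LSC) starts at position 0 and the order
#' is LSC-IRa-SSC-IRb. Of the two strand choices the one whose single-copy
#' regions carry more forward-strand genes is used (ties broken by
#' lexicographic sequence comparison), matching the conventional LSC-first
#' presentation.
#'
#' @param genome a "plastome_genome".
#' @param min_len minimum IR length in bp (default 1000).
#' @param max_mismatch_frac maximum mismatch fraction tolerated while
#'   extending the repeat (default 0: finished plastome IRs are identical).
#' @param k seed k-mer size (capped at `min_len`).
#' @return an object of class "quadripartite_layout": intervals `lsc`,
#'   `ira`, `ssc`, `irb` (0-based half-open on the canonical rotation),
#'   per-compartment `lengths`, `ir_identity`, and `genome`, the
#'   canonically rotated/oriented genome the coordinates refer to.
#' @export
find_inverted_repeats <- function(genome, min_len = 1000,
                                  max_mismatch_frac = 0, k = 21L) {
  k <- as.integer(min(k, max(8L, min_len %/% 2)))
  n <- genome$length
  if (n < 2 * min_len)
    stop("structure-not-found: genome shorter than two IR copies")
  s <- genome$sequence
  s2 <- paste0(s, substr(s, 1L, k - 1L))
  kmers <- stringi::stri_sub(s2, from = 1:n, length = k)
  rc <- chartr("ACGTN", "TGCAN", stringi::stri_reverse(kmers))
  j <- match(rc, kmers)                  # one hit per window; enough to vote
  hit <- which(!is.na(j) & j != seq_len(n))
  if (!length(hit))
    stop("structure-not-found: no inverted repeat of length >= ", min_len)
  d <- hit + j[hit]                      # anti-diagonal index
  cand <- as.integer(names(sort(table(d), decreasing = TRUE)))
  cand <- utils::head(cand, 8L)

  best <- NULL
  for (dd in cand) {
    arm <- arm_from_antidiagonal(s, rc, kmers, dd, k, n, max_mismatch_frac)
    if (is.null(arm)) next
    if (is.null(best) || arm$len > best$len) best <- arm
  }
  if (is.null(best) || best$len < min_len)
    stop("structure-not-found: no inverted repeat of length >= ", min_len)

  a1 <- best$a1; b1 <- best$b1; a2 <- best$a2; b2 <- best$b2  # 0-based, may exceed n
  ir_len <- best$len
  # single-copy gaps between the two IR copies (circular)
  gap1 <- circ_len(b1, a2, n); gap2 <- circ_len(b2, a1, n)
  if (pmod(b1, n) == pmod(a2, n) || pmod(b2, n) == pmod(a1, n))
    stop("structure-not-found: repeat copies are adjacent, no single-copy gap")
  if (gap1 >= gap2) {
    lsc_start <- pmod(b1, n); lsc_len <- gap1; ssc_len <- gap2
  } else {
    lsc_start <- pmod(b2, n); lsc_len <- gap2; ssc_len <- gap1
  }

  build <- function(g, lsc_start) {
    gr <- rotate_genome(g, lsc_start)
    layout_from_lengths(gr, lsc_len, ir_len, ssc_len, best$identity)
  }
  lay_fwd <- build(genome, lsc_start)
  # strand choice: the orientation with more forward-strand genes in the
  # single-copy regions wins (the IR contributes equally to both)
  grc <- revcomp_genome(genome)
  lsc_start_rc <- pmod(n - (lsc_start + lsc_len), n)
  lay_rev <- build(grc, lsc_start_rc)
  nf <- fwd_genes_single_copy(lay_fwd); nr <- fwd_genes_single_copy(lay_rev)
  lay <- if (nf > nr) lay_fwd
         else if (nr > nf) lay_rev
         else if (lay_fwd$genome$sequence <= lay_rev$genome$sequence) lay_fwd
         else lay_rev
  lay
}

arm_from_antidiagonal <- function(s, rc, kmers, dd, k, n, mmf) {
  # windows i on anti-diagonal dd whose partner window j = dd - i verifies
  jj <- dd - seq_len(n)
  jc <- pmod(jj - 1L, n) + 1L            # circular partner index
  ok <- which(rc == kmers[jc])
  if (!length(ok)) return(NULL)
  # contiguous runs of verified windows -> candidate arms; take the longest
  runs <- split(ok, cumsum(c(1L, diff(ok) != 1L)))
  run <- runs[[which.max(vapply(runs, length, integer(1)))]]
  i0 <- min(run); i1 <- max(run)
  # copy1 occupies windows [i0, i1] -> bases [i0-1, i1+k-1) 0-based
  a1 <- i0 - 1L; b1 <- i1 + k - 1L
  # partner arm: window j for i1 .. j for i0
  a2 <- (dd - i1) - 1L; b2 <- (dd - i0) + k - 1L
  a2 <- pmod(a2, n); b2 <- a2 + (b1 - a1)
  len <- b1 - a1
  # overlap guard: copies must be disjoint on the circle
  if (len > n / 2) return(NULL)
  if (intervals_overlap(a1, b1, a2, b2, n)) return(NULL)
  if (mmf > 0) {
    ext <- extend_mismatch(s, a1, b1, a2, b2, n, mmf)
    a1 <- ext$a1; b1 <- ext$b1; a2 <- ext$a2; b2 <- ext$b2
    len <- b1 - a1
  }
  seq1 <- circ_slice(s, pmod(a1, n), pmod(b1, n))
  seq2 <- circ_slice(s, pmod(a2, n), pmod(b2, n))
  idf <- mean(strsplit(seq1, "")[[1]] ==
              strsplit(revcomp(seq2), "")[[1]])
  list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, len = len, identity = idf)
}

intervals_overlap <- function(a1, b1, a2, b2, n) {
  pts <- function(a, b) pmod(seq.int(a, b - 1L), n)
  # cheap endpoint-based check (intervals are long; compare boundaries)
  inside <- function(x, a, b) pmod(x - a, n) < pmod(b - a - 1e-9, n) + 1e-9
  inside(pmod(a2, n), a1, b1) || inside(pmod(b2 - 1L, n), a1, b1) ||
    inside(pmod(a1, n), a2, b2) || inside(pmod(b1 - 1L, n), a2, b2)
}

extend_mismatch <- function(s, a1, b1, a2, b2, n, mmf) {
  r <- charToRaw(s); cr <- comp_raw(r)
  at <- function(i) r[pmod(i, n) + 1L]
  cat_ <- function(i) cr[pmod(i, n) + 1L]
  mm <- 0L; len <- b1 - a1
  # outward: left of copy1 pairs with right of copy2
  repeat {
    ok1 <- at(a1 - 1L) == cat_(b2)
    if (!ok1) { if ((mm + 1) / (len + 1) > mmf) break; mm <- mm + 1L }
    a1 <- a1 - 1L; b2 <- b2 + 1L; len <- len + 1L
    if (len >= n / 2) break
  }
  repeat {
    ok2 <- at(b1) == cat_(a2 - 1L)
    if (!ok2) { if ((mm + 1) / (len + 1) > mmf) break; mm <- mm + 1L }
    b1 <- b1 + 1L; a2 <- a2 - 1L; len <- len + 1L
    if (len >= n / 2) break
  }
  list(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
}

layout_from_lengths <- function(genome_canon, lsc_len, ir_len, ssc_len, idf) {
  n <- genome_canon$length
  stopifnot(lsc_len + 2 * ir_len + ssc_len == n)
  l1 <- lsc_len; l2 <- l1 + ir_len; l3 <- l2 + ssc_len
  structure(list(
    lsc = c(0, l1), ira = c(l1, l2), ssc = c(l2, l3), irb = c(l3, n),
    lengths = c(lsc = lsc_len, ira = ir_len, ssc = ssc_len, irb = ir_len),
    ir_identity = idf, genome = genome_canon),
    class = "quadripartite_layout")
}

fwd_genes_single_copy <- function(lay) {
  if (!length(lay$genome$features)) return(0L)
  l1 <- lay$lsc[2]; l2 <- lay$ira[2]; l3 <- lay$ssc[2]
  sum(vapply(lay$genome$features, function(f) {
    s <- feature_start(f)
    (s < l1 || (s >= l2 && s < l3)) && f$segments$strand[1] == "+"
  }, logical(1)))
}

#' @export
print.quadripartite_layout <- function(x, ...) {
  cat(sprintf("quadripartite layout: LSC %d | IRa %d | SSC %d | IRb %d bp (IR identity %.4f)\n",
              x$lengths["lsc"], x$lengths["ira"], x$lengths["ssc"],
              x$lengths["irb"], x$ir_identity))
  invisible(x)
}

#' Compartment of a position on the canonical rotation
#' @keywords internal
compartment_of <- function(layout, pos) {
  if (pos < layout$lsc[2]) "LSC"
  else if (pos < layout$ira[2]) "IRa"
  else if (pos < layout$ssc[2]) "SSC"
  else "IRb"
}

#' Gene context at the four single-copy/IR junctions
#'
#' For each junction (LSC-IRa, IRa-SSC, SSC-IRb, IRb-LSC) reports the
#' nearest feature on each flank with a signed distance in bp: positive =
#' gap between feature and junction, negative = the feature overlaps the
#' junction by that many bp (a spanning feature is reported on both flanks
#' with its two overlap extents).
#'
#' @param genome canonical "plastome_genome" (use `layout$genome`), or NULL
#'   to take it from `layout`.
#' @param layout a "quadripartite_layout".
#' @return data.frame with columns junction, side, feature, kind, distance.
#' @export
junction_context <- function(genome = NULL, layout) {
  if (is.null(genome)) genome <- layout$genome
  n <- genome$length
  feats <- genome$features
  if (!length(feats)) return(data.frame(junction = character(0)))
  ext <- t(vapply(feats, feature_extent, numeric(2), n = n))
  nm <- vapply(feats, function(f)
    paste0(f$name, ifelse(nzchar(f$copy_tag), paste0(".", f$copy_tag), "")),
    character(1))
  kind <- vapply(feats, `[[`, character(1), "kind")
  juncs <- c("LSC-IRa" = layout$lsc[2], "IRa-SSC" = layout$ira[2],
             "SSC-IRb" = layout$ssc[2], "IRb-LSC" = n)
  rows <- list()
  for (jn in names(juncs)) {
    b <- juncs[[jn]]
    # circular distances from feature extents to junction position b
    left_gap <- pmod(b - ext[, 2], n)    # 0 if feature ends exactly at b
    right_gap <- pmod(ext[, 1] - b, n)
    spans <- (pmod(b - ext[, 1], n) < (ext[, 2] - ext[, 1])) & left_gap != 0
    if (any(spans)) {
      for (i in which(spans)) {
        over_left <- pmod(b - ext[i, 1], n)
        over_right <- (ext[i, 2] - ext[i, 1]) - over_left
        rows[[length(rows) + 1]] <- data.frame(
          junction = jn, side = "left", feature = nm[i], kind = kind[i],
          distance = -over_left)
        rows[[length(rows) + 1]] <- data.frame(
          junction = jn, side = "right", feature = nm[i], kind = kind[i],
          distance = -over_right)
      }
    }
    il <- which.min(replace(left_gap, spans, NA))
    ir <- which.min(replace(right_gap, spans, NA))
    if (length(il))
      rows[[length(rows) + 1]] <- data.frame(
        junction = jn, side = "left", feature = nm[il], kind = kind[il],
        distance = left_gap[il])
    if (length(ir))
      rows[[length(rows) + 1]] <- data.frame(
        junction = jn, side = "right", feature = nm[ir], kind = kind[ir],
        distance = right_gap[ir])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structural summary of one genome
#'
#' GC% is computed as 100*(G+C)/length and rounded half-up to one decimal,
#' the presentation used in published plastome tables. CDS/tRNA/rRNA are
#' counted as distinct (name, copy_tag) features; pseudogenes are excluded
#' from the CDS count and listed separately. Gene totals are reported under
#' both conventions (IR duplicates counted once vs. per copy).
#'
#' @param genome canonical "plastome_genome" (NULL = take from layout).
#' @param layout a "quadripartite_layout", or NULL for sequence-only
#'   summaries (compartment lengths reported as NA).
#' @return a list of class "genome_summary".
#' @export
genome_summary <- function(genome = NULL, layout = NULL) {
  if (is.null(genome)) genome <- layout$genome
  lengths <- if (is.null(layout)) c(lsc = NA_real_, ira = NA_real_,
                                    ssc = NA_real_) else layout$lengths
  s <- genome$sequence
  gc <- round_half_up(
    100 * (stringi::stri_count_fixed(s, "G") +
           stringi::stri_count_fixed(s, "C")) / genome$length, 1)
  kinds <- vapply(genome$features, `[[`, character(1), "kind")
  nms <- vapply(genome$features, `[[`, character(1), "name")
  pseudo <- nms[kinds == "pseudogene"]
  counts <- c(CDS = sum(kinds == "CDS"), tRNA = sum(kinds == "tRNA"),
              rRNA = sum(kinds == "rRNA"))
  keep <- kinds %in% c("CDS", "tRNA", "rRNA")
  structure(list(
    id = genome$id, length = genome$length,
    lsc = unname(lengths["lsc"]), ssc = unname(lengths["ssc"]),
    ir = unname(lengths["ira"]), gc = gc,
    cds = unname(counts["CDS"]), trna = unname(counts["tRNA"]),
    rrna = unname(counts["rRNA"]),
    genes_with_copies = sum(keep),
    genes_unique = length(unique(nms[keep])),
    pseudogenes = pseudo), class = "genome_summary")
}

#' Cross-species structure comparison table
#'
#' One row per genome with the structural summary plus junction gene
#' context; genomes failing IR detection are flagged and the rest of the
#' table is still produced.
#'
#' @param genomes list of "plastome_genome".
#' @param min_len,max_mismatch_frac passed to [find_inverted_repeats()].
#' @return data.frame, one row per genome.
#' @export
cross_species_structure_table <- function(genomes, min_len = 1000,
                                          max_mismatch_frac = 0) {
  stopifnot(length(genomes) >= 2)
  rows <- lapply(genomes, function(g) {
    lay <- tryCatch(find_inverted_repeats(g, min_len, max_mismatch_frac),
                    error = function(e) NULL)
    if (is.null(lay)) {
      return(data.frame(id = g$id, length = g$length, lsc = NA, ssc = NA,
                        ir = NA, gc = NA, cds = NA, trna = NA, rrna = NA,
                        pseudogenes = "", ir_ssc_junction_genes = "",
                        status = "no_quadripartite"))
    }
    sm <- genome_summary(layout = lay)
    jc <- junction_context(layout = lay)
    irssc <- unique(jc$feature[jc$junction %in% c("IRa-SSC", "SSC-IRb") &
                               jc$distance <= 0])
    data.frame(id = sm$id, length = sm$length, lsc = sm$lsc, ssc = sm$ssc,
               ir = sm$ir, gc = sm$gc, cds = sm$cds, trna = sm$trna,
               rrna = sm$rrna,
               pseudogenes = paste(sm$pseudogenes, collapse = ","),
               ir_ssc_junction_genes = paste(irssc, collapse = ","),
               status = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
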