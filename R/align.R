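# Multiple alignment (center-star), conserved-block filtering, outlier-row
# removal and variability statistics. Alignments are named character
# vectors of equal-length gapped sequences ('-' = gap), one per genome.

#' Center-star multiple alignment of a region group
#'
#' Progressive alignment built from pairwise global alignments against the
#' center sequence (the member maximizing summed pairwise similarity),
#' merged under the once-a-gap-always-a-gap rule. Coding mode uses a
#' higher gap-open cost than non-coding mode, emulating a strict global
#' strategy for coding sequence and a long-gap-tolerant strategy for
#' spacers. An external aligner (e.g. mafft) can be substituted via
#' `external`; its output is ingested into the same alignment form.
#'
#' @param seqs named character vector of ungapped sequences (or a region
#'   group from [group_by_similarity()]).
#' @param mode "coding" or "noncoding".
#' @param external optional path/name of an external alignment command
#'   reading FASTA on stdin and writing aligned FASTA on stdout.
#' @return named character vector of gapped sequences (equal lengths).
#' @export
multiple_align <- function(seqs, mode = c("coding", "noncoding"),
                           external = NULL) {
  mode <- match.arg(mode)
  if (is.list(seqs) && !is.null(seqs$members))
    seqs <- vapply(seqs$members, `[[`, character(1), "seq")
  if (length(seqs) < 2) {
    warning("multiple_align: single member, passthrough alignment")
    return(seqs)
  }
  if (!is.null(external)) {
    tf <- tempfile(fileext = ".fa"); of <- tempfile(fileext = ".fa")
    on.exit(unlink(c(tf, of)), add = TRUE)
    write_fasta(seqs, tf)
    system2(external, c("--auto", "--quiet", tf), stdout = of)
    out <- read_fasta(of)
    return(stats::setNames(toupper(out), names(out))[names(seqs)])
  }
  gap_open <- if (mode == "coding") 8 else 4
  k <- length(seqs)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  # center = member maximizing summed pairwise similarity (score-only
  # alignments: no traceback needed for the selection)
  if (k == 2) {
    center_i <- 1L
  } else {
    simsum <- numeric(k)
    for (i in seq_len(k))
      simsum[i] <- sum(Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(seqs[-i]), Biostrings::DNAString(seqs[[i]]),
        type = "global", substitutionMatrix = submat,
        gapOpening = gap_open, gapExtension = 1, scoreOnly = TRUE))
    center_i <- which.max(simsum)
  }
  center <- seqs[[center_i]]
  others <- seqs[-center_i]
  m <- nchar(center)

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(others), Biostrings::DNAString(center),
    type = "global", substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))

  # for each pairwise alignment, split the other sequence by center slots:
  # ins[[p+1]] = characters inserted before center position p (1..m+1)
  parse_one <- function(gp, gs) {
    sv <- strsplit(gs, "")[[1]]
    pv <- strsplit(gp, "")[[1]]
    slot <- cumsum(sv != "-") + ifelse(sv != "-", 0L, 1L)
    # characters where center has a gap belong to the "before next center
    # char" slot; aligned chars sit at their own center position
    ins <- vector("list", m + 1L)
    at <- character(m)
    for (i in seq_along(sv)) {
      if (sv[i] == "-") {
        p <- slot[i]
        ins[[p]] <- c(ins[[p]], pv[i])
      } else {
        at[slot[i]] <- pv[i]
      }
    }
    list(ins = vapply(ins, function(x) if (is.null(x)) "" else
      paste(x, collapse = ""), character(1)), at = at)
  }
  parsed <- lapply(seq_along(others), function(i) parse_one(pat[i], sub[i]))
  gaplen <- sapply(parsed, function(z) nchar(z$ins))          # (m+1) x (k-1)
  if (is.null(dim(gaplen))) gaplen <- matrix(gaplen, nrow = m + 1L)
  G <- apply(gaplen, 1, max)

  cvec <- strsplit(center, "")[[1]]
  build_row <- function(ins, at) {
    parts <- character(2 * m + 1)
    for (p in seq_len(m + 1L)) {
      pad <- strrep("-", G[p] - nchar(ins[p]))
      parts[2 * p - 1] <- paste0(ins[p], pad)
      if (p <= m) parts[2 * p] <- at[p]
    }
    paste(parts, collapse = "")
  }
  center_row <- build_row(rep("", m + 1L), cvec)
  rows <- c(list(center_row),
            lapply(parsed, function(z) build_row(z$ins, z$at)))
  out <- stats::setNames(unlist(rows),
                         c(names(seqs)[center_i], names(others)))
  out[names(seqs)]
}

#' Conserved-block selection (Castresana-style) on an alignment
#'
#' With n rows, a column is conserved if one residue occurs in more than
#' n/2 rows and highly conserved if in at least 0.85*n rows; any column
#' containing a gap is non-conserved (strictest gap rule). Stretches of
#' more than 8 contiguous non-conserved columns are rejected, remaining
#' blocks are trimmed to highly conserved flanks, and blocks shorter than
#' 10 columns are rejected. The operation is idempotent.
#'
#' @param aln named character vector of gapped rows.
#' @param max_noncons maximum run of contiguous non-conserved columns.
#' @param min_block minimum block length in columns.
#' @param cons_frac,high_frac conservation thresholds.
#' @return list with `mask` (data.frame of kept half-open column intervals,
#'   0-based) and `alignment` (rows restricted to kept columns; possibly
#'   zero-width).
#' @export
block_filter <- function(aln, max_noncons = 8, min_block = 10,
                         cons_frac = 0.5, high_frac = 0.85) {
  stopifnot(length(aln) >= 2)
  M <- as_aln_matrix(aln)
  w <- ncol(M); n <- nrow(M)
  counts <- vapply(c("A", "C", "G", "T"), function(b) colSums(M == b),
                   numeric(w))
  if (w == 1) counts <- matrix(counts, nrow = 1)
  f <- apply(counts, 1, max)
  has_gap <- colSums(M == "-") > 0
  status <- integer(w)   # 0 nonconserved, 1 conserved, 2 highly conserved
  status[!has_gap & f >= high_frac * n] <- 2L
  status[!has_gap & status == 0L & f > cons_frac * n] <- 1L
  # reject runs of > max_noncons contiguous non-conserved columns
  keep <- rep(TRUE, w)
  r <- rle(status == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] > max_noncons)
      keep[starts[i]:ends[i]] <- FALSE
  # trim remaining blocks to highly conserved flanks; drop short blocks
  kr <- rle(keep)
  kends <- cumsum(kr$lengths); kstarts <- kends - kr$lengths + 1L
  for (i in seq_along(kr$lengths)) {
    if (!kr$values[i]) next
    a <- kstarts[i]; b <- kends[i]
    while (a <= b && status[a] != 2L) a <- a + 1L
    while (b >= a && status[b] != 2L) b <- b - 1L
    keep[kstarts[i]:kends[i]] <- FALSE
    if (a <= b && (b - a + 1L) >= min_block) keep[a:b] <- TRUE
  }
  kept <- which(keep)
  mask <- if (length(kept)) {
    # contiguous kept runs as 0-based half-open intervals
    idx <- split(kept, cumsum(c(1L, diff(kept) != 1L)))
    do.call(rbind, lapply(idx, function(v)
      data.frame(start = v[1] - 1L, end = v[length(v)])))
  } else data.frame(start = integer(0), end = integer(0))
  rownames(mask) <- NULL
  filtered <- if (length(kept))
    stats::setNames(apply(M[, kept, drop = FALSE], 1, paste, collapse = ""),
                    names(aln))
  else stats::setNames(rep("", n), names(aln))
  list(mask = mask, alignment = filtered,
       params = list(max_noncons = max_noncons, min_block = min_block,
                     cons_frac = cons_frac, high_frac = high_frac,
                     gap_rule = "none"))
}

#' Remove outlier rows from an alignment
#'
#' Scores each row by its mean pairwise identity (over shared non-gap
#' columns) to all other rows and removes rows scoring below
#' `max(floor, mean - k_sd * sd)`. Uniformly diverged sets are untouched
#' (divergence is not outlierness). Never removes more than ceil(n/3)
#' rows.
#'
#' @param aln named character vector of gapped rows.
#' @param k_sd standard-deviation multiplier (default 2).
#' @param floor absolute identity floor (default 0.5).
#' @return list with `alignment` (surviving rows) and `removed`
#'   (data.frame of removed rows and their scores).
#' @export
remove_outlier_rows <- function(aln, k_sd = 2.0, floor = 0.5) {
  n <- length(aln)
  if (n < 3) {
    warning("remove_outlier_rows: fewer than 3 rows, passthrough")
    return(list(alignment = aln,
                removed = data.frame(id = character(0), score = numeric(0))))
  }
  M <- as_aln_matrix(aln)
  score <- numeric(n)
  for (i in seq_len(n)) {
    ids <- vapply(setdiff(seq_len(n), i), function(j) {
      sh <- M[i, ] != "-" & M[j, ] != "-"
      if (!any(sh)) return(0)
      mean(M[i, sh] == M[j, sh])
    }, numeric(1))
    score[i] <- mean(ids)
  }
  thr <- max(floor, mean(score) - k_sd * stats::sd(score))
  out <- which(score < thr)
  cap <- ceiling(n / 3)
  if (length(out) > cap) out <- out[order(score[out])][seq_len(cap)]
  if (length(out))
    removed <- data.frame(id = names(aln)[out], score = score[out])
  else removed <- data.frame(id = character(0), score = numeric(0))
  keep <- setdiff(seq_len(n), out)
  list(alignment = aln[keep], removed = removed)
}

#' Variable-site statistics of an alignment
#'
#' A column is variable if at least two distinct characters among
#' {A,C,G,T} are present; gaps and N are ignored. Percent variation is
#' 100 * variable / length, rounded half-up to one decimal.
#'
#' @param aln named character vector of gapped rows (or one concatenated
#'   set from [concatenate_alignments()]), or a character matrix with one
#'   row per taxon.
#' @return list(length, variable, percent).
#' @export
variable_site_stats <- function(aln) {
  M <- as_aln_matrix(aln)
  w <- ncol(M)
  present <- vapply(c("A", "C", "G", "T"), function(b)
    colSums(M == b) > 0, logical(w))
  if (w == 1) present <- matrix(present, nrow = 1)
  nvar <- sum(rowSums(present) >= 2)
  list(length = w, variable = nvar,
       percent = round_half_up(100 * nvar / w, 1))
}

# alignment as character matrix (rows = taxa); accepts a named character
# vector of gapped strings or an existing matrix
as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  stopifnot(length(aln) >= 1)
  M <- do.call(rbind, strsplit(aln, ""))
  rownames(M) <- names(aln)
  M
}

#' Ungap an alignment row
#' @param x gapped sequence.
#' @return ungapped sequence.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Align a region group through the edited or filtered pathway
#'
#' The "edited" pathway (a deterministic proxy for manual curation)
#' removes outlier rows, re-aligns the survivors and applies no block
#' filter; a user-supplied curated alignment can be given instead via
#' `curated`. The "filtered" pathway applies the conserved-block filter
#' and then outlier removal.
#'
#' @param seqs named character vector of ungapped member sequences.
#' @param pathway "edited" or "filtered".
#' @param mode alignment mode, see [multiple_align()].
#' @param curated optional pre-curated alignment (named, equal lengths)
#'   used verbatim by the edited pathway.
#' @param aln optional precomputed base alignment of `seqs` (lets the two
#'   pathways share one alignment).
#' @param ... passed to [block_filter()] / [remove_outlier_rows()].
#' @return named character vector of gapped rows.
#' @export
align_region <- function(seqs, pathway = c("edited", "filtered"),
                         mode = "noncoding", curated = NULL, aln = NULL,
                         ...) {
  pathway <- match.arg(pathway)
  if (pathway == "edited" && !is.null(curated)) {
    stopifnot(length(unique(nchar(curated))) == 1)
    return(curated)
  }
  if (is.null(aln)) aln <- multiple_align(seqs, mode = mode)
  if (length(aln) < 3) return(aln)
  if (pathway == "edited") {
    kept <- remove_outlier_rows(aln, ...)
    if (nrow(kept$removed) > 0 && length(kept$alignment) >= 2)
      return(multiple_align(ungap_set(kept$alignment), mode = mode))
    return(kept$alignment)
  }
  bf <- block_filter(aln)
  if (!nchar(bf$alignment[[1]])) return(bf$alignment)
  remove_outlier_rows(bf$alignment, ...)$alignment
}

ungap_set <- function(aln) stats::setNames(vapply(aln, ungap, character(1)),
                                           names(aln))
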