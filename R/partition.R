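# Fragmentation of annotated genomes into coding and non-coding regions,
# reference-based homology grouping, and partition-scheme assembly.
#
# One IR copy (IRb) is excluded before fragmentation to avoid duplicating
# data. Coding regions are the spliced exon sequences of CDS/tRNA/rRNA
# features; non-coding regions are introns, intergenic spacers and
# pseudogene sequences. Overlapping genes are truncated at the midpoint of
# their overlap so no base is emitted twice; regions shorter than 50 bp
# are dropped (the threshold is inclusive: a 50 bp region is retained).

#' Fragment a canonical genome into coding and non-coding regions
#'
#' @param genome canonical "plastome_genome" (NULL = take from layout).
#' @param layout a "quadripartite_layout".
#' @param min_len minimum region length in bp retained (inclusive).
#' @return list of region records, each a list with genome_id, region_name,
#'   role ("coding"/"noncoding"), seq, start, end, strand.
#' @export
fragment_genome <- function(genome = NULL, layout, min_len = 50) {
  if (is.null(genome)) genome <- layout$genome
  n <- genome$length
  l3 <- layout$ssc[2]                 # keep [0, l3): LSC + IRa + SSC
  feats <- genome$features
  # drop features lying entirely within the excluded IRb
  keep <- vapply(feats, function(f) feature_start(f) < l3, logical(1))
  feats <- feats[keep]
  if (!length(feats)) stop("fragment_genome: no features outside IRb")

  nms <- vapply(feats, function(f)
    paste0(f$name, ifelse(nzchar(f$copy_tag), paste0(".", f$copy_tag), "")),
    character(1))
  kinds <- vapply(feats, `[[`, character(1), "kind")
  ext <- t(vapply(feats, feature_extent, numeric(2), n = n))
  ext[, 2] <- pmin(ext[, 2], l3)      # truncate IRb-crossing extents
  ord <- order(ext[, 1])
  feats <- feats[ord]; nms <- nms[ord]; kinds <- kinds[ord]
  ext <- ext[ord, , drop = FALSE]
  nf <- length(feats)

  # resolve overlapping neighbors at the overlap midpoint: effective
  # feature extents become disjoint [cut_start, cut_end)
  cut <- ext
  for (i in seq_len(nf - 1)) {
    if (cut[i, 2] > cut[i + 1, 1]) {
      mid <- floor((cut[i, 2] + cut[i + 1, 1]) / 2)
      cut[i, 2] <- mid
      cut[i + 1, 1] <- mid
    }
  }

  regions <- list()
  emit <- function(name, role, start, end, strand = "+", seq = NULL,
                   segments = NULL) {
    if (is.null(seq)) seq <- extract_sequence(genome, c(start, end), strand)
    if (nchar(seq) < min_len) return(invisible(NULL))
    if (is.null(segments))
      segments <- data.frame(start = start, end = end)
    regions[[length(regions) + 1]] <<- list(
      genome_id = genome$id, region_name = name, role = role,
      seq = seq, start = start, end = end, strand = strand,
      segments = segments)
  }

  for (i in seq_len(nf)) {
    f <- feats[[i]]
    segs <- f$segments
    # clip exon segments to the effective (overlap-resolved, IRb-excluded)
    # extent of the feature
    segs$end[segs$end <= segs$start] <- l3   # wrap into IRb -> clip at l3
    segs$start <- pmax(segs$start, cut[i, 1])
    segs$end <- pmin(segs$end, cut[i, 2])
    segs <- segs[segs$end > segs$start, , drop = FALSE]
    if (!nrow(segs)) next
    if (kinds[i] == "pseudogene") {
      for (j in seq_len(nrow(segs)))
        emit(paste0(nms[i], "_pseudo"), "noncoding",
             segs$start[j], segs$end[j], segs$strand[j])
      next
    }
    # spliced coding sequence (exons in 5'->3' feature order)
    cds <- paste(vapply(seq_len(nrow(segs)), function(j)
      extract_sequence(genome, c(segs$start[j], segs$end[j]),
                       segs$strand[j]), character(1)), collapse = "")
    emit(nms[i], "coding", min(segs$start), max(segs$end),
         segs$strand[1], seq = cds,
         segments = segs[order(segs$start), c("start", "end")])
    # introns: genomic gaps between consecutive exon segments
    if (nrow(segs) > 1) {
      gsort <- segs[order(segs$start), , drop = FALSE]
      for (j in seq_len(nrow(gsort) - 1)) {
        a <- gsort$end[j]; b <- gsort$start[j + 1]
        if (b > a) {
          nm <- if (nrow(gsort) > 2) paste0(nms[i], "_intron", j)
                else paste0(nms[i], "_intron")
          emit(nm, "noncoding", a, b, gsort$strand[1])
        }
      }
    }
  }

  # intergenic spacers: gaps between consecutive effective extents,
  # plus the leading gap before the first feature
  bounds <- rbind(c(0, cut[1, 1]),
                  cbind(cut[seq_len(nf - 1), 2], cut[seq.int(2, nf), 1]),
                  c(cut[nf, 2], l3))
  bnames <- c(paste0("start-", nms[1]),
              paste(nms[seq_len(nf - 1)], nms[seq.int(2, nf)], sep = "-"),
              paste0(nms[nf], "-end"))
  for (i in seq_len(nrow(bounds))) {
    if (bounds[i, 2] > bounds[i, 1])
      emit(bnames[i], "noncoding", bounds[i, 1], bounds[i, 2])
  }
  regions
}

#' Global similarity of two DNA sequences
#'
#' Needleman-Wunsch global alignment with pinned costs (match +1,
#' mismatch -1, gap open -4, gap extend -1); similarity is the fraction of
#' identical aligned positions over the alignment length (gaps included).
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_extend alignment costs.
#' @return similarity fraction in [0, 1].
#' @export
global_similarity <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 4, gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  Biostrings::pid(aln, type = "PID1") / 100
}

# vectorized similarity of many patterns against one subject
global_similarity_many <- function(patterns, subject, gap_open = 4,
                                   gap_extend = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Group regions across taxa by global similarity to a reference
#'
#' Every region of every non-reference genome is assigned to the reference
#' region of the same role with the highest global similarity, provided
#' that similarity reaches `threshold`; otherwise it is left unassigned
#' (and reported). At most one member per genome is kept per group (the
#' best-scoring candidate wins).
#'
#' @param regions list of region records pooled over all genomes
#'   (see [fragment_genome()]).
#' @param reference_id genome id supplying the group-defining exemplars.
#' @param threshold minimum global similarity (default 0.65).
#' @return list with `groups` (named list of region-group objects, each
#'   with region_name, role, members, similarity) and `unassigned`
#'   (data.frame of unplaced regions).
#' @export
group_by_similarity <- function(regions, reference_id, threshold = 0.65) {
  gids <- vapply(regions, `[[`, character(1), "genome_id")
  if (!any(gids == reference_id))
    stop("configuration error: reference genome '", reference_id,
         "' absent from region pool")
  refs <- regions[gids == reference_id]
  others <- regions[gids != reference_id]
  ref_names <- vapply(refs, `[[`, character(1), "region_name")
  ref_roles <- vapply(refs, `[[`, character(1), "role")
  ref_len <- nchar(vapply(refs, `[[`, character(1), "seq"))

  groups <- lapply(seq_along(refs), function(i) {
    list(region_name = ref_names[i], role = ref_roles[i],
         members = stats::setNames(list(refs[[i]]), reference_id),
         similarity = stats::setNames(1, reference_id))
  })
  names(groups) <- ref_names
  unassigned <- list()

  for (reg in others) {
    len <- nchar(reg$seq)
    # similarity cannot exceed min(len)/max(len): prefilter candidates
    cand <- which(ref_roles == reg$role &
                    pmin(ref_len, len) / pmax(ref_len, len) >= threshold)
    if (!length(cand)) {
      unassigned[[length(unassigned) + 1]] <- reg
      next
    }
    sims <- global_similarity_many(
      vapply(refs[cand], `[[`, character(1), "seq"), reg$seq)
    best <- which.max(sims)
    if (sims[best] < threshold) {
      unassigned[[length(unassigned) + 1]] <- reg
      next
    }
    gname <- ref_names[cand[best]]
    gid <- reg$genome_id
    cur <- groups[[gname]]$similarity[gid]
    if (is.na(cur) || sims[best] > cur) {
      if (!is.na(cur))   # displaced previous member becomes unassigned
        unassigned[[length(unassigned) + 1]] <- groups[[gname]]$members[[gid]]
      groups[[gname]]$members[[gid]] <- reg
      groups[[gname]]$similarity[gid] <- sims[best]
    } else {
      unassigned[[length(unassigned) + 1]] <- reg
    }
  }
  un <- if (length(unassigned)) data.frame(
    genome_id = vapply(unassigned, `[[`, character(1), "genome_id"),
    region_name = vapply(unassigned, `[[`, character(1), "region_name"),
    role = vapply(unassigned, `[[`, character(1), "role"))
  else data.frame(genome_id = character(0), region_name = character(0),
                  role = character(0))
  list(groups = groups, unassigned = un)
}

#' Assemble the five partition schemes
#'
#' Builds the canonical five concatenation schemes from aligned region
#' groups: coding, non-coding (edited and filtered variants), and the two
#' coding + non-coding combinations. Per scheme, the concatenated alignment
#' length, variable-site count and percent variation (1 decimal) are
#' computed; combined-scheme statistics are the sums of their parts.
#'
#' @param coding_alns named list of coding alignments (see [multiple_align()]).
#' @param noncoding_edited named list of non-coding alignments, edited
#'   pathway.
#' @param noncoding_filtered named list of non-coding alignments, filtered
#'   pathway.
#' @return data.frame of class "partition_schemes" with one row per scheme,
#'   plus a "members" attribute mapping scheme -> group names.
#' @export
build_schemes <- function(coding_alns, noncoding_edited,
                          noncoding_filtered) {
  if (!length(coding_alns) || !length(noncoding_edited) ||
      !length(noncoding_filtered))
    stop("build_schemes: empty scheme")
  stat_set <- function(alns) {
    per <- lapply(alns, variable_site_stats)
    len <- sum(vapply(per, `[[`, numeric(1), "length"))
    var <- sum(vapply(per, `[[`, numeric(1), "variable"))
    c(length = len, variable = var)
  }
  cod <- stat_set(coding_alns)
  ned <- stat_set(noncoding_edited)
  nfl <- stat_set(noncoding_filtered)
  comb <- function(a, b) a + b
  tab <- rbind(coding = cod,
               noncoding_edited = ned,
               noncoding_filtered = nfl,
               `coding+noncoding_edited` = comb(cod, ned),
               `coding+noncoding_filtered` = comb(cod, nfl))
  out <- data.frame(scheme = rownames(tab),
                    alignment_length = tab[, "length"],
                    variable_sites = tab[, "variable"],
                    pct_variation = round_half_up(
                      100 * tab[, "variable"] / tab[, "length"], 1))
  rownames(out) <- NULL
  attr(out, "members") <- list(
    coding = names(coding_alns),
    noncoding_edited = names(noncoding_edited),
    noncoding_filtered = names(noncoding_filtered))
  class(out) <- c("partition_schemes", "data.frame")
  out
}

#' Concatenate a set of alignments over their union of taxa
#'
#' Taxa missing from a member alignment are padded with gaps.
#' @param alns named list of alignments (named character matrices/vectors).
#' @return named character vector: one concatenated gapped sequence per
#'   taxon.
#' @export
concatenate_alignments <- function(alns) {
  taxa <- sort(unique(unlist(lapply(alns, names))))
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  for (a in alns) {
    w <- nchar(a[[1]])
    pad <- strrep("-", w)
    for (tx in taxa)
      rows[tx] <- paste0(rows[tx], if (tx %in% names(a)) a[[tx]] else pad)
  }
  rows
}
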