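# AnnotatedGenome: a circular DNA sequence plus a strand-aware feature list.
# Internal coordinates are 0-based half-open; a segment with end <= start
# wraps the origin. GenBank 1-based inclusive coordinates exist only at the
# file boundary (see read_genbank/write_genbank).

#' Create a feature
#'
#' A feature is a named locus (gene, tRNA, rRNA, pseudogene copy) made of one
#' or more segments. Segments are listed 5'->3' on the feature's own strand,
#' so for a minus-strand multi-exon feature the first segment is the one with
#' the largest genomic coordinate.
#'
#' @param name gene symbol, e.g. "ycf1", "trnQ-UUG".
#' @param kind one of "CDS", "tRNA", "rRNA", "intron", "pseudogene".
#' @param segments data.frame with columns start, end (0-based half-open,
#'   end <= start wraps the origin) and strand ("+"/"-").
#' @param copy_tag disambiguator for duplicated loci ("" if unique).
#' @return an object of class "plastome_feature".
#' @export
new_feature <- function(name, kind, segments, copy_tag = "") {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "intron", "pseudogene"))
  stopifnot(is.data.frame(segments), nrow(segments) >= 1,
            all(c("start", "end", "strand") %in% names(segments)))
  if (any(segments$start == segments$end))
    stop("feature segment with end == start: ", name)
  structure(list(name = name, kind = kind,
                 segments = segments[, c("start", "end", "strand")],
                 copy_tag = copy_tag),
            class = "plastome_feature")
}

# first-segment genomic start used for sorting / copy-tag assignment
feature_start <- function(f) f$segments$start[which.min(f$segments$start)]

# total feature length in bp
feature_length <- function(f, n) {
  sum(vapply(seq_len(nrow(f$segments)), function(i)
    circ_len(f$segments$start[i], f$segments$end[i], n), numeric(1)))
}

# [min_start, max_end) extent of a non-wrapping feature; wrapping features
# report their extent on the unrolled coordinates (max_end may exceed n)
feature_extent <- function(f, n) {
  s <- f$segments$start
  e <- ifelse(f$segments$end <= f$segments$start,
              f$segments$end + n, f$segments$end)
  c(min(s), max(e))
}

#' Create an annotated circular genome
#'
#' Duplicated locus names receive deterministic copy tags ("1", "2", ...)
#' in ascending start-coordinate order unless tags are already present.
#'
#' @param id taxon or accession label.
#' @param sequence DNA string; IUPAC ambiguity codes are mapped to N with a
#'   warning.
#' @param features list of [new_feature()] objects.
#' @return an object of class "plastome_genome".
#' @export
new_genome <- function(id, sequence, features = list()) {
  sequence <- sanitize_dna(sequence, paste0("genome ", id))
  n <- nchar(sequence)
  stopifnot(n > 0)
  if (length(features)) {
    for (f in features) {
      if (any(f$segments$start < 0 | f$segments$start >= n |
              f$segments$end < 0 | f$segments$end > n))
        stop("feature interval outside [0, length) after normalization: ",
             f$name)
    }
    ord <- order(vapply(features, feature_start, numeric(1)))
    features <- features[ord]
    features <- assign_copy_tags(features)
  }
  structure(list(id = id, sequence = sequence, length = n,
                 features = features),
            class = "plastome_genome")
}

assign_copy_tags <- function(features) {
  nms <- vapply(features, `[[`, character(1), "name")
  tags <- vapply(features, `[[`, character(1), "copy_tag")
  for (nm in unique(nms[duplicated(nms)])) {
    idx <- which(nms == nm)
    if (any(tags[idx] == "") || anyDuplicated(tags[idx])) {
      for (k in seq_along(idx)) features[[idx[k]]]$copy_tag <- as.character(k)
    }
  }
  features
}

#' @export
print.plastome_genome <- function(x, ...) {
  cat(sprintf("plastome genome '%s': %d bp, %d features\n",
              x$id, x$length, length(x$features)))
  invisible(x)
}

#' Extract a strand-resolved sequence from a circular genome
#'
#' @param genome a "plastome_genome".
#' @param interval numeric `c(start, end)` (0-based half-open, `end <= start`
#'   wraps the origin) or a list/vector with a third element strand.
#' @param strand "+" or "-"; for "-" the reverse complement is returned.
#' @return character scalar.
#' @examples
#' g <- new_genome("toy", "AAACCC")
#' extract_sequence(g, c(4, 2))          # wraps: "CCAA"
#' extract_sequence(g, c(0, 4), "-")     # revcomp of "AAAC"
#' @export
extract_sequence <- function(genome, interval, strand = "+") {
  if (length(interval) >= 3 && is.character(interval[[3]])) {
    strand <- interval[[3]]
    interval <- as.numeric(interval[1:2])
  }
  s <- circ_slice(genome$sequence, interval[[1]], interval[[2]])
  if (identical(strand, "-")) revcomp(s) else s
}

#' Extract the spliced, strand-resolved sequence of a feature
#'
#' Segments are concatenated in their stored (5'->3' on feature strand)
#' order, each strand-resolved individually.
#' @param genome a "plastome_genome".
#' @param feature a "plastome_feature".
#' @return character scalar.
#' @export
extract_feature <- function(genome, feature) {
  segs <- feature$segments
  paste(vapply(seq_len(nrow(segs)), function(i)
    extract_sequence(genome, c(segs$start[i], segs$end[i]), segs$strand[i]),
    character(1)), collapse = "")
}

#' Rotate a circular genome so that `offset` becomes position 0
#'
#' Lossless: sequence and all feature coordinates are shifted modulo length.
#' @param genome a "plastome_genome".
#' @param offset 0-based position that becomes the new origin.
#' @return rotated "plastome_genome".
#' @export
rotate_genome <- function(genome, offset) {
  n <- genome$length
  offset <- pmod(offset, n)
  if (offset == 0) return(genome)
  seq2 <- paste0(substr(genome$sequence, offset + 1L, n),
                 substr(genome$sequence, 1L, offset))
  feats <- lapply(genome$features, function(f) {
    f$segments$start <- pmod(f$segments$start - offset, n)
    f$segments$end <- pmod(f$segments$end - offset, n)
    # end == 0 means "up to the origin", store as n -> normalized half-open
    f$segments$end[f$segments$end == 0] <- n
    f
  })
  g <- new_genome(genome$id, seq2, feats)
  g
}

#' Reverse-complement a genome (strand flip), updating all features
#' @param genome a "plastome_genome".
#' @return flipped "plastome_genome".
#' @export
revcomp_genome <- function(genome) {
  n <- genome$length
  feats <- lapply(genome$features, function(f) {
    segs <- f$segments
    new_start <- pmod(n - segs$end, n)
    new_end <- pmod(n - segs$start, n)
    new_end[new_end == 0] <- n
    segs$start <- new_start
    segs$end <- new_end
    segs$strand <- ifelse(segs$strand == "+", "-", "+")
    # keep 5'->3' order on the (new) feature strand
    f$segments <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
    rownames(f$segments) <- NULL
    f
  })
  new_genome(genome$id, revcomp(genome$sequence), feats)
}
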