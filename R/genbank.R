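# GenBank flat-file reader/writer for single circular DNA records.
# No installed R package parses GenBank feature tables, so the (small,
# well-specified) subset needed here is implemented directly: LOCUS, the
# FEATURES table with CDS/tRNA/rRNA/intron keys, and ORIGIN. 1-based
# inclusive file coordinates are converted to the package's 0-based
# half-open convention at this boundary and nowhere else.

FEATURE_KEYS <- c("CDS", "tRNA", "rRNA", "intron")

#' Read a GenBank flat file into an annotated genome
#'
#' Parses a single circular DNA record. `join()` locations become
#' multi-segment features, `complement()` records the minus strand (with
#' segments re-ordered 5'->3' on the feature strand), and features carrying
#' a `/pseudo` qualifier get kind "pseudogene". Feature keys other than
#' CDS/tRNA/rRNA/intron (source, gene, misc_feature, ...) are ignored.
#'
#' @param path path to a GenBank flat file.
#' @return a "plastome_genome".
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1)
    stop("malformed record: expected exactly one LOCUS line in ", path)
  locus <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  id <- locus[2]

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1)
    stop("malformed record: no ORIGIN section (", path, ")")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L
  seq_lines <- lines[(origin_i + 1):(end_i - 1)]
  sequence <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  n <- nchar(sequence)
  if (n == 0) stop("malformed record: empty sequence in ", path)

  feat_i <- grep("^FEATURES", lines)
  raw_feats <- list()
  if (length(feat_i) == 1 && feat_i < origin_i) {
    block <- lines[(feat_i + 1):(origin_i - 1)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {          # new feature entry
        if (!is.null(cur)) raw_feats[[length(raw_feats) + 1]] <- cur
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(key = parts[1],
                    loc = paste(parts[-1], collapse = ""),
                    quals = character(0), line = ln)
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) {
          cur$quals <- c(cur$quals, txt)
        } else {                             # location continuation
          if (length(cur$quals) == 0) cur$loc <- paste0(cur$loc, txt)
          else cur$quals[length(cur$quals)] <-
              paste0(cur$quals[length(cur$quals)], txt)
        }
      }
    }
    if (!is.null(cur)) raw_feats[[length(raw_feats) + 1]] <- cur
  }

  features <- list()
  for (rf in raw_feats) {
    if (!(rf$key %in% FEATURE_KEYS)) next
    segs <- parse_location(rf$loc, n, rf$line)
    name <- qual_value(rf$quals, "gene")
    if (is.na(name)) name <- qual_value(rf$quals, "product")
    if (is.na(name)) name <- rf$key
    kind <- rf$key
    if (any(grepl("^/pseudo\\b", rf$quals))) kind <- "pseudogene"
    tag <- qual_value(rf$quals, "note")
    copy_tag <- if (!is.na(tag) && grepl("^copy_tag=", tag))
      sub("^copy_tag=", "", tag) else ""
    features[[length(features) + 1]] <-
      new_feature(name, kind, segs, copy_tag)
  }
  new_genome(id, sequence, features)
}

qual_value <- function(quals, key) {
  pat <- sprintf("^/%s=", key)
  hit <- grep(pat, quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^"|"$', "", sub(pat, "", hit[1]))
}

# Parse a GenBank location string into a 0-based half-open segment table.
parse_location <- function(loc, n, line) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  spans <- strsplit(loc, ",", fixed = TRUE)[[1]]
  seg <- lapply(spans, function(sp) {
    sp <- gsub("[<>]", "", sp)
    if (grepl("^\\d+\\.\\.\\d+$", sp)) {
      ab <- as.numeric(strsplit(sp, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", sp)) {
      ab <- rep(as.numeric(sp), 2)
    } else {
      stop("parse error in feature location at line: ", trimws(line))
    }
    if (ab[1] < 1 || ab[2] > n || ab[2] < ab[1])
      stop("parse error (coordinates out of range) at line: ", trimws(line))
    c(start = ab[1] - 1, end = ab[2])   # 1-based inclusive -> 0-based half-open
  })
  segs <- as.data.frame(do.call(rbind, seg))
  segs$strand <- strand
  # merge a trailing wrap pair join(x..n, 1..y) into one wrapping segment
  if (nrow(segs) >= 2) {
    k <- nrow(segs)
    for (i in seq_len(k - 1)) {
      if (segs$end[i] == n && segs$start[i + 1] == 0) {
        segs$end[i] <- segs$end[i + 1]
        segs <- segs[-(i + 1), , drop = FALSE]
        break
      }
    }
  }
  if (strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits a minimal record (LOCUS, FEATURES, ORIGIN) that [read_genbank()]
#' round-trips losslessly: intervals, strands, names, kinds and copy tags
#' are preserved.
#'
#' @param genome a "plastome_genome".
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- genome$length
  out <- c(sprintf("LOCUS       %s %d bp    DNA     circular PLN 01-JAN-1980",
                   genome$id, n),
           sprintf("DEFINITION  %s plastid genome.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  for (f in genome$features) {
    key <- if (f$kind == "pseudogene") "CDS" else f$kind
    loc <- format_location(f$segments, n)
    out <- c(out, sprintf("     %-16s%s", key, loc),
             sprintf('                     /gene="%s"', f$name))
    if (f$kind == "pseudogene")
      out <- c(out, "                     /pseudo")
    if (nzchar(f$copy_tag))
      out <- c(out, sprintf('                     /note="copy_tag=%s"',
                            f$copy_tag))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  pos <- seq(1, n, by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

format_location <- function(segs, n) {
  # undo the 5'->3' ordering for minus strand before formatting
  strand <- segs$strand[1]
  if (strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  spans <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    s <- segs$start[i]; e <- segs$end[i]
    if (e <= s) {  # wrapping segment -> two 1-based spans
      c(sprintf("%d..%d", s + 1, n), sprintf("%d..%d", 1, e))
    } else sprintf("%d..%d", s + 1, e)
  }))
  loc <- if (length(spans) > 1)
    sprintf("join(%s)", paste(spans, collapse = ",")) else spans
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write sequences to FASTA (80-column wrapped)
#'
#' @param seqs named character vector, or a list of region records (each with
#'   `genome_id`, `region_name`, `seq`), in which case headers are
#'   "genome_id|region_name".
#' @param path output path.
#' @param aligned if TRUE, all sequences must share one length.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, aligned = FALSE) {
  if (is.list(seqs) && !is.null(seqs[[1]]$genome_id)) {
    nm <- vapply(seqs, function(r) paste0(r$genome_id, "|", r$region_name),
                 character(1))
    seqs <- stats::setNames(vapply(seqs, `[[`, character(1), "seq"), nm)
  }
  if (!length(seqs)) stop("write_fasta: empty sequence set")
  if (aligned && length(unique(nchar(seqs))) != 1)
    stop("write_fasta: aligned set with unequal lengths")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}
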