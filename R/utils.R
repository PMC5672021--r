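# Low-level sequence helpers shared across modules. Sequences are plain
# character scalars over {A,C,G,T,N}; coordinates are 0-based half-open.

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

#' Complement (no reversal) of a DNA string
#' @param x character scalar.
#' @return character scalar.
#' @keywords internal
complement_seq <- function(x) chartr("ACGTN", "TGCAN", x)

# raw-vector complement lookup, used by the IR extension loop
.comp_raw <- local({
  tab <- raw(256)
  from <- utf8ToInt("ACGTN")
  to   <- utf8ToInt("TGCAN")
  tab[from + 1L] <- as.raw(to)
  tab
})

comp_raw <- function(r) .comp_raw[as.integer(r) + 1L]

#' Round half away from zero to a fixed number of decimals
#'
#' Base `round()` rounds half to even; published tables round half up.
#' @param x numeric.
#' @param digits integer number of decimals.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Normalize a position into [0, n)
pmod <- function(i, n) ((i %% n) + n) %% n

#' Extract a possibly wrapping slice of a circular sequence
#'
#' @param s character scalar (the full circular sequence).
#' @param start,end 0-based half-open interval; `end <= start` wraps the origin.
#' @return forward-strand character scalar.
#' @keywords internal
circ_slice <- function(s, start, end) {
  n <- nchar(s)
  start <- pmod(start, n)
  end_norm <- pmod(end, n)
  if (end_norm > start) {
    substr(s, start + 1L, end_norm)
  } else {
    # wraps the origin: [start, n) then [0, end)
    paste0(substr(s, start + 1L, n), substr(s, 1L, end_norm))
  }
}

# length of a circular interval (0 < len <= n)
circ_len <- function(start, end, n) {
  l <- pmod(end - start, n)
  if (l == 0L) n else l
}

#' Sanitize a DNA string: uppercase, map IUPAC ambiguity codes to N
#' @keywords internal
sanitize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0) {
    amb <- "RYSWKMBDHV"
    other <- gsub(sprintf("[%s]", amb), "", bad)
    if (nchar(other) > 0) {
      stop(sprintf("non-DNA alphabet in %s: characters '%s'", what,
                   paste(unique(strsplit(other, "")[[1]]), collapse = "")))
    }
    warning(sprintf("%d ambiguity code(s) in %s mapped to N",
                    nchar(bad), what))
    for (ch in strsplit(amb, "")[[1]]) x <- gsub(ch, "N", x, fixed = TRUE)
  }
  x
}

#' Random DNA string
#' @param n length in bp.
#' @param gc target GC fraction.
#' @keywords internal
random_dna <- function(n, gc = 0.38) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
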