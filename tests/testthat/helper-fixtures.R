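# Shared in-code fixtures: toy gene orders, small genomes with planted
# inverted repeats, tiny GenBank records, and a cross-file cache so the
# expensive end-to-end fixtures are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# signed gene order object from symbol/sign vectors
toy_order <- function(symbols, signs, compartment = "LSC") {
  d <- data.frame(symbol = symbols, name = symbols, sign = signs,
                  compartment = compartment,
                  start = seq_along(symbols) * 100,
                  end = seq_along(symbols) * 100 + 60)
  class(d) <- c("gene_order", "data.frame")
  d
}

# linear genome with an exact planted inverted repeat:
# [lsc | arm | ssc | revcomp(arm)]
planted_ir_genome <- function(lsc = 2000, arm = 600, ssc = 1200,
                              id = "toy", seed = 1) {
  set.seed(seed)
  a <- plastome:::random_dna(arm)
  parts <- c(plastome:::random_dna(lsc), a, plastome:::random_dna(ssc),
             revcomp(a))
  s <- paste(parts, collapse = "")
  # pin junction-flank bases so the maximal repeat is exactly the arm
  v <- strsplit(s, "")[[1]]
  v[c(1, lsc)] <- c("A", "A")
  v[c(lsc + arm + 1, lsc + arm + ssc)] <- c("A", "A")
  new_genome(id, paste(v, collapse = ""))
}

# minimal GenBank text for a given sequence and feature lines
genbank_text <- function(seq, feature_lines, id = "TESTREC") {
  n <- nchar(seq)
  body <- vapply(seq(1, n, 60), function(p) {
    chunk <- tolower(substr(seq, p, min(p + 59, n)))
    sprintf("%9d %s", p, chunk)
  }, character(1))
  c(sprintf("LOCUS       %s %d bp    DNA     circular PLN 01-JAN-1980",
            id, n),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    feature_lines, "ORIGIN", body, "//")
}

write_genbank_text <- function(seq, feature_lines, id = "TESTREC") {
  f <- tempfile(fileext = ".gb")
  writeLines(genbank_text(seq, feature_lines, id), f)
  f
}

# small simulated study set reused across test files
small_sim <- function() cached("small_sim", simulate_plastome_set(
  n_ingroup = 6, n_outgroup = 3, profile = "reduced", seed = 11))

small_layouts <- function() cached("small_layouts", lapply(
  small_sim()$genomes, find_inverted_repeats, min_len = 1000))
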