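# Synthetic annotated plastomes with known ground truth.
#
# A genome is modeled as an ordered list of elements (genes with
# exon/intron parts, and spacers) laid out as LSC | IR | SSC; the second
# IR copy (IRb) is materialized at instantiation as the exact mirror
# (reverse complement, reversed order) of the IR element list, so the two
# IR copies evolve in lockstep by construction (one mutation is applied to
# the shared element and appears in both copies), reflecting real plastome
# IR homogenization. Structural events (inversions, IR boundary shifts,
# gene loss, pseudogenization) operate on whole elements, so annotations
# stay consistent through every event and each tip's true gene order,
# layout and event history are known exactly.
#
# Junction anchoring: the first/last base of each single-copy compartment
# is pinned to 'A' (and excluded from mutation) so the maximal inverted
# repeat of the instantiated sequence is exactly the planted IR - the
# boundary bases never chance-extend the repeat.

GENE_KINDS <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA")

make_gene <- function(name, kind, length, strand, compartment,
                      n_introns = 0, intron_len = NULL) {
  if (kind == "CDS") {
    length <- max(3 * ceiling(length / 3), 33)
    body <- random_dna(length - 6)
    seqs <- paste0("ATG", body, "TAA")
  } else {
    seqs <- random_dna(length)
  }
  if (n_introns == 0) {
    parts <- list(list(label = "exon", seq = seqs))
  } else {
    if (is.null(intron_len)) intron_len <- rep(250, n_introns)
    L <- nchar(seqs)
    cut <- sort(sample.int(L - 2, n_introns)) # exon split points
    exons <- substring(seqs, c(1, cut + 1), c(cut, L))
    parts <- list()
    for (i in seq_along(exons)) {
      parts[[length(parts) + 1]] <- list(label = "exon", seq = exons[i])
      if (i <= n_introns)
        parts[[length(parts) + 1]] <- list(label = "intron",
                                           seq = random_dna(intron_len[i]))
    }
  }
  list(type = "gene", name = name, kind = kind, strand = strand,
       compartment = compartment, parts = parts)
}

make_spacer <- function(name, length, compartment) {
  list(type = "spacer", name = name, compartment = compartment,
       seq = random_dna(length))
}

element_length <- function(el) {
  if (el$type == "spacer") nchar(el$seq)
  else sum(vapply(el$parts, function(p) nchar(p$seq), numeric(1)))
}

#' Build a synthetic plastome template and its ancestral genome
#'
#' The "reduced" profile instantiates a ~18 kb genome (a faithful but
#' desk-scale quadripartite layout); the "default" profile a ~150 kb
#' genome with compartment sizes in the ranges observed for finished
#' angiosperm plastomes (LSC 80-90 kb, SSC ~12-13 kb, IR 20-31 kb).
#' Both include intron-bearing genes, a duplicated LSC tRNA locus, and an
#' IR-duplicated gene set.
#'
#' @param profile "reduced" or "default".
#' @param seed RNG seed; identical seeds give identical templates.
#' @return list with `model` (the element-list genome model), `template`
#'   (gene table data.frame) and `genome` (instantiated ancestral
#'   "plastome_genome").
#' @export
build_template <- function(profile = c("reduced", "default"), seed = 1) {
  profile <- match.arg(profile)
  set.seed(seed)
  els <- list()
  add <- function(el) els[[length(els) + 1]] <<- el
  rint <- function(lo, hi) sample(seq.int(lo, hi), 1)

  if (profile == "reduced") {
    lsc_genes <- list(
      c("psbA", "CDS", 700), c("matK", "CDS", 500), c("rps16", "CDS", 260),
      c("atpA", "CDS", 520), c("atpF", "CDS", 380), c("rpoB", "CDS", 900),
      c("trnQ-UUG", "tRNA", 72), c("psbD", "CDS", 420),
      c("trnQ-UUG", "tRNA", 72), c("ycf3", "CDS", 480),
      c("ycf4", "CDS", 340), c("petN", "CDS", 90), c("psbM", "CDS", 105),
      c("trnG-UCC", "tRNA", 72), c("clpP", "CDS", 560),
      c("rbcL", "CDS", 700))
    intron_genes <- c("rps16", "atpF", "trnG-UCC")
    two_intron_genes <- c("ycf3", "clpP")
    ir_genes <- list(
      c("rrn16", "rRNA", 600), c("trnV-GAC", "tRNA", 72),
      c("rrn23", "rRNA", 800), c("ndhB", "CDS", 540),
      c("ycf2", "CDS", 700))
    ir_intron <- "ndhB"
    ssc_genes <- list(
      c("ndhF", "CDS", 600), c("rpl32", "CDS", 160),
      c("ndhA", "CDS", 550), c("ycf1", "CDS", 800))
    ssc_intron <- "ndhA"
    spacer_rng <- c(100, 800); intron_rng <- c(150, 320)
    ir_spacer_rng <- c(90, 260); ssc_spacer_rng <- c(100, 800)
    ssc_tail <- 2200; lead <- 120
  } else {
    base <- list(
      c("psbA", "CDS", 1062), c("matK", "CDS", 1530), c("rps16", "CDS", 260),
      c("atpA", "CDS", 1524), c("atpF", "CDS", 555), c("atpH", "CDS", 246),
      c("atpI", "CDS", 744), c("rps2", "CDS", 711), c("rpoC2", "CDS", 4100),
      c("rpoC1", "CDS", 2050), c("rpoB", "CDS", 3212),
      c("trnQ-UUG", "tRNA", 72), c("psbD", "CDS", 1062),
      c("trnQ-UUG", "tRNA", 72), c("psbC", "CDS", 1386),
      c("psbZ", "CDS", 189), c("trnG-UCC", "tRNA", 72),
      c("rps14", "CDS", 303), c("psaB", "CDS", 2205),
      c("psaA", "CDS", 2253), c("ycf3", "CDS", 507),
      c("rps4", "CDS", 606), c("ndhJ", "CDS", 477), c("ndhK", "CDS", 678),
      c("ndhC", "CDS", 363), c("atpE", "CDS", 402), c("atpB", "CDS", 1497),
      c("rbcL", "CDS", 1428), c("accD", "CDS", 1530),
      c("psaI", "CDS", 111), c("ycf4", "CDS", 555), c("cemA", "CDS", 690),
      c("petA", "CDS", 963), c("psbJ", "CDS", 123), c("psbL", "CDS", 117),
      c("psbF", "CDS", 120), c("psbE", "CDS", 252), c("petL", "CDS", 96),
      c("petG", "CDS", 114), c("psaJ", "CDS", 135), c("rpl33", "CDS", 201),
      c("rps18", "CDS", 306), c("rpl20", "CDS", 354),
      c("clpP", "CDS", 591), c("psbB", "CDS", 1527), c("psbT", "CDS", 108),
      c("psbN", "CDS", 132), c("psbH", "CDS", 222), c("petB", "CDS", 648),
      c("petD", "CDS", 483), c("rpoA", "CDS", 1014), c("rps11", "CDS", 417),
      c("rpl36", "CDS", 114), c("rps8", "CDS", 405), c("rpl14", "CDS", 369),
      c("rpl16", "CDS", 408), c("rps3", "CDS", 657), c("rpl22", "CDS", 465),
      c("rps19", "CDS", 279), c("petN", "CDS", 90), c("psbM", "CDS", 105))
    lsc_genes <- base
    intron_genes <- c("rps16", "atpF", "trnG-UCC", "rpl16", "petB", "petD")
    two_intron_genes <- c("ycf3", "clpP")
    ir_genes <- list(
      c("rpl2", "CDS", 1485), c("rpl23", "CDS", 282),
      c("ycf2", "CDS", 6840), c("ndhB", "CDS", 1533),
      c("rps7", "CDS", 468), c("trnV-GAC", "tRNA", 72),
      c("rrn16", "rRNA", 1491), c("trnI-GAU", "tRNA", 72),
      c("trnA-UGC", "tRNA", 72), c("rrn23", "rRNA", 2810),
      c("rrn4.5", "rRNA", 103), c("rrn5", "rRNA", 121),
      c("trnR-ACG", "tRNA", 74), c("trnN-GUU", "tRNA", 72),
      c("ycf1", "CDS", 5400))
    ir_intron <- "ndhB"
    ssc_genes <- list(
      c("ndhF", "CDS", 2241), c("rpl32", "CDS", 174),
      c("ccsA", "CDS", 960), c("ndhD", "CDS", 1503),
      c("psaC", "CDS", 246), c("ndhE", "CDS", 306),
      c("ndhG", "CDS", 531), c("ndhI", "CDS", 504),
      c("ndhA", "CDS", 1092), c("ndhH", "CDS", 1182),
      c("rps15", "CDS", 273))
    ssc_intron <- "ndhA"
    spacer_rng <- c(250, 900); intron_rng <- c(450, 1100)
    ir_spacer_rng <- c(250, 900); ssc_spacer_rng <- c(150, 350)
    ssc_tail <- 800; lead <- 300
  }

  emit_genes <- function(genes, compartment, lead_len, tail_len,
                         sp_rng = spacer_rng) {
    add(make_spacer(paste0(compartment, "_spacer0"), lead_len, compartment))
    for (i in seq_along(genes)) {
      g <- genes[[i]]
      nint <- if (g[1] %in% two_intron_genes) 2
        else if (g[1] %in% c(intron_genes, ir_intron, ssc_intron)) 1 else 0
      strand <- if (compartment == "LSC")
        sample(c("+", "-"), 1, prob = c(0.8, 0.2)) else "+"
      add(make_gene(g[1], g[2], as.numeric(g[3]), strand, compartment,
                    n_introns = nint,
                    intron_len = if (nint) rint(intron_rng[1],
                                                intron_rng[2])[rep(1, nint)]))
      add(make_spacer(paste0(compartment, "_spacer", i),
                      if (i == length(genes)) tail_len
                      else rint(sp_rng[1], sp_rng[2]), compartment))
    }
  }
  emit_genes(lsc_genes, "LSC", lead, lead)
  emit_genes(ir_genes, "IR", lead, lead, sp_rng = ir_spacer_rng)
  emit_genes(ssc_genes, "SSC", lead, ssc_tail, sp_rng = ssc_spacer_rng)

  model <- list(id = "ancestor", elements = els)
  model <- fix_boundaries(model)
  tpl <- do.call(rbind, lapply(els, function(el) data.frame(
    name = if (el$type == "gene") el$name else el$name,
    type = el$type,
    kind = if (el$type == "gene") el$kind else "spacer",
    length = element_length(el),
    strand = if (el$type == "gene") el$strand else "+",
    compartment = el$compartment)))
  list(model = model, template = tpl, genome = instantiate_genome(model))
}

# Pin compartment-boundary bases so the maximal inverted repeat of the
# instantiated sequence equals the planted IR exactly. The repeat pair
# would chance-extend outward iff (last LSC base) == comp(first LSC base)
# and inward iff (first SSC base) == comp(last SSC base); whenever a pair
# violates that, the spacer-side base is repaired.
fix_boundaries <- function(model) {
  comp <- vapply(model$elements, `[[`, character(1), "compartment")
  get_base <- function(i, where) {
    el <- model$elements[[i]]
    s <- if (el$type == "spacer") el$seq else el$parts[[1]]$seq
    if (el$type == "gene" && where == "last")
      s <- el$parts[[length(el$parts)]]$seq
    if (where == "first") substr(s, 1, 1) else substr(s, nchar(s), nchar(s))
  }
  set_base <- function(i, where, v) {
    el <- model$elements[[i]]
    if (el$type != "spacer") return(FALSE)   # never edit coding sequence
    if (where == "first") substr(el$seq, 1, 1) <- v
    else substr(el$seq, nchar(el$seq), nchar(el$seq)) <- v
    model$elements[[i]] <<- el
    TRUE
  }
  repair <- function(i1, w1, i2, w2) {
    b1 <- get_base(i1, w1); b2 <- get_base(i2, w2)
    if (b1 != complement_seq(b2)) return(invisible(NULL))
    for (v in c("A", "C", "G", "T")) {
      if (v != complement_seq(b2) && set_base(i1, w1, v)) return(invisible(NULL))
    }
    for (v in c("A", "C", "G", "T")) {
      if (b1 != complement_seq(v) && set_base(i2, w2, v)) return(invisible(NULL))
    }
    invisible(NULL)
  }
  lsc <- which(comp == "LSC"); ssc <- which(comp == "SSC")
  repair(max(lsc), "last", lsc[1], "first")    # outward extension guard
  repair(ssc[1], "first", max(ssc), "last")    # inward extension guard
  model
}

#' Instantiate a genome model as an annotated plastome
#'
#' Lays out LSC, IRa, SSC and the mirrored IRb copy, and computes feature
#' coordinates (exon segments for intron-bearing genes). IRa is exactly
#' the reverse complement of IRb by construction.
#'
#' @param model a genome model (see [build_template()]).
#' @param id genome id for the result.
#' @return a "plastome_genome".
#' @export
instantiate_genome <- function(model, id = model$id) {
  comp <- vapply(model$elements, `[[`, character(1), "compartment")
  lsc <- model$elements[comp == "LSC"]
  ir <- model$elements[comp == "IR"]
  ssc <- model$elements[comp == "SSC"]
  stopifnot(length(lsc) > 0, length(ir) > 0, length(ssc) > 0)

  mirror <- function(el) {
    el$compartment <- "IRB"
    if (el$type == "spacer") {
      el$seq <- revcomp(el$seq)
    } else {
      el$strand <- if (el$strand == "+") "-" else "+"
      el$parts <- lapply(rev(el$parts), function(p) {
        p$seq <- revcomp(p$seq); p
      })
    }
    el
  }
  irb <- lapply(rev(ir), mirror)
  ordered <- c(lsc, ir, ssc, irb)

  pos <- 0
  seq_parts <- character(0)
  features <- list()
  for (el in ordered) {
    if (el$type == "spacer") {
      seq_parts <- c(seq_parts, el$seq)
      pos <- pos + nchar(el$seq)
      next
    }
    segs <- list()
    for (p in el$parts) {
      w <- nchar(p$seq)
      if (p$label == "exon")
        segs[[length(segs) + 1]] <- c(start = pos, end = pos + w)
      seq_parts <- c(seq_parts, p$seq)
      pos <- pos + w
    }
    sdf <- as.data.frame(do.call(rbind, segs))
    sdf$strand <- el$strand
    if (el$strand == "-") sdf <- sdf[rev(seq_len(nrow(sdf))), , drop = FALSE]
    rownames(sdf) <- NULL
    features[[length(features) + 1]] <-
      new_feature(el$name, el$kind, sdf)
  }
  new_genome(id, paste(seq_parts, collapse = ""), features)
}

# true compartment lengths of a model (lsc, ir, ssc)
model_layout <- function(model) {
  comp <- vapply(model$elements, `[[`, character(1), "compartment")
  lens <- vapply(model$elements, element_length, numeric(1))
  c(lsc = sum(lens[comp == "LSC"]), ir = sum(lens[comp == "IR"]),
    ssc = sum(lens[comp == "SSC"]))
}

#' Shift the IR/SSC boundaries of a genome model
#'
#' Symmetric expansion consumes `amount` bp from the head of the SSC into
#' the IR (duplicating it into both copies; a gene split by the new
#' boundary yields truncated pseudogene copies) while the mirror copy
#' overwrites an equal amount of spacer at the SSC tail, so the SSC
#' shrinks by 2*amount, each IR grows by `amount`, total length is
#' unchanged and the two IR copies remain exact mirrors. Contraction is
#' the inverse (IR-tail content is released into both SSC ends; the copy
#' released at the tail is flagged pseudogene).
#'
#' @param model a genome model.
#' @param direction "expand_into_ssc" or "contract".
#' @param amount shift in bp; must be smaller than half the current SSC
#'   (expansion) or the current IR (contraction).
#' @return list(model, events): the updated model and a data.frame logging
#'   pseudogenization/loss side effects.
#' @export
apply_ir_shift <- function(model, direction = c("expand_into_ssc",
                                                "contract"), amount) {
  direction <- match.arg(direction)
  if (amount == 0) return(list(model = model, events = NULL))
  lay <- model_layout(model)
  side_events <- list()
  log_ev <- function(kind, what) side_events[[length(side_events) + 1]] <<-
    data.frame(kind = kind, detail = what)

  comp <- vapply(model$elements, `[[`, character(1), "compartment")
  if (direction == "expand_into_ssc") {
    if (2 * amount >= lay["ssc"])
      stop("bounds error: ir shift of ", amount, " bp exhausts the SSC (",
           lay["ssc"], " bp)")
    ssc_idx <- which(comp == "SSC")
    # --- head side: move `amount` bp into the IR ---
    moved <- list(); acc <- 0; i <- 1
    while (acc < amount) {
      el <- model$elements[[ssc_idx[i]]]
      w <- element_length(el)
      if (acc + w <= amount) {
        el$compartment <- "IR"
        moved[[length(moved) + 1]] <- el
        model$elements[[ssc_idx[i]]] <- NA   # mark for removal
        acc <- acc + w
        i <- i + 1
      } else {
        take <- amount - acc
        if (el$type == "spacer") {
          head <- el; head$seq <- substr(el$seq, 1, take)
          head$compartment <- "IR"
          moved[[length(moved) + 1]] <- head
          el$seq <- substr(el$seq, take + 1, nchar(el$seq))
          model$elements[[ssc_idx[i]]] <- el
        } else {
          # gene split at the new boundary: truncated IR copy and the
          # remaining SSC stub both become pseudogenes
          full <- paste(vapply(el$parts, `[[`, character(1), "seq"),
                        collapse = "")
          irc <- el
          irc$kind <- "pseudogene"; irc$compartment <- "IR"
          irc$parts <- list(list(label = "exon",
                                 seq = substr(full, 1, take)))
          moved[[length(moved) + 1]] <- irc
          el$kind <- "pseudogene"
          el$parts <- list(list(label = "exon",
                                seq = substr(full, take + 1, nchar(full))))
          model$elements[[ssc_idx[i]]] <- el
          log_ev("pseudogenization", el$name)
        }
        acc <- amount
      }
    }
    # --- tail side: overwrite `amount` bp of spacer with the mirror copy ---
    acc <- 0; j <- length(ssc_idx)
    while (acc < amount) {
      el <- model$elements[[ssc_idx[j]]]
      if (!is.list(el) || el$type != "spacer")
        stop("generation error: ir expansion tail overwrite would cross a ",
             "gene; structural changes are restricted to non-coding regions")
      w <- nchar(el$seq)
      if (acc + w <= amount) {
        model$elements[[ssc_idx[j]]] <- NA
        acc <- acc + w; j <- j - 1
      } else {
        el$seq <- substr(el$seq, 1, w - (amount - acc))
        model$elements[[ssc_idx[j]]] <- el
        acc <- amount
      }
    }
    model$elements <- Filter(is.list, model$elements)
    # splice the moved elements onto the IR tail (the SSC-facing end)
    comp2 <- vapply(model$elements, `[[`, character(1), "compartment")
    last_ir <- max(which(comp2 == "IR"))
    model$elements <- append(model$elements, moved, after = last_ir)
  } else {
    if (amount >= lay["ir"])
      stop("bounds error: contraction of ", amount,
           " bp exhausts the IR (", lay["ir"], " bp)")
    ir_idx <- which(comp == "IR")
    released <- list(); acc <- 0; j <- length(ir_idx)
    while (acc < amount) {
      el <- model$elements[[ir_idx[j]]]
      w <- element_length(el)
      if (acc + w <= amount) {
        model$elements[ir_idx[j]] <- list(NULL)
        released <- c(list(el), released)
        acc <- acc + w; j <- j - 1
      } else {
        if (el$type != "spacer")
          stop("generation error: ir contraction boundary inside a gene")
        take <- amount - acc
        rel <- el; rel$seq <- substr(el$seq, nchar(el$seq) - take + 1,
                                     nchar(el$seq))
        released <- c(list(rel), released)
        el$seq <- substr(el$seq, 1, nchar(el$seq) - take)
        model$elements[[ir_idx[j]]] <- el
        acc <- amount
      }
    }
    model$elements <- Filter(is.list, model$elements)
    head_copy <- lapply(released, function(el) {
      el$compartment <- "SSC"; el
    })
    tail_copy <- lapply(rev(released), function(el) {
      el$compartment <- "SSC"
      if (el$type == "spacer") el$seq <- revcomp(el$seq)
      else {
        el$strand <- if (el$strand == "+") "-" else "+"
        el$kind <- "pseudogene"
        el$parts <- lapply(rev(el$parts), function(p) {
          p$seq <- revcomp(p$seq); p
        })
        log_ev("pseudogenization", el$name)
      }
      el
    })
    comp2 <- vapply(model$elements, `[[`, character(1), "compartment")
    ssc_first <- which(comp2 == "SSC")[1]
    ssc_last <- max(which(comp2 == "SSC"))
    model$elements <- c(model$elements[seq_len(ssc_first - 1)],
                        head_copy,
                        model$elements[seq.int(ssc_first, ssc_last)],
                        tail_copy,
                        if (ssc_last < length(model$elements))
                          model$elements[seq.int(ssc_last + 1,
                                                 length(model$elements))])
  }
  model <- fix_boundaries(model)
  events <- if (length(side_events)) do.call(rbind, side_events) else NULL
  list(model = model, events = events)
}

#' Invert a contiguous run of loci in a genome model
#'
#' The run from `from_gene` to `to_gene` (inclusive, with any elements
#' between them) is reverse complemented in place; both endpoints must be
#' flanked by spacers, so the inversion endpoints fall in non-coding
#' sequence.
#'
#' @param model a genome model.
#' @param from_gene,to_gene locus names bounding the inverted block.
#' @return the updated model.
#' @export
apply_inversion <- function(model, from_gene, to_gene) {
  nm <- vapply(model$elements, `[[`, character(1), "name")
  i <- which(nm == from_gene)[1]; j <- which(nm == to_gene)
  j <- j[length(j)]
  if (is.na(i) || !length(j) || j < i)
    stop("apply_inversion: locus range not found: ", from_gene, "..", to_gene)
  comp <- vapply(model$elements, `[[`, character(1), "compartment")
  if (length(unique(comp[i:j])) != 1)
    stop("apply_inversion: block crosses a compartment boundary")
  flank_ok <- (i == 1 || model$elements[[i - 1]]$type == "spacer") &&
    (j == length(model$elements) || model$elements[[j + 1]]$type == "spacer")
  if (!flank_ok)
    stop("generation error: inversion endpoints not in spacers")
  block <- lapply(rev(model$elements[i:j]), function(el) {
    if (el$type == "spacer") {
      el$seq <- revcomp(el$seq)
    } else {
      el$strand <- if (el$strand == "+") "-" else "+"
      el$parts <- lapply(rev(el$parts), function(p) {
        p$seq <- revcomp(p$seq); p
      })
    }
    el
  })
  model$elements[i:j] <- block
  model
}

#' Delete a gene from a genome model (feature and sequence)
#' @param model a genome model.
#' @param gene locus name.
#' @return the updated model.
#' @export
apply_gene_loss <- function(model, gene) {
  nm <- vapply(model$elements, `[[`, character(1), "name")
  typ <- vapply(model$elements, `[[`, character(1), "type")
  i <- which(nm == gene & typ == "gene")
  if (!length(i)) stop("apply_gene_loss: gene not found: ", gene)
  model$elements <- model$elements[-i[1]]
  model
}

#' Flag a gene as a pseudogene in a genome model
#' @param model a genome model.
#' @param gene locus name.
#' @return the updated model.
#' @export
apply_pseudogenization <- function(model, gene) {
  nm <- vapply(model$elements, `[[`, character(1), "name")
  typ <- vapply(model$elements, `[[`, character(1), "type")
  i <- which(nm == gene & typ == "gene")
  if (!length(i)) stop("apply_pseudogenization: gene not found: ", gene)
  model$elements[[i[1]]]$kind <- "pseudogene"
  model
}

#' Apply JC69/K80 substitutions to a DNA string
#'
#' The expected proportion of differing sites after branch length t is the
#' JC69 closed form p = 3/4 (1 - exp(-4 t / 3)).
#'
#' @param seq DNA string.
#' @param t branch length in expected substitutions/site.
#' @param model "JC69" or "K80".
#' @param kappa transition/transversion rate ratio (K80).
#' @param protect integer positions (1-based) never mutated.
#' @return mutated DNA string.
#' @export
mutate_sequence <- function(seq, t, model = "JC69", kappa = 2,
                            protect = integer(0)) {
  n <- nchar(seq)
  if (n == 0 || t <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  k <- stats::rbinom(1, n, p)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  pos <- setdiff(pos, protect)
  if (!length(pos)) return(seq)
  v <- strsplit(seq, "")[[1]]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in pos) {
    old <- v[i]
    if (!old %in% c("A", "C", "G", "T")) next
    others <- setdiff(c("A", "C", "G", "T"), old)
    wts <- if (model == "K80")
      ifelse(others == transition[[old]], kappa, 1) else rep(1, 3)
    v[i] <- sample(others, 1, prob = wts)
  }
  paste(v, collapse = "")
}

# indels within a spacer sequence: Poisson count, geometric(p) lengths
apply_indels <- function(seq, t, rate, geom_p = 0.3, max_len = 20) {
  n <- nchar(seq)
  if (n < 10 || rate <= 0 || t <= 0) return(seq)
  k <- stats::rpois(1, rate * t * n)
  for (z in seq_len(k)) {
    n <- nchar(seq)
    if (n < 10) break
    len <- min(stats::rgeom(1, geom_p) + 1, max_len, n - 5)
    pos <- sample.int(n - len, 1) + 1
    if (stats::runif(1) < 0.5) {
      seq <- paste0(substr(seq, 1, pos - 1), substr(seq, pos + len, n))
    } else {
      seq <- paste0(substr(seq, 1, pos - 1), random_dna(len),
                    substr(seq, pos, n))
    }
  }
  seq
}

# per-branch mutation of a whole model; coding parts at rate t, introns/
# spacers/pseudogenes at spacer_mult * t; indels spacer-only by default
mutate_model <- function(model, t, params) {
  mult <- params$spacer_mult %||% 1.5
  sub_model <- params$model %||% "JC69"
  kappa <- params$kappa %||% 2
  indel_rate <- params$indel_rate %||% 0
  model$elements <- lapply(model$elements, function(el) {
    if (el$type == "spacer") {
      el$seq <- mutate_sequence(el$seq, t * mult, sub_model, kappa)
      el$seq <- apply_indels(el$seq, t, indel_rate)
    } else {
      el$parts <- lapply(el$parts, function(p) {
        m <- if (p$label == "exon" && el$kind != "pseudogene") 1 else mult
        p$seq <- mutate_sequence(p$seq, t * m, sub_model, kappa)
        p
      })
    }
    el
  })
  fix_boundaries(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evolve a genome model along a tree with structural events
#'
#' Pre-order traversal from the root: on each branch the structural events
#' assigned to that branch are applied first, then substitutions (and
#' spacer indels). Tip genomes carry every event on their root-to-tip
#' path. Events reference branches by the child node: a tip label, or an
#' internal node number as in the "phylo" edge matrix.
#'
#' @param model ancestral genome model (see [build_template()]).
#' @param tree rooted "phylo" with branch lengths in expected
#'   substitutions/site.
#' @param params list: spacer_mult (default 1.5), model ("JC69"/"K80"),
#'   kappa, indel_rate (per site per unit branch length, default 0),
#'   seed.
#' @param events list of event lists: list(branch =, kind =, ...) with
#'   kind in "inversion" (from_gene, to_gene), "ir_expansion" /
#'   "ir_contraction" (amount), "gene_loss" (gene), "pseudogenization"
#'   (gene).
#' @return list: `genomes` (named list of tip "plastome_genome"),
#'   `models` (tip genome models), `tree`, `event_log` (data.frame),
#'   `tip_events` (events per tip), `layouts` (true compartment lengths
#'   per tip).
#' @export
evolve_along_tree <- function(model, tree, params = list(), events = list()) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree))
  if (!is.null(params$seed)) set.seed(params$seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  eo <- ape::reorder.phylo(tree, "cladewise")
  node_of <- function(branch) {
    if (is.character(branch)) {
      i <- match(branch, tree$tip.label)
      if (is.na(i)) stop("event references unknown branch: ", branch)
      i
    } else as.integer(branch)
  }
  ev_child <- vapply(events, function(e) node_of(e$branch), integer(1))
  if (length(ev_child) && any(!(ev_child %in% eo$edge[, 2])))
    stop("event references a node absent from the tree")

  models <- vector("list", ntip + ape::Nnode(tree))
  models[[root]] <- model
  logs <- list()
  node_events <- vector("list", length(models))
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    m <- models[[p]]
    node_events[ch] <- list(node_events[[p]])
    for (ei in which(ev_child == ch)) {
      e <- events[[ei]]
      m <- switch(e$kind,
        inversion = apply_inversion(m, e$from_gene, e$to_gene),
        ir_expansion = {
          r <- apply_ir_shift(m, "expand_into_ssc", e$amount)
          if (!is.null(r$events)) for (z in seq_len(nrow(r$events)))
            logs[[length(logs) + 1]] <- data.frame(
              branch = ch, kind = r$events$kind[z],
              detail = r$events$detail[z])
          r$model
        },
        ir_contraction = apply_ir_shift(m, "contract", e$amount)$model,
        gene_loss = apply_gene_loss(m, e$gene),
        pseudogenization = apply_pseudogenization(m, e$gene),
        stop("unknown event kind: ", e$kind))
      logs[[length(logs) + 1]] <- data.frame(
        branch = ch, kind = e$kind,
        detail = paste(unlist(e[setdiff(names(e), c("branch", "kind"))]),
                       collapse = ","))
      node_events[[ch]] <- c(node_events[[ch]], list(e))
    }
    m <- mutate_model(m, eo$edge.length[k], params)
    models[[ch]] <- m
  }
  tips <- seq_len(ntip)
  genomes <- lapply(tips, function(i) {
    g <- instantiate_genome(models[[i]], id = tree$tip.label[i])
    if (!isTRUE(params$ir_lockstep %||% TRUE)) {
      lay <- model_layout(models[[i]])
      n <- g$length
      irb <- circ_slice(g$sequence, n - lay["ir"], n)
      irb2 <- mutate_sequence(irb, sum_root_to_tip(tree, i), params$model
                              %||% "JC69", params$kappa %||% 2)
      g$sequence <- paste0(substr(g$sequence, 1, n - lay["ir"]), irb2)
    }
    g
  })
  names(genomes) <- tree$tip.label
  layouts <- lapply(tips, function(i) model_layout(models[[i]]))
  names(layouts) <- tree$tip.label
  tip_events <- stats::setNames(node_events[tips], tree$tip.label)
  event_log <- if (length(logs)) do.call(rbind, logs)
  else data.frame(branch = integer(0), kind = character(0),
                  detail = character(0))
  list(genomes = genomes, models = stats::setNames(models[tips],
                                                   tree$tip.label),
       tree = tree, event_log = event_log, tip_events = tip_events,
       layouts = layouts)
}

sum_root_to_tip <- function(tree, tip) {
  d <- ape::node.depth.edgelength(tree)
  d[tip]
}

#' Replay structural events on an ancestral model (no mutation)
#'
#' Used as the permutation-replay oracle: the gene order of the replayed
#' model must equal the gene order of the evolved tip.
#'
#' @param model ancestral genome model.
#' @param events list of event lists (a tip's root-to-tip events).
#' @return the replayed genome model.
#' @export
replay_events <- function(model, events) {
  for (e in events) {
    model <- switch(e$kind,
      inversion = apply_inversion(model, e$from_gene, e$to_gene),
      ir_expansion = apply_ir_shift(model, "expand_into_ssc", e$amount)$model,
      ir_contraction = apply_ir_shift(model, "contract", e$amount)$model,
      gene_loss = apply_gene_loss(model, e$gene),
      pseudogenization = apply_pseudogenization(model, e$gene),
      stop("unknown event kind: ", e$kind))
  }
  model
}

#' Simulate a complete study-like plastome set
#'
#' Builds a template, a rooted tree (an ingroup clade of `n_ingroup` taxa
#' plus `n_outgroup` successively more distant outgroups) and evolves the
#' template along it, optionally planting the study-like structural
#' scenario: an IR expansion on the ingroup stem plus LSC/IR inversions,
#' one gene loss and one pseudogenization on ingroup branches.
#'
#' @param n_ingroup,n_outgroup taxon counts (defaults 10 and 3).
#' @param profile template profile ("reduced"/"default").
#' @param seed RNG seed driving template, tree and evolution.
#' @param scenario "study" (plant the structural events), "none", or a
#'   custom event list.
#' @param ingroup_depth,outgroup_depth branch-length scales
#'   (substitutions/site).
#' @param params extra evolution parameters (see [evolve_along_tree()]).
#' @return the [evolve_along_tree()] result, plus `ancestor` (model),
#'   `template`, `ingroup`, `outgroup`.
#' @export
simulate_plastome_set <- function(n_ingroup = 10, n_outgroup = 3,
                                  profile = "reduced", seed = 1,
                                  scenario = "study",
                                  ingroup_depth = 0.02,
                                  outgroup_depth = 0.05,
                                  params = list()) {
  set.seed(seed)
  tpl <- build_template(profile, seed = seed)
  ing <- ape::rtree(n_ingroup, rooted = TRUE)
  ing$tip.label <- sprintf("sp%02d", seq_len(n_ingroup))
  ing$edge.length <- ing$edge.length * ingroup_depth
  ing_nwk <- sub(";$", "", ape::write.tree(ing))
  cur <- sprintf("%s:%.4f", ing_nwk, ingroup_depth)
  for (i in seq_len(n_outgroup)) {
    og_len <- outgroup_depth * (1 + 0.3 * i)
    cur <- sprintf("(%s,OG%d:%.4f):%.4f", cur, i, og_len, 0.01)
  }
  tree <- ape::read.tree(text = paste0(cur, ";"))

  events <- if (identical(scenario, "study")) {
    stem <- ape::getMRCA(tree, ing$tip.label)
    half <- ing$tip.label[seq_len(ceiling(n_ingroup / 2))]
    cl <- ape::getMRCA(tree, half[1:2])
    list(
      list(branch = stem, kind = "ir_expansion", amount = 400),
      list(branch = stem, kind = "inversion",
           from_gene = "atpA", to_gene = "rpoB"),
      list(branch = cl, kind = "inversion",
           from_gene = "petN", to_gene = "psbM"),
      list(branch = cl, kind = "inversion",
           from_gene = "rrn23", to_gene = "ndhB"),
      list(branch = ing$tip.label[1], kind = "inversion",
           from_gene = "trnV-GAC", to_gene = "trnV-GAC"),
      list(branch = ing$tip.label[2], kind = "gene_loss", gene = "ycf4"),
      list(branch = ing$tip.label[3], kind = "pseudogenization",
           gene = "rps16"))
  } else if (identical(scenario, "none")) list() else scenario
  res <- evolve_along_tree(tpl$model, tree, params = params, events = events)
  res$ancestor <- tpl$model
  res$template <- tpl$template
  res$ingroup <- ing$tip.label
  res$outgroup <- sprintf("OG%d", seq_len(n_outgroup))
  res
}

#' Write a simulation to disk (GenBank per tip, newick tree, event TSV)
#'
#' @param sim result of [simulate_plastome_set()] / [evolve_along_tree()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$genomes))
    write_genbank(sim$genomes[[id]], file.path(dir, paste0(id, ".gb")))
  ape::write.tree(sim$tree, file.path(dir, "true_tree.nwk"))
  utils::write.table(sim$event_log, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Simulate ungapped sequences along a tree (substitutions only)
#'
#' Evolves a single sequence down a rooted tree under JC69/K80 with no
#' indels, returning one sequence per tip - already aligned by
#' construction. Used for substitution-model calibration checks and
#' topology-recovery statistics.
#'
#' @param seq ancestral DNA string.
#' @param tree rooted "phylo" with branch lengths.
#' @param model "JC69" or "K80"; @param kappa K80 ratio.
#' @return named character vector of tip sequences.
#' @export
sim_seqs_on_tree <- function(seq, tree, model = "JC69", kappa = 2) {
  stopifnot(ape::is.rooted(tree))
  ntip <- length(tree$tip.label)
  eo <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", ntip + ape::Nnode(tree))
  seqs[[ntip + 1L]] <- seq
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    seqs[[ch]] <- mutate_sequence(seqs[[p]], eo$edge.length[k], model, kappa)
  }
  stats::setNames(unlist(seqs[seq_len(ntip)]), tree$tip.label)
}
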