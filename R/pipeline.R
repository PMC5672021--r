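# End-to-end orchestration: structure -> rearrangement -> partitioning ->
# alignment/filtering -> schemes -> trees -> Kendall-Colijn -> ranking,
# from one flat configuration, with deterministic outputs under a fixed
# seed. Intermediate artifacts are always written; warnings are collected
# into the report, never swallowed.

#' Default pipeline configuration
#'
#' Every threshold defaults to the value used throughout the package: a
#' 50 bp region floor, 0.65 similarity for homology grouping, a
#' 500-1100 bp marker amplicon window, and the conserved-block and
#' outlier-removal defaults.
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    input_dir = NULL,          # GenBank directory (or NULL to simulate)
    simulate_profile = "reduced",
    simulate_taxa = 10,
    simulate_outgroups = 3,
    scenario = "study",
    reference_id = NULL,       # defaults to first ingroup genome
    outgroup_taxa = NULL,
    min_region_len = 50,
    similarity_threshold = 0.65,
    marker_min_len = 500,
    marker_max_len = 1100,
    ir_min_len = 1000,
    bootstrap_reps = 50,
    seed = 1,
    out_dir = NULL)
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  cfg
}

#' Run the full plastome comparison pipeline
#'
#' Executes every stage on a set of annotated genomes (read from GenBank
#' files or simulated in place), producing the structure table, the
#' rearrangement matrix, the five partition schemes with their trees, and
#' the standardized marker ranking. Fails fast on structural errors
#' (missing reference, non-monophyletic ingroup); per-region problems are
#' logged and skipped. Deterministic given `seed`.
#'
#' @param config a configuration list (see [default_config()]) or the
#'   path to a flat YAML file of the same keys.
#' @return a "pipeline_report" list: structure_table, rearrangements,
#'   schemes, scheme_trees, best_tree, marker_scores, candidate report,
#'   warnings, and the echoed config.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_config(config)
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  # ---- inputs -------------------------------------------------------
  if (!is.null(cfg$input_dir)) {
    files <- sort(list.files(cfg$input_dir, pattern = "\\.gb$",
                             full.names = TRUE))
    if (length(files) < 4)
      stop("pipeline: need >= 4 genomes (3 outgroup + >= 1 ingroup)")
    genomes <- lapply(files, read_genbank)
    names(genomes) <- vapply(genomes, `[[`, character(1), "id")
    if (is.null(cfg$outgroup_taxa))
      stop("pipeline: outgroup_taxa must be set for GenBank input")
    true_tree <- NULL
  } else {
    sim <- simulate_plastome_set(
      n_ingroup = cfg$simulate_taxa, n_outgroup = cfg$simulate_outgroups,
      profile = cfg$simulate_profile, seed = cfg$seed,
      scenario = cfg$scenario)
    genomes <- sim$genomes
    cfg$outgroup_taxa <- cfg$outgroup_taxa %||% sim$outgroup
    true_tree <- sim$tree
  }
  ingroup <- setdiff(names(genomes), cfg$outgroup_taxa)
  if (is.null(cfg$reference_id)) cfg$reference_id <- sort(ingroup)[1]
  if (!cfg$reference_id %in% names(genomes))
    stop("pipeline: reference genome '", cfg$reference_id,
         "' not among inputs")

  # ---- structure ----------------------------------------------------
  layouts <- lapply(genomes, function(g)
    find_inverted_repeats(g, min_len = cfg$ir_min_len))
  structure_table <- cross_species_structure_table(
    genomes, min_len = cfg$ir_min_len)

  # ---- rearrangement ------------------------------------------------
  orders <- lapply(layouts, function(l) gene_order(layout = l))
  rearrangements <- rearrangement_matrix(orders, cfg$reference_id)
  bp_pool <- do.call(rbind, lapply(
    setdiff(names(orders), cfg$reference_id), function(id)
      breakpoint_regions(orders[[id]], orders[[cfg$reference_id]])))

  # ---- partitioning -------------------------------------------------
  regions <- unlist(lapply(layouts, function(l)
    fragment_genome(layout = l, min_len = cfg$min_region_len)),
    recursive = FALSE)
  grouping <- group_by_similarity(regions, cfg$reference_id,
                                  threshold = cfg$similarity_threshold)
  if (nrow(grouping$unassigned))
    note("%d region(s) unassigned at similarity threshold %.2f",
         nrow(grouping$unassigned), cfg$similarity_threshold)
  full <- Filter(function(g) length(g$members) >= 3, grouping$groups)
  coding_groups <- Filter(function(g) g$role == "coding", full)
  noncod_groups <- Filter(function(g) g$role == "noncoding", full)
  if (!length(coding_groups) || !length(noncod_groups))
    stop("pipeline: empty coding or non-coding partition")

  # ---- alignment ----------------------------------------------------
  member_seqs <- function(g) vapply(g$members, `[[`, character(1), "seq")
  coding_alns <- lapply(coding_groups, function(g)
    multiple_align(member_seqs(g), mode = "coding"))
  noncod_base <- lapply(noncod_groups, function(g)
    multiple_align(member_seqs(g), mode = "noncoding"))
  ned <- lapply(seq_along(noncod_groups), function(i)
    align_region(member_seqs(noncod_groups[[i]]), pathway = "edited",
                 mode = "noncoding", aln = noncod_base[[i]]))
  names(ned) <- names(noncod_groups)
  nfl <- lapply(seq_along(noncod_groups), function(i)
    align_region(member_seqs(noncod_groups[[i]]), pathway = "filtered",
                 mode = "noncoding", aln = noncod_base[[i]]))
  names(nfl) <- names(noncod_groups)
  nfl <- Filter(function(a) length(a) >= 2 && nchar(a[[1]]) > 0, nfl)
  ned <- Filter(function(a) length(a) >= 2, ned)

  # ---- schemes and trees --------------------------------------------
  schemes <- build_schemes(coding_alns, ned, nfl)
  concats <- list(
    coding = concatenate_alignments(coding_alns),
    noncoding_edited = concatenate_alignments(ned),
    noncoding_filtered = concatenate_alignments(nfl),
    `coding+noncoding_edited` = concatenate_alignments(c(coding_alns, ned)),
    `coding+noncoding_filtered` = concatenate_alignments(c(coding_alns, nfl)))
  scheme_trees <- lapply(seq_along(concats), function(i)
    bootstrap_support(concats[[i]], n_reps = cfg$bootstrap_reps,
                      seed = cfg$seed + i))
  names(scheme_trees) <- names(concats)
  best_tree <- root_and_prune(scheme_trees[["coding+noncoding_edited"]],
                              intersect(cfg$outgroup_taxa,
                                        scheme_trees[[4]]$tip.label))

  # ---- marker ranking -----------------------------------------------
  cand <- select_marker_candidates(
    noncod_groups, breakpoints = bp_pool, reference_id = cfg$reference_id,
    min_len = cfg$marker_min_len, max_len = cfg$marker_max_len)
  marker_scores <- NULL
  if (length(cand$kept) >= 2) {
    cand_alns <- ned[intersect(cand$kept, names(ned))]
    cand_alns <- lapply(cand_alns, function(a) {
      keep <- intersect(names(a), best_tree$tip.label)
      a[keep]
    })
    cand_alns <- Filter(function(a) length(a) >= 3, cand_alns)
    cand_trees <- lapply(cand_alns, function(a)
      tryCatch(neighbor_joining(jc69_distances(a)),
               error = function(e) NULL))
    ok <- !vapply(cand_trees, is.null, logical(1))
    cand_alns <- cand_alns[ok]; cand_trees <- cand_trees[ok]
    # all metrics on the shared ingroup tip set
    common <- Reduce(intersect, c(lapply(cand_trees, `[[`, "tip.label"),
                                  list(best_tree$tip.label)))
    if (length(common) >= 4 && length(cand_trees) >= 2) {
      ref_pruned <- ape::keep.tip(best_tree, common)
      cand_trees <- lapply(cand_trees, function(tr) {
        tr <- ape::keep.tip(tr, common)
        ape::root(tr, outgroup = common[1], resolve.root = TRUE)
      })
      ref_rooted <- ape::root(ape::unroot(ref_pruned),
                              outgroup = common[1], resolve.root = TRUE)
      cand_alns <- lapply(cand_alns, function(a) a[common])
      marker_scores <- rank_markers(cand_alns, cand_trees, ref_rooted)
    } else note("marker ranking skipped: too few comparable regions")
  } else note("marker ranking skipped: fewer than 2 candidate regions")

  report <- structure(list(
    config = cfg, structure_table = structure_table,
    rearrangements = rearrangements, schemes = schemes,
    scheme_trees = scheme_trees, best_tree = best_tree,
    marker_candidates = cand, marker_scores = marker_scores,
    unassigned_regions = grouping$unassigned, true_tree = true_tree,
    warnings = warnings_log), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, dir) {
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(report$structure_table, "structure.tsv")
  wt(report$rearrangements, "rearrangements.tsv")
  wt(report$schemes, "schemes.tsv")
  if (!is.null(report$marker_scores)) wt(report$marker_scores, "markers.tsv")
  if (nrow(report$unassigned_regions))
    wt(report$unassigned_regions, "unassigned_regions.tsv")
  for (nm in names(report$scheme_trees))
    ape::write.tree(report$scheme_trees[[nm]],
                    file.path(dir, paste0("tree_", gsub("[+]", "_", nm),
                                          ".nwk")))
  ape::write.tree(report$best_tree, file.path(dir, "best_tree_ingroup.nwk"))
  cfg <- report$config
  yaml::write_yaml(cfg[order(names(cfg))], file.path(dir, "config_echo.yaml"))
  writeLines(report$warnings, file.path(dir, "warnings.log"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("plastome pipeline report\n")
  cat(sprintf("  genomes: %d (%d ingroup)\n", nrow(x$structure_table),
              nrow(x$structure_table) - length(x$config$outgroup_taxa)))
  cat(sprintf("  schemes: %d | inversions detected: %d | warnings: %d\n",
              nrow(x$schemes), sum(x$rearrangements$n_inversions),
              length(x$warnings)))
  if (!is.null(x$marker_scores))
    cat(sprintf("  top marker: %s (composite %.3f)\n",
                x$marker_scores$region[1], x$marker_scores$composite[1]))
  invisible(x)
}
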