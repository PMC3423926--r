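#' Configuration for the full analysis pipeline
#'
#' Consolidates the workflow defaults: taxonomic groups are clustered only
#' when they hold more than `min_otus` OTUs, cluster reliability uses
#' `n_boot` feature-bootstrap replicates, diversity is compared at
#' `rarefaction_depth` reads, and enrichment uses unadjusted p below
#' `alpha`.
#'
#' @param input path to an OTU report TSV, or `NULL` to simulate.
#' @param metadata path to a sample metadata TSV (required with `input`).
#' @param simulation a [community_spec()] used when `input` is `NULL`.
#' @param taxon_subsets named character vector `rank = name` pairs to
#'   analyze separately (e.g. `c(class = "Class_003")`); `NULL` picks the
#'   `n_auto_subsets` classes richest in OTUs.
#' @param n_auto_subsets how many classes to auto-select.
#' @param min_otus cluster a taxon only when it has more than this many
#'   OTUs.
#' @param n_boot bootstrap replicates for cluster support.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param rarefaction_depth depth for the diversity comparison.
#' @param alpha significance level for responder calls.
#' @param alignment optional aligned FASTA of representative sequences for
#'   the responder tree stage.
#' @param compress_threshold branch-compression threshold for that tree.
#' @param seed integer seed (drives simulation and all resampling).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, metadata = NULL,
                            simulation = community_spec(),
                            taxon_subsets = NULL, n_auto_subsets = 3,
                            min_otus = 50, n_boot = 500, n_perm = 999,
                            rarefaction_depth = 400, alpha = 0.05,
                            alignment = NULL, compress_threshold = 0.03,
                            seed = 1, out_dir = NULL) {
  stopifnot(min_otus > 0, n_boot > 0, n_perm > 0, rarefaction_depth > 0,
            alpha > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full community-response workflow
#'
#' Stages, in order: (1) Pearson similarity, UPGMA with bootstrap support,
#' per-soil percent dissimilarity d and its permutation test, for the total
#' community and each taxon subset with more than `min_otus` OTUs; (2)
#' rarefaction curves per sample; (3) per-soil diversity reduction at the
#' configured depth; (4) taxonomy sweep with enriched and diminished
#' responder reports; (5) optionally, the responder tree with bootstrap and
#' branch compression. All artifacts plus a run log (seed, versions) are
#' written to `out_dir` when set.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_report` list with one element per stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$input)) {
    sim <- simulate_community(cfg$simulation, cfg$seed)
    otu <- sim$otu; groups <- sim$groups
  } else {
    if (is.null(cfg$metadata)) stop("stage input: metadata required", call. = FALSE)
    otu <- read_otu_report(cfg$input)
    groups <- read_sample_metadata(cfg$metadata)
    sim <- NULL
  }
  glab <- group_labels(groups, otu$sample_ids)
  soils <- unique(groups$soil[match(otu$sample_ids, groups$sample_id)])

  subsets <- cfg$taxon_subsets
  if (is.null(subsets)) {
    cls <- table(otu$lineage$class)
    cls <- cls[names(cls) != UNCLASSIFIED]
    cls <- sort(cls, decreasing = TRUE)
    pick <- utils::head(names(cls)[cls > cfg$min_otus], cfg$n_auto_subsets)
    subsets <- stats::setNames(pick, rep("class", length(pick)))
  }
  targets <- c(list(Bacteria = otu),
               stats::setNames(lapply(seq_along(subsets), function(i)
                 subset_by_taxon(otu, names(subsets)[i], subsets[i])),
                 subsets))

  clustering <- list()
  for (nm in names(targets)) {
    tb <- targets[[nm]]
    if (nrow(tb$counts) <= cfg$min_otus && nm != "Bacteria") next
    tree <- bootstrap_support(tb, n_boot = cfg$n_boot, seed = cfg$seed)
    sim_mat <- pearson_similarity(tb)
    dtests <- list()
    for (s in soils) {
      gs <- list(tb$sample_ids[glab == paste(s, "spiked", sep = ".")],
                 tb$sample_ids[glab == paste(s, "control", sep = ".")])
      dtests[[s]] <- permutation_test_d(sim_mat, gs, n_perm = cfg$n_perm,
                                        seed = cfg$seed)
    }
    clustering[[nm]] <- list(similarity = sim_mat, tree = tree, d_tests = dtests)
  }

  rc <- rarefaction_curve(otu)

  reductions <- list()
  for (s in soils) {
    ctrl <- otu$counts[, glab == paste(s, "control", sep = "."), drop = FALSE]
    spik <- otu$counts[, glab == paste(s, "spiked", sep = "."), drop = FALSE]
    reductions[[s]] <- tryCatch(
      diversity_reduction(ctrl, spik, depth = cfg$rarefaction_depth,
                          seed = cfg$seed),
      error = function(e) e)
  }

  sweep <- sweep_taxonomy(otu, groups)
  enriched <- enriched_taxa(sweep, alpha = cfg$alpha)
  diminished <- diminished_otus(otu, groups, alpha = cfg$alpha)

  tree_stage <- NULL
  if (!is.null(cfg$alignment)) {
    aln <- read_alignment(cfg$alignment)
    bt <- bootstrap_tree(aln, n_boot = cfg$n_boot, seed = cfg$seed)
    tree_stage <- list(tree = bt,
                       compressed = compress_branches(midpoint_root(bt),
                                                      cfg$compress_threshold))
  }

  report <- list(clustering = clustering, rarefaction = rc,
                 diversity_reduction = reductions, sweep = sweep,
                 enriched = enriched, diminished = diminished,
                 tree = tree_stage,
                 truth = if (!is.null(sim)) sim$truth,
                 log = list(seed = cfg$seed,
                            package_version = as.character(utils::packageVersion("soilresponders")),
                            r_version = R.version.string))
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir)) write_pipeline_report(report, otu, groups, cfg)
  report
}

write_pipeline_report <- function(report, otu, groups, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$out_dir, ...)
  write_otu_report(otu, p("otu_report.tsv"))
  utils::write.table(as.data.frame(groups), p("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(report$clustering)) {
    cl <- report$clustering[[nm]]
    utils::write.csv(unclass(cl$similarity), p(sprintf("similarity_%s.csv", nm)))
    upgma_newick(cl$tree, p(sprintf("upgma_%s.nwk", nm)))
    dt <- do.call(rbind, lapply(names(cl$d_tests), function(s) {
      t <- cl$d_tests[[s]]
      data.frame(taxon = nm, soil = s, d = t$observed$d, p = t$p,
                 mode = t$mode, n_partitions = t$n_evaluated,
                 min_attainable_p = 1 / t$n_evaluated)
    }))
    utils::write.table(dt, p(sprintf("d_tests_%s.tsv", nm)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$rarefaction, p("rarefaction.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$sweep), p("taxon_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$enriched$enriched, p("enriched.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$diminished), p("diminished.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$tree)) {
    ape::write.tree(report$tree$tree, p("responder_tree.nwk"))
    ape::write.tree(report$tree$compressed, p("responder_tree_compressed.nwk"))
  }
  jsonlite::write_json(report$log, p("run_log.json"), auto_unbox = TRUE)
  invisible(cfg$out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Community-response pipeline report\n")
  for (nm in names(x$clustering)) {
    cat(" ", nm, ": ")
    ds <- vapply(x$clustering[[nm]]$d_tests, function(t)
      sprintf("d=%.1f (p=%.3g)", t$observed$d, t$p), "")
    cat(paste(names(ds), ds, sep = " ", collapse = "; "), "\n")
  }
  for (s in names(x$diversity_reduction)) {
    r <- x$diversity_reduction[[s]]
    if (!inherits(r, "error"))
      cat(sprintf("  %s: richness reduction %.1f%% at depth %d\n",
                  s, r$reduction_pct, r$depth))
  }
  cat("  enriched taxon x soil hits:", nrow(x$enriched$enriched),
      "| common:", nrow(x$enriched$common), "\n")
  cat("  diminished OTU x soil hits:", nrow(x$diminished), "\n")
  invisible(x)
}
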