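#' Pairwise Pearson similarity between community profiles
#'
#' The community-structure comparison used throughout the package: the
#' pairwise Pearson correlation coefficient between per-sample profiles
#' (OTU counts or gel lane intensities), expressed in percent (r x 100).
#' Correlation is invariant to per-sample positive rescaling, so raw counts
#' and relative abundances give identical similarities and samples with
#' different read depths are directly comparable.
#'
#' @param x an [otu_table()], or a numeric matrix with features (OTUs, gel
#'   positions) in rows and samples in columns.
#' @return a `similarity_matrix`: symmetric sample x sample matrix in
#'   percent, diagonal 100.
#' @export
pearson_similarity <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%d", seq_len(ncol(m)))
  if (nrow(m) < 2) stop("need at least two features to correlate", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate (constant) profile for sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  s <- 100 * stats::cor(m)
  diag(s) <- 100
  structure(s, class = c("similarity_matrix", "matrix"))
}

#' Mark a precomputed matrix as a percent similarity matrix
#'
#' Use when similarities come from elsewhere (e.g. gel-analysis software)
#' rather than [pearson_similarity()]. Validates symmetry, a diagonal of
#' 100 and the `[-100, 100]` range.
#'
#' @param m square numeric matrix in percent.
#' @return a `similarity_matrix`.
#' @export
similarity_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- rownames(m) %||% sprintf("S%d", seq_len(ncol(m)))
  rownames(m) <- colnames(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("similarity matrix must be square and symmetric", call. = FALSE)
  if (max(abs(diag(m) - 100)) > 1e-8)
    stop("similarity diagonal must be 100 (percent scale)", call. = FALSE)
  if (any(m < -100 - 1e-8) || any(m > 100 + 1e-8))
    stop("similarities must lie in [-100, 100]", call. = FALSE)
  structure(m, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, digits = 1, ...) {
  cat("Pearson similarity (%) over", ncol(x), "samples\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

as_similarity <- function(x) {
  if (inherits(x, "similarity_matrix")) return(x)
  pearson_similarity(x)
}

#' UPGMA clustering of a similarity matrix
#'
#' Average-linkage agglomeration on the dissimilarity `100 - similarity`,
#' with cluster-size weights (the UPGMA definition). Node heights are
#' ultrametric leaf-to-node distances (half the merge dissimilarity). Tied
#' merges are broken deterministically by the lexicographically smallest
#' member-label set.
#'
#' @param sim a `similarity_matrix` (from [pearson_similarity()]) or any
#'   symmetric percent-similarity matrix.
#' @return an object of class `upgma_tree` with elements `merge` and
#'   `height` (hclust conventions; heights are leaf-to-node distances),
#'   `labels`, and `clusters` (the member-label set under each internal
#'   node). Coerce with [as.hclust()] or `ape::as.phylo(as.hclust(x))`.
#' @export
upgma <- function(sim) {
  sim <- as_similarity(sim)
  D <- 100 - unclass(sim)
  labels <- colnames(D)
  n <- length(labels)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  members <- as.list(seq_len(n))          # leaf indices per active cluster
  node_id <- as.list(-seq_len(n))         # hclust coding: leaves negative
  sizes <- rep(1L, n)
  active <- rep(TRUE, n + 0L)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  clusters <- vector("list", n - 1L)
  d <- D
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      i <- idx[a]; j <- idx[b]
      dij <- d[i, j]
      if (dij < best_d - 1e-12) {
        best <- c(i, j); best_d <- dij
        best_key <- paste(sort(labels[c(members[[i]], members[[j]])]), collapse = "\r")
      } else if (abs(dij - best_d) <= 1e-12) {
        key <- paste(sort(labels[c(members[[i]], members[[j]])]), collapse = "\r")
        if (key < best_key) { best <- c(i, j); best_key <- key }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(node_id[[i]], node_id[[j]]))
    height[step] <- best_d / 2
    new_members <- c(members[[i]], members[[j]])
    clusters[[step]] <- sort(labels[new_members])
    # UPGMA update: size-weighted average distance to the merged cluster
    for (k in which(active)) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- (sizes[i] * d[i, k] + sizes[j] * d[j, k]) /
        (sizes[i] + sizes[j])
    }
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    node_id[[i]] <- step
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = labels,
                 clusters = clusters, support = NULL),
            class = "upgma_tree")
}

#' @export
as.hclust.upgma_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, labels = x$labels,
                 order = leaf_order(x$merge), method = "upgma (average)",
                 call = match.call(), dist.method = "100 - pearson"),
            class = "hclust")
}

leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over", length(x$labels), "samples\n")
  for (k in seq_along(x$clusters)) {
    cat(sprintf("  node %2d  h=%6.2f  {%s}", k, x$height[k],
                paste(x$clusters[[k]], collapse = ",")))
    if (!is.null(x$support)) cat(sprintf("  support=%.0f", x$support[k]))
    cat("\n")
  }
  invisible(x)
}

#' @export
plot.upgma_tree <- function(x, ...) {
  plot(as.hclust(x), ...)
  invisible(x)
}

#' Export a UPGMA tree to Newick
#'
#' Bootstrap supports (if present) become internal node labels.
#'
#' @param x an `upgma_tree`.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
upgma_newick <- function(x, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(x))
  if (!is.null(x$support)) {
    # ape orders internal nodes root-first; map by clade membership
    lab <- character(phy$Nnode)
    parts <- ape::prop.part(phy)
    for (p in seq_along(parts)) {
      set <- sort(attr(parts, "labels")[parts[[p]]])
      k <- which(vapply(x$clusters, identical, logical(1), set))
      lab[p] <- if (length(k) == 1) sprintf("%.0f", x$support[k]) else ""
    }
    phy$node.label <- lab
  }
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Bootstrap support for UPGMA clusters
#'
#' Features (OTUs or gel positions) are resampled with replacement `n_boot`
#' times; each replicate is re-clustered, and the support of an internal
#' node of the original tree is the percentage of replicates in which the
#' exact same sample set forms a cluster. Replicates where resampling
#' produces a constant profile are discarded (counted in attribute
#' `n_discarded`) without shrinking the denominator.
#'
#' @param x an [otu_table()] or feature x sample matrix.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @return the original `upgma_tree` with `support` filled in (percent per
#'   internal node, in merge order).
#' @export
bootstrap_support <- function(x, n_boot = 500, seed = 1) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  tree <- upgma(pearson_similarity(m))
  keys <- vapply(tree$clusters, paste, character(1), collapse = "\r")
  hits <- integer(length(keys))
  discarded <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nrow(m), replace = TRUE)
      mb <- m[rows, , drop = FALSE]
      if (any(apply(mb, 2L, stats::sd) == 0)) { discarded <- discarded + 1L; next }
      tb <- upgma(pearson_similarity(mb))
      bk <- vapply(tb$clusters, paste, character(1), collapse = "\r")
      hits <- hits + as.integer(keys %in% bk)
    }
  })
  tree$support <- 100 * hits / n_boot
  attr(tree, "n_discarded") <- discarded
  tree
}

#' Percent dissimilarity d between two sample groups
#'
#' The treatment-effect statistic: mean within-group pairwise Pearson
#' similarity minus mean between-group pairwise similarity, in percent
#' points. Within-group pairs from both groups are pooled by default
#' (`within_mode = "pooled"`); `"groupwise"` averages the two per-group
#' means instead.
#'
#' @param sim a `similarity_matrix` (or profile input accepted by
#'   [pearson_similarity()]).
#' @param groups a list of two character vectors of sample ids, or a
#'   two-level factor/character vector aligned with the samples.
#' @param within_mode `"pooled"` or `"groupwise"`.
#' @return object of class `dissimilarity_d` with elements `d`,
#'   `mean_within`, `mean_between`, `sizes`.
#' @export
dissimilarity_d <- function(sim, groups, within_mode = c("pooled", "groupwise")) {
  within_mode <- match.arg(within_mode)
  sim <- as_similarity(sim)
  g <- normalize_groups(groups, colnames(sim))
  i1 <- match(g[[1]], colnames(sim)); i2 <- match(g[[2]], colnames(sim))
  s <- unclass(sim)
  pair_mean <- function(idx) {
    if (length(idx) < 2) return(c(sum = 0, n = 0))
    v <- s[idx, idx][upper.tri(diag(length(idx)))]
    c(sum = sum(v), n = length(v))
  }
  w1 <- pair_mean(i1); w2 <- pair_mean(i2)
  mean_within <- if (within_mode == "pooled")
    (w1["sum"] + w2["sum"]) / (w1["n"] + w2["n"])
  else
    mean(c(w1["sum"] / w1["n"], w2["sum"] / w2["n"]))
  between <- s[i1, i2, drop = FALSE]
  mean_between <- mean(between)
  structure(list(d = unname(mean_within - mean_between),
                 mean_within = unname(mean_within),
                 mean_between = unname(mean_between),
                 sizes = c(length(i1), length(i2)),
                 within_mode = within_mode),
            class = "dissimilarity_d")
}

#' @export
print.dissimilarity_d <- function(x, ...) {
  cat(sprintf("Percent dissimilarity d = %.2f (within %.2f - between %.2f; n = %d vs %d)\n",
              x$d, x$mean_within, x$mean_between, x$sizes[1], x$sizes[2]))
  invisible(x)
}

# groups -> list of two id vectors, validated against the sample ids
normalize_groups <- function(groups, ids) {
  if (is.list(groups)) {
    stopifnot(length(groups) == 2)
    g <- lapply(groups, as.character)
  } else {
    f <- as.factor(groups)
    if (nlevels(f) != 2) stop("need exactly two groups", call. = FALSE)
    if (length(f) != length(ids))
      stop("group vector length must match sample count", call. = FALSE)
    g <- split(ids, f)
  }
  miss <- setdiff(unlist(g), ids)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (length(intersect(g[[1]], g[[2]])))
    stop("groups overlap", call. = FALSE)
  g
}

#' Permutation test for the dissimilarity d
#'
#' Tests whether the observed d between two groups exceeds what arbitrary
#' reassignments of the samples into groups of the same sizes produce.
#' When the number of distinct unordered partitions is at most `cap`, all
#' of them are enumerated (exhaustive mode; the observed partition is one of
#' them); otherwise `n_perm` Monte-Carlo reassignments are drawn and the
#' observed partition is added to numerator and denominator. One-sided:
#' large d indicates a group effect. p is always positive, with floor
#' 1/(number of partitions evaluated).
#'
#' @param x profiles (feature x sample matrix or [otu_table()]) or a
#'   precomputed `similarity_matrix`.
#' @param groups as in [dissimilarity_d()].
#' @param n_perm Monte-Carlo draws when enumeration exceeds `cap`.
#' @param seed integer seed (used in Monte-Carlo mode).
#' @param cap largest partition count still enumerated exhaustively.
#' @param within_mode passed to [dissimilarity_d()].
#' @return object of class `perm_test_d`: `observed` (a `dissimilarity_d`),
#'   `null_d`, `p`, `n_partitions`, `mode`, `seed`.
#' @export
permutation_test_d <- function(x, groups, n_perm = 999, seed = 1,
                               cap = 10000, within_mode = "pooled") {
  sim <- as_similarity(x)
  ids <- colnames(sim)
  g <- normalize_groups(groups, ids)
  n1 <- length(g[[1]]); n2 <- length(g[[2]])
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples", call. = FALSE)
  pool <- c(g[[1]], g[[2]])
  n <- n1 + n2
  s <- unclass(sim)[pool, pool]
  obs <- dissimilarity_d(sim, g, within_mode = within_mode)
  n_part <- if (n1 == n2) choose(n, n1) / 2 else choose(n, n1)

  d_of <- function(sel) {          # sel: indices (into pool) forming group 1
    dissimilarity_d(structure(s, class = c("similarity_matrix", "matrix")),
                    list(pool[sel], pool[-sel]), within_mode = within_mode)$d
  }
  if (n_part <= cap) {
    sels <- if (n1 == n2) {
      cmb <- utils::combn(n - 1L, n1 - 1L)          # fix sample 1 in group 1
      rbind(1L, cmb + 1L)
    } else utils::combn(n, n1)
    null_d <- apply(sels, 2L, d_of)
    stopifnot(ncol(sels) == n_part)
    p <- sum(null_d >= obs$d - 1e-12) / n_part
    mode <- "exhaustive"
    n_eval <- n_part
  } else {
    null_d <- with_seed(seed, vapply(seq_len(n_perm), function(b)
      d_of(sample.int(n, n1)), numeric(1)))
    p <- (1 + sum(null_d >= obs$d - 1e-12)) / (n_perm + 1)
    mode <- "monte_carlo"
    n_eval <- n_perm + 1
  }
  structure(list(observed = obs, null_d = null_d, p = p,
                 n_partitions = n_part, n_evaluated = n_eval,
                 mode = mode, seed = seed),
            class = "perm_test_d")
}

#' @export
print.perm_test_d <- function(x, ...) {
  cat(sprintf("Permutation test for percent dissimilarity d\n  d = %.2f, p = %.4g (%s over %d partitions)\n",
              x$observed$d, x$p, x$mode, x$n_evaluated))
  floor_p <- 1 / x$n_evaluated
  if (floor_p > 0.05)
    cat(sprintf("  note: smallest attainable p with this design is %.3f; significance at 0.05 is unattainable\n",
                floor_p))
  invisible(x)
}
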