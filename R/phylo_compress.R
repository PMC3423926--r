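#' Read an aligned FASTA file
#'
#' @param path FASTA with aligned sequences (equal lengths, alphabet
#'   A/C/G/T/-/N; case-insensitive).
#' @return character matrix (sequences in rows, sites in columns) with
#'   unique row names.
#' @export
read_alignment <- function(path) {
  d <- ape::read.FASTA(path)
  if (length(unique(lengths(d))) != 1)
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  m <- toupper(as.character(as.matrix(d)))
  if (anyDuplicated(rownames(m)))
    stop("duplicate sequence ids", call. = FALSE)
  m
}

#' Pairwise distances from an alignment
#'
#' Sites with a gap or N in either sequence of a pair are excluded
#' (pairwise deletion); `p` is the mismatch fraction over the remaining
#' sites. `"p_distance"` returns `p` itself; `"JC69"` applies the
#' Jukes-Cantor correction `d = -(3/4) log(1 - 4p/3)`, which is undefined
#' at `p >= 0.75`.
#'
#' @param aln character matrix from [read_alignment()] (or a named
#'   character vector of equal-length sequences).
#' @param model `"JC69"` (default) or `"p_distance"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln, model = c("JC69", "p_distance")) {
  model <- match.arg(model)
  m <- as_alignment_matrix(aln)
  ids <- rownames(m)
  n <- nrow(m)
  valid <- m == "A" | m == "C" | m == "G" | m == "T"
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    ok <- valid[i, ] & valid[j, ]
    nv <- sum(ok)
    if (nv == 0)
      stop("no comparable sites between '", ids[i], "' and '", ids[j], "'",
           call. = FALSE)
    p <- sum(m[i, ok] != m[j, ok]) / nv
    d <- if (model == "p_distance") p else {
      if (p >= 0.75)
        stop("JC69 distance undefined (p = ", signif(p, 3), " >= 0.75) between '",
             ids[i], "' and '", ids[j], "'", call. = FALSE)
      -0.75 * log(1 - 4 * p / 3)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) return(toupper(aln))
  if (is.character(aln)) {
    L <- nchar(aln)
    if (length(unique(L)) != 1) stop("sequences are not aligned", call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln) %||% sprintf("seq%d", seq_along(aln))
    return(m)
  }
  stop("expected a character matrix or vector of sequences", call. = FALSE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via `ape::nj`. Negative estimated branch
#' lengths (possible on non-additive inputs) are clamped to zero, with the
#' total clamped length recorded in attribute `clamped_deficit`.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  attr(tr, "clamped_deficit") <- sum(-tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement `n_boot` times; the
#' support of an internal node is the percentage of replicate NJ trees
#' containing the same bipartition. Replicates whose resampled alignment
#' yields an undefined distance are discarded (counted, denominator
#' unchanged).
#'
#' @param aln alignment as in [pairwise_distance()].
#' @param n_boot replicate count.
#' @param seed integer seed.
#' @param model distance model, as in [pairwise_distance()].
#' @return a `phylo` tree whose `node.label` carries percent supports
#'   (`NA` for the root); attribute `n_discarded` counts dropped
#'   replicates.
#' @export
bootstrap_tree <- function(aln, n_boot = 100, seed = 1, model = "JC69") {
  m <- as_alignment_matrix(aln)
  main <- neighbor_joining(pairwise_distance(m, model))
  discarded <- 0L
  reps <- with_seed(seed, {
    out <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      tb <- tryCatch(neighbor_joining(pairwise_distance(m[, cols, drop = FALSE],
                                                        model)),
                     error = function(e) NULL)
      if (is.null(tb)) discarded <- discarded + 1L else out[[b]] <- tb
    }
    out[!vapply(out, is.null, logical(1))]
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / n_boot)
  attr(main, "n_discarded") <- discarded
  main
}

#' Compress tight clades of a phylogenetic tree
#'
#' Reduces tree complexity for display: every maximal subtree in which all
#' leaves lie within `threshold` path length of the subtree root collapses
#' to a single leaf placed at that root, labelled
#' `"<representative> (+k)"`, where the representative is the
#' lexicographically smallest member label and `k` the number of other
#' members. At `threshold = 0` only zero-length clades collapse; at or
#' above the tree height everything collapses to one node. Total leaf
#' membership is conserved (attribute `members`, a named count per
#' remaining leaf).
#'
#' @param tree a rooted `phylo` tree with branch lengths (root an unrooted
#'   tree first, e.g. with [midpoint_root()]).
#' @param threshold path-length threshold (same units as branch lengths).
#' @return a `phylo` tree (or, when everything collapses, a single-leaf
#'   `phylo`), with attribute `members`.
#' @export
compress_branches <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"), threshold >= 0)
  n_tip <- length(tree$tip.label)
  nd <- ape::dist.nodes(tree)
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(v) {
    if (v <= n_tip) return(v)
    unlist(lapply(kids[[as.character(v)]], tips_under))
  }
  internal <- seq.int(n_tip + 1L, n_tip + tree$Nnode)
  tipsets <- lapply(internal, tips_under)
  maxd <- vapply(seq_along(internal), function(k)
    max(nd[internal[k], tipsets[[k]]]), numeric(1))
  ok <- maxd <= threshold + 1e-12
  names(ok) <- internal
  parent <- integer(max(tree$edge)); parent[tree$edge[, 2]] <- tree$edge[, 1]
  maximal <- internal[ok & vapply(internal, function(v)
    v == root || !ok[as.character(parent[v])], logical(1))]

  members <- stats::setNames(rep(1L, n_tip), tree$tip.label)
  if (length(maximal) == 0 || n_tip < 2) {
    attr(tree, "members") <- members
    return(tree)
  }
  if (root %in% maximal) {         # whole tree collapses to one node
    labs <- sort(tree$tip.label)
    lab <- sprintf("%s (+%d)", labs[1], n_tip - 1L)
    out <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = lab, edge.length = 0, Nnode = 1L),
                     class = "phylo")
    attr(out, "members") <- stats::setNames(n_tip, lab)
    return(out)
  }
  drop <- character(0); relabel <- list()
  for (v in maximal) {
    tl <- sort(tree$tip.label[tips_under(v)])
    rep_tip <- tl[1]
    relabel[[rep_tip]] <- list(new = sprintf("%s (+%d)", rep_tip, length(tl) - 1L),
                               k = length(tl),
                               delta = nd[v, match(rep_tip, tree$tip.label)])
    drop <- c(drop, setdiff(tl, rep_tip))
  }
  out <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  members <- stats::setNames(rep(1L, length(out$tip.label)), out$tip.label)
  for (rep_tip in names(relabel)) {
    info <- relabel[[rep_tip]]
    i <- match(rep_tip, out$tip.label)
    e <- which(out$edge[, 2] == i)
    # pull the representative back up to the subtree root
    out$edge.length[e] <- max(0, out$edge.length[e] - info$delta)
    out$tip.label[i] <- info$new
    names(members)[i] <- info$new
    members[i] <- info$k
  }
  attr(out, "members") <- members
  out
}

#' Midpoint-root an unrooted tree
#'
#' Thin wrapper over `phangorn::midpoint`, used to obtain the rooted
#' rendering on which [compress_branches()] operates.
#'
#' @param tree an unrooted `phylo`.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}
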