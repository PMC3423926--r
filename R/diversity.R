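#' Summary quantities of an abundance vector
#'
#' @param v non-negative integer counts for one sample or pooled group.
#' @return list with `N` (total reads), `S_obs` (observed OTUs), `F1`
#'   (singletons), `F2` (doubletons).
#' @export
abundance_summary <- function(v) {
  v <- check_counts(v)
  list(N = sum(v), S_obs = sum(v > 0), F1 = sum(v == 1), F2 = sum(v == 2))
}

check_counts <- function(v) {
  v <- as.numeric(v)
  if (anyNA(v) || any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  v
}

#' Expected rarefied richness
#'
#' The expected number of distinct OTUs in a random subsample of `k` reads
#' drawn without replacement, by the hypergeometric formula
#' `sum_i 1 - C(N - N_i, k) / C(N, k)`, evaluated in log space so large
#' depths do not overflow.
#'
#' @param v abundance vector (non-negative integer counts).
#' @param k subsample depth(s); each must satisfy `0 <= k <= sum(v)`.
#' @return expected richness, one value per element of `k`.
#' @export
expected_richness <- function(v, k) {
  v <- check_counts(v)
  N <- sum(v)
  if (any(k < 0) || any(k > N))
    stop("depth k must be between 0 and the total count ", N, call. = FALSE)
  if (any(k != round(k))) stop("depth k must be integral", call. = FALSE)
  vi <- v[v > 0]
  vapply(k, function(kk) {
    if (kk == 0) return(0)
    # P(OTU i absent from the subsample) = C(N - N_i, k) / C(N, k)
    p_abs <- ifelse(N - vi < kk, 0, exp(lchoose(N - vi, kk) - lchoose(N, kk)))
    sum(1 - p_abs)
  }, numeric(1))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` by default; the
#' classic form `S_obs + F1^2 / (2 F2)` is available and falls back to the
#' bias-corrected form (with a warning) when there are no doubletons.
#'
#' @param v abundance vector.
#' @param bias_corrected use the bias-corrected form?
#' @return the Chao1 estimate (always `>= S_obs`).
#' @export
chao1 <- function(v, bias_corrected = TRUE) {
  a <- abundance_summary(v)
  if (bias_corrected) return(a$S_obs + a$F1 * (a$F1 - 1) / (2 * (a$F2 + 1)))
  if (a$F2 == 0) {
    warning("classic Chao1 undefined with no doubletons; using bias-corrected form",
            call. = FALSE)
    return(a$S_obs + a$F1 * (a$F1 - 1) / 2)
  }
  a$S_obs + a$F1^2 / (2 * a$F2)
}

#' Shannon diversity
#'
#' `H = -sum p_i log p_i` over nonzero proportions, natural log by default.
#'
#' @param v abundance vector.
#' @param base logarithm base (`exp(1)` natural, 2 for bits).
#' @return H.
#' @export
shannon <- function(v, base = exp(1)) {
  v <- check_counts(v)
  p <- v[v > 0] / sum(v)
  -sum(p * log(p, base = base))
}

#' Pielou's evenness
#'
#' `J = H / log(S_obs)`. Undefined for a single-OTU sample, in which case
#' `NA` is returned with a warning stating the reason.
#'
#' @param v abundance vector.
#' @param base logarithm base, as in [shannon()].
#' @return J in `[0, 1]`, or `NA` when undefined.
#' @export
pielou <- function(v, base = exp(1)) {
  v <- check_counts(v)
  S <- sum(v > 0)
  if (S < 2) {
    warning("Pielou evenness undefined: fewer than two observed OTUs", call. = FALSE)
    return(NA_real_)
  }
  shannon(v, base) / log(S, base = base)
}

index_fun <- function(index) {
  switch(index,
         richness = function(v) sum(v > 0),
         chao1 = chao1,
         shannon = shannon,
         pielou = function(v) suppressWarnings(pielou(v)),
         stop("unknown index: ", index, call. = FALSE))
}

#' Rarefaction-normalized diversity index
#'
#' Subsamples the abundance vector without replacement to a fixed depth
#' `n_iter` times and evaluates the index on each subsample, removing the
#' bias caused by unequal read depths. At `depth = sum(v)` the subsample is
#' the full sample, so the mean equals the plain index and the sd is 0.
#'
#' @param v abundance vector.
#' @param depth subsample depth (`<= sum(v)`).
#' @param index one of `"richness"`, `"chao1"`, `"shannon"`, `"pielou"`.
#' @param n_iter number of random subsamples.
#' @param seed integer seed.
#' @return object of class `rarefied_index`: `mean`, `sd`, `values`,
#'   `depth`, `index`, `n_iter`, `seed`.
#' @export
rarefied_index <- function(v, depth, index = "richness", n_iter = 100, seed = 1) {
  v <- check_counts(v)
  N <- sum(v)
  if (depth > N) stop("depth exceeds total count ", N, call. = FALSE)
  f <- index_fun(index)
  reads <- rep.int(seq_along(v), v)
  vals <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    sub <- tabulate(sample(reads, depth), nbins = length(v))
    f(sub)
  }, numeric(1)))
  structure(list(mean = mean(vals), sd = stats::sd(vals), values = vals,
                 depth = depth, index = index, n_iter = n_iter, seed = seed),
            class = "rarefied_index")
}

#' @export
print.rarefied_index <- function(x, ...) {
  cat(sprintf("rarefied %s at depth %d: %.4g +/- %.4g (%d subsamples)\n",
              x$index, x$depth, x$mean, x$sd, x$n_iter))
  invisible(x)
}

#' Rarefaction curves for an OTU table
#'
#' Analytic expected richness per sample over a grid of depths. Depths
#' beyond a sample's total are reported as `NA` for that sample.
#'
#' @param x an [otu_table()] or count matrix (samples in columns).
#' @param depths depth grid; defaults to 20 points up to the largest sample.
#' @return data.frame with columns `sample`, `depth`, `richness`.
#' @export
rarefaction_curve <- function(x, depths = NULL) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  tot <- colSums(m)
  if (is.null(depths))
    depths <- unique(round(seq(1, max(tot), length.out = 20)))
  do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    ok <- depths <= tot[j]
    r <- rep(NA_real_, length(depths))
    r[ok] <- expected_richness(m[, j], depths[ok])
    data.frame(sample = colnames(m)[j] %||% paste0("S", j),
               depth = depths, richness = r)
  }))
}

#' Percent diversity reduction between control and treated groups
#'
#' The average rarefied richness at a fixed depth (default 400 reads) is
#' computed per sample and averaged within each group; the reduction is
#' `100 (control - treated) / control`. Samples shallower than `depth` are
#' excluded with a warning; if a group loses all samples the comparison is
#' an error.
#'
#' @param control,treated [otu_table()]s or count matrices (samples in
#'   columns) for the two groups.
#' @param depth rarefaction depth.
#' @param index `"richness"` (analytic, default) or any
#'   [rarefied_index()] index (Monte-Carlo).
#' @param n_iter,seed used only for Monte-Carlo indices.
#' @return list of class `diversity_reduction`: `reduction_pct`,
#'   `mean_control`, `mean_treated`, `per_sample`.
#' @export
diversity_reduction <- function(control, treated, depth = 400,
                                index = "richness", n_iter = 100, seed = 1) {
  one_group <- function(x, label) {
    m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
    tot <- colSums(m)
    shallow <- tot < depth
    if (any(shallow))
      warning(label, ": excluding sample(s) below depth ", depth, ": ",
              paste(colnames(m)[shallow], collapse = ", "), call. = FALSE)
    if (all(shallow))
      stop(label, ": no sample reaches depth ", depth, call. = FALSE)
    keep <- which(!shallow)
    vals <- vapply(keep, function(j) {
      if (index == "richness") expected_richness(m[, j], depth)
      else rarefied_index(m[, j], depth, index, n_iter, seed)$mean
    }, numeric(1))
    names(vals) <- colnames(m)[keep]
    vals
  }
  vc <- one_group(control, "control")
  vt <- one_group(treated, "treated")
  red <- 100 * (mean(vc) - mean(vt)) / mean(vc)
  structure(list(reduction_pct = red, mean_control = mean(vc),
                 mean_treated = mean(vt),
                 per_sample = list(control = vc, treated = vt),
                 depth = depth, index = index),
            class = "diversity_reduction")
}

#' @export
print.diversity_reduction <- function(x, ...) {
  cat(sprintf("%s at depth %d: control %.1f, treated %.1f -> reduction %.1f%%\n",
              x$index, x$depth, x$mean_control, x$mean_treated, x$reduction_pct))
  invisible(x)
}
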