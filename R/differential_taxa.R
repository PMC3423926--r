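#' Fit the per-taxon binomial group model
#'
#' For one taxon, the per-sample reads in the taxon (`y`) out of the sample
#' depth (`n`) are modelled by a one-factor binomial logistic GLM,
#' `cbind(y, n - y) ~ group`. Complete separation (a group with zero reads
#' everywhere, or saturated) invalidates Wald inference and is flagged; the
#' contrast step then falls back to Fisher exact tests on pooled counts.
#'
#' @param y integer vector of taxon reads per sample.
#' @param n integer vector of sample depths.
#' @param group factor of group labels (>= 2 levels, >= 2 samples each).
#' @param family `"quasibinomial"` (default) estimates a dispersion scale
#'   factor from the replicates, keeping the test calibrated when
#'   replicate-to-replicate variation exceeds binomial sampling noise — the
#'   rule rather than the exception in soil communities; `"binomial"` is
#'   the plain logistic model.
#' @param rho intraclass correlation of reads within a sample (the
#'   Dirichlet-multinomial overdispersion parameter). Under such
#'   overdispersion the variance of a count is inflated by
#'   `1 + (n_s - 1) rho`, which grows with depth, so deeper samples are
#'   noisier than a constant scale factor assumes; the model downweights
#'   each sample by that factor. Estimate it from the whole table with
#'   [estimate_icc()]; 0 disables the weighting.
#' @return object of class `taxon_glm`: `fit` (the glm), `separation`
#'   flag, `skip` flag (all samples zero), `dispersion` (estimated scale
#'   factor; 1 for plain binomial), plus the data.
#' @export
fit_group_glm <- function(y, n, group,
                          family = c("quasibinomial", "binomial"),
                          rho = 0) {
  family <- match.arg(family)
  group <- droplevels(as.factor(group))
  stopifnot(length(y) == length(n), length(y) == length(group))
  if (nlevels(group) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(group) < 2)) stop("need at least two samples per group", call. = FALSE)
  if (any(y < 0) || any(y > n)) stop("need 0 <= y <= n", call. = FALSE)
  skip <- all(y == 0)
  gs_y <- tapply(y, group, sum)
  gs_n <- tapply(n, group, sum)
  separation <- any(gs_y == 0) || any(gs_y == gs_n)
  w <- 1 / (1 + (n - 1) * rho)
  fit <- if (!skip)
    suppressWarnings(stats::glm(cbind(y, n - y) ~ group, weights = w,
                                family = if (family == "binomial")
                                  stats::binomial() else stats::quasibinomial()))
  else NULL
  dispersion <- 1
  if (!skip && family == "quasibinomial")
    dispersion <- sum(stats::residuals(fit, "pearson")^2) / fit$df.residual
  structure(list(fit = fit, y = y, n = n, group = group,
                 group_y = gs_y, group_n = gs_n, family = family,
                 dispersion = dispersion, rho = rho, weights = w,
                 separation = separation, skip = skip),
            class = "taxon_glm")
}

#' Estimate the within-sample read intraclass correlation
#'
#' Moment estimator of the Dirichlet-multinomial overdispersion parameter
#' `rho` (equal to `1 / (1 + precision)` for a Dirichlet with the given
#' precision): for every sufficiently abundant taxon and replicate group,
#' the within-group Pearson chi-square per degree of freedom estimates
#' `1 + (n_bar - 1) rho`; the pooled estimate is the median over taxon x
#' group cells, floored at 0. Used to weight [fit_group_glm()] so that
#' deep samples are not treated as more informative than replicate
#' variation warrants.
#'
#' @param x an [otu_table()] or count matrix (samples in columns).
#' @param groups a [sample_groups()] table (or a factor/character vector of
#'   group labels aligned with the samples).
#' @param min_reads only taxa with at least this many pooled reads enter
#'   the estimate.
#' @return the estimated `rho` in `[0, 1)`.
#' @export
estimate_icc <- function(x, groups, min_reads = 50) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  glab <- if (inherits(groups, "sample_groups"))
    group_labels(groups, colnames(m)) else as.character(groups)
  depth <- colSums(m)
  keep <- rowSums(m) >= min_reads
  m <- m[keep, , drop = FALSE]
  vals <- c()
  for (g in unique(glab)) {
    js <- which(glab == g)
    if (length(js) < 2) next
    n <- depth[js]
    for (i in seq_len(nrow(m))) {
      y <- m[i, js]
      pi_hat <- sum(y) / sum(n)
      if (pi_hat <= 0 || pi_hat >= 1) next
      x2 <- sum((y - n * pi_hat)^2 / (n * pi_hat * (1 - pi_hat)))
      # X2 ~ lambda * chisq(df); dividing by the chi-square median (not the
      # mean) makes the median over cells an unbiased-in-median estimate
      lambda <- x2 / stats::qchisq(0.5, df = length(js) - 1)
      vals <- c(vals, (lambda - 1) / (mean(n) - 1))
    }
  }
  if (!length(vals)) return(0)
  max(0, stats::median(vals))
}

#' All pairwise group contrasts with Tukey-style adjustment
#'
#' On the regular path, `multcomp::glht` provides the pairwise log-odds
#' contrasts with unadjusted and single-step (Tukey-style) adjusted
#' p-values. When the fit is separated (a group entirely without the
#' taxon), Wald statistics are meaningless, so each pair is tested by a
#' Fisher exact test on the pooled group counts, log-odds are estimated
#' with a Haldane 0.5 correction, and Bonferroni adjustment is used; such
#' rows carry `method = "fisher"`.
#'
#' @param obj a `taxon_glm` from [fit_group_glm()].
#' @return data.frame with one row per group pair: `contrast`
#'   (`"B - A"`), `estimate` (log-odds difference), `z`, `p` (unadjusted),
#'   `p_adj` (`>= p` always), `method`, `direction` (sign of the
#'   estimate).
#' @export
tukey_contrasts <- function(obj) {
  stopifnot(inherits(obj, "taxon_glm"))
  if (obj$skip) stop("taxon has zero reads everywhere; nothing to test", call. = FALSE)
  lv <- levels(obj$group)
  pairs <- utils::combn(lv, 2)
  if (!obj$separation && obj$family == "quasibinomial") {
    cf <- stats::coef(obj$fit)
    V <- summary(obj$fit)$cov.unscaled * obj$dispersion
    K <- matrix(0, ncol(pairs), length(cf))
    lab <- character(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]       # contrast b - a, treatment coding
      if (a != lv[1]) K[k, match(paste0("group", a), names(cf))] <- -1
      K[k, match(paste0("group", b), names(cf))] <- 1
      lab[k] <- paste(b, "-", a)
    }
    est <- drop(K %*% cf)
    KV <- K %*% V %*% t(K)
    tstat <- est / sqrt(diag(KV))
    df <- obj$fit$df.residual
    p <- 2 * stats::pt(-abs(tstat), df)
    R <- stats::cov2cor(KV)
    p_adj <- vapply(seq_along(tstat), function(k)
      with_seed(1L, 1 - mvtnorm::pmvt(lower = rep(-abs(tstat[k]), length(tstat)),
                                      upper = rep(abs(tstat[k]), length(tstat)),
                                      df = df, corr = R)[1]),
      numeric(1))
    out <- data.frame(contrast = lab, estimate = est, z = tstat, p = p,
                      p_adj = pmin(pmax(p_adj, p), 1),
                      method = "glm_tukey_quasi", stringsAsFactors = FALSE)
  } else if (!obj$separation) {
    gl <- multcomp::glht(obj$fit, linfct = multcomp::mcp(group = "Tukey"))
    s_un <- suppressWarnings(summary(gl, test = multcomp::adjusted("none")))
    # single-step adjustment integrates a multivariate normal with randomized
    # quadrature; fix a local seed so results are reproducible
    s_ad <- with_seed(1L, suppressWarnings(
      summary(gl, test = multcomp::adjusted("single-step"))))
    est <- unname(s_un$test$coefficients)
    z <- unname(s_un$test$tstat)
    p <- unname(s_un$test$pvalues)
    p_adj <- pmax(unname(s_ad$test$pvalues), p)
    out <- data.frame(contrast = names(s_un$test$coefficients),
                      estimate = est, z = z, p = p, p_adj = pmin(p_adj, 1),
                      method = "glm_tukey", stringsAsFactors = FALSE)
  } else {
    # pool overdispersion-deflated effective counts: a read in a sample of
    # depth n carries 1/(1+(n-1)rho) of an independent observation
    ye <- round(tapply(obj$y * obj$weights, obj$group, sum))
    ne <- round(tapply(obj$n * obj$weights, obj$group, sum))
    ye <- pmin(ye, ne)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ya <- ye[[a]]; na <- ne[[a]]
      yb <- ye[[b]]; nb <- ne[[b]]
      ft <- stats::fisher.test(matrix(c(yb, nb - yb, ya, na - ya), 2,
                                      byrow = TRUE))
      est <- log((yb + 0.5) / (nb - yb + 0.5)) - log((ya + 0.5) / (na - ya + 0.5))
      data.frame(contrast = paste(b, "-", a), estimate = est, z = NA_real_,
                 p = ft$p.value, p_adj = min(1, ft$p.value * ncol(pairs)),
                 method = "fisher", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  out$direction <- sign(out$estimate)
  rownames(out) <- NULL
  out
}

#' Test every taxon at every rank for group differences
#'
#' The taxonomy sweep: the table is aggregated at each requested rank
#' (plus the raw OTU level), and every taxon with a nonzero total is tested
#' with [fit_group_glm()] + [tukey_contrasts()]. Trials are the full sample
#' depths, which aggregation preserves.
#'
#' @param x an [otu_table()].
#' @param groups a [sample_groups()] table covering the samples.
#' @param ranks ranks to sweep; `"otu"` means the unaggregated rows.
#' @param drop_unclassified drop unclassified bins before testing?
#' @param family passed to [fit_group_glm()]; `"quasibinomial"` (default)
#'   or the plain `"binomial"` model.
#' @param rho overdispersion intraclass correlation passed to
#'   [fit_group_glm()]; `NULL` (default) estimates it once from the whole
#'   table with [estimate_icc()] (0 under `family = "binomial"`).
#' @return data.frame of class `taxon_sweep`, one row per taxon x contrast:
#'   `rank`, `taxon`, `contrast`, `estimate`, `z`, `p`, `p_adj`, `method`,
#'   `direction`, plus per-group mean and sd relative abundance (%) in
#'   attribute `"abundance"`.
#' @export
sweep_taxonomy <- function(x, groups,
                           ranks = c("phylum", "class", "order", "family",
                                     "genus", "otu"),
                           drop_unclassified = FALSE,
                           family = c("quasibinomial", "binomial"),
                           rho = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(x, "otu_table"))
  glab <- factor(group_labels(groups, x$sample_ids))
  depth <- colSums(x$counts)
  if (is.null(rho))
    rho <- if (family == "quasibinomial") estimate_icc(x, groups) else 0
  res <- list(); abund <- list()
  for (rk in ranks) {
    tab <- if (rk == "otu") x else aggregate_at_rank(x, rk, drop_unclassified)
    for (i in seq_len(nrow(tab$counts))) {
      y <- tab$counts[i, ]
      if (sum(y) == 0) next
      fit <- fit_group_glm(y, depth, glab, family = family, rho = rho)
      ct <- tukey_contrasts(fit)
      ct$rank <- rk
      ct$taxon <- tab$otu_ids[i]
      res[[length(res) + 1L]] <- ct
      pct <- 100 * y / depth
      abund[[length(abund) + 1L]] <-
        data.frame(rank = rk, taxon = tab$otu_ids[i],
                   group = levels(glab),
                   mean_pct = as.numeric(tapply(pct, glab, mean)),
                   sd_pct = as.numeric(tapply(pct, glab, stats::sd)),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[, c("rank", "taxon", "contrast", "estimate", "z", "p", "p_adj",
                 "method", "direction")]
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "rho") <- rho
  attr(out, "abundance") <- do.call(rbind, abund)
  class(out) <- c("taxon_sweep", "data.frame")
  out
}

# parse "B - A" contrast labels into a two-column matrix
split_contrast <- function(contrast) {
  parts <- strsplit(contrast, " - ", fixed = TRUE)
  cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' Taxa enriched in the spiked soils
#'
#' Applies the enrichment criterion to a taxonomy sweep: for each soil, a
#' taxon is enriched when its spiked-vs-control contrast within that soil
#' has the spiked side higher and an unadjusted p below `alpha`. The
#' common responders are the taxa enriched in every soil.
#'
#' @param sweep a `taxon_sweep` from [sweep_taxonomy()].
#' @param alpha significance level on the unadjusted p (the replication
#'   path uses 0.05; `q_bh` is available in the sweep for stricter use).
#' @param soils soil names; default all soils seen in the contrasts.
#' @return object of class `responder_report` with elements `enriched`
#'   (data.frame: `soil`, `rank`, `taxon`, `estimate`, `p`, `method`) and
#'   `common` (taxa enriched in all soils, per rank).
#' @export
enriched_taxa <- function(sweep, alpha = 0.05, soils = NULL) {
  cm <- split_contrast(sweep$contrast)
  grp <- unique(as.vector(cm))
  soil_of <- sub("\\.(control|spiked)$", "", grp)
  treat_of <- sub("^.*\\.", "", grp)
  if (is.null(soils)) soils <- unique(soil_of)
  picks <- list()
  for (s in soils) {
    gs <- paste(s, "spiked", sep = "."); gc <- paste(s, "control", sep = ".")
    hit_fwd <- cm[, 1] == gs & cm[, 2] == gc   # "spiked - control"
    hit_rev <- cm[, 1] == gc & cm[, 2] == gs
    sel <- (hit_fwd & sweep$estimate > 0 | hit_rev & sweep$estimate < 0) &
      sweep$p < alpha
    if (any(sel))
      picks[[s]] <- data.frame(soil = s,
                               sweep[sel, c("rank", "taxon", "estimate", "p",
                                            "method")],
                               stringsAsFactors = FALSE)
  }
  enr <- if (length(picks)) do.call(rbind, picks) else
    data.frame(soil = character(), rank = character(), taxon = character(),
               estimate = numeric(), p = numeric(), method = character())
  rownames(enr) <- NULL
  common <- if (nrow(enr)) {
    cnt <- stats::aggregate(list(n_soils = enr$soil),
                            by = enr[c("rank", "taxon")],
                            FUN = function(z) length(unique(z)))
    cnt[cnt$n_soils == length(soils), c("rank", "taxon")]
  } else enr[c("rank", "taxon")]
  rownames(common) <- NULL
  structure(list(enriched = enr, common = common, alpha = alpha,
                 soils = soils),
            class = "responder_report")
}

#' @export
print.responder_report <- function(x, ...) {
  cat("Responder report (alpha =", x$alpha, ")\n")
  if (!is.null(x$enriched)) {
    cat("  enriched:", nrow(x$enriched), "taxon x soil hits;",
        nrow(x$common), "common to all soils\n")
    for (rk in unique(x$common$rank))
      cat("    common", rk, ":",
          paste(x$common$taxon[x$common$rank == rk], collapse = ", "), "\n")
  }
  if (!is.null(x$diminished))
    cat("  diminished:", nrow(x$diminished), "OTU x soil hits\n")
  invisible(x)
}

#' OTUs diminished in the spiked soils
#'
#' Applies the two explicit decline rules per soil. With `S` the number of
#' OTUs detected in that soil's control samples, the average detection is
#' the mean OTU share `1/S`. Rule 1: the OTU's control relative abundance
#' is at least five times the average and the OTU is never detected in the
#' corresponding spiked samples. Rule 2: at least four times the average
#' and significantly higher (p < `alpha`) in the control than in the spiked
#' soil by the OTU-level contrast (GLM, or Fisher fallback under
#' separation). Rule 1 takes precedence when both fire.
#'
#' @param x an [otu_table()] at the OTU level.
#' @param groups a [sample_groups()] table; every soil must carry both
#'   treatments.
#' @param alpha significance level for rule 2.
#' @param family passed to [fit_group_glm()] for the rule-2 contrast.
#' @param rho as in [sweep_taxonomy()].
#' @return data.frame of class `diminished_report`: `otu_id`, `soil`,
#'   `rule` (`"rule1"`/`"rule2"`), `control_share_pct`, `fold_over_average`,
#'   `p` (`NA` for rule 1).
#' @export
diminished_otus <- function(x, groups, alpha = 0.05,
                            family = c("quasibinomial", "binomial"),
                            rho = NULL) {
  family <- match.arg(family)
  if (is.null(rho))
    rho <- if (family == "quasibinomial") estimate_icc(x, groups) else 0
  stopifnot(inherits(x, "otu_table"))
  glab <- group_labels(groups, x$sample_ids)
  soils <- unique(groups$soil[match(x$sample_ids, groups$sample_id)])
  out <- list()
  for (s in soils) {
    ctrl <- x$sample_ids[glab == paste(s, "control", sep = ".")]
    spik <- x$sample_ids[glab == paste(s, "spiked", sep = ".")]
    if (length(ctrl) == 0 || length(spik) == 0)
      stop("soil ", s, " lacks a control or spiked group", call. = FALSE)
    pc <- rowSums(x$counts[, ctrl, drop = FALSE])
    ps <- rowSums(x$counts[, spik, drop = FALSE])
    detected <- pc > 0
    S <- sum(detected)
    avg <- 1 / S
    share <- pc / sum(pc)
    fold <- share / avg
    rule1 <- detected & fold >= 5 & ps == 0
    cand2 <- which(detected & fold >= 4 & !rule1)
    rule2 <- logical(nrow(x$counts)); p2 <- rep(NA_real_, nrow(x$counts))
    sub_ids <- c(ctrl, spik)
    gl <- factor(rep(c("control", "spiked"), c(length(ctrl), length(spik))))
    depth <- colSums(x$counts)[sub_ids]
    for (i in cand2) {
      y <- x$counts[i, sub_ids]
      ft <- fit_group_glm(y, depth, gl, family = family, rho = rho)
      ct <- tukey_contrasts(ft)      # single contrast "spiked - control"
      sc <- split_contrast(ct$contrast)
      est_ctrl_minus_spiked <- ifelse(sc[, 1] == "control", ct$estimate,
                                      -ct$estimate)
      if (est_ctrl_minus_spiked > 0 && ct$p < alpha) {
        rule2[i] <- TRUE; p2[i] <- ct$p
      }
    }
    hit <- rule1 | rule2
    if (any(hit))
      out[[s]] <- data.frame(otu_id = x$otu_ids[hit], soil = s,
                             rule = ifelse(rule1[hit], "rule1", "rule2"),
                             control_share_pct = 100 * share[hit],
                             fold_over_average = fold[hit],
                             p = p2[hit], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(otu_id = character(), soil = character(), rule = character(),
               control_share_pct = numeric(), fold_over_average = numeric(),
               p = numeric())
  rownames(res) <- NULL
  class(res) <- c("diminished_report", "data.frame")
  res
}
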