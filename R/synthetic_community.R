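#' Specification of a synthetic two-soil spiking experiment
#'
#' Defines every parameter of the simulated community from which OTU tables,
#' gel-fingerprint lanes and ground-truth responder lists are generated. The
#' defaults emulate a two-soil phenanthrene-spiking design sequenced at day
#' 63: 2 soils x \{control, spiked\} x 3 replicates, uneven per-sample read
#' depths around 2500, a long-tailed (lognormal) species abundance
#' distribution over 2000 species-level OTUs, replicate-to-replicate
#' overdispersion via a Dirichlet draw, two common responder genera planted
#' at 20% and 5% target relative abundance in the spiked groups, and ten
#' OTUs that disappear entirely after spiking.
#'
#' @param n_otus number of species-level OTUs.
#' @param n_phyla,n_classes,n_orders,n_families,n_genera shape of the
#'   generated taxonomy.
#' @param unclassified_fraction fraction of OTUs whose lineage is truncated
#'   (set to `"unclassified"`) below some rank.
#' @param meanlog,sdlog lognormal law for baseline OTU abundances.
#' @param soils soil names (one community baseline each).
#' @param n_replicates sequenced replicates per soil x treatment group.
#' @param divergence fraction of OTU abundances independently redrawn per
#'   soil; 0 makes all soils identical.
#' @param dirichlet_precision Dirichlet concentration (precision) for
#'   replicate overdispersion; `Inf` disables it (plain multinomial).
#' @param depth_mean,depth_sd,depth_floor truncated-normal law for read
#'   depths per sample (redrawn until `>= depth_floor`).
#' @param enriched data.frame with columns `target` (target relative
#'   abundance of the responder genus in spiked groups) and `scope`
#'   (`"both"` or one soil name). One responder genus is planted per row.
#' @param n_diminished number of OTUs planted as absent-after-spiking.
#' @param diminished_share control relative abundance assigned to each
#'   planted diminished OTU (must clear the 5x-average detection rule).
#' @param diminished_scope `"both"` or a soil name.
#' @param dgge_positions,dgge_bands,dgge_replicates,dgge_band_sd,
#'   dgge_effect_fold,dgge_n_responders,dgge_noise parameters of the
#'   gel-fingerprint generator: gradient positions per lane, bands per soil,
#'   lanes per group, Gaussian band width (in positions), intensity fold
#'   change of responder bands in spiked lanes, number of responder bands,
#'   additive noise sd.
#' @return an object of class `community_spec`.
#' @export
community_spec <- function(n_otus = 2000,
                           n_phyla = 15, n_classes = 30, n_orders = 60,
                           n_families = 100, n_genera = 180,
                           unclassified_fraction = 0.3,
                           meanlog = 0, sdlog = 1.5,
                           soils = c("Cambisol", "Luvisol"),
                           n_replicates = 3,
                           divergence = 0.8,
                           dirichlet_precision = 300,
                           depth_mean = 2500, depth_sd = 800, depth_floor = 200,
                           enriched = data.frame(target = c(0.20, 0.05),
                                                 scope = "both"),
                           n_diminished = 10,
                           diminished_share = 0.02,
                           diminished_scope = "both",
                           dgge_positions = 100, dgge_bands = 25,
                           dgge_replicates = 4, dgge_band_sd = 1.5,
                           dgge_effect_fold = 5, dgge_n_responders = 3,
                           dgge_noise = 0.02) {
  enriched <- as.data.frame(enriched, stringsAsFactors = FALSE)
  if (nrow(enriched) > 0) {
    stopifnot(all(enriched$target > 0), sum(enriched$target) < 1)
  }
  stopifnot(n_otus >= n_genera, n_genera >= n_families, n_families >= n_orders,
            n_orders >= n_classes, n_classes >= n_phyla,
            divergence >= 0, divergence <= 1,
            dirichlet_precision > 0, depth_floor >= 1,
            n_diminished >= 0, diminished_share > 0)
  spec <- as.list(environment())
  structure(spec, class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat("Synthetic community spec:\n")
  cat("  ", x$n_otus, " OTUs, ", x$n_genera, " genera, ", x$n_phyla, " phyla\n", sep = "")
  cat("  design: ", length(x$soils), " soils x {control, spiked} x ",
      x$n_replicates, " replicates\n", sep = "")
  cat("  depths ~ N(", x$depth_mean, ", ", x$depth_sd, "^2), floor ",
      x$depth_floor, "; Dirichlet precision ", x$dirichlet_precision, "\n", sep = "")
  cat("  planted: ", nrow(x$enriched), " enriched genera, ",
      x$n_diminished, " diminished OTUs\n", sep = "")
  invisible(x)
}

#' Generate a random six-rank taxonomy
#'
#' Builds a nested taxonomy (each genus under exactly one family, each family
#' under one order, and so on) and assigns each OTU to a genus; a fraction of
#' lineages is truncated to `"unclassified"` below a randomly chosen rank,
#' mimicking reads that a classifier could not place at fine ranks.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed; the output is deterministic given the seed.
#' @return data.frame of `spec$n_otus` six-rank lineages.
#' @export
generate_taxonomy <- function(spec, seed) {
  with_seed(seed, gen_taxonomy(spec))
}

gen_taxonomy <- function(spec) {
  nm <- function(rank, n) sprintf("%s_%03d", rank, seq_len(n))
  phyla    <- nm("Phylum", spec$n_phyla)
  classes  <- nm("Class", spec$n_classes)
  orders   <- nm("Order", spec$n_orders)
  families <- nm("Family", spec$n_families)
  genera   <- nm("Genus", spec$n_genera)
  # parent maps: ensure every parent has at least one child
  parent_of <- function(n_child, n_parent)
    c(seq_len(n_parent), sample.int(n_parent, n_child - n_parent, replace = TRUE))
  cls_phy <- parent_of(spec$n_classes, spec$n_phyla)
  ord_cls <- parent_of(spec$n_orders, spec$n_classes)
  fam_ord <- parent_of(spec$n_families, spec$n_orders)
  gen_fam <- parent_of(spec$n_genera, spec$n_families)
  g <- c(seq_len(spec$n_genera),
         sample.int(spec$n_genera, spec$n_otus - spec$n_genera, replace = TRUE))
  f <- gen_fam[g]; o <- fam_ord[f]; cl <- ord_cls[o]; ph <- cls_phy[cl]
  lin <- data.frame(domain = "Bacteria", phylum = phyla[ph], class = classes[cl],
                    order = orders[o], family = families[f], genus = genera[g],
                    stringsAsFactors = FALSE)
  # truncate a fraction of lineages below a random rank (mostly at genus)
  n_unc <- round(spec$unclassified_fraction * spec$n_otus)
  if (n_unc > 0) {
    rows <- sample.int(spec$n_otus, n_unc)
    cut_at <- sample(2:6, n_unc, replace = TRUE,
                     prob = c(0.05, 0.05, 0.10, 0.20, 0.60))
    for (i in seq_along(rows))
      lin[rows[i], seq.int(cut_at[i], 6L)] <- UNCLASSIFIED
  }
  lin
}

#' Generate true per-sample community profiles and ground truth
#'
#' Draws baseline lognormal OTU abundances, diverges a fraction of them per
#' soil, plants the responder genera (their spiked-group relative abundance
#' is rescaled to the configured target) and the diminished OTUs (assigned
#' `diminished_share` in controls; probability exactly 0 in the scoped
#' spiked groups), and renormalizes everything else.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed.
#' @return a list of class `community_profiles`: `profiles` (OTU x sample
#'   matrix of true proportions), `groups` (a [sample_groups()] table),
#'   `taxonomy` (lineage data.frame), and `truth` (list with `enriched`
#'   genera + targets, `diminished` OTU ids, and per-group profiles).
#' @export
generate_true_profiles <- function(spec, seed) {
  with_seed(seed, {
    tax <- gen_taxonomy(spec)
    otu_ids <- sprintf("OTU_%05d", seq_len(spec$n_otus))
    w <- stats::rlnorm(spec$n_otus, spec$meanlog, spec$sdlog)

    # pick responder genera once, common to all soils: classified genera with
    # a moderate baseline share (>= 0.2%) so a control population exists
    base_p <- w / sum(w)
    gshare <- tapply(base_p, tax$genus, sum)
    gshare <- gshare[names(gshare) != UNCLASSIFIED]
    cand <- names(gshare)[gshare >= 0.002 & gshare <= 0.05]
    if (nrow(spec$enriched) > length(cand))
      stop("too few candidate genera for the requested enriched set", call. = FALSE)
    resp_genera <- sample(cand, nrow(spec$enriched))

    # diminished OTUs: classified, outside responder genera
    dim_pool <- which(tax$genus != UNCLASSIFIED & !(tax$genus %in% resp_genera))
    dim_otus <- if (spec$n_diminished > 0)
      sort(sample(dim_pool, spec$n_diminished)) else integer(0)

    soils <- spec$soils
    group_profiles <- list()
    for (s in soils) {
      ws <- w
      nd <- round(spec$divergence * spec$n_otus)
      if (nd > 0) {
        idx <- sample.int(spec$n_otus, nd)
        ws[idx] <- stats::rlnorm(nd, spec$meanlog, spec$sdlog)
      }
      ctrl <- ws / sum(ws)
      # pin planted diminished OTUs at diminished_share each in the control
      if (length(dim_otus)) {
        rest <- setdiff(seq_len(spec$n_otus), dim_otus)
        ctrl[rest] <- ctrl[rest] / sum(ctrl[rest]) *
          (1 - spec$diminished_share * length(dim_otus))
        ctrl[dim_otus] <- spec$diminished_share
      }
      spik <- ctrl
      dim_here <- spec$diminished_scope %in% c("both", s)
      if (dim_here) spik[dim_otus] <- 0
      # responder genera scaled to their targets, scope permitting
      enr_rows <- which(spec$enriched$scope %in% c("both", s))
      enr_members <- integer(0); total_target <- 0
      for (r in enr_rows) {
        memb <- which(tax$genus == resp_genera[r])
        spik[memb] <- spik[memb] / sum(spik[memb]) * spec$enriched$target[r]
        enr_members <- c(enr_members, memb)
        total_target <- total_target + spec$enriched$target[r]
      }
      rest <- setdiff(seq_len(spec$n_otus), enr_members)
      spik[rest] <- spik[rest] / sum(spik[rest]) * (1 - total_target)
      group_profiles[[paste(s, "control", sep = ".")]] <- ctrl
      group_profiles[[paste(s, "spiked", sep = ".")]] <- spik
    }

    code <- function(s, tr) paste0(substr(s, 1, 1), if (tr == "control") "A" else "P")
    meta <- do.call(rbind, lapply(soils, function(s)
      do.call(rbind, lapply(c("control", "spiked"), function(tr)
        data.frame(sample_id = paste0(code(s, tr), seq_len(spec$n_replicates)),
                   soil = s, treatment = tr, replicate = seq_len(spec$n_replicates),
                   stringsAsFactors = FALSE)))))
    groups <- sample_groups(meta)
    profiles <- vapply(seq_len(nrow(groups)),
                       function(i) group_profiles[[groups$group[i]]],
                       numeric(spec$n_otus))
    dimnames(profiles) <- list(otu_ids, groups$sample_id)
    truth <- list(enriched = data.frame(genus = resp_genera,
                                        target = spec$enriched$target,
                                        scope = spec$enriched$scope,
                                        stringsAsFactors = FALSE),
                  diminished = otu_ids[dim_otus],
                  diminished_scope = spec$diminished_scope,
                  group_profiles = group_profiles)
    structure(list(profiles = profiles, groups = groups, taxonomy = tax,
                   truth = truth),
              class = "community_profiles")
  })
}

#' Draw sequencing reads from true community profiles
#'
#' Per sample, a read depth is drawn from a truncated normal (redraw until
#' `>= depth_floor`), the true profile is perturbed by a Dirichlet draw with
#' the configured precision (zeros stay exactly zero), and counts are drawn
#' multinomially. OTUs observed in no sample are dropped, as in a real OTU
#' report.
#'
#' @param profiles a `community_profiles` object from
#'   [generate_true_profiles()].
#' @param spec the [community_spec()] that generated it.
#' @param seed integer seed.
#' @return an [otu_table()].
#' @export
sample_reads <- function(profiles, spec, seed) {
  stopifnot(inherits(profiles, "community_profiles"))
  with_seed(seed, {
    p <- profiles$profiles
    n_samp <- ncol(p)
    counts <- matrix(0L, nrow(p), n_samp, dimnames = dimnames(p))
    for (j in seq_len(n_samp)) {
      depth <- 0
      while (depth < spec$depth_floor)
        depth <- round(stats::rnorm(1, spec$depth_mean, spec$depth_sd))
      prob <- p[, j]
      if (is.finite(spec$dirichlet_precision)) {
        nz <- prob > 0
        g <- stats::rgamma(sum(nz), shape = spec$dirichlet_precision * prob[nz])
        prob[nz] <- g / sum(g)
      }
      counts[, j] <- stats::rmultinom(1, depth, prob)[, 1]
    }
    seen <- rowSums(counts) > 0
    otu_table(counts[seen, , drop = FALSE],
              profiles$taxonomy[seen, , drop = FALSE],
              otu_ids = rownames(p)[seen],
              sample_ids = colnames(p))
  })
}

#' Generate gel-fingerprint lane profiles
#'
#' Emulates densitometric curves from a denaturing-gradient gel: each soil
#' has a fixed set of band positions with lognormal intensities, a band is a
#' Gaussian peak along the gradient, responder bands are `dgge_effect_fold`
#' times more intense in spiked lanes, and additive Gaussian noise is applied
#' (intensities floored at 0). With zero noise, replicate lanes are
#' identical.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed.
#' @return numeric matrix, gradient position x lane, with a
#'   [sample_groups()] table attached as attribute `groups`.
#' @export
generate_dgge_profiles <- function(spec, seed) {
  with_seed(seed, {
    pos <- seq_len(spec$dgge_positions)
    lanes <- list(); meta <- list()
    for (s in spec$soils) {
      centers <- sort(sample(seq(3, spec$dgge_positions - 2), spec$dgge_bands))
      inten <- stats::rlnorm(spec$dgge_bands, 0, 1)
      resp <- sample.int(spec$dgge_bands, spec$dgge_n_responders)
      curve <- function(int) {
        y <- numeric(spec$dgge_positions)
        for (b in seq_along(centers))
          y <- y + int[b] * exp(-((pos - centers[b])^2) / (2 * spec$dgge_band_sd^2))
        y
      }
      base <- curve(inten)
      eff <- inten; eff[resp] <- eff[resp] * spec$dgge_effect_fold
      spiked <- curve(eff)
      for (tr in c("control", "spiked")) {
        tmpl <- if (tr == "control") base else spiked
        for (r in seq_len(spec$dgge_replicates)) {
          lane <- tmpl + stats::rnorm(spec$dgge_positions, 0, spec$dgge_noise)
          lane[lane < 0] <- 0
          id <- paste0("D", substr(s, 1, 1), if (tr == "control") "A" else "P", r)
          lanes[[id]] <- lane
          meta[[id]] <- data.frame(sample_id = id, soil = s, treatment = tr,
                                   replicate = r, stringsAsFactors = FALSE)
        }
      }
    }
    m <- do.call(cbind, lanes)
    rownames(m) <- paste0("pos", pos)
    attr(m, "groups") <- sample_groups(do.call(rbind, meta))
    m
  })
}

#' Simulate a complete spiking experiment
#'
#' Convenience wrapper chaining [generate_true_profiles()], [sample_reads()]
#' and [generate_dgge_profiles()] under one seed.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed.
#' @return list with `otu` ([otu_table()]), `groups`, `taxonomy`, `truth`,
#'   and `dgge` (lane matrix).
#' @export
simulate_community <- function(spec = community_spec(), seed = 1) {
  prof <- generate_true_profiles(spec, seed)
  otu <- sample_reads(prof, spec, seed + 1000L)
  dgge <- generate_dgge_profiles(spec, seed + 2000L)
  list(otu = otu, groups = prof$groups, taxonomy = prof$taxonomy,
       truth = prof$truth, dgge = dgge)
}

#' Write a simulated experiment to disk
#'
#' Writes `otu_report.tsv`, `metadata.tsv`, `dgge.csv` and
#' `ground_truth.json` into a directory.
#'
#' @param sim result of [simulate_community()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_report(sim$otu, file.path(dir, "otu_report.tsv"))
  utils::write.table(as.data.frame(sim$groups)[c("sample_id", "soil", "treatment", "replicate")],
                     file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(sim$dgge, file.path(dir, "dgge.csv"))
  truth <- sim$truth[c("enriched", "diminished", "diminished_scope")]
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
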