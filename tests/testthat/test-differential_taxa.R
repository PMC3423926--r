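test_that("group GLM contrasts match a two-proportion oracle on clear effects", {
  g <- factor(rep(c("A", "B"), each = 3))
  n <- rep(1000, 6)
  y <- c(10, 11, 9, 50, 49, 51)
  fit <- fit_group_glm(y, n, g, family = "binomial")
  expect_false(fit$separation)
  ct <- tukey_contrasts(fit)
  expect_equal(nrow(ct), 1)
  expect_lt(ct$p, 0.05)
  expect_gt(ct$estimate, 0)      # B - A on the log-odds scale
  # Fisher oracle on pooled counts agrees in decision
  or <- fisher.test(matrix(c(150, 2850, 30, 2970), 2, byrow = TRUE))
  expect_lt(or$p.value, 0.05)
  # equal proportions: comfortably non-significant
  fit0 <- fit_group_glm(c(10, 12, 11, 10, 11, 12), n, g, family = "binomial")
  expect_gt(tukey_contrasts(fit0)$p, 0.5)
})

test_that("two-group Wald z-square equals the GLM chi-square", {
  g <- factor(rep(c("A", "B"), each = 3))
  y <- c(5, 8, 6, 14, 18, 13); n <- rep(500, 6)
  fit <- fit_group_glm(y, n, g, family = "binomial")
  ct <- tukey_contrasts(fit)
  wald <- summary(fit$fit)$coefficients["groupB", "z value"]
  expect_equal(ct$z^2, wald^2, tolerance = 1e-10)
})

test_that("separation triggers the exact-test fallback with a flag", {
  g <- factor(rep(c("A", "B"), each = 3))
  n <- rep(1000, 6)
  fit <- fit_group_glm(c(0, 0, 0, 20, 25, 22), n, g, family = "binomial")
  expect_true(fit$separation)
  ct <- tukey_contrasts(fit)
  expect_equal(ct$method, "fisher")
  or <- fisher.test(matrix(c(67, 2933, 0, 3000), 2, byrow = TRUE))
  expect_equal(ct$p, or$p.value)
  expect_gt(ct$estimate, 0)
  # all-zero taxon is a skip, not a test
  fit0 <- fit_group_glm(rep(0L, 6), n, g)
  expect_true(fit0$skip)
  expect_error(tukey_contrasts(fit0), "zero reads")
})

test_that("four groups yield six contrasts with adjusted >= unadjusted p", {
  set.seed(31)
  g <- factor(rep(c("A", "B", "C", "D"), each = 3))
  y <- rbinom(12, 800, 0.02); n <- rep(800, 12)
  y[1] <- max(y[1], 1)
  for (fam in c("quasibinomial", "binomial")) {
    fit <- fit_group_glm(y, n, g, family = fam)
    ct <- tukey_contrasts(fit)
    expect_equal(nrow(ct), 6)
    expect_true(all(ct$p_adj >= ct$p - 1e-12), info = fam)
    expect_true(all(ct$p >= 0 & ct$p_adj <= 1), info = fam)
    expect_equal(ct$direction, sign(ct$estimate), info = fam)
  }
})

test_that("overdispersion weighting keeps null rejection near nominal", {
  # beta-binomial replicates with icc rho: the plain binomial GLM rejects
  # far too often; the DM-weighted quasi model stays near 0.05
  rho <- 1 / 100
  set.seed(55)
  rej_quasi <- rej_plain <- logical(300)
  for (r in seq_len(300)) {
    n <- pmax(200, round(rnorm(6, 2500, 800)))
    p <- rbeta(6, 0.02 * (1 / rho - 1), 0.98 * (1 / rho - 1))
    y <- rbinom(6, n, p)
    g <- factor(rep(c("A", "B"), each = 3))
    if (all(y == 0)) next
    ctq <- tukey_contrasts(fit_group_glm(y, n, g, rho = rho))
    ctp <- tukey_contrasts(fit_group_glm(y, n, g, family = "binomial"))
    rej_quasi[r] <- ctq$p < 0.05
    rej_plain[r] <- ctp$p < 0.05
  }
  expect_lt(mean(rej_quasi), 0.10)
  expect_gt(mean(rej_plain), 0.20)
})

test_that("the icc estimator recovers the simulated overdispersion", {
  spec <- community_spec(n_otus = 400, n_phyla = 4, n_classes = 8,
                         n_orders = 12, n_families = 20, n_genera = 40,
                         dirichlet_precision = 100, n_diminished = 0)
  sim <- simulate_community(spec, seed = 17)
  rho_hat <- estimate_icc(sim$otu, sim$groups)
  expect_gt(rho_hat, 1 / 101 / 3)
  expect_lt(rho_hat, 3 / 101)
})

test_that("the taxonomy sweep tests every nonzero taxon and finds planted effects", {
  spec <- community_spec(n_otus = 300, n_phyla = 4, n_classes = 8,
                         n_orders = 12, n_families = 20, n_genera = 40,
                         n_diminished = 5)
  sim <- simulate_community(spec, seed = 23)
  sw <- sweep_taxonomy(sim$otu, sim$groups, ranks = c("phylum", "genus"))
  # bookkeeping: 6 contrasts per taxon, all nonzero taxa covered
  expect_equal(nrow(sw) %% 6, 0)
  n_taxa <- length(unique(paste(sw$rank, sw$taxon)))
  ph <- aggregate_at_rank(sim$otu, "phylum")
  ge <- aggregate_at_rank(sim$otu, "genus")
  expect_equal(n_taxa, nrow(ph$counts) + nrow(ge$counts))
  enr <- enriched_taxa(sw)
  for (g in sim$truth$enriched$genus)
    expect_equal(sum(enr$enriched$taxon == g & enr$enriched$rank == "genus"), 2,
                 info = g)
  expect_true(all(sim$truth$enriched$genus %in% enr$common$taxon))
  # alpha = 0 flags nothing
  expect_equal(nrow(enriched_taxa(sw, alpha = 0)$enriched), 0)
})

test_that("permuting group labels destroys the planted significance", {
  spec <- community_spec(n_otus = 300, n_phyla = 4, n_classes = 8,
                         n_orders = 12, n_families = 20, n_genera = 40,
                         n_diminished = 0)
  sim <- simulate_community(spec, seed = 29)
  perm_groups <- sim$groups
  set.seed(1)
  perm_groups$group <- sample(perm_groups$group)
  sw <- sweep_taxonomy(sim$otu, perm_groups, ranks = "genus")
  expect_gt(median(sw$p, na.rm = TRUE), 0.1)
})

test_that("diminished rules follow the worked fixture arithmetic", {
  # 20 OTUs detected in control -> average share 5%; rule1 needs >= 25%
  # and absence after spiking; rule2 needs >= 20% and significance
  lin <- data.frame(domain = "Bacteria", phylum = "P", class = "C",
                    order = "O", family = "F",
                    genus = paste0("G", 1:21))
  counts <- matrix(0L, 21, 4,
                   dimnames = list(paste0("o", 1:21),
                                   c("CA1", "CA2", "CP1", "CP2")))
  counts[1, ] <- c(150, 150, 0, 0)       # 30% of control, absent -> rule1
  counts[2, ] <- c(50, 50, 30, 28)       # 10% of control, present -> nothing
  counts[3:20, ] <- rep(c(16, 17, 30, 30), each = 18)
  counts[21, ] <- c(3, 4, 500, 520)      # enriched, never diminished
  x <- otu_table(counts, lin)
  meta <- sample_groups(data.frame(sample_id = colnames(counts),
                                   soil = "Cambisol",
                                   treatment = rep(c("control", "spiked"), each = 2),
                                   replicate = c(1, 2, 1, 2)))
  dm <- diminished_otus(x, meta)
  expect_true("o1" %in% dm$otu_id[dm$rule == "rule1"])
  expect_false("o2" %in% dm$otu_id)
  expect_false("o21" %in% dm$otu_id)
  r1 <- dm[dm$otu_id == "o1", ]
  expect_equal(r1$control_share_pct, 100 * 300 / sum(counts[, 1:2]))
  expect_gte(r1$fold_over_average, 5)
  # direction exclusivity: nothing is both enriched and diminished in one soil
  sw <- sweep_taxonomy(x, meta, ranks = "otu")
  enr <- enriched_taxa(sw)
  expect_length(intersect(paste(enr$enriched$soil, enr$enriched$taxon),
                          paste(dm$soil, dm$otu_id)), 0)
})

test_that("planted absent OTUs are recovered by rule 1", {
  # with 400 OTUs the control community holds ~280 detected OTUs, so the
  # 5x-average bar sits near 1.8%; plant well clear of it
  spec <- community_spec(n_otus = 400, n_phyla = 4, n_classes = 8,
                         n_orders = 12, n_families = 20, n_genera = 40,
                         n_diminished = 6, diminished_share = 0.04)
  sim <- simulate_community(spec, seed = 37)
  dm <- diminished_otus(sim$otu, sim$groups)
  for (s in c("Cambisol", "Luvisol")) {
    rec <- sim$truth$diminished %in% dm$otu_id[dm$soil == s & dm$rule == "rule1"]
    expect_gte(sum(rec), 5)
  }
})

test_that("a soil without both treatments is a usage error", {
  x <- random_table(n_otus = 40, n_samples = 4, seed = 2)
  meta <- sample_groups(data.frame(sample_id = x$sample_ids,
                                   soil = "Cambisol", treatment = "control",
                                   replicate = 1:4))
  expect_error(diminished_otus(x, meta), "lacks")
})
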