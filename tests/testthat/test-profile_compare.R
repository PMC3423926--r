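test_that("Pearson similarity matches the textbook formula and its limits", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  s <- pearson_similarity(m)
  expect_equal(s["a", "b"], 100)
  expect_equal(s["a", "c"], -100)
  expect_equal(diag(unclass(s)), c(a = 100, b = 100, c = 100))
  # brute-force r from sums on random profiles
  set.seed(42)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("p", "q", "r")))
  s <- pearson_similarity(x)
  brute_r <- function(u, v) {
    n <- length(u)
    (n * sum(u * v) - sum(u) * sum(v)) /
      sqrt((n * sum(u^2) - sum(u)^2) * (n * sum(v^2) - sum(v)^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(unclass(s)[i, j], 100 * brute_r(x[, i], x[, j]),
                 tolerance = 1e-9)
})

test_that("similarity is invariant to per-sample positive rescaling", {
  set.seed(7)
  x <- matrix(rpois(80, 5) + 1, 20, 4)
  s1 <- pearson_similarity(x)
  x2 <- sweep(x, 2, c(0.3, 7, 1, 100), "*")
  s2 <- pearson_similarity(x2)
  expect_lt(max(abs(unclass(s1) - unclass(s2))), 1e-9)
  xc <- x; xc[, 2] <- 5
  colnames(xc) <- c("w", "bad", "y", "z")
  expect_error(pearson_similarity(xc), "degenerate.*bad")
})

test_that("UPGMA reproduces the hand-worked three-sample case", {
  # dissimilarities AB=2, AC=8, BC=8 -> merge {A,B} at height 1, then C at 4
  s <- 100 - rbind(c(0, 2, 8), c(2, 0, 8), c(8, 8, 0))
  dimnames(s) <- list(c("A", "B", "C"), c("A", "B", "C"))
  tr <- upgma(similarity_matrix(s))
  expect_equal(tr$clusters[[1]], c("A", "B"))
  expect_equal(tr$height[1], 1)
  expect_equal(tr$height[2], 4)
  # equidistant points merge at a single height
  s2 <- 100 - matrix(6, 3, 3, dimnames = dimnames(s)); diag(s2) <- 100
  tr2 <- upgma(similarity_matrix(s2))
  expect_equal(tr2$height, c(3, 3))
  # lexicographic tie-break: {A,B} merges before {A,C}/{B,C}
  expect_equal(tr2$clusters[[1]], c("A", "B"))
})

test_that("UPGMA heights agree with hclust average linkage and are ultrametric", {
  set.seed(12)
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 40), 40, 8, dimnames = list(NULL, letters[1:8]))
    s <- pearson_similarity(x)
    tr <- upgma(s)
    hc <- stats::hclust(stats::as.dist(100 - unclass(s)), method = "average")
    expect_equal(sort(tr$height), sort(hc$height / 2), tolerance = 1e-10)
    expect_true(all(diff(tr$height) >= -1e-10))   # monotone merge heights
    # ultrametric property via cophenetic distances: max over any triple's
    # two largest pairwise distances are equal
    cp <- as.matrix(stats::cophenetic(as.hclust(tr)))
    for (t in 1:20) {
      ijk <- sample(8, 3)
      dd <- sort(c(cp[ijk[1], ijk[2]], cp[ijk[1], ijk[3]], cp[ijk[2], ijk[3]]))
      expect_equal(dd[2], dd[3], tolerance = 1e-9)
    }
  }
})

test_that("bootstrap support is 100 for a duplicated sample pair and bounded", {
  set.seed(3)
  base <- matrix(rpois(200, 8), 50, 4)
  m <- cbind(t1 = base[, 1], t2 = base[, 1], u = base[, 2] + 40 * rpois(50, 2),
             v = base[, 3] + 40 * rpois(50, 3))
  tr <- bootstrap_support(m, n_boot = 100, seed = 5)
  k <- which(vapply(tr$clusters, identical, logical(1), c("t1", "t2")))
  expect_length(k, 1)
  expect_equal(tr$support[k], 100)
  expect_true(all(tr$support >= 0 & tr$support <= 100))
  tr2 <- bootstrap_support(m, n_boot = 100, seed = 5)
  expect_identical(tr$support, tr2$support)
})

test_that("d equals the stated hand example and a brute-force pair loop", {
  # within pairs {90, 80}, four between pairs all 60 -> d = 85 - 60 = 25
  s <- matrix(60, 4, 4, dimnames = list(c("a1", "a2", "b1", "b2"),
                                        c("a1", "a2", "b1", "b2")))
  s["a1", "a2"] <- s["a2", "a1"] <- 90
  s["b1", "b2"] <- s["b2", "b1"] <- 80
  diag(s) <- 100
  d <- dissimilarity_d(similarity_matrix(s), list(c("a1", "a2"), c("b1", "b2")))
  expect_equal(d$d, 25)
  expect_equal(d$mean_within, 85)
  expect_equal(d$mean_between, 60)
  # identical profiles -> d = 0
  m <- matrix(rep(c(1, 5, 2, 7), 4), 4, 4,
              dimnames = list(NULL, c("x1", "x2", "y1", "y2")))
  expect_equal(dissimilarity_d(pearson_similarity(m),
                               list(c("x1", "x2"), c("y1", "y2")))$d, 0)

  brute_d <- function(s, g1, g2) {
    w <- c(); b <- c()
    ids <- c(g1, g2)
    for (i in ids) for (j in ids) {
      if (i >= j) next
      if ((i %in% g1) == (j %in% g1)) w <- c(w, s[i, j]) else b <- c(b, s[i, j])
    }
    mean(w) - mean(b)
  }
  set.seed(9)
  for (rep in 1:10) {
    x <- matrix(rnorm(8 * 30), 30, 8, dimnames = list(NULL, letters[1:8]))
    s <- unclass(pearson_similarity(x))
    g1 <- sample(letters[1:8], 4); g2 <- setdiff(letters[1:8], g1)
    expect_lt(abs(dissimilarity_d(pearson_similarity(x), list(g1, g2))$d -
                    brute_d(s, g1, g2)), 1e-12)
    # permuting sample order leaves d unchanged
    perm <- sample(8)
    expect_equal(dissimilarity_d(pearson_similarity(x[, perm]),
                                 list(g1, g2))$d,
                 brute_d(s, g1, g2), tolerance = 1e-12)
  }
})

test_that("exhaustive permutation matches an independent enumeration", {
  set.seed(21)
  x <- matrix(rnorm(8 * 25), 25, 8, dimnames = list(NULL, letters[1:8]))
  g1 <- letters[1:4]; g2 <- letters[5:8]
  pt <- permutation_test_d(x, list(g1, g2))
  expect_equal(pt$mode, "exhaustive")
  expect_equal(pt$n_partitions, 35)
  # independent generator: all combinations containing sample "a"
  s <- unclass(pearson_similarity(x))
  combs <- utils::combn(letters[2:8], 3)
  dvals <- apply(combs, 2, function(cc) {
    gA <- c("a", cc)
    dissimilarity_d(pearson_similarity(x), list(gA, setdiff(letters[1:8], gA)))$d
  })
  expect_equal(sort(pt$null_d), sort(dvals), tolerance = 1e-12)
  expect_equal(pt$p, mean(dvals >= pt$observed$d - 1e-12))
})

test_that("maximal separation yields the minimum attainable p", {
  # two tight, far-apart groups of 4: observed partition dominates all others
  set.seed(2)
  base1 <- rnorm(30); base2 <- rnorm(30) * -1
  x <- cbind(matrix(rep(base1, 4), 30) + rnorm(120, 0, 0.01),
             matrix(rep(base2, 4), 30) + rnorm(120, 0, 0.01))
  colnames(x) <- letters[1:8]
  pt <- permutation_test_d(x, list(letters[1:4], letters[5:8]))
  expect_equal(pt$p, 1 / 35)
  # 2 vs 2: three partitions, p can never undercut 1/3
  y <- x[, c(1, 2, 5, 6)]
  pt2 <- permutation_test_d(y, list(c("a", "b"), c("e", "f")))
  expect_equal(pt2$n_partitions, 3)
  expect_equal(pt2$p, 1 / 3)
})

test_that("Monte-Carlo mode engages beyond the cap and is seed-stable", {
  set.seed(4)
  x <- matrix(rnorm(8 * 20), 20, 8, dimnames = list(NULL, letters[1:8]))
  pt <- permutation_test_d(x, list(letters[1:4], letters[5:8]), n_perm = 200,
                           seed = 11, cap = 10)
  expect_equal(pt$mode, "monte_carlo")
  expect_length(pt$null_d, 200)
  expect_gte(pt$p, 1 / 201)
  pt2 <- permutation_test_d(x, list(letters[1:4], letters[5:8]), n_perm = 200,
                            seed = 11, cap = 10)
  expect_identical(pt$p, pt2$p)
  expect_error(permutation_test_d(x, list("a", letters[5:8])), "at least 2")
})
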