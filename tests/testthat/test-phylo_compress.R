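test_that("pairwise distances match closed forms and handle gaps pairwise", {
  a <- c(x = "ACGTACGTAC", y = "ACGTACGTAC", z = "ACGTACGTAA")
  d <- pairwise_distance(a, "p_distance")
  expect_equal(d["x", "y"], 0)
  expect_equal(d["x", "z"], 0.1)
  # JC69 closed form: p = 0.3 -> d = -(3/4) ln(0.6)
  b <- c(p = paste(rep("A", 10), collapse = ""),
         q = paste(c(rep("C", 3), rep("A", 7)), collapse = ""))
  expect_equal(pairwise_distance(b, "JC69")["p", "q"], -0.75 * log(0.6),
               tolerance = 1e-12)
  # gap/N columns are dropped per pair: only 8 comparable sites, 1 mismatch
  g <- c(u = "AC-TACGTNC", v = "ACGTACGTAG")
  expect_equal(pairwise_distance(g, "p_distance")["u", "v"], 1 / 8)
  # saturated pairs and empty overlap are explicit errors naming the pair
  s <- c(m = "AAAAAAAA", n = "CCCCCCCC")
  expect_error(pairwise_distance(s, "JC69"), "JC69 distance undefined")
  e <- c(m = "AAAA----", n = "----CCCC")
  expect_error(pairwise_distance(e), "no comparable sites")
})

test_that("p-distance is symmetric, bounded, and the JC69 small-p limit matches", {
  set.seed(15)
  for (rep in 1:5) {
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), "")
    names(seqs) <- paste0("s", 1:4)
    d <- pairwise_distance(seqs, "p_distance")
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
  }
  # one mismatch in a long alignment: JC69/p ratio -> 1
  long <- c(a = paste(rep("A", 20000), collapse = ""),
            b = paste(c("C", rep("A", 19999)), collapse = ""))
  p <- pairwise_distance(long, "p_distance")["a", "b"]
  j <- pairwise_distance(long, "JC69")["a", "b"]
  expect_lt(abs(j / p - 1), 1e-4)
})

test_that("distances agree with the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(44)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T", "-"), 80, TRUE,
                 prob = c(0.23, 0.23, 0.23, 0.23, 0.08)), collapse = ""), "")
  names(seqs) <- paste0("t", 1:6)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  aln <- read_alignment(f)
  ours <- pairwise_distance(aln, "p_distance")
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(aln), model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
})

test_that("neighbor joining reconstructs an additive matrix exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)): AB=3 AC=5 AD=6 BC=6 BD=7 CD=7
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighbor_joining(D)
  # topology AB|CD
  parts <- ape::prop.part(ape::unroot(tr))
  sets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(list(c("A", "B")) %in% sets || list(c("C", "D")) %in% sets)
  # path lengths reproduce the input matrix exactly
  path <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_lt(max(abs(path - D)), 1e-9)
  # three leaves: solve the star equations by hand
  D3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D3["a", "b"] <- 3; D3["a", "c"] <- 4; D3["b", "c"] <- 5
  D3 <- D3 + t(D3)
  tr3 <- neighbor_joining(D3)
  el <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(el[["a"]], 1)   # (3 + 4 - 5) / 2
  expect_equal(el[["b"]], 2)
  expect_equal(el[["c"]], 3)
})

test_that("leaf order permutation yields an isomorphic NJ tree", {
  set.seed(5)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:6)
  d <- pairwise_distance(seqs, "p_distance")
  t1 <- neighbor_joining(d)
  perm <- sample(6)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
})

test_that("bootstrap supports are bounded, seed-stable and certain for twins", {
  set.seed(20)
  core <- sample(c("A", "C", "G", "T"), 120, TRUE)
  mut <- function(x, k) { i <- sample(length(x), k); x[i] <- sample(c("A", "C", "G", "T"), k, TRUE); x }
  seqs <- c(a = paste(core, collapse = ""),
            b = paste(core, collapse = ""),
            c = paste(mut(core, 45), collapse = ""),
            d = paste(mut(core, 50), collapse = ""),
            e = paste(mut(core, 55), collapse = ""))
  bt <- bootstrap_tree(seqs, n_boot = 60, seed = 9)
  expect_true(all(bt$node.label >= 0 & bt$node.label <= 100))
  bt2 <- bootstrap_tree(seqs, n_boot = 60, seed = 9)
  expect_identical(bt$node.label, bt2$node.label)
  # the a/b cherry is invariant under column resampling
  mrca <- ape::getMRCA(bt, c("a", "b"))
  expect_equal(unname(bt$node.label[mrca - length(bt$tip.label)]), 100)
})

test_that("branch compression collapses exactly the tight clades", {
  # 5-leaf rooted tree with one tight cherry (0.01 branches)
  tr <- ape::read.tree(text = "(((a:0.01,b:0.01):0.2,c:0.25):0.1,(d:0.3,e:0.35):0.05);")
  cp <- compress_branches(tr, 0.03)
  expect_true("a (+1)" %in% cp$tip.label)
  expect_false("b" %in% cp$tip.label)
  expect_setequal(setdiff(cp$tip.label, "a (+1)"), c("c", "d", "e"))
  members <- attr(cp, "members")
  expect_equal(sum(members), 5)
  expect_equal(unname(members[["a (+1)"]]), 2)
  # the compressed leaf sits where the cherry root was: its new terminal
  # edge equals the cherry stem (0.2)
  i <- match("a (+1)", cp$tip.label)
  expect_equal(cp$edge.length[cp$edge[, 2] == i], 0.2)
  # threshold 0: nothing collapses (no zero-length clades here)
  cp0 <- compress_branches(tr, 0)
  expect_setequal(cp0$tip.label, c("a", "b", "c", "d", "e"))
  # threshold at/above tree height: a single node carrying all leaves
  cpall <- compress_branches(tr, 10)
  expect_equal(length(cpall$tip.label), 1)
  expect_equal(cpall$tip.label, "a (+4)")
  expect_equal(sum(attr(cpall, "members")), 5)
})

test_that("compression conserves membership on random ultrametric trees", {
  set.seed(33)
  for (rep in 1:5) {
    tr <- ape::rcoal(10)
    for (th in c(0, 0.2, 0.5, 1)) {
      cp <- compress_branches(tr, th)
      expect_equal(sum(attr(cp, "members")), 10)
    }
  }
})

test_that("alignment reader enforces equal lengths and unique ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_alignment(f), "not aligned")
  write_fasta(tiny_alignment(), f)
  m <- read_alignment(f)
  expect_equal(dim(m), c(5L, 20L))
  expect_setequal(rownames(m), names(tiny_alignment()))
})
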