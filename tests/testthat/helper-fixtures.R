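# Small fixtures built in code, shared across test files.

# a 5-OTU x 4-sample table with two phyla, an unclassified genus under two
# different families, and hand-checkable counts
tiny_table <- function() {
  lin <- data.frame(
    domain = "Bacteria",
    phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
               "Actinobacteria", "Actinobacteria"),
    class  = c("Alphaproteobacteria", "Alphaproteobacteria",
               "Betaproteobacteria", "Actinobacteridae", "Actinobacteridae"),
    order  = c("Sphingomonadales", "Sphingomonadales", "Burkholderiales",
               "Frankineae", "Frankineae"),
    family = c("Sphingomonadaceae", "Sphingomonadaceae", "Comamonadaceae",
               "FamA", "FamB"),
    genus  = c("Sphingomonas", "Sphingomonas", "unclassified",
               "unclassified", "unclassified"),
    stringsAsFactors = FALSE)
  counts <- matrix(c(3, 1, 0, 2,
                     4, 0, 1, 1,
                     2, 5, 3, 0,
                     1, 2, 0, 4,
                     0, 2, 6, 3),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("otu", 1:5), c("s1", "s2", "s3", "s4")))
  otu_table(counts, lin)
}

# random valid table for property-style tests
random_table <- function(n_otus = 30, n_samples = 6, seed = 1) {
  set.seed(seed)
  # nested taxonomy: each genus under one family, family under one order, ...
  g <- sample(1:8, n_otus, TRUE)
  f <- ceiling(g / 2); o <- ceiling(f / 1.5); cl <- ceiling(o / 2)
  ph <- ceiling(cl / 1.5)
  lin <- data.frame(domain = "Bacteria",
                    phylum = paste0("P", ph), class = paste0("C", cl),
                    order = paste0("O", o), family = paste0("F", f),
                    genus = paste0("G", g), stringsAsFactors = FALSE)
  repeat {
    counts <- matrix(rpois(n_otus * n_samples, 3), n_otus, n_samples)
    if (all(rowSums(counts) > 0) && all(colSums(counts) > 0)) break
  }
  dimnames(counts) <- list(sprintf("OTU%03d", seq_len(n_otus)),
                           sprintf("S%d", seq_len(n_samples)))
  otu_table(counts, lin)
}

# two-soil metadata for n replicates per group, matching generator sample ids
four_group_meta <- function(n_rep = 3, soils = c("Cambisol", "Luvisol")) {
  sample_groups(do.call(rbind, lapply(soils, function(s)
    do.call(rbind, lapply(c("control", "spiked"), function(tr)
      data.frame(sample_id = paste0(substr(s, 1, 1),
                                    if (tr == "control") "A" else "P",
                                    seq_len(n_rep)),
                 soil = s, treatment = tr, replicate = seq_len(n_rep)))))))
}

# small aligned sequences with a known structure: a/b identical-ish cherry,
# c/d a second cherry, e an outgroup
tiny_alignment <- function() {
  c(a = "ACGTACGTACGTACGTACGT",
    b = "ACGTACGTACGTACGTACGA",
    c = "ACGTTCGAACGTACCTACGT",
    d = "ACGTTCGAACGTACCTTCGT",
    e = "ACGAACGATGGTACGTTGCA")
}

write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}
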