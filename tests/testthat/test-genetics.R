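truth8 <- data.frame(individual_id = sprintf("i%02d", 1:8),
                     phylogroup = rep(c("PG1", "PG2"), each = 4),
                     stringsAsFactors = FALSE)

test_that("concatenation books the published partition arithmetic", {
  parts <- simulate_gene_partitions(truth8, seed = 4)
  cat3 <- concatenate_partitions(parts, min_genes = 2L)
  expect_equal(cat3$total_length, 1603L)
  expect_equal(cat3$boundaries$end - cat3$boundaries$start + 1L,
               c(627L, 461L, 515L))
  expect_true(all(nchar(cat3$sequences) == 1603L))
})

test_that("the minimum-gene rule excludes and pads correctly", {
  parts <- simulate_gene_partitions(truth8, seed = 4)
  # i01 keeps only COI; i02 keeps COI + 16S
  parts$`16S`$sequences <- parts$`16S`$sequences[-1]
  parts$ANT$sequences <- parts$ANT$sequences[-(1:2)]
  cat2 <- concatenate_partitions(parts, min_genes = 2L)
  expect_false("i01" %in% cat2$ids)
  expect_equal(cat2$excluded$individual_id, "i01")
  expect_equal(cat2$excluded$n_genes, 1L)
  expect_true("i02" %in% cat2$ids)
  ant <- cat2$boundaries[cat2$boundaries$gene == "ANT", ]
  padded <- substr(cat2$sequences[["i02"]], ant$start, ant$end)
  expect_equal(padded, strrep("?", 515L))
  expect_equal(cat2$total_length, 1603L)

  # single partition, min_genes = 1: identity concatenation
  solo <- concatenate_partitions(list(parts$COI), min_genes = 1L)
  expect_identical(solo$sequences[["i03"]], parts$COI$sequences[["i03"]])

  ragged <- parts$COI
  ragged$sequences[1] <- substr(ragged$sequences[1], 1, 100)
  expect_error(gene_partition("COI", ragged$sequences), "ragged")
})

test_that("SNP ambiguity coding follows the IUPAC table", {
  expect_equal(code_ambiguity("ACGT", data.frame(position = 2, base1 = "A",
                                                 base2 = "G")), "ARGT")
  expect_equal(code_ambiguity("ACGT", data.frame(position = integer(),
                                                 base1 = character(),
                                                 base2 = character())), "ACGT")
  pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"),
                c("A", "T"), c("C", "G"))
  codes <- vapply(pairs, function(p) {
    substr(code_ambiguity("AAAA", data.frame(position = 1, base1 = p[1],
                                             base2 = p[2])), 1, 1)
  }, character(1))
  expect_setequal(codes, c("R", "Y", "M", "K", "W", "S"))
  # order of the two bases does not matter
  expect_equal(code_ambiguity("ACGT", data.frame(position = 2, base1 = "G",
                                                 base2 = "A")), "ARGT")
  expect_error(code_ambiguity("ACGT", data.frame(position = 1, base1 = "A",
                                                 base2 = "A")), "identical bases")
  once <- code_ambiguity("ACGT", data.frame(position = 2, base1 = "A", base2 = "G"))
  expect_error(code_ambiguity(once, data.frame(position = 2, base1 = "A",
                                               base2 = "G")), "refusing to re-code")
})

test_that("posterior-sample accounting matches grid enumeration", {
  acc <- posterior_sample_accounting(
    tree_sample_plan(8, 20000000, 1000, burnin_frac = 0.1,
                     include_generation_zero = TRUE))
  expect_equal(acc$retained, 144008)

  none <- posterior_sample_accounting(
    tree_sample_plan(3, 1000, 10, burnin_frac = 0,
                     include_generation_zero = TRUE))
  expect_equal(none$retained, 3 * 101)

  small <- posterior_sample_accounting(
    tree_sample_plan(2, 10, 1, burnin_frac = 0.1,
                     include_generation_zero = TRUE))
  expect_equal(small$retained, 20)

  set.seed(8)
  for (k in 1:20) {
    freq <- sample(c(1, 2, 5, 10), 1)
    gens <- freq * sample(10:200, 1)
    runs <- sample(1:8, 1)
    burn <- runif(1, 0, 0.5)
    inc0 <- sample(c(TRUE, FALSE), 1)
    plan <- tree_sample_plan(runs, gens, freq, burn, inc0)
    expect_equal(posterior_sample_accounting(plan)$retained,
                 posterior_enumeration_oracle(runs, gens, freq, burn, inc0))
  }
  expect_error(tree_sample_plan(1, 100, 3), "does not divide")
})

test_that("distance-threshold phylogroup assignment clusters by divergence", {
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, 200, replace = TRUE)
  mutate_at <- function(s, pos) {
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1), "")
    s
  }
  blockB <- mutate_at(anc, sample(200, 40))  # 20% divergent
  seqs <- c(a1 = paste(anc, collapse = ""), a2 = paste(anc, collapse = ""),
            b1 = paste(blockB, collapse = ""), b2 = paste(blockB, collapse = ""))
  part <- gene_partition("16S", seqs, coding = FALSE)
  pa <- assign_phylogroups(part, "distance_threshold", threshold = 0.05)
  expect_equal(unname(pa$assignment[c("a1", "a2")]), c("PG1", "PG1"))
  expect_equal(unname(pa$assignment[c("b1", "b2")]), c("PG2", "PG2"))

  # identical sequences: one phylogroup; threshold >= 1: one group; 0: split by identity
  same <- gene_partition("16S", c(x = seqs[["a1"]], y = seqs[["a1"]]), coding = FALSE)
  expect_equal(length(unique(assign_phylogroups(same, threshold = 0)$assignment)), 1L)
  expect_equal(length(unique(assign_phylogroups(part, threshold = 1)$assignment)), 1L)
  expect_equal(length(unique(assign_phylogroups(part, threshold = 0)$assignment)), 2L)

  # cross-check p-distance against ape on unambiguous sequences
  dn <- ape::dist.dna(ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), ""))),
                      model = "raw", pairwise.deletion = TRUE)
  expect_equal(unname(p_dist_test(part, "a1", "b1")),
               as.matrix(dn)["a1", "b1"], tolerance = 1e-12)

  # provided mode validates coverage and passes labels through
  lab <- c(a1 = "PGx", a2 = "PGx", b1 = "PGy", b2 = "PGy")
  expect_identical(assign_phylogroups(part, "provided", labels = lab)$assignment,
                   lab)
  expect_error(assign_phylogroups(part, "provided", labels = lab[-1]),
               "labels missing")
  expect_error(assign_phylogroups(part, "distance_threshold", min_shared = 500L),
               "share only")
})

test_that("tree tips are annotated and Newick round-trips preserve topology", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "tree.nwk")
  writeLines("(A,(B,C));", path)
  tree <- read_tree(path)
  pa <- phylogroup_assignment(c(A = "PG1", B = "PG2", C = "PG2"))
  ann <- annotate_tree_tips(tree, pa)
  expect_length(ann$tip_phylogroup, 3L)
  expect_length(ann$unmatched, 0L)

  ann2 <- annotate_tree_tips(tree, phylogroup_assignment(c(A = "PG1", B = "PG2")))
  expect_equal(ann2$unmatched, "C")

  set.seed(2)
  rt <- ape::rtree(12)
  p2 <- file.path(dir, "rt.nwk")
  ape::write.tree(rt, p2)
  back <- read_tree(p2)
  expect_equal(ape::dist.topo(ape::unroot(rt), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  writeLines("((A,B,;", file.path(dir, "bad.nwk"))
  expect_error(read_tree(file.path(dir, "bad.nwk")), "malformed Newick|error")
})

test_that("coding partitions reject internal stop codons", {
  good <- c(x = "ATGGCTGCTAAA", y = "ATGGCTGCTAAA")
  expect_silent(gene_partition("ANT", good))
  bad <- c(x = "ATGTAAGCTAAA", y = "ATGGCTGCTAAA")  # TAA at codon 2
  expect_error(gene_partition("ANT", bad), "internal stop codon")
  # TGA is Trp in the invertebrate mitochondrial code: fine for COI, fatal for ANT
  tga <- c(x = "ATGTGAGCTAAA", y = "ATGGCTGCTAAA")
  expect_silent(gene_partition("COI", tga))
  expect_error(gene_partition("ANT", tga), "internal stop codon")
})
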