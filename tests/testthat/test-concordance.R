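test_that("crosstab counts co-scored individuals and reports exclusions", {
  ids <- paste0("i", 1:10)
  a <- setNames(rep(c("G1", "G2"), each = 5), ids)
  b <- setNames(rep(c("P1", "P2"), each = 5), ids)
  ct <- crosstab(a, b)
  expect_equal(unname(diag(ct$counts)), c(5, 5))
  expect_equal(sum(ct$counts) - sum(diag(ct$counts)), 0)
  expect_equal(ct$n, 10L)

  a2 <- c(x = "G1", y = "G1", z = "G2")
  b2 <- c(x = "P1", y = "P2", z = "P2")
  ct2 <- crosstab(a2, b2)
  expect_equal(unname(ct2$counts), matrix(c(1, 0, 1, 1), 2, 2))

  ct3 <- crosstab(c(a2, w = "G9"), b2)
  expect_equal(ct3$excluded_a, "w")
  expect_equal(ct3$n, 3L)
  expect_error(crosstab(c(q = "G1"), b2), "no individual")
})

test_that("mapping cardinality generalizes the one/two/several breakdown", {
  ids <- paste0("i", 1:10)
  diag_ct <- crosstab(setNames(rep(c("G1", "G2"), 5), ids),
                      setNames(rep(c("P1", "P2"), 5), ids))
  mc <- mapping_cardinality(diag_ct)
  expect_equal(unname(mc$fractions), c(1, 0, 0))

  ct2 <- crosstab(c(x = "G1", y = "G1", z = "G2"),
                  c(x = "P1", y = "P2", z = "P2"))
  mc2 <- mapping_cardinality(ct2)
  expect_equal(unname(mc2$fractions), c(0.5, 0.5, 0))
  expect_equal(sum(mc2$fractions), 1)

  # lumped-nuclear scenario: nuclear clusters span several phylogroups
  cohort <- simulate_cohort(scenario_preset("lumped_nuclear", seed = 2))
  nuc <- cohort_truth_labels(cohort, "nuclear_cluster")
  pg <- cohort_truth_labels(cohort, "phylogroup")
  mc3 <- mapping_cardinality(crosstab(nuc, pg))
  expect_gt(mc3$fractions[["two"]], 0)
  expect_equal(sum(mc3$fractions), 1)
})

test_that("adjusted Rand index matches the all-pairs oracle", {
  ids <- paste0("i", 1:6)
  expect_equal(adjusted_rand(setNames(c(1, 1, 1, 2, 2, 2), ids),
                             setNames(c(5, 5, 5, 9, 9, 9), ids)), 1)
  a <- setNames(c("A", "A", "A", "B", "B", "B"), ids)
  b <- setNames(c("A", "A", "B", "A", "B", "B"), ids)
  expect_equal(adjusted_rand(a, b), ari_pair_oracle(a, b), tolerance = 1e-12)

  set.seed(17)
  for (k in 1:50) {
    n <- sample(3:8, 1)
    idn <- paste0("x", seq_len(n))
    pa <- setNames(sample(3, n, replace = TRUE), idn)
    pb <- setNames(sample(3, n, replace = TRUE), idn)
    if (length(unique(pa)) == 1 && length(unique(pb)) == 1) next
    expect_equal(adjusted_rand(pa, pb), ari_pair_oracle(pa, pb),
                 tolerance = 1e-12)
  }
  # both partitions trivial: identical up to relabelling
  expect_equal(adjusted_rand(setNames(rep("A", 4), paste0("i", 1:4)),
                             setNames(rep("Z", 4), paste0("i", 1:4))), 1)
})

test_that("ARI has null expectation zero under random relabelling", {
  set.seed(23)
  ids <- paste0("i", 1:30)
  a <- setNames(rep(c("A", "B", "C"), each = 10), ids)
  aris <- replicate(1000, {
    adjusted_rand(a, setNames(sample(unname(a)), ids))
  })
  se <- sd(aris) / sqrt(length(aris))
  expect_lt(abs(mean(aris)), 3 * se)
})

test_that("exception screen flags and adjudicates the preset disagreement patterns", {
  conc <- simulate_cohort(scenario_preset("concordant", seed = 6))
  st <- run_chemo_pipeline(conc)
  phylo <- phylogroup_assignment(cohort_truth_labels(conc, "phylogroup"))
  ex <- exception_screen(st$groups, phylo, st$pca)
  expect_equal(nrow(ex), 0L)

  conv <- simulate_cohort(scenario_preset("convergent_chemistry", seed = 6))
  stc <- run_chemo_pipeline(conv)
  exc <- exception_screen(stc$groups,
                          phylogroup_assignment(cohort_truth_labels(conv, "phylogroup")),
                          stc$pca)
  shared <- exc[exc$type == "shared_chemistry", ]
  expect_equal(nrow(shared), 1L)
  expect_equal(shared$status, "convergent")
  expect_setequal(strsplit(shared$members, ",")[[1]], c("PG24", "PG29"))

  spl <- simulate_cohort(scenario_preset("split_phylogroup", seed = 6))
  sts <- run_chemo_pipeline(spl)
  exs <- exception_screen(sts$groups,
                          phylogroup_assignment(cohort_truth_labels(spl, "phylogroup")),
                          sts$pca)
  split_rows <- exs[exs$type == "split_phylogroup", ]
  expect_equal(nrow(split_rows), 1L)
  expect_equal(split_rows$unit, "PG1")
  expect_equal(split_rows$status, "not-differentiated")

  # PCA missing an adjudicated individual is an error
  pca_short <- sts$pca
  keep <- pca_short$ids != "SA_01"
  pca_short$ids <- pca_short$ids[keep]
  pca_short$scores <- pca_short$scores[keep, , drop = FALSE]
  expect_error(exception_screen(sts$groups,
                                phylogroup_assignment(cohort_truth_labels(spl, "phylogroup")),
                                pca_short), "lacks scores")
})

test_that("tree context separates convergent sharing from single-origin candidates", {
  # two phylogroups forming a clade (adjacent) vs straddling the tree
  scores <- rbind(matrix(0, 4, 2), matrix(0, 4, 2))
  rownames(scores) <- paste0("i", 1:8)
  colnames(scores) <- c("PC1", "PC2")
  chem <- structure(list(threshold = 0.3,
                         assignment = setNames(rep("CG1", 8), rownames(scores)),
                         groups = list(CG1 = rownames(scores))),
                    class = "chemo_groups")
  gen <- setNames(rep(c("PG1", "PG2"), each = 4), rownames(scores))
  tree_adj <- ape::read.tree(text = "((((i1,i2),(i3,i4)),((i5,i6),(i7,i8))),(o1,o2));")
  ex_adj <- exception_screen(chem, gen, fake_pca(scores), tree = tree_adj)
  expect_equal(ex_adj$status, "single-origin-candidate")

  tree_far <- ape::read.tree(text = "(((i1,i2),(o1,o2)),((i3,i4),((i5,i6),(i7,i8))));")
  ex_far <- exception_screen(chem, gen, fake_pca(scores), tree = tree_far)
  expect_equal(ex_far$status, "unresolved-shared")

  ex_notree <- exception_screen(chem, gen, fake_pca(scores))
  expect_equal(ex_notree$status, "unresolved-shared")
})

test_that("the concordance report assembles crosstab, cardinality, ARI and exceptions", {
  cohort <- simulate_cohort(scenario_preset("concordant", seed = 12))
  st <- run_chemo_pipeline(cohort)
  phylo <- phylogroup_assignment(cohort_truth_labels(cohort, "phylogroup"))
  rep <- concordance_report(st$groups, phylo, st$pca)
  expect_equal(rep$agreement_index, 1)
  expect_equal(unname(rep$cardinality_phylo_to_chemo$fractions), c(1, 0, 0))
  expect_equal(rep$crosstab$n, nrow(cohort$truth))
  expect_equal(nrow(rep$exceptions), 0L)
  path <- file.path(withr::local_tempdir(), "report.json")
  write_concordance(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$agreement_index, 1)
})
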