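make_spec <- function(id, values) {
  structure(list(individual_id = id, bin_labels = seq(200L, length.out = length(values)),
                 values = values, config = binning_config()),
            class = "tcm_spectrum")
}

test_that("correlation similarity is exact, symmetric and size-independent", {
  set.seed(1)
  a <- c(1:20, rep(0, 280))
  b <- sample(a)
  specs <- list(make_spec("A", a), make_spec("B", b), make_spec("C", 3.7 * a))
  sim <- correlation_matrix(specs)
  expect_identical(diag(sim$r), c(A = 1, B = 1, C = 1))
  expect_identical(sim$r, t(sim$r))
  # size independence: a scaled copy correlates perfectly
  expect_equal(sim$r["A", "C"], 1, tolerance = 1e-12)
  # longhand covariance / sd*sd oracle
  longhand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(sim$r["A", "B"], longhand, tolerance = 1e-12)

  expect_error(correlation_matrix(list(make_spec("A", a),
                                       make_spec("flat", rep(2, 300)))),
               "zero-variance spectrum of individual 'flat'")
})

test_that("dendrograms reproduce hand-computed average-linkage merges", {
  r <- matrix(c(1, 0.95, 0.1,
                0.95, 1, 0.1,
                0.1, 0.1, 1), 3, 3)
  sim <- sim_from_matrix(r, c("A", "B", "C"))
  dend <- build_dendrogram(sim, "average")
  expect_equal(dend$height, c(0.05, 0.9), tolerance = 1e-12)

  groups <- cut_groups(dend, 0.3)
  expect_equal(sort(groups$groups[[groups$assignment[["A"]]]]), c("A", "B"))
  expect_length(groups$groups, 2L)

  # two individuals: one merge at 1 - r
  d2 <- build_dendrogram(sim_from_matrix(matrix(c(1, .6, .6, 1), 2),
                                         c("x", "y")))
  expect_equal(d2$height, 0.4, tolerance = 1e-12)
})

test_that("merge heights and memberships are invariant to input order", {
  set.seed(7)
  m <- matrix(rnorm(8 * 300), 8)
  rownames(m) <- paste0("id", 1:8)
  sim <- correlation_matrix(m)
  dend <- build_dendrogram(sim)
  groups <- cut_groups(dend, 0.1)
  perm <- sample(8)
  sim_p <- correlation_matrix(m[perm, ])
  dend_p <- build_dendrogram(sim_p)
  groups_p <- cut_groups(dend_p, 0.1)
  expect_equal(dend$height, dend_p$height, tolerance = 1e-12)
  for (id in rownames(m)) {
    same <- names(groups$assignment)[groups$assignment == groups$assignment[[id]]]
    same_p <- names(groups_p$assignment)[groups_p$assignment == groups_p$assignment[[id]]]
    expect_setequal(same, same_p)
  }
})

test_that("all linkages agree with stats::hclust on random tie-free matrices", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 50), n)
    rownames(m) <- paste0("s", seq_len(n))
    sim <- correlation_matrix(m)
    d <- stats::as.dist(1 - sim$r)
    for (linkage in c("average", "complete", "single")) {
      mine <- build_dendrogram(sim, linkage)
      ref <- stats::hclust(d, method = linkage)
      expect_equal(mine$height, ref$height, tolerance = 1e-10)
      for (k in seq_len(n - 1)) {
        expect_equal(unname(stats::cutree(mine, k))[order(rownames(m))] |>
                       (\(x) as.integer(factor(x, levels = unique(x))))(),
                     unname(stats::cutree(ref, k))[order(rownames(m))] |>
                       (\(x) as.integer(factor(x, levels = unique(x))))())
      }
    }
  }
})

test_that("cutting obeys the threshold semantics and is monotone", {
  set.seed(3)
  m <- matrix(rnorm(6 * 40), 6)
  rownames(m) <- paste0("s", 1:6)
  sim <- correlation_matrix(m)
  dend <- build_dendrogram(sim)
  expect_length(cut_groups(dend, -1)$groups, 1L)
  expect_length(cut_groups(dend, max(sim$r[upper.tri(sim$r)]) + 1e-9)$groups, 6L)
  counts <- vapply(seq(-1, 1, by = 0.05),
                   function(t) length(cut_groups(dend, t)$groups), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # a cut exactly at a merge height keeps that merge together
  t_exact <- 1 - dend$height[1]
  n_at <- length(cut_groups(dend, t_exact)$groups)
  expect_equal(n_at, 5L)
})

test_that("PCA is centred, variance-conserving and matches an eigen oracle", {
  set.seed(5)
  base <- matrix(rnorm(2 * 10), 10)
  m <- cbind(base %*% matrix(c(3, 1, 1, 2), 2), matrix(0, 10, 4))
  rownames(m) <- paste0("s", 1:10)
  p <- suppressWarnings(tcm_pca(m, n_components = 10L))
  expect_equal(sum(p$explained_variance), p$total_variance, tolerance = 1e-10)
  expect_equal(p$total_variance, sum(apply(m, 2, var)), tolerance = 1e-10)
  # eigen oracle for the dominant direction, up to sign
  ev <- eigen(stats::cov(m))
  v1 <- ev$vectors[, 1]
  got <- p$loadings[, 1]
  expect_equal(abs(sum(v1 * got)), 1, tolerance = 1e-8)
  # full reconstruction of the centred matrix
  centred <- scale(m, center = TRUE, scale = FALSE)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - centred)), 1e-8)
  # degenerate: identical rows
  same <- matrix(1, 3, 5); rownames(same) <- c("a", "b", "c")
  p0 <- tcm_pca(same, 2)
  expect_true(all(abs(p0$scores) < 1e-12))
  expect_equal(sum(p0$explained_variance), 0)
  # truncation warns
  expect_warning(tcm_pca(m, n_components = 20L), "truncated")
})

test_that("group separation classifies coincident and distant clusters correctly", {
  scores <- rbind(c(0, 0), c(0, 0))
  rownames(scores) <- c("a", "b")
  colnames(scores) <- c("PC1", "PC2")
  sep <- group_separation(fake_pca(scores), c(a = "G1", b = "G2"))
  expect_equal(sep$ratio, 0)
  expect_equal(sep$status, "overlapping")

  set.seed(2)
  s2 <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40), 20) + 10)
  rownames(s2) <- paste0("i", 1:40)
  colnames(s2) <- c("PC1", "PC2")
  labels <- setNames(rep(c("G1", "G2"), each = 20), rownames(s2))
  sep2 <- group_separation(fake_pca(s2), labels)
  d_hand <- sqrt(sum((colMeans(s2[1:20, ]) - colMeans(s2[21:40, ]))^2))
  expect_equal(sep2$centroid_distance, d_hand, tolerance = 1e-12)
  expect_gt(sep2$ratio, 5)
  expect_equal(sep2$status, "separated")
})

test_that("per-individual rescaling changes no chemometric output", {
  design <- mini_design(noise_sd = 1, abundance_cv = 0.3, n_per_chemotype = 4L,
                        seed = 9)
  specs <- extract_tcm_cohort(simulate_cohort(design))
  set.seed(21)
  scaled <- lapply(specs, function(s) { s$values <- s$values * runif(1, 0.2, 5); s })
  expect_equal(correlation_matrix(specs)$r, correlation_matrix(scaled)$r,
               tolerance = 1e-10)
  g1 <- cut_groups(build_dendrogram(correlation_matrix(specs)), 0.3)
  g2 <- cut_groups(build_dendrogram(correlation_matrix(scaled)), 0.3)
  expect_identical(g1$assignment, g2$assignment)
})
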