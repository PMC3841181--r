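# Small builders and independent oracles shared across the test files.

make_run <- function(id = "r1", rt, mz, intensity, scan_index = NULL) {
  df <- data.frame(rt = rt, mz = mz, intensity = intensity)
  if (!is.null(scan_index)) df$scan_index <- scan_index
  mass_spec_run(id, df)
}

# One compound, one or two fragments, small scan grid: fast fixture.
mini_design <- function(noise_sd = 0, baseline_level = 0, baseline_drift = 0,
                        abundance_cv = 0, compound_cv = 0,
                        rt_window = c(0, 17), scan_interval = 0.1,
                        fragment_mz = c(250L, 251L),
                        fragment_intensity = c(1, 0.5),
                        rt_center = 8, rt_sigma = 0.5, n_per_chemotype = 2L,
                        seed = 1L) {
  cmp <- compound_spec("cmp1", rt_center, rt_sigma, fragment_mz,
                       fragment_intensity, base_abundance = 1000)
  cohort_design(chemotype_spec("CT1", list(cmp)),
                n_per_chemotype = n_per_chemotype,
                abundance_cv = abundance_cv, compound_cv = compound_cv,
                baseline_level = baseline_level, baseline_drift = baseline_drift,
                noise_sd = noise_sd, rt_window = rt_window,
                scan_interval = scan_interval, seed = seed)
}

# Closed-form signal of a noiseless baseline-free compound on the scan grid.
gaussian_sum_oracle <- function(rts, rt_center, rt_sigma, amplitude,
                                rt_start = 2, rt_end = 17) {
  keep <- rts >= rt_start & rts <= rt_end
  sum(amplitude * exp(-0.5 * ((rts[keep] - rt_center) / rt_sigma)^2))
}

# Similarity matrix object built directly from a correlation matrix.
sim_from_matrix <- function(r, ids = rownames(r)) {
  dimnames(r) <- list(ids, ids)
  structure(list(ids = ids, r = r, method = "pearson"),
            class = "similarity_matrix")
}

# PCA-shaped object with prescribed scores, for geometry tests.
fake_pca <- function(scores, ids = rownames(scores)) {
  structure(list(ids = ids, scores = scores,
                 loadings = diag(ncol(scores)),
                 explained_variance = rep(1, ncol(scores)),
                 total_variance = ncol(scores)),
            class = "tcm_pca")
}

# Brute-force adjusted Rand index by enumerating all unordered pairs.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  total <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / total
  maximum <- ((s11 + s10) + (s11 + s01)) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (s11 - expected) / (maximum - expected)
}

# Enumerates the sampling grid of an MCMC plan and applies per-run burn-in.
posterior_enumeration_oracle <- function(n_runs, n_generations, sample_freq,
                                         burnin_frac, include_zero) {
  gens <- seq(if (include_zero) 0 else sample_freq, n_generations,
              by = sample_freq)
  discard <- floor(burnin_frac * length(gens))
  n_runs * length(gens[seq_along(gens) > discard])
}

# Hand p-distance between two sequences of a partition (A/C/G/T sites only).
p_dist_test <- function(partition, id1, id2) {
  a <- strsplit(partition$sequences[[id1]], "")[[1]]
  b <- strsplit(partition$sequences[[id2]], "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  mean(a[ok] != b[ok])
}

cohort_truth_labels <- function(cohort, col = "chemotype_id") {
  stats::setNames(cohort$truth[[col]], cohort$truth$individual_id)
}

run_chemo_pipeline <- function(cohort, threshold = 0.3, n_components = 2) {
  specs <- extract_tcm_cohort(cohort)
  sim <- correlation_matrix(specs)
  dend <- build_dendrogram(sim)
  list(specs = specs, sim = sim, dend = dend,
       groups = cut_groups(dend, threshold),
       pca = tcm_pca(specs, n_components))
}
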