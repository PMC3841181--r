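test_that("default extraction yields one bin per nominal mass, 200-499", {
  run <- make_run(rt = 5, mz = 250.4, intensity = 10)
  spec <- extract_tcm(run, binning_config())
  expect_length(spec$values, 300L)
  expect_equal(spec$bin_labels, 200:499)
  expect_equal(unname(spec$values[spec$bin_labels == 250]), 10)
  expect_true(all(spec$values[spec$bin_labels != 250] == 0))
})

test_that("binning sums within half-open unit bins and drops out-of-range masses", {
  run <- make_run(rt = c(5, 6, 5, 5), mz = c(250.4, 250.9, 199.9, 500.0),
                  intensity = c(10, 7, 99, 99))
  spec <- extract_tcm(run, binning_config())
  expect_equal(unname(spec$values[spec$bin_labels == 250]), 17)
  expect_equal(sum(spec$values), 17)  # 199.9 and 500.0 contribute nothing
})

test_that("peaks outside the RT window or mass range never influence the output", {
  base <- data.frame(rt = c(5, 9), mz = c(250.5, 300.5), intensity = c(10, 4))
  injected <- rbind(base,
                    data.frame(rt = c(1.5, 17.5), mz = c(250.5, 300.5),
                               intensity = c(500, 500)),
                    data.frame(rt = c(5, 9), mz = c(150.0, 510.0),
                               intensity = c(500, 500)))
  s0 <- extract_tcm(mass_spec_run("x", base), binning_config())
  s1 <- extract_tcm(mass_spec_run("x", injected), binning_config())
  expect_identical(s0$values, s1$values)
  expect_error(extract_tcm(make_run(rt = 1, mz = 250, intensity = 1),
                           binning_config()), "no scans in RT window")
})

test_that("per-channel minimum baseline correction removes a constant offset", {
  rts <- seq(2, 10, by = 0.5)
  signal <- exp(-0.5 * ((rts - 6) / 0.5)^2) * 100
  run <- make_run(rt = rep(rts, 2),
                  mz = rep(c(250.4, 300.4), each = length(rts)),
                  intensity = c(signal + 5, rep(5, length(rts))))
  corrected <- baseline_correct(run, binning_config())
  ch <- floor(corrected$peaks$mz)
  mins <- tapply(corrected$peaks$intensity, ch, min)
  expect_true(all(mins == 0))
  got <- corrected$peaks$intensity[ch == 250]
  expect_equal(got, signal + 5 - min(signal + 5), tolerance = 1e-12)

  zero <- make_run(rt = rts, mz = rep(250.4, length(rts)),
                   intensity = rep(0, length(rts)))
  expect_identical(baseline_correct(zero, binning_config())$peaks$intensity,
                   zero$peaks$intensity)
})

test_that("rolling-minimum baseline matches a brute-force running minimum", {
  design <- mini_design(baseline_level = 20, baseline_drift = 10,
                        scan_interval = 0.1)
  run <- simulate_run("x", design$chemotypes[[1]], design)
  cfg <- binning_config(baseline_method = "rolling_min", rolling_window = 1)
  corrected <- baseline_correct(run, cfg)

  # independent oracle on one signal-free channel region: brute-force window minima
  pk <- run$peaks
  in_win <- pk$rt >= cfg$rt_start & pk$rt <= cfg$rt_end
  for (channel in c(250L, 251L)) {
    sel <- in_win & floor(pk$mz) == channel
    rt <- pk$rt[sel]; y <- pk$intensity[sel]
    base <- sapply(rt, function(t) min(y[abs(rt - t) <= 0.5]))
    expect_equal(corrected$peaks$intensity[corrected$peaks$rt %in% rt &
                                             floor(corrected$peaks$mz) == channel],
                 pmax(y - base, 0), tolerance = 1e-12)
  }
  # residual baseline after correction is bounded by drift x window
  far <- corrected$peaks$rt > 12 & corrected$peaks$rt <= 17  # beyond the peak
  expect_true(all(corrected$peaks$intensity[far] <= 10 * 1 + 1e-9))
})

test_that("normalization modes behave as documented", {
  run <- make_run(rt = c(5, 5, 5), mz = c(200.1, 201.1, 202.1),
                  intensity = c(2, 2, 4))
  spec <- extract_tcm(run, binning_config())
  expect_identical(normalize_tcm(spec, "none"), spec)
  u <- normalize_tcm(spec, "unit_sum")
  expect_equal(unname(u$values[1:4]), c(0.25, 0.25, 0.5, 0))
  m <- normalize_tcm(spec, "unit_max")
  expect_equal(max(m$values), 1)
  spec$values[] <- 0
  expect_error(normalize_tcm(spec, "unit_sum"), "all-zero")
})

test_that("aggregate sum vs mean are proportional per run and correlation-equivalent", {
  design <- mini_design(noise_sd = 2, abundance_cv = 0.2, seed = 3,
                        n_per_chemotype = 4L)
  cohort <- simulate_cohort(design)
  cfg_sum <- binning_config(aggregate = "sum")
  cfg_mean <- binning_config(aggregate = "mean")
  for (run in cohort$runs) {
    s <- extract_tcm(run, cfg_sum)$values
    m <- extract_tcm(run, cfg_mean)$values
    nz <- s > 0 & m > 0
    ratio <- (s / m)[nz]
    # every channel is recorded in every scan, so the scan count is shared
    expect_lt(max(ratio) - min(ratio), 1e-9)
  }
  specs_sum <- lapply(cohort$runs, extract_tcm, config = cfg_sum)
  specs_mean <- lapply(cohort$runs, extract_tcm, config = cfg_mean)
  expect_equal(correlation_matrix(specs_sum)$r, correlation_matrix(specs_mean)$r,
               tolerance = 1e-12)
})

test_that("TCM tables round-trip through TSV", {
  design <- mini_design(n_per_chemotype = 3L, abundance_cv = 0.2, seed = 2)
  specs <- extract_tcm_cohort(simulate_cohort(design))
  path <- file.path(withr::local_tempdir(), "tcm.tsv")
  write_tcm(specs, path)
  back <- read_tcm(path)
  expect_equal(names(back), names(specs))
  for (id in names(specs)) {
    expect_equal(back[[id]]$values, unname(specs[[id]]$values), tolerance = 1e-12)
    expect_equal(back[[id]]$bin_labels, specs[[id]]$bin_labels)
  }
})
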