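#' Binning configuration for TCM extraction
#'
#' Defaults follow the published analysis: nominal masses 200-499 (300
#' half-open unit bins `[m, m+1)`), retention-time window 2-17 min, summed
#' aggregation, and a parameter-free per-channel-minimum baseline. The figure
#' captions' 2.5-17 min window is available by setting `rt_start = 2.5`.
#'
#' @param mz_low,mz_high integer nominal-mass bounds; bins are
#'   `[mz_low, mz_high)`, so the number of bins is `mz_high - mz_low`.
#' @param rt_start,rt_end retention-time window, minutes (inclusive).
#' @param aggregate `"sum"` (add all peak intensities per bin) or `"mean"`
#'   (divide each bin by the number of scans contributing to it).
#' @param baseline_method `"per_bin_min"` (subtract each channel's minimum
#'   over the RT window) or `"rolling_min"` (subtract a centred running
#'   minimum).
#' @param rolling_window width of the running-minimum window, minutes.
#' @return an object of class `binning_config`.
#' @export
binning_config <- function(mz_low = 200L, mz_high = 500L,
                           rt_start = 2.0, rt_end = 17.0,
                           aggregate = c("sum", "mean"),
                           baseline_method = c("per_bin_min", "rolling_min"),
                           rolling_window = 1.0) {
  aggregate <- match.arg(aggregate)
  baseline_method <- match.arg(baseline_method)
  mz_low <- as.integer(mz_low); mz_high <- as.integer(mz_high)
  if (!is_count(mz_low + 1) || !is_count(mz_high) || mz_low >= mz_high) {
    stopf("need integer mz_low < mz_high")
  }
  if (!is_number(rt_start) || !is_number(rt_end) || rt_start >= rt_end) {
    stopf("need rt_start < rt_end")
  }
  if (!is_number(rolling_window) || rolling_window <= 0) {
    stopf("rolling_window must be > 0")
  }
  structure(list(mz_low = mz_low, mz_high = mz_high,
                 rt_start = rt_start, rt_end = rt_end,
                 aggregate = aggregate, baseline_method = baseline_method,
                 rolling_window = rolling_window),
            class = "binning_config")
}

#' @export
print.binning_config <- function(x, ...) {
  cat(sprintf("Binning: m/z [%d, %d) (%d bins), RT %.4g-%.4g min, aggregate=%s, baseline=%s\n",
              x$mz_low, x$mz_high, x$mz_high - x$mz_low,
              x$rt_start, x$rt_end, x$aggregate, x$baseline_method))
  invisible(x)
}

nominal_mass <- function(mz) as.integer(floor(mz))

#' Baseline-correct a run per nominal-mass channel
#'
#' Within the configured RT window, each nominal-mass channel has a baseline
#' estimate subtracted and the result clipped at zero. `per_bin_min` uses the
#' channel's minimum recorded intensity over the window; `rolling_min` uses a
#' centred running minimum of width `rolling_window`. Baselines are estimated
#' from the scans where the channel was recorded (centroided data carry no
#' explicit zeros). Scans outside the RT window are left untouched.
#'
#' @param run a [mass_spec_run()].
#' @param config a [binning_config()].
#' @return a baseline-corrected [mass_spec_run()].
#' @export
baseline_correct <- function(run, config = binning_config()) {
  stopifnot(inherits(run, "mass_spec_run"), inherits(config, "binning_config"))
  pk <- run$peaks
  in_win <- pk$rt >= config$rt_start & pk$rt <= config$rt_end
  if (!any(in_win)) {
    stopf("run '%s': no scans in RT window [%g, %g]",
          run$individual_id, config$rt_start, config$rt_end)
  }
  sub <- pk[in_win, ]
  chan <- nominal_mass(sub$mz)
  if (config$baseline_method == "per_bin_min") {
    base <- stats::ave(sub$intensity, chan, FUN = min)
  } else {
    half <- config$rolling_window / 2
    base <- numeric(nrow(sub))
    for (ch in unique(chan)) {
      idx <- which(chan == ch)
      rt <- sub$rt[idx]
      y <- sub$intensity[idx]
      base[idx] <- vapply(rt, function(t) min(y[rt >= t - half & rt <= t + half]),
                          numeric(1))
    }
  }
  sub$intensity <- pmax(sub$intensity - base, 0)
  pk[in_win, ] <- sub
  out <- run
  out$peaks <- pk
  out
}

#' Extract the total chromatogram mass (TCM) spectrum
#'
#' The chemical fingerprint of one individual: every peak whose retention
#' time lies in `[rt_start, rt_end]` and whose nominal mass `floor(m/z)` lies
#' in `[mz_low, mz_high)` contributes its intensity to that nominal-mass bin.
#' With `aggregate = "sum"` contributions are added; with `"mean"` each bin is
#' divided by the number of scans contributing to it. Under the default
#' configuration this yields a 300-value spectrum over nominal masses 200-499.
#'
#' @param run a [mass_spec_run()], normally baseline-corrected first with
#'   [baseline_correct()].
#' @param config a [binning_config()].
#' @return an object of class `tcm_spectrum`: list with `individual_id`,
#'   `bin_labels` (integer nominal masses), `values` (nonnegative intensity
#'   per bin) and `config`.
#' @export
extract_tcm <- function(run, config = binning_config()) {
  stopifnot(inherits(run, "mass_spec_run"), inherits(config, "binning_config"))
  pk <- run$peaks
  in_win <- pk$rt >= config$rt_start & pk$rt <= config$rt_end
  if (!any(in_win)) {
    stopf("run '%s': no scans in RT window [%g, %g]",
          run$individual_id, config$rt_start, config$rt_end)
  }
  pk <- pk[in_win, ]
  bin <- nominal_mass(pk$mz)
  keep <- bin >= config$mz_low & bin < config$mz_high
  pk <- pk[keep, ]
  bin <- bin[keep]
  labels <- seq.int(config$mz_low, config$mz_high - 1L)
  values <- numeric(length(labels))
  if (nrow(pk)) {
    idx <- bin - config$mz_low + 1L
    sums <- vapply(split(pk$intensity, idx), sum, numeric(1))
    values[as.integer(names(sums))] <- sums
    if (config$aggregate == "mean") {
      counts <- vapply(split(pk$scan_index, idx),
                       function(s) length(unique(s)), numeric(1))
      pos <- as.integer(names(counts))
      values[pos] <- values[pos] / counts
    }
  }
  structure(list(individual_id = run$individual_id,
                 bin_labels = labels, values = values, config = config),
            class = "tcm_spectrum")
}

#' @export
print.tcm_spectrum <- function(x, ...) {
  nz <- sum(x$values > 0)
  cat(sprintf("TCM spectrum '%s': %d bins (m/z %d-%d), %d nonzero, total %.6g\n",
              x$individual_id, length(x$values), x$bin_labels[1],
              x$bin_labels[length(x$bin_labels)], nz, sum(x$values)))
  invisible(x)
}

#' @export
plot.tcm_spectrum <- function(x, ...) {
  graphics::plot(x$bin_labels, x$values, type = "h", xlab = "nominal m/z",
                 ylab = "intensity", main = x$individual_id, ...)
  invisible(x)
}

#' Rescale a TCM spectrum
#'
#' The correlation similarity used downstream compares spectral shapes and is
#' unaffected by per-individual rescaling; normalization is offered for
#' plotting and export.
#'
#' @param spec a [extract_tcm()] result.
#' @param mode `"none"` (identity), `"unit_sum"` (divide by the total) or
#'   `"unit_max"` (divide by the maximum).
#' @return a `tcm_spectrum`.
#' @export
normalize_tcm <- function(spec, mode = c("none", "unit_sum", "unit_max")) {
  stopifnot(inherits(spec, "tcm_spectrum"))
  mode <- match.arg(mode)
  if (mode == "none") return(spec)
  denom <- if (mode == "unit_sum") sum(spec$values) else max(spec$values)
  if (denom <= 0) stopf("spectrum '%s' is all-zero; cannot normalize", spec$individual_id)
  spec$values <- spec$values / denom
  spec
}

#' Stack TCM spectra into an individuals-by-bins matrix
#'
#' @param specs list of `tcm_spectrum` objects sharing identical bin labels.
#' @return numeric matrix, rownames = individual ids, colnames = nominal
#'   masses.
#' @export
tcm_matrix <- function(specs) {
  if (inherits(specs, "tcm_spectrum")) specs <- list(specs)
  if (length(specs) == 0L) stopf("no spectra supplied")
  ok <- vapply(specs, inherits, logical(1), "tcm_spectrum")
  if (!all(ok)) stopf("all elements must be tcm_spectrum objects")
  labels <- specs[[1]]$bin_labels
  same <- vapply(specs, function(s) identical(s$bin_labels, labels), logical(1))
  if (!all(same)) stopf("spectra have differing bin labels; re-extract with one config")
  ids <- vapply(specs, `[[`, character(1), "individual_id")
  if (anyDuplicated(ids)) stopf("duplicated individual ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- do.call(rbind, lapply(specs, `[[`, "values"))
  dimnames(m) <- list(ids, as.character(labels))
  m
}

#' Run the per-individual fingerprint stage on a set of runs
#'
#' Convenience wrapper: baseline-correct every run, then extract its TCM
#' spectrum.
#'
#' @param runs list of [mass_spec_run()] objects.
#' @param config a [binning_config()].
#' @return named list of `tcm_spectrum` objects.
#' @export
extract_tcm_cohort <- function(runs, config = binning_config()) {
  if (inherits(runs, "simulated_cohort")) runs <- runs$runs
  specs <- lapply(runs, function(r) extract_tcm(baseline_correct(r, config), config))
  names(specs) <- vapply(specs, `[[`, character(1), "individual_id")
  specs
}

#' Write TCM spectra as TSV
#'
#' One row per individual: `individual_id` followed by one column per nominal
#' mass. A provenance comment records the package version and configuration
#' fingerprint.
#'
#' @param specs list of `tcm_spectrum` objects.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_tcm <- function(specs, path) {
  m <- tcm_matrix(specs)
  df <- data.frame(individual_id = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("individual_id", paste0("mz", colnames(m)))
  write_stamped_tsv(df, path, config_fingerprint(unclass(specs[[1]]$config)))
}

#' Read TCM spectra written by [write_tcm()]
#'
#' @param path TSV path.
#' @param config the [binning_config()] to attach (defaults inferred from the
#'   column labels).
#' @return named list of `tcm_spectrum` objects.
#' @export
read_tcm <- function(path, config = NULL) {
  df <- read_stamped_tsv(path)
  if (names(df)[1] != "individual_id") stopf("'%s' is not a TCM table", path)
  labels <- as.integer(sub("^mz", "", names(df)[-1]))
  if (any(is.na(labels))) stopf("'%s' has malformed mass columns", path)
  if (is.null(config)) {
    config <- binning_config(mz_low = min(labels), mz_high = max(labels) + 1L)
  }
  specs <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(individual_id = df$individual_id[i], bin_labels = labels,
                   values = as.numeric(df[i, -1]), config = config),
              class = "tcm_spectrum")
  })
  names(specs) <- df$individual_id
  specs
}
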