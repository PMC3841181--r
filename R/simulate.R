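#' Describe one chromatographic compound
#'
#' A compound is modelled as a Gaussian elution peak carrying a fixed fragment
#' pattern: a set of nominal (integer) m/z channels with relative intensities.
#' Relative intensities are rescaled so the strongest fragment is 1.
#'
#' @param compound_id character identifier, unique within a chemotype.
#' @param rt_center elution apex, minutes.
#' @param rt_sigma Gaussian peak width (standard deviation), minutes; > 0.
#' @param fragment_mz integer nominal masses in `[200, 500)`.
#' @param fragment_intensity relative intensities in `(0, 1]`, one per fragment.
#' @param base_abundance peak-apex intensity scale, arbitrary detector units.
#' @return an object of class `compound_spec`.
#' @export
compound_spec <- function(compound_id, rt_center, rt_sigma,
                          fragment_mz, fragment_intensity,
                          base_abundance = 1e6) {
  if (!is_string(compound_id)) stopf("compound_id must be a non-empty string")
  if (!is_number(rt_center) || rt_center < 0) stopf("rt_center must be a nonnegative number")
  if (!is_number(rt_sigma) || rt_sigma <= 0) stopf("rt_sigma must be > 0")
  fragment_mz <- as.integer(fragment_mz)
  if (length(fragment_mz) == 0L) stopf("compound '%s' needs at least one fragment", compound_id)
  if (any(fragment_mz < 200L | fragment_mz >= 500L)) {
    stopf("compound '%s': fragment m/z must lie in [200, 500)", compound_id)
  }
  if (length(fragment_intensity) != length(fragment_mz)) {
    stopf("compound '%s': fragment_intensity length mismatch", compound_id)
  }
  if (any(!is.finite(fragment_intensity)) || any(fragment_intensity <= 0)) {
    stopf("compound '%s': relative intensities must be finite and > 0", compound_id)
  }
  fragment_intensity <- fragment_intensity / max(fragment_intensity)
  if (!is_number(base_abundance) || base_abundance <= 0) {
    stopf("base_abundance must be > 0")
  }
  structure(list(compound_id = compound_id, rt_center = rt_center,
                 rt_sigma = rt_sigma, fragment_mz = fragment_mz,
                 fragment_intensity = fragment_intensity,
                 base_abundance = base_abundance),
            class = "compound_spec")
}

#' Describe a chemotype as a weighted suite of compounds
#'
#' @param chemotype_id character identifier, unique within a cohort design.
#' @param compounds list of [compound_spec()] objects (at least one).
#' @param proportions strictly positive per-compound relative abundance
#'   weights; recycled default 1.
#' @return an object of class `chemotype_spec`.
#' @export
chemotype_spec <- function(chemotype_id, compounds,
                           proportions = rep(1, length(compounds))) {
  if (!is_string(chemotype_id)) stopf("chemotype_id must be a non-empty string")
  if (inherits(compounds, "compound_spec")) compounds <- list(compounds)
  if (length(compounds) == 0L) stopf("chemotype '%s' needs at least one compound", chemotype_id)
  ok <- vapply(compounds, inherits, logical(1), "compound_spec")
  if (!all(ok)) stopf("all compounds must be compound_spec objects")
  ids <- vapply(compounds, `[[`, character(1), "compound_id")
  if (anyDuplicated(ids)) stopf("chemotype '%s': duplicated compound ids", chemotype_id)
  if (length(proportions) != length(compounds) ||
      any(!is.finite(proportions)) || any(proportions <= 0)) {
    stopf("chemotype '%s': proportions must be strictly positive, one per compound",
          chemotype_id)
  }
  names(compounds) <- ids
  structure(list(chemotype_id = chemotype_id, compounds = compounds,
                 proportions = stats::setNames(as.numeric(proportions), ids)),
            class = "chemotype_spec")
}

#' Map chemotypes to genetic labels
#'
#' Encodes the genetic side of a simulated cohort: each chemotype maps to one
#' or more mitochondrial phylogroup labels (individuals are assigned
#' round-robin when several), and phylogroups optionally map to nuclear
#' cluster labels (several phylogroups may share one nuclear label, emulating
#' the lower resolution of slow nuclear markers).
#'
#' @param chemotype_to_phylogroup named list: chemotype id -> character vector
#'   of phylogroup labels.
#' @param phylogroup_to_nuclear optional named character vector: phylogroup ->
#'   nuclear cluster label.
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(chemotype_to_phylogroup, phylogroup_to_nuclear = NULL) {
  if (!is.list(chemotype_to_phylogroup) || is.null(names(chemotype_to_phylogroup)) ||
      any(!nzchar(names(chemotype_to_phylogroup)))) {
    stopf("chemotype_to_phylogroup must be a fully named list")
  }
  lens <- lengths(chemotype_to_phylogroup)
  if (any(lens == 0L)) stopf("every chemotype must map to at least one phylogroup")
  if (!is.null(phylogroup_to_nuclear)) {
    if (is.null(names(phylogroup_to_nuclear))) stopf("phylogroup_to_nuclear must be named")
    pgs <- unique(unlist(chemotype_to_phylogroup, use.names = FALSE))
    missing_pg <- setdiff(pgs, names(phylogroup_to_nuclear))
    if (length(missing_pg)) {
      stopf("phylogroup_to_nuclear lacks labels for: %s", paste(missing_pg, collapse = ", "))
    }
  }
  structure(list(chemotype_to_phylogroup = chemotype_to_phylogroup,
                 phylogroup_to_nuclear = phylogroup_to_nuclear),
            class = "genetic_map")
}

#' Design a simulated LC/MS cohort
#'
#' Fixes every knob of the generator: the chemotypes, replication, the
#' multiplicative abundance noise (a per-individual global lognormal factor
#' times per-compound lognormal jitter), additive detector noise, linear
#' baseline drift, the acquisition grid, and the genetic label structure.
#'
#' @param chemotypes list of [chemotype_spec()] objects with distinct ids.
#' @param n_per_chemotype individuals per chemotype (>= 1).
#' @param abundance_cv coefficient of variation of the per-individual global
#'   lognormal abundance factor (unitless).
#' @param compound_cv coefficient of variation of the per-compound lognormal
#'   jitter; default half the global CV.
#' @param baseline_level constant baseline intensity added to every recorded
#'   channel.
#' @param baseline_drift linear baseline slope, intensity units per minute.
#' @param noise_sd standard deviation of additive zero-mean Gaussian detector
#'   noise (intensities are truncated at zero).
#' @param rt_window acquisition window `c(start, end)` in minutes.
#' @param scan_interval spacing of the uniform scan grid, minutes.
#' @param genetic_map a [genetic_map()]; defaults to one phylogroup per
#'   chemotype (PG1, PG2, ...).
#' @param seed integer seed making the cohort reproducible.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(chemotypes, n_per_chemotype = 5L,
                          abundance_cv = 0.15, compound_cv = abundance_cv / 2,
                          baseline_level = 0, baseline_drift = 0, noise_sd = 0,
                          rt_window = c(0, 17), scan_interval = 0.05,
                          genetic_map = NULL, seed = 1L) {
  if (inherits(chemotypes, "chemotype_spec")) chemotypes <- list(chemotypes)
  if (length(chemotypes) == 0L) stopf("need at least one chemotype")
  ok <- vapply(chemotypes, inherits, logical(1), "chemotype_spec")
  if (!all(ok)) stopf("all chemotypes must be chemotype_spec objects")
  ids <- vapply(chemotypes, `[[`, character(1), "chemotype_id")
  if (anyDuplicated(ids)) stopf("duplicated chemotype ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(chemotypes) <- ids
  if (!is_count(n_per_chemotype)) stopf("n_per_chemotype must be a count >= 1")
  if (!is_number(abundance_cv) || abundance_cv < 0) stopf("abundance_cv must be >= 0")
  if (!is_number(compound_cv) || compound_cv < 0) stopf("compound_cv must be >= 0")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.numeric(rt_window) || length(rt_window) != 2L || rt_window[1] >= rt_window[2]) {
    stopf("rt_window must be c(start, end) with start < end")
  }
  if (!is_number(scan_interval) || scan_interval <= 0) stopf("scan_interval must be > 0")
  if (is.null(genetic_map)) {
    genetic_map <- genetic_map(stats::setNames(
      as.list(paste0("PG", seq_along(ids))), ids))
  }
  if (!inherits(genetic_map, "genetic_map")) stopf("genetic_map must be a genetic_map object")
  unmapped <- setdiff(ids, names(genetic_map$chemotype_to_phylogroup))
  if (length(unmapped)) stopf("genetic_map lacks phylogroups for chemotype(s): %s",
                              paste(unmapped, collapse = ", "))
  if (!is_number(seed)) stopf("seed must be a number")
  structure(list(chemotypes = chemotypes,
                 n_per_chemotype = as.integer(n_per_chemotype),
                 abundance_cv = abundance_cv, compound_cv = compound_cv,
                 baseline_level = baseline_level, baseline_drift = baseline_drift,
                 noise_sd = noise_sd, rt_window = as.numeric(rt_window),
                 scan_interval = scan_interval, genetic_map = genetic_map,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("Cohort design: %d chemotypes x %d individuals\n",
              length(x$chemotypes), x$n_per_chemotype))
  cat(sprintf("  RT window %.4g-%.4g min, scan every %.4g min\n",
              x$rt_window[1], x$rt_window[2], x$scan_interval))
  cat(sprintf("  abundance CV %.3g (compound jitter %.3g), noise sd %.3g, baseline %.3g + %.3g/min\n",
              x$abundance_cv, x$compound_cv, x$noise_sd,
              x$baseline_level, x$baseline_drift))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Measured m/z are emitted slightly above the nominal mass so the unit-mass
# floor() binning downstream is exercised with realistic non-integer values.
MZ_EMIT_OFFSET <- 0.4

scan_grid <- function(design) {
  rts <- seq(design$rt_window[1], design$rt_window[2], by = design$scan_interval)
  round(rts, 9)
}

#' Simulate one individual's LC/MS run
#'
#' The signal at scan time `t` on the channel of fragment `f` of compound `c`
#' is `global_factor * jitter_c * proportion_c * base_abundance_c *
#' rel_intensity_f * exp(-((t - rt_center_c)^2) / (2 * rt_sigma_c^2))`, summed
#' over compounds sharing the channel, plus `baseline_level + baseline_drift
#' * t`, plus zero-mean Gaussian noise; the result is truncated at zero.
#' Peaks are recorded on every nominal-mass channel carried by the chemotype
#' (centroided acquisition: channels without any compound are not recorded).
#'
#' Random draws (one global factor, one jitter per compound in listed order,
#' then the noise matrix) come from the current R random number stream, so
#' runs are reproducible under `set.seed()`; [simulate_cohort()] manages the
#' stream for whole cohorts.
#'
#' @param individual_id character id of the simulated individual.
#' @param chemotype a [chemotype_spec()].
#' @param design a [cohort_design()] supplying noise, baseline and grid.
#' @return a [mass_spec_run()].
#' @export
simulate_run <- function(individual_id, chemotype, design) {
  stopifnot(inherits(chemotype, "chemotype_spec"), inherits(design, "cohort_design"))
  rts <- scan_grid(design)
  if (length(rts) == 0L) stopf("empty scan grid: check rt_window and scan_interval")
  channels <- sort(unique(unlist(lapply(chemotype$compounds, `[[`, "fragment_mz"))))
  n_scan <- length(rts)
  n_chan <- length(channels)
  signal <- matrix(0, n_scan, n_chan)

  global <- lognormal_factor(1L, design$abundance_cv)
  jitter <- lognormal_factor(length(chemotype$compounds), design$compound_cv)
  for (k in seq_along(chemotype$compounds)) {
    cmp <- chemotype$compounds[[k]]
    amp <- global * jitter[k] * chemotype$proportions[k] * cmp$base_abundance
    shape <- exp(-0.5 * ((rts - cmp$rt_center) / cmp$rt_sigma)^2)
    cols <- match(cmp$fragment_mz, channels)
    signal[, cols] <- signal[, cols] +
      outer(amp * shape, cmp$fragment_intensity)
  }
  signal <- signal + design$baseline_level + design$baseline_drift * rts
  if (design$noise_sd > 0) {
    signal <- signal + matrix(stats::rnorm(n_scan * n_chan, 0, design$noise_sd),
                              n_scan, n_chan)
  }
  signal[signal < 0] <- 0

  peaks <- data.frame(
    scan_index = rep(seq_len(n_scan), each = n_chan),
    rt = rep(rts, each = n_chan),
    mz = rep(channels + MZ_EMIT_OFFSET, times = n_scan),
    intensity = as.vector(t(signal))
  )
  mass_spec_run(individual_id, peaks, mz_range = c(200, 500))
}

#' Simulate a full cohort of individuals
#'
#' Generates `n_per_chemotype` runs per chemotype under the design's seed and
#' builds the truth tables (chemotype, phylogroup, nuclear cluster) used to
#' score the downstream analysis. When a chemotype maps to several
#' phylogroups, individuals are assigned to them in rotation.
#'
#' @param design a [cohort_design()].
#' @return an object of class `simulated_cohort`: list with `runs` (named list
#'   of [mass_spec_run()]), `truth` (data.frame with columns individual_id,
#'   chemotype_id, phylogroup, nuclear_cluster) and `design`.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    runs <- list()
    rows <- list()
    nuc <- design$genetic_map$phylogroup_to_nuclear
    for (ct in design$chemotypes) {
      pgs <- design$genetic_map$chemotype_to_phylogroup[[ct$chemotype_id]]
      for (i in seq_len(design$n_per_chemotype)) {
        id <- sprintf("%s_%02d", ct$chemotype_id, i)
        runs[[id]] <- simulate_run(id, ct, design)
        pg <- pgs[((i - 1L) %% length(pgs)) + 1L]
        rows[[id]] <- data.frame(
          individual_id = id, chemotype_id = ct$chemotype_id, phylogroup = pg,
          nuclear_cluster = if (is.null(nuc)) NA_character_ else unname(nuc[[pg]]),
          stringsAsFactors = FALSE)
      }
    }
    structure(list(runs = runs,
                   truth = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                   design = design),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d individuals, %d chemotypes, %d phylogroups\n",
              length(x$runs), length(unique(x$truth$chemotype_id)),
              length(unique(x$truth$phylogroup))))
  invisible(x)
}

preset_compound <- function(id, rt, mz2, abundance, rt_sigma = 0.15,
                            relint = c(1, 0.6)) {
  compound_spec(id, rt_center = rt, rt_sigma = rt_sigma,
                fragment_mz = mz2, fragment_intensity = relint,
                base_abundance = abundance)
}

# Four disjoint three-compound suites used by the concordant-style presets.
preset_suites <- function(abundance = 1e6) {
  mz <- list(CT1 = list(c(210L, 211L), c(225L, 226L), c(240L, 241L)),
             CT2 = list(c(260L, 261L), c(275L, 276L), c(290L, 291L)),
             CT3 = list(c(310L, 311L), c(325L, 326L), c(340L, 341L)),
             CT4 = list(c(360L, 361L), c(375L, 376L), c(390L, 391L)))
  rt <- c(4, 8, 12)
  lapply(names(mz), function(ct) {
    cmps <- lapply(seq_along(mz[[ct]]), function(k) {
      preset_compound(sprintf("%s_c%d", ct, k), rt[k], mz[[ct]][[k]], abundance)
    })
    chemotype_spec(ct, cmps, proportions = c(1, 0.7, 0.5))
  })
}

#' Built-in cohort scenarios
#'
#' Named designs reproducing the qualitative genetic/chemical patterns the
#' concordance analysis must distinguish:
#' \describe{
#'   \item{concordant}{one chemotype per phylogroup (bijective map).}
#'   \item{convergent_chemistry}{two chemotypes share the same compound set
#'     with different proportion vectors, each in its own phylogroup, so the
#'     correlation dendrogram merges them while PCA separates them.}
#'   \item{lumped_nuclear}{concordant chemistry, but several phylogroups share
#'     one nuclear-cluster label.}
#'   \item{split_phylogroup}{one phylogroup spans two chemotypes whose suites
#'     differ in their own minor compounds but share two low-abundance
#'     ubiquitous compounds, so the dendrogram splits them while their clouds
#'     overlap on the leading principal components.}
#' }
#'
#' @param name one of `"concordant"`, `"convergent_chemistry"`,
#'   `"lumped_nuclear"`, `"split_phylogroup"`.
#' @param seed integer seed stored in the returned design.
#' @return a [cohort_design()].
#' @export
scenario_preset <- function(name, seed = 1L) {
  if (!is_string(name)) stopf("name must be a string")
  switch(
    name,
    concordant = {
      suites <- preset_suites()
      cohort_design(
        suites, n_per_chemotype = 5L, abundance_cv = 0.15, compound_cv = 0.075,
        baseline_level = 50, baseline_drift = 5, noise_sd = 20,
        genetic_map = genetic_map(
          list(CT1 = "PG1", CT2 = "PG2", CT3 = "PG3", CT4 = "PG4"),
          c(PG1 = "NC1", PG2 = "NC2", PG3 = "NC3", PG4 = "NC4")),
        seed = seed)
    },
    convergent_chemistry = {
      shared_mz <- list(c(220L, 221L), c(250L, 251L), c(280L, 281L), c(310L, 311L))
      shared_rt <- c(4, 7, 10, 13)
      cmps <- lapply(1:4, function(k) {
        preset_compound(sprintf("p%d", k), shared_rt[k], shared_mz[[k]], 1e6)
      })
      ctx <- chemotype_spec("CTA", cmps, proportions = c(4, 3, 2, 1))
      cty <- chemotype_spec("CTB", cmps, proportions = c(1, 2, 3, 4))
      ctz <- chemotype_spec("CTC", list(
        preset_compound("z1", 5, c(350L, 351L), 1e6),
        preset_compound("z2", 9, c(380L, 381L), 1e6)), proportions = c(1, 0.8))
      cohort_design(
        list(ctx, cty, ctz), n_per_chemotype = 6L,
        abundance_cv = 0.15, compound_cv = 0.075,
        baseline_level = 50, baseline_drift = 5, noise_sd = 20,
        genetic_map = genetic_map(list(CTA = "PG24", CTB = "PG29", CTC = "PG1")),
        seed = seed)
    },
    lumped_nuclear = {
      suites <- preset_suites()
      cohort_design(
        suites, n_per_chemotype = 5L, abundance_cv = 0.15, compound_cv = 0.075,
        baseline_level = 50, baseline_drift = 5, noise_sd = 20,
        genetic_map = genetic_map(
          list(CT1 = "PG1", CT2 = "PG2", CT3 = "PG3", CT4 = "PG4"),
          c(PG1 = "NC1", PG2 = "NC1", PG3 = "NC2", PG4 = "NC3")),
        seed = seed)
    },
    split_phylogroup = {
      # Two low-abundance compounds shared by the split pair reuse the major
      # compounds' channels of the two context chemotypes, so the split pair's
      # within-group scatter lies along the leading PCs while the pair's own
      # (disjoint, minor) compounds only reach lower components.
      ubiq <- function() list(
        preset_compound("u_c", 6, c(430L, 431L), 2e5),
        preset_compound("u_d", 11, c(470L, 471L), 2e5))
      own <- function(prefix, mzs) lapply(seq_along(mzs), function(k) {
        preset_compound(sprintf("%s%d", prefix, k), c(4, 8, 12)[k], mzs[[k]], 4e5)
      })
      sa <- chemotype_spec("SA", c(own("a", list(c(210L, 211L), c(225L, 226L),
                                                 c(240L, 241L))), ubiq()))
      sb <- chemotype_spec("SB", c(own("b", list(c(260L, 261L), c(275L, 276L),
                                                 c(290L, 291L))), ubiq()))
      ctc <- chemotype_spec("CTC", list(
        preset_compound("c1", 6, c(430L, 431L), 5e6),
        preset_compound("c2", 9, c(330L, 331L), 5e6)))
      ctd <- chemotype_spec("CTD", list(
        preset_compound("d1", 11, c(470L, 471L), 5e6),
        preset_compound("d2", 14, c(370L, 371L), 5e6)))
      cohort_design(
        list(sa, sb, ctc, ctd), n_per_chemotype = 16L,
        abundance_cv = 0.3, compound_cv = 0.5,
        baseline_level = 50, baseline_drift = 5, noise_sd = 20,
        genetic_map = genetic_map(
          list(SA = "PG1", SB = "PG1", CTC = "PG2", CTD = "PG3")),
        seed = seed)
    },
    stopf("unknown scenario preset '%s'; choose one of %s", name,
          "concordant, convergent_chemistry, lumped_nuclear, split_phylogroup")
  )
}

#' Write a simulated cohort to disk
#'
#' One run file per individual (scan-table TSV or mzML), a truth table TSV
#' (individual_id, chemotype_id, phylogroup, nuclear_cluster) and the design
#' serialized as JSON.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param format `"scan_table"` or `"mzml"`.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, format = c("scan_table", "mzml")) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "mzml") "mzML" else "tsv"
  paths <- vapply(cohort$runs, function(run) {
    p <- file.path(dir, sprintf("%s.%s", run$individual_id, ext))
    write_run(run, p, format = format)
    p
  }, character(1))
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(cohort$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  design_path <- file.path(dir, "design.json")
  jsonlite::write_json(design_to_list(cohort$design), design_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, truth = truth_path, design = design_path))
}

design_to_list <- function(design) {
  list(
    chemotypes = lapply(design$chemotypes, function(ct) list(
      chemotype_id = ct$chemotype_id,
      proportions = as.list(ct$proportions),
      compounds = lapply(ct$compounds, function(cmp) {
        cmp_list <- unclass(cmp)
        cmp_list$fragment_mz <- as.list(cmp_list$fragment_mz)
        cmp_list$fragment_intensity <- as.list(cmp_list$fragment_intensity)
        cmp_list
      }))),
    n_per_chemotype = design$n_per_chemotype,
    abundance_cv = design$abundance_cv, compound_cv = design$compound_cv,
    baseline_level = design$baseline_level, baseline_drift = design$baseline_drift,
    noise_sd = design$noise_sd, rt_window = design$rt_window,
    scan_interval = design$scan_interval,
    genetic_map = list(
      chemotype_to_phylogroup = design$genetic_map$chemotype_to_phylogroup,
      phylogroup_to_nuclear = design$genetic_map$phylogroup_to_nuclear),
    seed = design$seed)
}

#' Simulate aligned gene partitions for a cohort's phylogroups
#'
#' Star-phylogeny sequence sampler for testing the genetic bookkeeping: each
#' gene gets a random stop-codon-free ancestral sequence; each phylogroup
#' receives substitutions at a per-gene rate (slowest for the nuclear gene),
#' and individuals add a small private rate on top of their phylogroup
#' haplotype. Coding genes (COI, ANT) never acquire internal stop codons.
#'
#' @param truth data.frame with columns `individual_id` and `phylogroup`
#'   (e.g. the `truth` table of [simulate_cohort()]).
#' @param lengths named integer vector of partition lengths.
#' @param rates named per-gene substitution rates between the ancestor and a
#'   phylogroup haplotype (substitutions per site).
#' @param individual_rate per-site rate of private substitutions within a
#'   phylogroup.
#' @param seed integer seed.
#' @return named list of [gene_partition()] objects.
#' @export
simulate_gene_partitions <- function(truth,
                                     lengths = c(COI = 627L, `16S` = 461L, ANT = 515L),
                                     rates = c(COI = 0.08, `16S` = 0.04, ANT = 0.008),
                                     individual_rate = 0.002, seed = 1L) {
  stopifnot(is.data.frame(truth),
            all(c("individual_id", "phylogroup") %in% names(truth)))
  genes <- names(lengths)
  if (!setequal(genes, names(rates))) stopf("lengths and rates must name the same genes")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- list()
    for (gene in genes) {
      L <- as.integer(lengths[[gene]])
      coding <- gene %in% c("COI", "ANT")
      stops <- stop_codons(gene)
      anc <- random_sequence(L, coding, stops)
      pgs <- unique(truth$phylogroup)
      hap <- lapply(pgs, function(pg) {
        mutate_sequence(anc, round(rates[[gene]] * L), coding, stops)
      })
      names(hap) <- pgs
      seqs <- vapply(seq_len(nrow(truth)), function(i) {
        n_priv <- stats::rbinom(1L, L, individual_rate)
        paste(mutate_sequence(hap[[truth$phylogroup[i]]], n_priv, coding, stops),
              collapse = "")
      }, character(1))
      names(seqs) <- truth$individual_id
      out[[gene]] <- gene_partition(gene, seqs)
    }
    out
  })
}

stop_codons <- function(gene) {
  # COI is read with the invertebrate mitochondrial code (TGA encodes Trp);
  # the nuclear ANT uses the standard code.
  if (gene == "COI") c("TAA", "TAG") else c("TAA", "TAG", "TGA")
}

random_sequence <- function(L, coding, stops) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, L, replace = TRUE)
  if (coding) {
    n_codon <- L %/% 3L
    for (k in seq_len(n_codon)) {
      idx <- (3L * (k - 1L) + 1L):(3L * k)
      while (paste(s[idx], collapse = "") %in% stops) {
        s[idx[3L]] <- sample(bases, 1L)
      }
    }
  }
  s
}

mutate_sequence <- function(s, n_mut, coding, stops) {
  if (n_mut <= 0L) return(s)
  bases <- c("A", "C", "G", "T")
  pos <- sample(length(s), min(n_mut, length(s)))
  for (p in pos) {
    alt <- setdiff(bases, s[p])
    if (coding && p <= 3L * (length(s) %/% 3L)) {
      codon_start <- 3L * ((p - 1L) %/% 3L) + 1L
      codon <- s[codon_start:(codon_start + 2L)]
      off <- p - codon_start + 1L
      ok <- vapply(alt, function(b) {
        codon[off] <- b
        !(paste(codon, collapse = "") %in% stops)
      }, logical(1))
      alt <- alt[ok]
    }
    if (length(alt)) s[p] <- sample(alt, 1L)
  }
  s
}
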