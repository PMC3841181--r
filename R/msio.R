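#' Construct and validate an LC/MS run
#'
#' The internal run model: one individual's centroided MS1 acquisition as a
#' long table of (scan_index, rt, m/z, intensity) peaks. Validation sorts
#' scans by retention time, rejects negative or non-finite intensities,
#' rejects duplicated retention times across distinct scans, and (when an
#' acquisition m/z range is declared) rejects peaks outside it. Retention
#' times are stored in minutes, rounded to nine decimals so that write/read
#' round trips are exact.
#'
#' @param individual_id character id of the individual.
#' @param peaks data.frame with numeric columns `rt` (minutes), `mz`,
#'   `intensity`, and optionally `scan_index`.
#' @param mz_range optional `c(low, high)`; peaks must satisfy
#'   `low <= mz < high`.
#' @return an object of class `mass_spec_run` with elements `individual_id`,
#'   `peaks` (sorted by rt then m/z), `scan_rt` (sorted unique retention
#'   times), `acquisition_window`, `mz_range`.
#' @export
mass_spec_run <- function(individual_id, peaks, mz_range = NULL) {
  if (!is_string(individual_id)) stopf("individual_id must be a non-empty string")
  if (!is.data.frame(peaks) || !all(c("rt", "mz", "intensity") %in% names(peaks))) {
    stopf("peaks must be a data.frame with columns rt, mz, intensity")
  }
  if (nrow(peaks) == 0L) stopf("run '%s' has no scans", individual_id)
  rt <- round(as.numeric(peaks$rt), 9)
  mz <- as.numeric(peaks$mz)
  intensity <- as.numeric(peaks$intensity)
  if (any(!is.finite(rt)) || any(rt < 0)) stopf("run '%s': retention times must be finite and >= 0",
                                                individual_id)
  if (any(!is.finite(mz))) stopf("run '%s': m/z values must be finite", individual_id)
  bad <- which(!is.finite(intensity) | intensity < 0)
  if (length(bad)) {
    stopf("run '%s': negative or non-finite intensity at rt %.6g (m/z %.6g)",
          individual_id, rt[bad[1]], mz[bad[1]])
  }
  if ("scan_index" %in% names(peaks)) {
    si <- as.integer(peaks$scan_index)
    tab <- unique(data.frame(si = si, rt = rt))
    if (anyDuplicated(tab$rt)) {
      dup <- tab$rt[duplicated(tab$rt)][1]
      stopf("run '%s': duplicated retention time %.9g across distinct scans",
            individual_id, dup)
    }
    if (anyDuplicated(tab$si)) {
      stopf("run '%s': scan index maps to several retention times", individual_id)
    }
  }
  if (!is.null(mz_range)) {
    if (length(mz_range) != 2L || mz_range[1] >= mz_range[2]) {
      stopf("mz_range must be c(low, high) with low < high")
    }
    out <- which(mz < mz_range[1] | mz >= mz_range[2])
    if (length(out)) {
      stopf("run '%s': m/z %.6g outside declared range [%g, %g)",
            individual_id, mz[out[1]], mz_range[1], mz_range[2])
    }
  } else {
    mz_range <- c(min(mz), max(mz) + 1)
  }
  ord <- order(rt, mz)
  scan_rt <- sort(unique(rt))
  peaks <- data.frame(
    scan_index = match(rt[ord], scan_rt),
    rt = rt[ord], mz = mz[ord], intensity = intensity[ord])
  structure(list(individual_id = individual_id, peaks = peaks,
                 scan_rt = scan_rt,
                 acquisition_window = range(scan_rt),
                 mz_range = as.numeric(mz_range)),
            class = "mass_spec_run")
}

#' @export
print.mass_spec_run <- function(x, ...) {
  cat(sprintf("LC/MS run '%s': %d scans, %d peaks, RT %.4g-%.4g min, m/z [%g, %g)\n",
              x$individual_id, length(x$scan_rt), nrow(x$peaks),
              x$acquisition_window[1], x$acquisition_window[2],
              x$mz_range[1], x$mz_range[2]))
  invisible(x)
}

#' Total ion current of a run
#'
#' Summed intensity per scan, in retention-time order.
#' @param run a [mass_spec_run()].
#' @return data.frame with columns `rt` and `tic`.
#' @export
total_ion_current <- function(run) {
  stopifnot(inherits(run, "mass_spec_run"))
  tic <- vapply(split(run$peaks$intensity, run$peaks$scan_index), sum, numeric(1))
  data.frame(rt = run$scan_rt, tic = as.numeric(tic))
}

guess_run_format <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "scan_table"
}

#' Read an LC/MS run
#'
#' Supported formats: `"scan_table"` — a TSV with columns `scan_index`,
#' `rt_min`, `mz`, `intensity` (comment lines starting with `#` ignored) —
#' and `"mzml"` (centroided MS1 spectra, read through \pkg{mzR}). The
#' individual id is taken from the file name stem.
#'
#' @param path file to read.
#' @param format `"scan_table"`, `"mzml"`, or `"auto"` (by extension).
#' @return a validated [mass_spec_run()].
#' @export
read_run <- function(path, format = c("auto", "scan_table", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") format <- guess_run_format(path)
  id <- tools::file_path_sans_ext(basename(path))
  if (format == "scan_table") {
    df <- tryCatch(read_stamped_tsv(path),
                   error = function(e) stopf("cannot parse scan table '%s': %s",
                                             path, conditionMessage(e)))
    need <- c("scan_index", "rt_min", "mz", "intensity")
    if (!all(need %in% names(df))) {
      stopf("scan table '%s' must have columns: %s", path, paste(need, collapse = ", "))
    }
    peaks <- data.frame(scan_index = df$scan_index, rt = df$rt_min,
                        mz = df$mz, intensity = df$intensity)
  } else {
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle))
    hdr <- mzR::header(handle)
    pk <- mzR::peaks(handle)
    if (is.matrix(pk)) pk <- list(pk)
    peaks <- do.call(rbind, lapply(seq_along(pk), function(i) {
      m <- pk[[i]]
      if (nrow(m) == 0L) return(NULL)
      data.frame(scan_index = i, rt = hdr$retentionTime[i] / 60,
                 mz = m[, 1], intensity = m[, 2])
    }))
    if (is.null(peaks)) stopf("mzML file '%s' contains no peaks", path)
  }
  mass_spec_run(id, peaks)
}

#' Write an LC/MS run
#'
#' Writes either the plain scan-table TSV or a minimal centroided MS1 mzML
#' (64-bit floats, no compression). Values are serialized at full double
#' precision, so a write/read round trip reproduces retention times, m/z and
#' intensities exactly.
#'
#' @param run a [mass_spec_run()].
#' @param path output file.
#' @param format `"scan_table"` or `"mzml"`.
#' @return invisibly, `path`.
#' @export
write_run <- function(run, path, format = c("scan_table", "mzml")) {
  stopifnot(inherits(run, "mass_spec_run"))
  format <- match.arg(format)
  if (nrow(run$peaks) == 0L) stopf("refusing to serialize run '%s' with no scans",
                                   run$individual_id)
  if (format == "scan_table") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# chemotax %s scan table for %s",
                       chemotax_version(), run$individual_id), con)
    writeLines("scan_index\trt_min\tmz\tintensity", con)
    writeLines(sprintf("%d\t%.17g\t%.17g\t%.17g",
                       run$peaks$scan_index, run$peaks$rt,
                       run$peaks$mz, run$peaks$intensity), con)
  } else {
    writeLines(build_mzml(run), path)
  }
  invisible(path)
}

encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L, endian = "little"))
}

binary_array_xml <- function(x, accession, name, unit) {
  b <- encode_doubles(x)
  paste0(
    sprintf('<binaryDataArray encodedLength="%d">', nchar(b)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value="" %s/>',
            accession, name, unit),
    sprintf("<binary>%s</binary></binaryDataArray>", b))
}

build_mzml <- function(run) {
  spectra <- vapply(seq_along(run$scan_rt), function(i) {
    sel <- run$peaks$scan_index == i
    mz <- run$peaks$mz[sel]
    inten <- run$peaks$intensity[sel]
    paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i - 1L, i, length(mz)),
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<scanList count="1"><scan>',
      sprintf(paste0('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time"',
                     ' value="%.17g" unitCvRef="UO" unitAccession="UO:0000031"',
                     ' unitName="minute"/>'), run$scan_rt[i]),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      binary_array_xml(mz, "MS:1000514", "m/z array",
                       'unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'),
      binary_array_xml(inten, "MS:1000515", "intensity array",
                       paste0('unitCvRef="MS" unitAccession="MS:1000131"',
                              ' unitName="number of detector counts"')),
      "</binaryDataArrayList></spectrum>")
  }, character(1))
  paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology"',
    ' URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology"',
    ' URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    "</cvList>\n",
    "<fileDescription><fileContent>",
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    "</fileContent></fileDescription>\n",
    sprintf(paste0('<softwareList count="1"><software id="chemotax" version="%s">',
                   '<cvParam cvRef="MS" accession="MS:1000799"',
                   ' name="custom unreleased software tool" value="chemotax"/>',
                   "</software></softwareList>\n"), chemotax_version()),
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    "</instrumentConfiguration></instrumentConfigurationList>\n",
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="chemotax">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    "</processingMethod></dataProcessing></dataProcessingList>\n",
    sprintf('<run id="%s" defaultInstrumentConfigurationRef="ic">\n', run$individual_id),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">\n',
            length(run$scan_rt)),
    paste(spectra, collapse = "\n"),
    "\n</spectrumList></run></mzML>")
}
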