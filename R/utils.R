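stopf <- function(fmt, ..., call. = FALSE) stop(sprintf(fmt, ...), call. = call.)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_number(x) && x >= 1 && x == as.integer(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' @keywords internal
#' @noRd
fnv1a32 <- function(x) {
  # FNV-1a over the UTF-8 bytes; used only as a provenance fingerprint.
  # Arithmetic kept in doubles; the 32-bit product is split 16/16 so every
  # intermediate stays below 2^53.
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint an R object for provenance stamps
#'
#' Deterministic short hash of the deparsed object, used to stamp pipeline
#' outputs so a result file can be traced to the configuration that made it.
#' @param x any R object
#' @return 8-character hexadecimal string
#' @keywords internal
config_fingerprint <- function(x) {
  fnv1a32(deparse(x, control = c("keepNA", "niceNames", "showAttributes")))
}

chemotax_version <- function() {
  as.character(utils::packageVersion("chemotax"))
}

# Writes a TSV with a one-line provenance comment header.
write_stamped_tsv <- function(df, path, fingerprint = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(fingerprint)) {
    writeLines(sprintf("# chemotax %s config=%s", chemotax_version(), fingerprint), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stamped_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# Restores the caller-visible RNG state on exit; seeds locally.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
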