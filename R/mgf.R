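# MGF (Mascot Generic Format) reader/writer, tolerant of the MS-DIAL
# alignment-export dialect (PRECURSORMZ/RETENTIONTIME keys, per-feature
# linked-peak and adduct annotations).  No installed package parses MGF, so
# the format is handled here; the dialect is small and line-oriented.

new_spectrum <- function(feature_id, precursor_mz, rt = NA_real_,
                         fragments = data.frame(mz = numeric(), intensity = numeric()),
                         linked_to = NA_character_, adduct_label = NA_character_,
                         meta = list()) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L)
  fragments <- fragments[order(fragments$mz), , drop = FALSE]
  rownames(fragments) <- NULL
  if (any(fragments$intensity < 0)) stop("negative fragment intensity in ", feature_id)
  structure(list(feature_id = as.character(feature_id),
                 precursor_mz = precursor_mz, rt = rt,
                 fragments = fragments, linked_to = linked_to,
                 adduct_label = adduct_label, meta = meta),
            class = "rg_spectrum")
}

#' @export
print.rg_spectrum <- function(x, ...) {
  cat(sprintf("<rg_spectrum> %s  m/z %.4f  rt %.2f  %d fragments\n",
              x$feature_id, x$precursor_mz, x$rt, nrow(x$fragments)))
  invisible(x)
}

#' Read an MGF file of MS/MS spectra
#'
#' Accepts both the generic dialect (\code{PEPMASS}, \code{RTINSECONDS}) and
#' MS-DIAL export keys (\code{PRECURSORMZ}, \code{RETENTIONTIME} in minutes).
#' The feature id is taken from \code{TITLE}, falling back to the 1-based
#' entry index.  Optional headers that are not understood are preserved in
#' each record's \code{meta} list.  \code{LINKEDFEATURE} and \code{ADDUCT}
#' headers populate the linked-peak and adduct annotations used by detection
#' filter (iv).
#'
#' @param path MGF file path.
#' @return List of \code{rg_spectrum} records, fragments sorted by m/z.
#'   An empty file returns an empty list with a warning.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning("empty MGF file: ", path)
    return(list())
  }
  records <- list()
  i <- 1L
  entry <- 0L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line != "BEGIN IONS") { i <- i + 1L; next }
    entry <- entry + 1L
    headers <- list()
    mz <- numeric(); int <- numeric()
    i <- i + 1L
    repeat {
      if (i > n) stop("unterminated MGF entry ", entry, " (missing END IONS)")
      line <- trimws(lines[i])
      if (line == "END IONS") { i <- i + 1L; break }
      if (nzchar(line)) {
        if (grepl("=", line, fixed = TRUE)) {
          key <- toupper(sub("=.*$", "", line))
          val <- sub("^[^=]*=", "", line)
          headers[[key]] <- val
        } else {
          parts <- strsplit(line, "[ \t]+")[[1L]]
          vals <- suppressWarnings(as.numeric(parts))
          if (length(vals) < 2L || anyNA(vals[1:2])) {
            stop("malformed ion line ", i, " in ", path, ": '", line, "'")
          }
          mz <- c(mz, vals[1L]); int <- c(int, vals[2L])
        }
      }
      i <- i + 1L
    }
    fid <- headers[["TITLE"]]
    if (is.null(fid) || !nzchar(fid)) fid <- paste0("scan_", entry)
    pm <- headers[["PRECURSORMZ"]]
    if (is.null(pm)) pm <- headers[["PEPMASS"]]
    if (is.null(pm)) stop("entry '", fid, "' lacks a precursor m/z (PEPMASS/PRECURSORMZ)")
    pm <- as.numeric(strsplit(trimws(pm), "[ \t]+")[[1L]][1L])
    rt <- headers[["RETENTIONTIME"]]
    if (is.null(rt) && !is.null(headers[["RTINSECONDS"]])) {
      rt <- as.numeric(headers[["RTINSECONDS"]]) / 60
    }
    rt <- if (is.null(rt)) NA_real_ else as.numeric(rt)
    linked <- headers[["LINKEDFEATURE"]]
    add <- headers[["ADDUCT"]]
    known <- c("TITLE", "PRECURSORMZ", "PEPMASS", "RETENTIONTIME",
               "RTINSECONDS", "LINKEDFEATURE", "ADDUCT")
    meta <- headers[setdiff(names(headers), known)]
    records[[length(records) + 1L]] <- new_spectrum(
      fid, pm, rt, data.frame(mz = mz, intensity = int),
      linked_to = if (is.null(linked)) NA_character_ else linked,
      adduct_label = if (is.null(add)) NA_character_ else add,
      meta = meta
    )
  }
  if (!length(records)) warning("no BEGIN IONS entries in ", path)
  records
}

#' Write spectra to an MGF file
#'
#' Round-trips with \code{\link{read_mgf}}: m/z and intensities are written
#' with six decimals.
#'
#' @param records List of \code{rg_spectrum} objects.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_mgf <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", rec$feature_id), con)
    writeLines(sprintf("PRECURSORMZ=%.6f", rec$precursor_mz), con)
    if (!is.na(rec$rt)) writeLines(sprintf("RETENTIONTIME=%.4f", rec$rt), con)
    writeLines("CHARGE=1-", con)
    if (!is.na(rec$linked_to)) writeLines(paste0("LINKEDFEATURE=", rec$linked_to), con)
    if (!is.na(rec$adduct_label)) writeLines(paste0("ADDUCT=", rec$adduct_label), con)
    for (key in names(rec$meta)) writeLines(paste0(key, "=", rec$meta[[key]]), con)
    fr <- rec$fragments[order(rec$fragments$mz), , drop = FALSE]
    if (nrow(fr)) {
      writeLines(sprintf("%.6f %.6f", fr$mz, fr$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
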