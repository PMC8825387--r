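# Tab-separated peak-area alignment tables (MS-DIAL export style): one row
# per aligned feature, one column per sample, plus a sample -> role mapping
# (leaf / root / blank) supplied explicitly rather than guessed from names.

#' Read a peak-area alignment table
#'
#' @param path TSV file with a \code{feature_id} column and one numeric
#'   peak-area column per sample.
#' @param sample_roles Named character vector mapping sample column names to
#'   roles among \code{"leaf"}, \code{"root"}, \code{"blank"}.  Columns of
#'   the file not mentioned are ignored (with a message); at least one blank
#'   column is required because the blank filter cannot run without one.
#' @return An object of class \code{rg_alignment}: list with \code{areas}
#'   (data frame keyed by feature_id), \code{roles}, and \code{n_missing}
#'   (count of empty/NA cells coerced to 0, each coercion warned about once
#'   in aggregate).
#' @export
read_alignment <- function(path, sample_roles) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(length(sample_roles) > 0, !is.null(names(sample_roles)))
  bad_roles <- setdiff(unique(sample_roles), c("leaf", "root", "blank"))
  if (length(bad_roles)) stop("unknown sample role(s): ", paste(bad_roles, collapse = ", "))
  if (!any(sample_roles == "blank")) {
    stop("no blank column configured; the blank filter cannot run")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"feature_id" %in% names(tab)) stop("alignment table lacks a feature_id column")
  tab$feature_id <- as.character(tab$feature_id)
  if (anyDuplicated(tab$feature_id)) {
    stop("duplicated feature_id in alignment table: ",
         paste(unique(tab$feature_id[duplicated(tab$feature_id)]), collapse = ", "))
  }
  missing_cols <- setdiff(names(sample_roles), names(tab))
  if (length(missing_cols)) {
    stop("sample column(s) absent from table: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(tab), c("feature_id", names(sample_roles)))
  if (length(extra)) {
    message("ignoring unmapped column(s): ", paste(extra, collapse = ", "))
  }
  areas <- tab[, c("feature_id", names(sample_roles)), drop = FALSE]
  n_missing <- 0L
  for (col in names(sample_roles)) {
    v <- suppressWarnings(as.numeric(areas[[col]]))
    n_missing <- n_missing + sum(is.na(v))
    v[is.na(v)] <- 0
    if (any(v < 0)) stop("negative peak area in column ", col)
    areas[[col]] <- v
  }
  if (n_missing > 0L) {
    warning(n_missing, " missing area cell(s) set to 0")
  }
  structure(list(areas = areas, roles = sample_roles, n_missing = n_missing),
            class = "rg_alignment")
}

#' Per-organ aggregated areas for one feature
#'
#' Aggregates sample columns by role with the maximum (a feature is treated
#' as present in an organ if any replicate shows it).
#'
#' @param table \code{rg_alignment}.
#' @param feature_id Feature key.
#' @return Named numeric vector \code{c(leaf=, root=, blank=)}; roles with
#'   no column yield 0.
#' @export
organ_areas <- function(table, feature_id) {
  i <- match(feature_id, table$areas$feature_id)
  if (is.na(i)) stop("feature '", feature_id, "' not in alignment table")
  out <- c(leaf = 0, root = 0, blank = 0)
  for (role in c("leaf", "root", "blank")) {
    cols <- names(table$roles)[table$roles == role]
    if (length(cols)) out[[role]] <- max(as.numeric(table$areas[i, cols]))
  }
  out
}

#' Write an alignment table
#'
#' @param table \code{rg_alignment} (or a plain data frame with feature_id).
#' @param path Output TSV path.
#' @export
write_alignment <- function(table, path) {
  df <- if (inherits(table, "rg_alignment")) table$areas else table
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
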