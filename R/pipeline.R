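# Pipeline wiring: one config, staged execution, attrition logging,
# versioned provenance in every output.

#' Build or load the pipeline configuration
#'
#' The configuration carries input paths, the sample-role mapping, and every
#' threshold of the detection and prediction stages as a named key with its
#' standard default.  Unknown keys are rejected.
#'
#' @param path YAML file; alternatively pass fields via \code{...}.
#' @param ... Fields overriding the defaults: \code{mgf}, \code{areas},
#'   \code{roles} (named list/vector sample -> leaf/root/blank),
#'   \code{out_dir}, \code{db} (moiety database YAML path or NULL for the
#'   shipped defaults), \code{tolerance} (fragment match, Da),
#'   \code{blank_ratio_min}, \code{area_min}, \code{relative_intensity_min},
#'   \code{keep_linked}, \code{mode} (prediction, default/extended),
#'   \code{precursor_tolerance}, \code{n_top}.
#' @return List of class \code{rg_pipeline_config}.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    mgf = NULL, areas = NULL, roles = NULL, out_dir = NULL, db = NULL,
    tolerance = 0.01, blank_ratio_min = 10, area_min = 1000,
    relative_intensity_min = 0.10, keep_linked = "higher",
    mode = "default", precursor_tolerance = 0.01, n_top = 20L
  )
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  dots <- list(...)
  user[names(dots)] <- dots
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(user)] <- user
  structure(defaults, class = "rg_pipeline_config")
}

pipeline_provenance <- function(db) {
  list(package = "rgspect",
       version = as.character(utils::packageVersion("rgspect")),
       db_checksum = substr(digest_db(db), 1, 12))
}

digest_db <- function(db) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  utils::write.csv(db[, c("name", "class", "formula", "frequent")], tmp,
                   row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Stages in order: read inputs, detect RG peaks, annotate their spectra,
#' predict components, compute co-occurrence statistics, and write a summary
#' with the headline counts (detected peaks, annotation coverage, fraction
#' of peaks with at least one candidate prediction).  Any stage error aborts
#' with the stage name.  Re-running on identical inputs and config yields
#' identical outputs.
#'
#' @param config \code{\link{pipeline_config}} (or a YAML path).
#' @return List of class \code{rg_pipeline_result}: \code{detection},
#'   \code{annotations}, \code{candidates}, \code{correlations},
#'   \code{summary}; files are written when \code{out_dir} is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(path = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  db <- stage("database", if (is.null(config$db)) moiety_db() else moiety_db(config$db))
  records <- stage("read_mgf", read_mgf(config$mgf))
  roles <- unlist(config$roles)
  table <- stage("read_alignment", read_alignment(config$areas, roles))
  dcfg <- detection_config(
    blank_ratio_min = config$blank_ratio_min, area_min = config$area_min,
    relative_intensity_min = config$relative_intensity_min,
    fragment_match_tolerance = config$tolerance,
    keep_linked = config$keep_linked)
  if (!length(records)) {
    summary <- list(n_features = 0L, n_detected = 0L,
                    annotation_coverage = NA_real_, pct_with_prediction = NA_real_)
    return(structure(list(detection = NULL, annotations = NULL,
                          candidates = NULL, correlations = NULL,
                          summary = summary), class = "rg_pipeline_result"))
  }
  detection <- stage("detect", detect_rg(records, table, db, dcfg))
  ids <- vapply(records, function(r) r$feature_id, character(1))
  det_records <- records[ids %in% detection$detected$feature_id]
  annotations <- if (length(det_records)) {
    stage("annotate", annotate_spectra(det_records, db, config$tolerance,
                                       config$n_top))
  } else list()
  pcfg <- prediction_config(mode = config$mode,
                            precursor_tolerance = config$precursor_tolerance,
                            db = db)
  candidates <- stage("predict", predict_components(detection, annotations, db, pcfg))
  correlations <- if (nrow(detection$detected) >= 2L) {
    fm <- build_fragment_matrix(detection, records)
    list(fragments = stage("correlate", fragment_correlations(fm)),
         organ = organ_correlation(detection))
  } else list(fragments = NULL, organ = NULL)

  n_det <- nrow(detection$detected)
  n_pred <- sum(vapply(candidates, nrow, integer(1)) > 0)
  summary <- list(
    n_features = length(records),
    n_detected = n_det,
    attrition = as.list(detection$attrition),
    annotation_coverage = if (length(annotations)) annotation_coverage(annotations)
                          else NA_real_,
    n_with_prediction = n_pred,
    pct_with_prediction = if (n_det) 100 * n_pred / n_det else NA_real_,
    provenance = pipeline_provenance(db)
  )
  result <- structure(list(detection = detection, annotations = annotations,
                           candidates = candidates, correlations = correlations,
                           summary = summary),
                      class = "rg_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' Write pipeline outputs
#'
#' Detection TSV, annotation JSON, prediction TSV, correlation TSV and a
#' summary JSON (all carrying the package version and database checksum).
#'
#' @param result \code{rg_pipeline_result}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(result$detection)) {
    paths$detection <- file.path(out_dir, "detected.tsv")
    utils::write.table(result$detection$detected, paths$detection, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (length(result$annotations)) {
    paths$annotations <- file.path(out_dir, "annotations.json")
    ann <- lapply(result$annotations, function(a) {
      list(feature_id = a$feature_id, precursor_mz = a$precursor_mz,
           annotated_fraction = a$annotated_fraction,
           max_annotated_mz = a$max_annotated_mz, residual = a$residual,
           assignments = a$assignments, losses = a$losses)
    })
    jsonlite::write_json(ann, paths$annotations, auto_unbox = TRUE,
                         digits = NA, na = "null", dataframe = "rows")
  }
  if (length(result$candidates)) {
    paths$predictions <- file.path(out_dir, "predictions.tsv")
    tab <- do.call(rbind, lapply(names(result$candidates), function(fid) {
      x <- result$candidates[[fid]]
      if (!nrow(x)) return(NULL)
      cbind(feature_id = fid, as.data.frame(x))
    }))
    if (is.null(tab)) tab <- data.frame(feature_id = character())
    utils::write.table(tab, paths$predictions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(result$correlations$fragments)) {
    paths$correlations <- file.path(out_dir, "correlations.tsv")
    utils::write.table(result$correlations$fragments, paths$correlations,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(result$summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}

#' @export
print.rg_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<rg_pipeline_result>\n")
  cat(sprintf("  features: %d   detected RGs: %d\n", s$n_features, s$n_detected))
  if (!is.na(s$annotation_coverage)) {
    cat(sprintf("  annotation coverage: %.1f%%\n", 100 * s$annotation_coverage))
  }
  if (!is.null(s$pct_with_prediction) && !is.na(s$pct_with_prediction)) {
    cat(sprintf("  peaks with >=1 prediction: %d (%.1f%%)\n",
                s$n_with_prediction, s$pct_with_prediction))
  }
  invisible(x)
}
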