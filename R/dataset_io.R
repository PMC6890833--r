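# Reading ABIDE-style ROI time-series files and phenotype tables, and
# writing cross-validation metric reports.
#
# File dialect: whitespace-delimited numeric text, one scan timepoint per
# line, one column per region.  Lines starting with '#' are comments; blank
# lines are ignored.  This matches the ".1D" ROI exports distributed with
# ABIDE-style preprocessing pipelines.

#' Construct a per-subject ROI time-series object
#'
#' Bundles one subject's region-averaged signal matrix (rows = timepoints,
#' columns = regions) with its identifier, binary diagnosis label
#' (1 = patient, 0 = control) and acquisition site.
#'
#' @param data numeric matrix, T timepoints x m regions; all entries finite.
#' @param subject_id character scalar.
#' @param label binary diagnosis label (`1` patient, `0` control) or `NA`
#'   when not yet joined to a phenotype table.
#' @param site_id character scalar or `NA`.
#' @return An object of class `roi_ts`.
#' @export
roi_timeseries <- function(data, subject_id, label = NA_integer_,
                           site_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop_fc("time series for subject '%s' must be at least 2x2 (got %dx%d)",
            subject_id, nrow(data), ncol(data), class = "fcdiag_shape_error")
  if (!all(is.finite(data)))
    stop_fc("time series for subject '%s' contains non-finite values",
            subject_id, class = "fcdiag_nonfinite_error")
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop_fc("label must be 0, 1 or NA", class = "fcdiag_value_error")
  structure(
    list(subject_id = as.character(subject_id), data = data,
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         site_id = as.character(site_id)),
    class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s: %d timepoints x %d regions, label = %s, site = %s\n",
              x$subject_id, nrow(x$data), ncol(x$data),
              ifelse(is.na(x$label), "NA", x$label), x$site_id))
  invisible(x)
}

#' Read one subject's ROI time series from a .1D-style text file
#'
#' Parses a whitespace-delimited numeric file (rows = timepoints, columns =
#' regions).  Lines beginning with `#` and blank lines are skipped.  Row and
#' column order in the returned matrix match the file.
#'
#' @param path path to the file.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param label,site_id optional phenotype fields to attach (see
#'   [load_dataset()] for bulk joining).
#' @param header if `TRUE`, the first non-comment line is treated as column
#'   names and skipped.
#' @return An object of class [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, subject_id = NULL,
                                label = NA_integer_, site_id = NA_character_,
                                header = FALSE) {
  if (!file.exists(path))
    stop_fc("file not found: %s", path, class = "fcdiag_io_error")
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  body <- lines[keep]
  if (header && length(body) > 0L) {
    body <- body[-1L]
    line_no <- line_no[-1L]
  }
  if (length(body) == 0L)
    stop_fc("no data rows in %s (file is empty or comment-only)", path,
            class = "fcdiag_empty_error")
  tokens <- strsplit(trimws(body), "[ \t]+")
  widths <- lengths(tokens)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop_fc("ragged row in %s: line %d has %d values, expected %d",
            path, line_no[bad], widths[bad], widths[1L],
            class = "fcdiag_format_error")
  }
  flat <- unlist(tokens, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  bad_tok <- is.na(vals) & !toupper(flat) %in% c("NA", "NAN")
  if (any(bad_tok))
    stop_fc("non-numeric token '%s' in %s", flat[which(bad_tok)[1L]], path,
            class = "fcdiag_parse_error")
  if (!all(is.finite(vals)))
    stop_fc("non-finite value in %s: preprocessed series must be complete",
            path, class = "fcdiag_nonfinite_error")
  mat <- matrix(vals, nrow = length(body), ncol = widths[1L], byrow = TRUE)
  roi_timeseries(mat, subject_id = subject_id, label = label,
                 site_id = site_id)
}

#' Write an ROI time series in the .1D dialect
#'
#' Values are printed with 17 significant digits so that a written matrix
#' re-read with [read_roi_timeseries()] round-trips to within floating-point
#' printing precision.
#'
#' @param x an `roi_ts` object or numeric matrix.
#' @param path output path.
#' @export
write_roi_timeseries <- function(x, path) {
  mat <- if (inherits(x, "roi_ts")) x$data else as.matrix(x)
  rows <- apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(rows, path)
  invisible(path)
}

#' Read a phenotype table and map diagnosis codes to binary labels
#'
#' The internal label convention is 1 = patient, 0 = control everywhere; the
#' mapping from source diagnosis codes happens only here.  The default
#' mapping follows the ABIDE convention (`DX_GROUP` 1 = patient, 2 = control).
#'
#' @param path path to a CSV file.
#' @param label_mapping named vector mapping raw diagnosis codes (as
#'   character names) to `0`/`1`.
#' @param subject_col,dx_col,site_col column names in the CSV.
#' @return A data frame of class `phenotype_table` with columns
#'   `subject_id`, `dx_code`, `label`, `site_id`.
#' @export
read_phenotypes <- function(path, label_mapping = c(`1` = 1L, `2` = 0L),
                            subject_col = "SUB_ID", dx_col = "DX_GROUP",
                            site_col = "SITE_ID") {
  if (!file.exists(path))
    stop_fc("file not found: %s", path, class = "fcdiag_io_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c(subject_col, dx_col, site_col))
    if (!col %in% names(tab))
      stop_fc("phenotype file %s lacks column '%s'", path, col,
              class = "fcdiag_format_error")
  ids <- trimws(tab[[subject_col]])
  if (anyDuplicated(ids))
    stop_fc("duplicate subject id '%s' in %s", ids[duplicated(ids)][1L], path,
            class = "fcdiag_duplicate_error")
  codes <- trimws(tab[[dx_col]])
  unknown <- setdiff(unique(codes), names(label_mapping))
  if (length(unknown) > 0L)
    stop_fc("diagnosis code '%s' not present in label_mapping", unknown[1L],
            class = "fcdiag_mapping_error")
  out <- data.frame(subject_id = ids, dx_code = codes,
                    label = as.integer(label_mapping[codes]),
                    site_id = trimws(tab[[site_col]]),
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", class(out))
  out
}

#' Load a directory of ROI time-series files joined to a phenotype table
#'
#' Expects one `<subject_id><suffix>` file per phenotype record.
#'
#' @param dir directory containing the time-series files.
#' @param phenotypes a `phenotype_table` from [read_phenotypes()].
#' @param suffix file suffix appended to each subject id (default `".1D"`).
#' @return A list of `roi_ts` objects, one per phenotype record.
#' @export
load_dataset <- function(dir, phenotypes, suffix = ".1D") {
  lapply(seq_len(nrow(phenotypes)), function(i) {
    p <- file.path(dir, paste0(phenotypes$subject_id[i], suffix))
    read_roi_timeseries(p, subject_id = phenotypes$subject_id[i],
                        label = phenotypes$label[i],
                        site_id = phenotypes$site_id[i])
  })
}

#' Write a cross-validation metrics report
#'
#' Writes one row per fold plus a `mean` row (accuracy, sensitivity,
#' specificity, AUC) to `path`, and the per-fold ROC points
#' (fpr, tpr, threshold) to a sibling file `<path without .csv>_roc.csv`.
#'
#' @param results a `cv_result` from [cross_validate()] or a data frame with
#'   columns `fold`, `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @param path output CSV path.
#' @return Invisibly, the two paths written.
#' @export
write_metrics <- function(results, path) {
  if (inherits(results, "cv_result")) {
    folds <- results$folds
    roc <- do.call(rbind, lapply(seq_along(results$details), function(i) {
      pts <- results$details[[i]]$roc_points
      cbind(fold = i, pts)
    }))
  } else {
    folds <- as.data.frame(results)
    roc <- NULL
  }
  if (is.null(folds) || nrow(folds) == 0L)
    stop_fc("empty results: nothing to write", class = "fcdiag_empty_error")
  need <- c("fold", "accuracy", "sensitivity", "specificity", "auc")
  if (!all(need %in% names(folds)))
    stop_fc("results must have columns %s", paste(need, collapse = ", "),
            class = "fcdiag_format_error")
  folds <- folds[, need]
  mean_row <- data.frame(fold = "mean",
                         accuracy = mean(folds$accuracy, na.rm = TRUE),
                         sensitivity = mean(folds$sensitivity, na.rm = TRUE),
                         specificity = mean(folds$specificity, na.rm = TRUE),
                         auc = mean(folds$auc, na.rm = TRUE))
  folds$fold <- as.character(folds$fold)
  out <- rbind(folds, mean_row)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop_fc("cannot write metrics to %s", path, class = "fcdiag_io_error")
  roc_path <- paste0(sub("\\.csv$", "", path), "_roc.csv")
  if (!is.null(roc)) utils::write.csv(roc, roc_path, row.names = FALSE)
  invisible(c(metrics = path, roc = roc_path))
}
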