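#' Read a feature table from CSV or TSV
#'
#' Expects a delimited file with a header, a sample-identifier first column,
#' one outcome column, and numeric feature columns. The delimiter is
#' inferred from the extension (`.tsv`/`.tab`/`.txt` are tab-separated,
#' anything else comma-separated). Missing or non-numeric cells are an
#' error that names the offending cell; no imputation is attempted.
#'
#' @param path File path.
#' @param outcome Name of the outcome column that must be present.
#' @return A tibble with the columns in file order; the identifier column
#'   name is recorded in the `"id_col"` attribute.
#' @export
read_feature_table <- function(path, outcome = "y") {
  delim <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  if (!outcome %in% names(data)) {
    stop_hifit(sprintf("outcome column '%s' not found; available columns: %s",
                       outcome, paste(names(data), collapse = ", ")))
  }
  id_col <- names(data)[1]
  value_cols <- setdiff(names(data), id_col)
  for (col in value_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop_hifit(sprintf("non-numeric value in column '%s', row %d", col,
                         if (is.na(bad)) 1L else bad))
    }
    if (anyNA(v)) {
      stop_hifit(sprintf("missing value in column '%s', row %d", col,
                         which(is.na(v))[1]))
    }
  }
  attr(data, "id_col") <- id_col
  data
}

#' Write a feature table to CSV or TSV
#'
#' Inverse of [read_feature_table()]; the delimiter again follows the
#' extension, so a written table reads back identically.
#'
#' @param data Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  delim <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Write pipeline results to a directory
#'
#' Emits the importance table (`importance.csv`, with >= 6 significant
#' digits on every statistic), the selected feature list
#' (`selected_features.txt`), held-out metrics when present
#' (`metrics.json`), an echo of the run configuration sufficient to
#' reproduce the run (`config.json`), and a manifest with an MD5 hash of
#' every emitted file (`manifest.json`).
#'
#' @param result A [hifit()] result.
#' @param dir Output directory (created if needed).
#' @return A tibble manifest (file, md5), invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "hifit_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  imp_path <- file.path(dir, "importance.csv")
  readr::write_csv(result$importance, imp_path)
  files <- c(files, imp_path)

  sel_path <- file.path(dir, "selected_features.txt")
  writeLines(result$final_features, sel_path)
  files <- c(files, sel_path)

  if (!is.null(result$metrics)) {
    met_path <- file.path(dir, "metrics.json")
    jsonlite::write_json(as.list(result$metrics), met_path,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, met_path)
  }

  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(result$config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, cfg_path)

  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
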