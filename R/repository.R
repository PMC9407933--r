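#' Feature table of repository entries
#'
#' The repository index: one row per fully measured subject, holding the five
#' simplified features (F1-F4 strength in newtons, anterior reach D1 in cm)
#' extracted from that subject's full ICZ model.
#'
#' @param x A data frame with columns `entry_id`, `F1_N`, `F2_N`, `F3_N`,
#'   `F4_N`, `D1_cm`.
#' @return A data frame of class `"icz_feature_table"` with validated,
#'   uniquely identified rows in stable order.
#' @seealso [compute_feature_bounds()], [load_repository()]
#' @export
feature_table <- function(x) {
  need <- c("entry_id", "F1_N", "F2_N", "F3_N", "F4_N", "D1_cm")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    miss <- if (is.data.frame(x)) setdiff(need, names(x)) else need
    icz_schema_error(sprintf("feature table is missing column(s): %s",
                             paste(miss, collapse = ", ")))
  }
  x <- as.data.frame(x)[need]
  if (nrow(x) == 0L) icz_validation_error("feature table must be non-empty")
  x$entry_id <- as.character(x$entry_id)
  if (anyNA(x$entry_id) || any(!nzchar(x$entry_id))) {
    icz_validation_error("entry_id values must be non-empty")
  }
  dup <- x$entry_id[duplicated(x$entry_id)]
  if (length(dup) > 0L) {
    icz_schema_error(sprintf("duplicated entry_id: %s",
                             paste(unique(dup), collapse = ", ")))
  }
  for (nm in need[-1L]) {
    v <- x[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L]
      icz_schema_error(sprintf("column %s, row %s: non-numeric or missing value",
                               nm, if (length(bad)) bad else "?"))
    }
    if (any(v <= 0)) {
      icz_validation_error(sprintf(
        "column %s, row %d: feature values must be strictly positive (got %g)",
        nm, which(v <= 0)[1L], v[which(v <= 0)[1L]]
      ))
    }
  }
  rownames(x) <- NULL
  class(x) <- c("icz_feature_table", "data.frame")
  x
}

#' Per-feature bounds of a repository
#'
#' For each of the five features, the minimum and maximum over the repository
#' rows and the normalization interval `R = max - min` used by min-max
#' normalization.  Bounds are computed over repository rows only; a query
#' user's values are never included.
#'
#' @param table An [feature_table()].
#' @return A data frame of class `"icz_feature_bounds"` with columns
#'   `feature` (`F1`, `F2`, `F3`, `F4`, `D1`), `min_value`, `max_value`, `R`.
#' @examples
#' ws <- example_worksheet()
#' compute_feature_bounds(ws$table)
#' @export
compute_feature_bounds <- function(table) {
  table <- feature_table(table)
  cols <- c(F1 = "F1_N", F2 = "F2_N", F3 = "F3_N", F4 = "F4_N", D1 = "D1_cm")
  out <- data.frame(
    feature = names(cols),
    min_value = vapply(cols, function(cn) min(table[[cn]]), numeric(1)),
    max_value = vapply(cols, function(cn) max(table[[cn]]), numeric(1)),
    row.names = NULL
  )
  out$R <- out$max_value - out$min_value
  class(out) <- c("icz_feature_bounds", "data.frame")
  out
}

REPO_CSV_HEADER <- c("entry_id", "F1_N", "F2_N", "F3_N", "F4_N", "D1_cm")

#' Save and load a feature repository
#'
#' The on-disk format is a UTF-8 comma-separated file with header
#' `entry_id,F1_N,F2_N,F3_N,F4_N,D1_cm`.  `path` may be the CSV file itself
#' or a repository directory containing `features.csv` plus (optionally) one
#' `<entry_id>.json` full ICZ model per subject under `models/`.
#'
#' @param table An [feature_table()].
#' @param path CSV file path (for `save_repository`) or CSV/directory path
#'   (for `load_repository`).
#' @return `load_repository()` returns an `"icz_feature_table"`; when full
#'   models are present their directory is attached as attribute
#'   `"models_dir"`.  `save_repository()` returns `path` invisibly.
#'   Row order is preserved exactly across save/load.
#' @export
save_repository <- function(table, path) {
  table <- feature_table(table)
  if (dir.exists(path)) path <- file.path(path, "features.csv")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname save_repository
#' @export
load_repository <- function(path) {
  models_dir <- NULL
  if (dir.exists(path)) {
    csv <- file.path(path, "features.csv")
    if (!file.exists(csv)) {
      icz_schema_error(sprintf("repository directory %s has no features.csv", path))
    }
    md <- file.path(path, "models")
    if (dir.exists(md)) models_dir <- md
    path <- csv
  }
  if (!file.exists(path)) {
    icz_schema_error(sprintf("repository file not found: %s", path))
  }
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                    check.names = FALSE),
    error = function(e) icz_schema_error(sprintf("cannot parse %s: %s",
                                                 path, conditionMessage(e)))
  )
  miss <- setdiff(REPO_CSV_HEADER, names(raw))
  if (length(miss) > 0L) {
    icz_schema_error(sprintf("%s is missing column(s): %s",
                             path, paste(miss, collapse = ", ")))
  }
  raw <- raw[REPO_CSV_HEADER]
  for (nm in REPO_CSV_HEADER[-1L]) {
    num <- suppressWarnings(as.numeric(raw[[nm]]))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      icz_schema_error(sprintf(
        "%s: column %s, row %d: non-numeric value '%s'",
        path, nm, bad, raw[[nm]][bad]
      ))
    }
    raw[[nm]] <- num
  }
  out <- feature_table(raw)
  if (!is.null(models_dir)) attr(out, "models_dir") <- models_dir
  out
}

#' Load the full ICZ model linked to a repository entry
#'
#' @param table A table returned by [load_repository()] from a repository
#'   directory with a `models/` subdirectory.
#' @param entry_id Entry identifier.
#' @return An [icz_model()].
#' @export
load_repository_model <- function(table, entry_id) {
  md <- attr(table, "models_dir")
  if (is.null(md)) {
    icz_schema_error("this repository has no linked full models (no models/ directory)")
  }
  if (!entry_id %in% table$entry_id) {
    icz_validation_error(sprintf("unknown entry_id '%s'", entry_id))
  }
  read_icz_model(file.path(md, paste0(entry_id, ".json")))
}
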