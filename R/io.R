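#' Read a criterion-specification config
#'
#' The config is a YAML or JSON list of entries
#' `{name, direction: max|min, rule: 1-5 | "numeric", scale: [min, max]}`.
#' `scale` is optional when a built-in rule is named (the rule's value
#' range is used). Format is chosen by file extension (`.json` vs
#' `.yaml`/`.yml`).
#'
#' @param path config file path.
#' @return list of [criterion_spec()].
#' @export
read_criteria_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(spec$criteria)) spec <- spec$criteria
  lapply(spec, function(s) {
    if (is.null(s$name) || is.null(s$direction)) {
      stop("each criterion needs `name` and `direction`", call. = FALSE)
    }
    rule <- if (is.null(s$rule)) "numeric" else s$rule
    sc <- unlist(s$scale)
    criterion_spec(s$name, direction = s$direction, rule = rule,
                   scale_min = if (length(sc)) sc[1] else NULL,
                   scale_max = if (length(sc)) sc[2] else NULL)
  })
}

#' Read an assessment table or decision matrix from CSV
#'
#' Layout: header row of criterion names, first column the alternative
#' names, remaining cells either qualitative labels or numeric scores.
#' Cells are treated as qualitative if any is non-numeric.
#'
#' @param path CSV path (UTF-8, comma-separated).
#' @param criteria list of [criterion_spec()] (e.g. from
#'   [read_criteria_config()]) matching the CSV columns by position.
#' @return A [raw_assessment_table()] or [decision_matrix()].
#' @export
read_decision_csv <- function(path, criteria) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (ncol(df) < 2L) stop("CSV needs an alternative column plus criteria",
                          call. = FALSE)
  alt <- as.character(df[[1L]])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  if (length(criteria) != ncol(cells)) {
    stop(sprintf("criteria config has %d entries but CSV has %d criterion columns",
                 length(criteria), ncol(cells)), call. = FALSE)
  }
  numeric_ok <- suppressWarnings(!anyNA(as.numeric(cells)))
  if (numeric_ok) {
    x <- matrix(as.numeric(cells), nrow(cells), ncol(cells))
    decision_matrix(x, criteria, alt)
  } else {
    raw_assessment_table(cells, criteria, alt)
  }
}

#' Write a decision matrix or assessment table to CSV
#'
#' Inverse layout of [read_decision_csv()].
#'
#' @param x a [decision_matrix()] or [raw_assessment_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_csv <- function(x, path) {
  cells <- if (inherits(x, "decision_matrix")) x$x else x$labels
  df <- data.frame(alternative = x$alternatives, cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a criterion-specification config
#'
#' @param criteria list of [criterion_spec()].
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_criteria_config <- function(criteria, path) {
  spec <- lapply(criteria, function(s) {
    list(name = s$name, direction = s$direction,
         rule = if (is.null(s$rule)) "numeric" else s$rule$rule_id,
         scale = c(s$scale_min, s$scale_max))
  })
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}
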