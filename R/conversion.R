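#' Ordinal conversion rules
#'
#' A conversion rule maps an ordered vocabulary of qualitative labels
#' (best/largest first) onto descending consecutive integers ending at 1.
#' Five built-in rules cover the vocabularies used by the bundled case
#' study; custom rules can be constructed for other ordinal scales.
#'
#' @param rule_id small integer identifier.
#' @param ordered_labels character vector of labels, best first.
#' @param values integer scores assigned to the labels; must be
#'   descending consecutive integers ending at 1. Defaults to
#'   `length(ordered_labels):1`.
#' @return An object of class `conversion_rule` with elements
#'   `rule_id`, `ordered_labels`, `values`.
#' @examples
#' r <- conversion_rule(1, c("excellent", "very good", "good", "fair", "poor"))
#' rule_lookup(r, "good") # 3
#' @export
conversion_rule <- function(rule_id, ordered_labels,
                            values = seq(length(ordered_labels), 1L)) {
  rule_id <- as.integer(rule_id)
  ordered_labels <- as.character(ordered_labels)
  values <- as.integer(values)
  if (length(ordered_labels) != length(values)) {
    stop("`ordered_labels` and `values` must have equal length", call. = FALSE)
  }
  if (length(values) < 1L || values[length(values)] != 1L ||
      any(diff(values) != -1L)) {
    stop("`values` must be descending consecutive integers ending at 1",
         call. = FALSE)
  }
  key <- tolower(trimws(ordered_labels))
  if (anyDuplicated(key)) {
    stop("labels must be unique within a rule (case-insensitive)",
         call. = FALSE)
  }
  structure(
    list(rule_id = rule_id, ordered_labels = ordered_labels, values = values),
    class = "conversion_rule"
  )
}

#' Built-in qualitative-to-numeric conversion rules
#'
#' Returns the five ordinal vocabularies used to score the bundled case
#' study:
#' \describe{
#'   \item{1}{excellent / very good / good / fair / poor -> 5..1}
#'   \item{2}{lengthy / moderate / minimal -> 3..1}
#'   \item{3}{high / medium / low / none -> 4..1}
#'   \item{4}{substantial / moderate / minimal / none -> 4..1}
#'   \item{5}{easiest / easy / moderate / difficult -> 4..1}
#' }
#'
#' @return A named list of [conversion_rule()] objects, names `"1"`..`"5"`.
#' @export
builtin_rules <- function() {
  rules <- list(
    conversion_rule(1L, c("excellent", "very good", "good", "fair", "poor")),
    conversion_rule(2L, c("lengthy", "moderate", "minimal")),
    conversion_rule(3L, c("high", "medium", "low", "none")),
    conversion_rule(4L, c("substantial", "moderate", "minimal", "none")),
    conversion_rule(5L, c("easiest", "easy", "moderate", "difficult"))
  )
  names(rules) <- vapply(rules, function(r) as.character(r$rule_id), "")
  rules
}

#' Look up the numeric score of a qualitative label
#'
#' Matching is case-insensitive and ignores surrounding whitespace.
#'
#' @param rule a [conversion_rule()].
#' @param label character vector of labels to resolve.
#' @return integer vector of scores.
#' @export
rule_lookup <- function(rule, label) {
  stopifnot(inherits(rule, "conversion_rule"))
  idx <- match(tolower(trimws(label)), tolower(trimws(rule$ordered_labels)))
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop(sprintf("label(s) %s not in vocabulary of rule %d (%s)",
                 paste(sQuote(bad), collapse = ", "), rule$rule_id,
                 paste(rule$ordered_labels, collapse = ", ")),
         call. = FALSE)
  }
  rule$values[idx]
}

#' @export
print.conversion_rule <- function(x, ...) {
  cat(sprintf("Conversion rule %d: %s\n", x$rule_id,
              paste(sprintf("%s=%d", x$ordered_labels, x$values),
                    collapse = ", ")))
  invisible(x)
}

#' Criterion specification
#'
#' Describes one decision criterion: its optimization direction
#' (`"max"` for benefit, `"min"` for cost), the conversion rule used to
#' score it (or `"numeric"` for directly numeric input), and the
#' attainable scale bounds. The bounds default to the rule's value range
#' and are used for reflection of cost criteria prior to entropy
#' weighting, so they describe the attainable scale, not the observed
#' column range.
#'
#' @param name criterion name.
#' @param direction `"max"` (benefit) or `"min"` (cost).
#' @param rule a [conversion_rule()], a built-in rule id 1-5, or
#'   `"numeric"`.
#' @param scale_min,scale_max integer scale bounds; defaulted from the
#'   rule when one is given.
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(name, direction = c("max", "min"),
                           rule = "numeric",
                           scale_min = NULL, scale_max = NULL) {
  direction <- match.arg(direction)
  if (is.character(rule) && length(rule) == 1L && grepl("^[0-9]+$", rule)) {
    rule <- as.integer(rule)
  }
  if (is.numeric(rule) && length(rule) == 1L) {
    rules <- builtin_rules()
    key <- as.character(as.integer(rule))
    if (!key %in% names(rules)) {
      stop("built-in rule id must be 1..5", call. = FALSE)
    }
    rule <- rules[[key]]
  }
  if (inherits(rule, "conversion_rule")) {
    if (is.null(scale_min)) scale_min <- min(rule$values)
    if (is.null(scale_max)) scale_max <- max(rule$values)
  } else if (identical(rule, "numeric")) {
    rule <- NULL
  } else {
    stop("`rule` must be a conversion_rule, a rule id 1-5, or \"numeric\"",
         call. = FALSE)
  }
  if (is.null(scale_min) || is.null(scale_max)) {
    stop("numeric criteria require explicit `scale_min` and `scale_max`",
         call. = FALSE)
  }
  scale_min <- as.integer(scale_min)
  scale_max <- as.integer(scale_max)
  if (scale_min < 1L || scale_max <= scale_min) {
    stop("need scale_min >= 1 and scale_max > scale_min", call. = FALSE)
  }
  structure(
    list(name = as.character(name), direction = direction, rule = rule,
         scale_min = scale_min, scale_max = scale_max),
    class = "criterion_spec"
  )
}

#' @export
print.criterion_spec <- function(x, ...) {
  cat(sprintf("Criterion %s [%s, scale %d-%d, rule %s]\n", sQuote(x$name),
              x$direction, x$scale_min, x$scale_max,
              if (is.null(x$rule)) "numeric" else x$rule$rule_id))
  invisible(x)
}

#' Raw qualitative assessment table
#'
#' Alternatives-by-criteria grid of qualitative labels, each column
#' governed by its criterion's conversion rule. Validates rectangularity
#' and vocabulary membership on construction.
#'
#' @param labels character matrix (alternatives x criteria) of labels.
#' @param criteria list of [criterion_spec()], one per column, each with
#'   a conversion rule.
#' @param alternatives alternative names; defaults to the row names of
#'   `labels`.
#' @return An object of class `raw_assessment_table`.
#' @export
raw_assessment_table <- function(labels, criteria, alternatives = rownames(labels)) {
  labels <- as.matrix(labels)
  if (!is.character(labels)) storage.mode(labels) <- "character"
  if (anyNA(labels)) stop("label grid contains missing cells", call. = FALSE)
  if (length(criteria) != ncol(labels)) {
    stop(sprintf("got %d criteria for %d label columns (ragged input?)",
                 length(criteria), ncol(labels)), call. = FALSE)
  }
  ok <- vapply(criteria, inherits, TRUE, what = "criterion_spec")
  if (!all(ok)) stop("`criteria` must be a list of criterion_spec", call. = FALSE)
  if (is.null(alternatives)) {
    alternatives <- paste0("Alternative ", seq_len(nrow(labels)))
  }
  if (length(alternatives) != nrow(labels)) {
    stop("alternative names do not match the number of rows", call. = FALSE)
  }
  dimnames(labels) <- list(alternatives,
                           vapply(criteria, `[[`, "", "name"))
  # fail construction on out-of-vocabulary cells, naming the offender
  for (j in seq_along(criteria)) {
    rule <- criteria[[j]]$rule
    if (is.null(rule)) {
      stop(sprintf("criterion %s is numeric; qualitative labels need a rule",
                   sQuote(criteria[[j]]$name)), call. = FALSE)
    }
    hit <- tolower(trimws(labels[, j])) %in% tolower(trimws(rule$ordered_labels))
    if (!all(hit)) {
      i <- which(!hit)[1L]
      stop(sprintf("cell [%s, %s]: label %s not in vocabulary of rule %d",
                   alternatives[i], criteria[[j]]$name,
                   sQuote(labels[i, j]), rule$rule_id), call. = FALSE)
    }
  }
  structure(
    list(alternatives = as.character(alternatives), criteria = criteria,
         labels = labels),
    class = "raw_assessment_table"
  )
}

#' @export
print.raw_assessment_table <- function(x, ...) {
  cat(sprintf("Qualitative assessment table: %d alternatives x %d criteria\n",
              length(x$alternatives), length(x$criteria)))
  print(x$labels, quote = FALSE)
  invisible(x)
}

#' Numeric decision matrix
#'
#' The central container: a numeric alternatives-by-criteria matrix
#' `x[i, j]` with an attached list of [criterion_spec()] giving each
#' column's direction and scale. Scores must lie within their criterion's
#' scale bounds.
#'
#' @param x numeric matrix (alternatives x criteria).
#' @param criteria list of [criterion_spec()], one per column.
#' @param alternatives alternative names; defaults to `rownames(x)`.
#' @return An object of class `decision_matrix`.
#' @export
decision_matrix <- function(x, criteria, alternatives = rownames(x)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("need at least 1 alternative and 1 criterion", call. = FALSE)
  }
  if (length(criteria) != ncol(x)) {
    stop("criteria list does not match the number of columns", call. = FALSE)
  }
  ok <- vapply(criteria, inherits, TRUE, what = "criterion_spec")
  if (!all(ok)) stop("`criteria` must be a list of criterion_spec", call. = FALSE)
  if (any(!is.finite(x))) stop("scores must be finite", call. = FALSE)
  for (j in seq_along(criteria)) {
    sp <- criteria[[j]]
    if (any(x[, j] < sp$scale_min | x[, j] > sp$scale_max)) {
      stop(sprintf("criterion %s: scores outside scale [%d, %d]",
                   sQuote(sp$name), sp$scale_min, sp$scale_max), call. = FALSE)
    }
  }
  if (is.null(alternatives)) {
    alternatives <- paste0("Alternative ", seq_len(nrow(x)))
  }
  dimnames(x) <- list(alternatives, vapply(criteria, `[[`, "", "name"))
  structure(
    list(alternatives = as.character(alternatives), criteria = criteria,
         x = x, reverse_scored = FALSE),
    class = "decision_matrix"
  )
}

#' @export
print.decision_matrix <- function(x, ...) {
  dirs <- vapply(x$criteria, `[[`, "", "direction")
  cat(sprintf("Decision matrix: %d alternatives x %d criteria%s\n",
              nrow(x$x), ncol(x$x),
              if (isTRUE(x$reverse_scored)) " (cost columns reverse-scored)" else ""))
  hdr <- x$x
  rownames(hdr) <- x$alternatives
  colnames(hdr) <- paste0(colnames(x$x), " (", dirs, ")")
  print(hdr)
  invisible(x)
}

#' @export
as.matrix.decision_matrix <- function(x, ...) x$x

#' Criterion directions of a decision problem
#' @param x a `decision_matrix` or `raw_assessment_table`.
#' @return character vector of `"max"` / `"min"`.
#' @export
criterion_directions <- function(x) {
  vapply(x$criteria, `[[`, "", "direction")
}

#' Convert a qualitative table to a numeric decision matrix
#'
#' Applies each criterion's conversion rule label-by-label; ordering of
#' alternatives and criteria is preserved. Unknown labels are rejected
#' with the offending cell named (this is enforced at table construction
#' and re-checked here).
#'
#' @param raw a [raw_assessment_table()].
#' @return A [decision_matrix()].
#' @examples
#' convert_table(load_case_study())
#' @export
convert_table <- function(raw) {
  stopifnot(inherits(raw, "raw_assessment_table"))
  x <- matrix(NA_real_, nrow(raw$labels), ncol(raw$labels))
  for (j in seq_along(raw$criteria)) {
    x[, j] <- rule_lookup(raw$criteria[[j]]$rule, raw$labels[, j])
  }
  decision_matrix(x, raw$criteria, raw$alternatives)
}
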