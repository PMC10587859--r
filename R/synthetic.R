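#' Generate a random decision problem
#'
#' Produces decision problems with the structure the analysis assumes:
#' small integer scores on bounded ordinal scales (the built-in rule
#' vocabularies), a mix of benefit and cost criteria, and optional
#' degenerate (constant) columns. Cells are sampled uniformly over the
#' rule vocabulary unless per-label probabilities are supplied;
#' degenerate columns are held constant at one sampled level. Output is
#' deterministic for a given seed and does not disturb the caller's
#' global random state.
#'
#' @param n_alternatives number of alternatives (>= 2).
#' @param criteria list of [criterion_spec()]s, or an integer count, in
#'   which case each criterion draws a random built-in rule and
#'   direction.
#' @param label_mode `"numeric"` returns a [decision_matrix()];
#'   `"qualitative"` returns a [raw_assessment_table()] whose labels are
#'   the sampled rule vocabulary terms.
#' @param degenerate_columns indices of criteria forced constant.
#' @param label_probs optional list (by criterion index) of probability
#'   weights over that criterion's scale levels, best-to-worst, for
#'   skewed or near-degenerate stress cases.
#' @param seed integer seed; identical inputs give identical output.
#' @return A `decision_matrix` or `raw_assessment_table`.
#' @examples
#' sim <- simulate_decision_problem(7, 8, seed = 42)
#' entropy_weights(sim)
#' @export
simulate_decision_problem <- function(n_alternatives,
                                      criteria,
                                      label_mode = c("numeric", "qualitative"),
                                      degenerate_columns = integer(),
                                      label_probs = NULL,
                                      seed = 1L) {
  label_mode <- match.arg(label_mode)
  m <- as.integer(n_alternatives)
  if (is.na(m) || m < 2L) {
    stop("need at least 2 alternatives to generate a problem", call. = FALSE)
  }
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    if (is.numeric(criteria) && length(criteria) == 1L) {
      n <- as.integer(criteria)
      if (n < 1L) stop("need at least 1 criterion", call. = FALSE)
      rules <- builtin_rules()
      criteria <- lapply(seq_len(n), function(j) {
        criterion_spec(paste0("C", j),
                       direction = sample(c("max", "min"), 1L),
                       rule = rules[[sample(length(rules), 1L)]])
      })
    }
    n <- length(criteria)
    x <- matrix(NA_integer_, m, n)
    for (j in seq_len(n)) {
      sp <- criteria[[j]]
      levels <- seq(sp$scale_min, sp$scale_max)
      probs <- if (!is.null(label_probs) && !is.null(label_probs[[j]])) {
        rev(label_probs[[j]])  # user gives best-to-worst; levels ascend
      } else NULL
      if (j %in% degenerate_columns) {
        x[, j] <- sample(levels, 1L, prob = probs)
      } else {
        x[, j] <- sample(levels, m, replace = TRUE, prob = probs)
      }
    }
    list(x = x, criteria = criteria)
  })
  criteria <- rng$criteria
  alt <- paste0("Alternative ", seq_len(m))
  if (label_mode == "numeric") {
    return(decision_matrix(rng$x, criteria, alt))
  }
  lab <- matrix(NA_character_, m, length(criteria))
  for (j in seq_along(criteria)) {
    rule <- criteria[[j]]$rule
    if (is.null(rule)) {
      stop(sprintf("criterion %s has no conversion rule; qualitative mode unavailable",
                   sQuote(criteria[[j]]$name)), call. = FALSE)
    }
    lab[, j] <- rule$ordered_labels[match(rng$x[, j], rule$values)]
  }
  raw_assessment_table(lab, criteria, alt)
}
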