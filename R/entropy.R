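#' Reflect cost-criterion columns onto their benefit orientation
#'
#' Entropy weighting measures how much a criterion discriminates among
#' alternatives, which presumes all columns point the same way. Each
#' cost (min-direction) column is reflected about its attainable scale,
#' `x' = scale_max + scale_min - x`, so that a low (good) cost score
#' becomes a high score; benefit columns are untouched. The result is
#' flagged so the reflection cannot be applied twice.
#'
#' @param matrix a [decision_matrix()].
#' @return A `decision_matrix` with `reverse_scored = TRUE`.
#' @export
reverse_score_cost_criteria <- function(matrix) {
  stopifnot(inherits(matrix, "decision_matrix"))
  if (isTRUE(matrix$reverse_scored)) {
    stop("matrix is already reverse-scored; refusing to reflect twice",
         call. = FALSE)
  }
  out <- matrix
  for (j in seq_along(matrix$criteria)) {
    sp <- matrix$criteria[[j]]
    if (sp$direction == "min") {
      out$x[, j] <- sp$scale_max + sp$scale_min - matrix$x[, j]
    }
  }
  out$reverse_scored <- TRUE
  out
}

#' Column shares of a decision matrix
#'
#' Normalizes each criterion column to proportions
#' `p[i, j] = x[i, j] / sum_i x[i, j]`, the distribution whose Shannon
#' entropy measures how evenly the alternatives score on that criterion.
#'
#' @param matrix a [decision_matrix()] or plain numeric matrix with all
#'   entries strictly positive.
#' @return Numeric matrix of shares; every column sums to 1.
#' @export
column_shares <- function(matrix) {
  x <- if (inherits(matrix, "decision_matrix")) matrix$x else as.matrix(matrix)
  if (any(x <= 0)) {
    stop("column shares require strictly positive scores", call. = FALSE)
  }
  sweep(x, 2L, colSums(x), "/")
}

#' Normalized Shannon entropy per criterion
#'
#' `e[j] = -(1/ln m) * sum_i p[i, j] ln p[i, j]` with the convention
#' `0 * ln 0 = 0`. Because each column of `p` is a probability
#' distribution over the `m` alternatives, `e[j]` lies in \[0, 1\], with
#' 1 for a perfectly uniform (constant-score) column.
#'
#' @param p share matrix from [column_shares()].
#' @param m number of alternatives used in the `1/ln(m)` normalizer;
#'   defaults to `nrow(p)`. Must be at least 2.
#' @return Numeric vector of entropies, one per criterion.
#' @export
entropy_per_criterion <- function(p, m = nrow(p)) {
  p <- as.matrix(p)
  if (m < 2L) stop("entropy normalizer needs m >= 2 alternatives", call. = FALSE)
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(m)
  # a uniform column attains the maximum exactly; snap away the
  # floating-point residue of log(1/m)/log(m) so d = |1 - e| is an
  # exact 0 for constant-score criteria
  uniform <- apply(p, 2L, function(col) diff(range(col)) == 0)
  e[uniform & abs(e - 1) < 1e-9] <- 1
  e
}

#' Dispersion (divergence from uniformity) per criterion
#'
#' `d[j] = |1 - e[j]|`: zero for a constant column, growing as the
#' column discriminates more among alternatives.
#'
#' @param e entropy vector from [entropy_per_criterion()].
#' @return Numeric vector of dispersions.
#' @export
dispersion <- function(e) abs(1 - e)

#' Objective criterion weights from Shannon entropy
#'
#' Pipeline: reflect cost columns onto benefit orientation (optional but
#' default), form column shares, compute normalized entropies and
#' dispersions, and normalize the dispersions to a weight vector summing
#' to 1. Criteria whose scores spread more across alternatives receive
#' larger weights; a constant column gets weight 0.
#'
#' @param matrix a [decision_matrix()].
#' @param reverse_score reflect cost columns first (default `TRUE`).
#'   Disabling is an ablation switch only: it changes cost-criterion
#'   weights and is not recommended.
#' @return A [weight_vector()] with `provenance = "entropy"` and a
#'   `diagnostics` attribute list holding `e`, `d` and `m`.
#' @examples
#' w <- entropy_weights(case_study_matrix())
#' round(w, 2)
#' @export
entropy_weights <- function(matrix, reverse_score = TRUE) {
  stopifnot(inherits(matrix, "decision_matrix"))
  work <- if (reverse_score && !isTRUE(matrix$reverse_scored)) {
    reverse_score_cost_criteria(matrix)
  } else {
    matrix
  }
  m <- nrow(work$x)
  p <- column_shares(work)
  e <- entropy_per_criterion(p, m)
  d <- dispersion(e)
  if (sum(d) <= 0) {
    stop(paste("degenerate matrix: every column is constant, so entropy",
               "weights are undefined; consider equal_weights()"),
         call. = FALSE)
  }
  w <- weight_vector(d / sum(d), provenance = "entropy",
                     criteria = colnames(work$x))
  attr(w, "diagnostics") <- list(e = e, d = d, m = m)
  w
}

#' Entropy weighting report in tabular form
#'
#' Lays out the entropy `e`, dispersion `d` and weight `w` of each
#' criterion as a data frame (criteria in columns, one row per
#' quantity), convenient for printing or CSV export.
#'
#' @param w a weight vector produced by [entropy_weights()].
#' @param digits optional rounding for display; `NULL` keeps full
#'   precision.
#' @return A data.frame with rows `e_j`, `d_j`, `w_j`.
#' @export
entropy_report <- function(w, digits = NULL) {
  diag <- attr(w, "diagnostics")
  if (is.null(diag)) stop("weight vector carries no entropy diagnostics",
                          call. = FALSE)
  tab <- rbind(e_j = diag$e, d_j = diag$d, w_j = as.numeric(w))
  colnames(tab) <- names(w)
  if (!is.null(digits)) tab <- round_half_up(tab, digits)
  as.data.frame(tab)
}
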