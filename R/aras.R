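#' Optimal-alternative row
#'
#' The ideal alternative scores the column maximum on every benefit
#' criterion and the column minimum on every cost criterion; it is
#' prepended to the matrix before normalization so each alternative is
#' scored relative to it.
#'
#' @param matrix a [decision_matrix()].
#' @return Named numeric vector, one entry per criterion.
#' @export
optimal_row <- function(matrix) {
  stopifnot(inherits(matrix, "decision_matrix"))
  dirs <- criterion_directions(matrix)
  x0 <- vapply(seq_along(dirs), function(j) {
    if (dirs[j] == "min") min(matrix$x[, j]) else max(matrix$x[, j])
  }, numeric(1))
  names(x0) <- colnames(matrix$x)
  x0
}

#' Extend a decision matrix with its optimal row
#'
#' @param matrix a [decision_matrix()].
#' @return An object of class `extended_matrix`: the optimal row at
#'   index 1 followed by the alternatives, with criteria carried through.
#' @export
extend_matrix <- function(matrix) {
  x0 <- optimal_row(matrix)
  rows <- rbind(optimal = x0, matrix$x)
  structure(
    list(alternatives = matrix$alternatives, criteria = matrix$criteria,
         rows = rows),
    class = "extended_matrix"
  )
}

#' Direction-aware normalization of an extended matrix
#'
#' Benefit columns are divided by their sum over all rows (optimal row
#' included). Cost columns are first inverted entry-wise
#' (`x* = 1/x`) and the reciprocals normalized the same way, so a small
#' cost turns into a large share. Every normalized column sums to 1.
#'
#' @param ext an [extend_matrix()] result.
#' @return Numeric matrix of shares, rows `optimal` then alternatives.
#' @export
normalize_extended <- function(ext) {
  stopifnot(inherits(ext, "extended_matrix"))
  dirs <- vapply(ext$criteria, `[[`, "", "direction")
  out <- ext$rows
  for (j in seq_along(dirs)) {
    col <- ext$rows[, j]
    if (dirs[j] == "min") {
      if (any(col <= 0)) {
        stop(sprintf("cost criterion %s: reciprocal undefined for values <= 0",
                     sQuote(colnames(ext$rows)[j])), call. = FALSE)
      }
      col <- 1 / col
    } else {
      if (any(col < 0) || sum(col) <= 0) {
        stop(sprintf("benefit criterion %s: need non-negative values with a positive sum",
                     sQuote(colnames(ext$rows)[j])), call. = FALSE)
      }
    }
    out[, j] <- col / sum(col)
  }
  out
}

#' Weight a normalized matrix
#'
#' Multiplies each normalized column by its criterion weight; the
#' weighted column sums then equal the weights.
#'
#' @param normalized share matrix from [normalize_extended()].
#' @param w a [weight_vector()] matching the column count.
#' @return Weighted share matrix.
#' @export
apply_weights <- function(normalized, w) {
  if (length(w) != ncol(normalized)) {
    stop(sprintf("weight vector length %d does not match %d criteria",
                 length(w), ncol(normalized)), call. = FALSE)
  }
  sweep(normalized, 2L, as.numeric(w), "*")
}

#' Optimality values, utility degrees and ranking
#'
#' Row sums of the weighted matrix give the optimality function `S_i`;
#' dividing by the optimal row's value `S_opt` gives each alternative's
#' utility degree `K_i` in (0, 1]. Alternatives are ranked by descending
#' `K`, ties broken by original input order (stable sort).
#'
#' @param weighted weighted share matrix from [apply_weights()]; row 1
#'   must be the optimal row.
#' @return An object of class `aras_result` with elements `S` (per
#'   alternative), `S_opt`, `K`, `ranking` (alternative names in rank
#'   order) and `rank_index` (permutation of alternative indices).
#' @export
optimality_and_utility <- function(weighted) {
  S_all <- rowSums(weighted)
  S_opt <- S_all[1L]
  if (S_opt <= 0) stop("optimal-row optimality value must be positive",
                       call. = FALSE)
  S <- S_all[-1L]
  K <- S / S_opt
  ord <- order(-K)  # stable: ties keep input order
  alternatives <- rownames(weighted)[-1L]
  structure(
    list(alternatives = alternatives, S = unname(S), S_opt = unname(S_opt),
         K = unname(K), ranking = alternatives[ord], rank_index = ord),
    class = "aras_result"
  )
}

#' Run the full ARAS pipeline
#'
#' Composition of [optimal_row()] / [extend_matrix()],
#' [normalize_extended()], [apply_weights()] and
#' [optimality_and_utility()]. Cost criteria are handled by the
#' reciprocal transform inside normalization; the input matrix must not
#' be reverse-scored (that reflection belongs to entropy weighting
#' only).
#'
#' @param matrix a [decision_matrix()].
#' @param w a [weight_vector()]; defaults to [entropy_weights()] of the
#'   matrix.
#' @return An [optimality_and_utility()] result.
#' @examples
#' res <- run_aras(case_study_matrix())
#' res$ranking[1] # the recommended alternative
#' @export
run_aras <- function(matrix, w = entropy_weights(matrix)) {
  stopifnot(inherits(matrix, "decision_matrix"))
  if (isTRUE(matrix$reverse_scored)) {
    stop("run ARAS on the original direction-annotated matrix, not the reverse-scored one",
         call. = FALSE)
  }
  weighted <- apply_weights(normalize_extended(extend_matrix(matrix)), w)
  res <- optimality_and_utility(weighted)
  res$weights <- w
  res
}

#' @export
print.aras_result <- function(x, digits = 3, ...) {
  cat(sprintf("ARAS result (S_opt = %s)\n",
              format(round_half_up(x$S_opt, digits))))
  ord <- x$rank_index
  tab <- data.frame(
    alternative = x$alternatives[ord],
    S = round_half_up(x$S[ord], digits),
    K = round_half_up(x$K[ord], digits),
    rank = seq_along(ord)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tabulate an ARAS result
#'
#' @param result an [run_aras()] result.
#' @param digits optional display rounding (half away from zero);
#'   `NULL` keeps full precision.
#' @return data.frame with columns `alternative`, `S`, `K`, `rank`
#'   (1 = best), in input-alternative order.
#' @export
aras_table <- function(result, digits = NULL) {
  stopifnot(inherits(result, "aras_result"))
  rank <- order(result$rank_index)
  S <- result$S
  K <- result$K
  if (!is.null(digits)) {
    S <- round_half_up(S, digits)
    K <- round_half_up(K, digits)
  }
  data.frame(alternative = result$alternatives, S = S, K = K, rank = rank,
             stringsAsFactors = FALSE)
}
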