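#' Criterion weight vector
#'
#' A non-negative numeric vector summing to 1 (within 1e-12), tagged
#' with how it was produced.
#'
#' @param w numeric weights.
#' @param provenance one of `"entropy"`, `"equal"`, `"dominance"`,
#'   `"manual"`.
#' @param criteria optional criterion names.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(w,
                          provenance = c("manual", "entropy", "equal",
                                         "dominance"),
                          criteria = names(w)) {
  provenance <- match.arg(provenance)
  w <- as.numeric(w)
  if (length(w) < 1L || any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-12) {
    stop(sprintf("weights must sum to 1 (got %.15g)", sum(w)), call. = FALSE)
  }
  names(w) <- criteria
  structure(w, provenance = provenance, class = c("weight_vector", "numeric"))
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat(sprintf("Weight vector (%s):\n", attr(x, "provenance")))
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Equal criterion weights
#'
#' Every criterion gets weight `1/n`; the baseline sensitivity scenario
#' (`S0`).
#'
#' @param n_criteria number of criteria (>= 1).
#' @param criteria optional criterion names.
#' @return A [weight_vector()] with `provenance = "equal"`.
#' @examples
#' equal_weights(8) # each 0.125
#' @export
equal_weights <- function(n_criteria, criteria = NULL) {
  n <- as.integer(n_criteria)
  if (is.na(n) || n < 1L) stop("need at least one criterion", call. = FALSE)
  weight_vector(rep(1 / n, n), provenance = "equal", criteria = criteria)
}

#' Single-criterion dominance weights
#'
#' One criterion is made `k` times as important as each of the others:
#' dominant weight `k / (n - 1 + k)`, remaining weights
#' `1 / (n - 1 + k)`. The ratio `k` is preserved exactly and the vector
#' sums to 1; `k = 1` recovers [equal_weights()]. For 8 criteria, `k = 3`
#' gives 0.30 / 0.10 (scenario S1) and `k = 2` gives 2/9 / 1/9, which
#' round to the conventional 0.22 / 0.11 (scenario S2).
#'
#' @param n_criteria number of criteria (>= 2).
#' @param dominant_index index of the dominant criterion (1-based), or a
#'   criterion name when `criteria` is given.
#' @param k dominance factor (>= 1).
#' @param criteria optional criterion names.
#' @return A [weight_vector()] with `provenance = "dominance"`.
#' @examples
#' dominance_weights(8, 1, 3) # 0.30 on criterion 1, 0.10 elsewhere
#' @export
dominance_weights <- function(n_criteria, dominant_index, k, criteria = NULL) {
  n <- as.integer(n_criteria)
  if (is.na(n) || n < 2L) stop("dominance needs at least 2 criteria",
                               call. = FALSE)
  if (is.character(dominant_index)) {
    if (is.null(criteria)) {
      stop("criterion names required to resolve a named dominant criterion",
           call. = FALSE)
    }
    dominant_index <- match(dominant_index, criteria)
  }
  j <- as.integer(dominant_index)
  if (is.na(j) || j < 1L || j > n) {
    stop("dominant criterion index out of range", call. = FALSE)
  }
  if (!is.finite(k) || k < 1) stop("dominance factor k must be >= 1",
                                   call. = FALSE)
  w <- rep(1 / (n - 1 + k), n)
  w[j] <- k / (n - 1 + k)
  weight_vector(w, provenance = "dominance", criteria = criteria)
}
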