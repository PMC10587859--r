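#' Dominance-scenario grid
#'
#' Runs ARAS once per (criterion, dominance factor) combination with
#' [dominance_weights()], alongside the entropy- and equal-weight
#' baselines. By convention `k = 3` is labelled `"S1"` and `k = 2`
#' `"S2"`; other factors get `"k=<value>"` labels.
#'
#' @param matrix a [decision_matrix()].
#' @param k_values dominance factors to sweep (default `c(3, 2)`).
#' @return An object of class `scenario_grid`: list with `cells` (a
#'   list indexed by `"<criterion>|<label>"` of [run_aras()] results),
#'   `criteria`, `labels`, `k_values`, and `baselines` (entropy and
#'   equal [run_aras()] results).
#' @export
run_scenario_grid <- function(matrix, k_values = c(3, 2)) {
  stopifnot(inherits(matrix, "decision_matrix"))
  crit <- vapply(matrix$criteria, `[[`, "", "name")
  n <- length(crit)
  labels <- vapply(k_values, function(k) {
    if (isTRUE(all.equal(k, 3))) "S1"
    else if (isTRUE(all.equal(k, 2))) "S2"
    else paste0("k=", format(k))
  }, "")
  cells <- list()
  for (j in seq_len(n)) {
    for (s in seq_along(k_values)) {
      w <- dominance_weights(n, j, k_values[s], criteria = crit)
      cells[[paste(crit[j], labels[s], sep = "|")]] <- run_aras(matrix, w)
    }
  }
  baselines <- list(
    entropy = run_aras(matrix, entropy_weights(matrix)),
    equal = run_aras(matrix, equal_weights(n, criteria = crit))
  )
  structure(
    list(cells = cells, criteria = crit, labels = labels,
         k_values = k_values, baselines = baselines),
    class = "scenario_grid"
  )
}

#' Fetch one scenario cell
#'
#' @param grid a [run_scenario_grid()] result.
#' @param criterion criterion name or index.
#' @param label scenario label (e.g. `"S1"`).
#' @return The stored [run_aras()] result.
#' @export
scenario_cell <- function(grid, criterion, label) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (is.numeric(criterion)) criterion <- grid$criteria[criterion]
  key <- paste(criterion, label, sep = "|")
  cell <- grid$cells[[key]]
  if (is.null(cell)) stop(sprintf("no scenario cell %s", sQuote(key)),
                          call. = FALSE)
  cell
}

#' Compare two rankings
#'
#' Computes whether two ARAS runs over the same alternatives rank them
#' identically, their Kendall rank correlation, and the earliest rank
#' position at which the orderings diverge.
#'
#' @param a,b [run_aras()] results on the same alternative set.
#' @return A list with `identical` (logical), `kendall_tau`, and
#'   `first_divergence` (rank position, or `NA` if identical).
#' @export
compare_rankings <- function(a, b) {
  stopifnot(inherits(a, "aras_result"), inherits(b, "aras_result"))
  if (!identical(a$alternatives, b$alternatives)) {
    stop("rankings are over different alternative sets", call. = FALSE)
  }
  ra <- order(a$rank_index)  # rank of each alternative in input order
  rb <- order(b$rank_index)
  tau <- stats::cor(ra, rb, method = "kendall")
  same <- identical(a$rank_index, b$rank_index)
  div <- which(a$rank_index != b$rank_index)
  list(identical = same,
       kendall_tau = tau,
       first_divergence = if (same) NA_integer_ else div[1L])
}

#' Long-format table of a scenario grid
#'
#' One row per (criterion, scenario, alternative): its utility degree
#' and rank. Useful for CSV export and for rendering a wide scenario
#' table.
#'
#' @param grid a [run_scenario_grid()] result.
#' @param digits optional display rounding; `NULL` keeps full precision.
#' @return data.frame with columns `criterion`, `scenario`, `rank`,
#'   `alternative`, `K`.
#' @export
scenario_table <- function(grid, digits = NULL) {
  stopifnot(inherits(grid, "scenario_grid"))
  rows <- list()
  for (crit in grid$criteria) {
    for (lab in grid$labels) {
      res <- scenario_cell(grid, crit, lab)
      K <- res$K[res$rank_index]
      if (!is.null(digits)) K <- round_half_up(K, digits)
      rows[[paste(crit, lab)]] <- data.frame(
        criterion = crit, scenario = lab, rank = seq_along(K),
        alternative = res$ranking, K = K, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best-option summary across scenarios
#'
#' For every scenario cell, the top-ranked alternative and its utility
#' degree, plus the baseline (entropy-weighted) winner — a textual
#' stand-in for a clinician-facing decision flowchart.
#'
#' @param grid a [run_scenario_grid()] result.
#' @param digits display rounding for `K` (default 2).
#' @return A list with `baseline_winner`, `baseline_K`, and `cells`, a
#'   data.frame with columns `criterion`, `scenario`, `winner`, `K`.
#' @export
best_option_report <- function(grid, digits = 2) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (length(grid$cells) == 0L) {
    cells <- data.frame(criterion = character(), scenario = character(),
                        winner = character(), K = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    cells <- do.call(rbind, lapply(names(grid$cells), function(key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      res <- grid$cells[[key]]
      data.frame(criterion = parts[1L], scenario = parts[2L],
                 winner = res$ranking[1L],
                 K = round_half_up(max(res$K), digits),
                 stringsAsFactors = FALSE)
    }))
    rownames(cells) <- NULL
  }
  base <- grid$baselines$entropy
  list(baseline_winner = base$ranking[1L],
       baseline_K = round_half_up(max(base$K), digits),
       cells = cells)
}

#' @export
print.scenario_grid <- function(x, digits = 2, ...) {
  cat(sprintf("Scenario grid: %d criteria x {%s} + baselines\n",
              length(x$criteria), paste(x$labels, collapse = ", ")))
  rep <- best_option_report(x, digits = digits)
  cat(sprintf("Baseline (entropy) winner: %s (K = %.2f)\n",
              rep$baseline_winner, rep$baseline_K))
  if (nrow(rep$cells)) print(rep$cells, row.names = FALSE)
  invisible(x)
}
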