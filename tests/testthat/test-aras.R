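cs <- case_study_matrix()

test_that("the optimal row takes column max on benefit, min on cost", {
  expect_identical(unname(optimal_row(cs)), c(5, 5, 1, 1, 1, 3, 5, 4))
  sp <- list(criterion_spec("a", "min", 1), criterion_spec("b", "min", 2))
  allcost <- decision_matrix(matrix(c(2, 4, 1, 3), 2, 2), sp)
  expect_identical(unname(optimal_row(allcost)), c(2, 1))
  one <- decision_matrix(matrix(c(3, 2), 1, 2),
                         list(criterion_spec("a", "max", 1),
                              criterion_spec("b", "min", 2)))
  expect_identical(unname(optimal_row(one)), c(3, 2))
})

test_that("normalization handles both directions and sums columns to 1", {
  nrm <- normalize_extended(extend_matrix(cs))
  expect_equal(unname(colSums(nrm)), rep(1, 8), tolerance = 1e-12)
  # treatment time (cost): reciprocals of (1;1,1,2,3,2,3,3) sum to 5
  expect_equal(unname(nrm[, 3]),
               c(0.2, 0.2, 0.2, 0.1, 1 / 15, 0.1, 1 / 15, 1 / 15))
  # esthetic potential (benefit): optimal share 5/26
  expect_equal(unname(nrm[1, 1]), 5 / 26)
  # constant benefit column normalizes to uniform shares
  sp <- list(criterion_spec("a", "max", 1))
  const <- decision_matrix(matrix(3, 4, 1), sp)
  expect_equal(unname(normalize_extended(extend_matrix(const))[, 1]),
               rep(1 / 5, 5))
})

test_that("weighting scales columns so their sums equal the weights", {
  nrm <- normalize_extended(extend_matrix(cs))
  w <- entropy_weights(cs)
  wtd <- apply_weights(nrm, w)
  expect_equal(unname(colSums(wtd)), unname(as.numeric(w)), tolerance = 1e-12)
  expect_equal(wtd, sweep(nrm, 2, as.numeric(w), "*"), tolerance = 1e-15)
  expect_equal(apply_weights(nrm, equal_weights(8)), nrm / 8, tolerance = 1e-15)
  expect_error(apply_weights(nrm, equal_weights(5)), "does not match")
})

test_that("the baseline runs reproduce the published ranking table", {
  res_e <- run_aras(cs, entropy_weights(cs))
  res_q <- run_aras(cs, equal_weights(8, criteria = colnames(cs$x)))
  expect_equal(round_half_up(res_e$S_opt, 3), printed_table4$entropy$S_opt)
  expect_equal(round_half_up(res_e$S, 3), printed_table4$entropy$S)
  expect_equal(round_half_up(res_e$K, 3), printed_table4$entropy$K)
  expect_equal(round_half_up(res_q$S_opt, 3), printed_table4$equal$S_opt)
  expect_equal(round_half_up(res_q$S, 3), printed_table4$equal$S)
  expect_equal(round_half_up(res_q$K, 3), printed_table4$equal$K)
  expect_identical(res_e$rank_index, printed_table4$ranking)
  expect_identical(res_q$rank_index, printed_table4$ranking)
  expect_identical(res_e$ranking[1],
                   "Implant-supported fixed provisional restoration")
})

test_that("ties keep input order and identical alternatives score equally", {
  sp <- list(criterion_spec("a", "max", 1), criterion_spec("b", "min", 2))
  twin <- decision_matrix(matrix(c(4, 4, 2, 2), 2, 2), sp, c("first", "second"))
  res <- run_aras(twin, equal_weights(2))
  expect_equal(res$K[1], res$K[2], tolerance = 1e-15)
  expect_identical(res$ranking, c("first", "second"))
})

test_that("run_aras refuses a reverse-scored matrix", {
  expect_error(run_aras(reverse_score_cost_criteria(cs)), "reverse-scored")
})

test_that("ARAS matches the loop oracle with sound invariants", {
  for (seed in 101:125) {
    dm <- random_problem(seed)
    n <- length(dm$criteria)
    set.seed(seed)
    w_raw <- stats::runif(n) + 0.05
    w <- weight_vector(w_raw / sum(w_raw))
    res <- run_aras(dm, w)
    orc <- oracle_aras(dm$x, criterion_directions(dm), as.numeric(w))
    expect_equal(res$S_opt, orc$S_opt, tolerance = 1e-12)
    expect_equal(res$S, orc$S, tolerance = 1e-12)
    expect_equal(res$K, orc$K, tolerance = 1e-12)
    # K in (0, 1], optimal row exactly 1, total weighted mass is 1
    expect_true(all(res$K > 0 & res$K <= 1 + 1e-12))
    expect_equal(res$S_opt + sum(res$S), 1, tolerance = 1e-12)
    expect_true(res$S_opt >= max(res$S) - 1e-12)
    expect_true(is.integer(res$rank_index) &&
                  setequal(res$rank_index, seq_len(nrow(dm$x))))
  }
})

test_that("K is invariant to positive column rescaling", {
  w <- entropy_weights(cs)
  base <- run_aras(cs, w)
  for (j in c(1, 3, 6)) {
    scaled <- cs
    scaled$x[, j] <- scaled$x[, j] * 3
    scaled$criteria[[j]]$scale_max <- scaled$criteria[[j]]$scale_max * 3L
    res <- run_aras(scaled, w)
    expect_equal(res$K, base$K, tolerance = 1e-12)
  }
})

test_that("raising a benefit score never lowers that alternative's K", {
  for (seed in 201:215) {
    dm <- random_problem(seed)
    dirs <- criterion_directions(dm)
    if (!any(dirs == "max")) next
    n <- length(dirs)
    set.seed(seed)
    w_raw <- stats::runif(n) + 0.05
    w <- weight_vector(w_raw / sum(w_raw))
    j <- which(dirs == "max")[1]
    headroom <- which(dm$x[, j] < dm$criteria[[j]]$scale_max)
    if (!length(headroom)) next
    i <- headroom[1]
    before <- oracle_aras(dm$x, dirs, as.numeric(w))$K[i]
    bumped <- dm
    bumped$x[i, j] <- bumped$x[i, j] + 1
    after <- run_aras(bumped, w)$K[i]
    expect_true(after >= before - 1e-12)
  }
})
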