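# Naive double-loop oracles for the entropy-weighting and ARAS equations.
# Deliberately slow and literal; they stay independent of the vectorized
# implementation they check.

oracle_entropy_weights <- function(x, directions, scale_min, scale_max,
                                   reverse = TRUE) {
  m <- nrow(x); n <- ncol(x)
  if (reverse) {
    for (j in seq_len(n)) {
      if (directions[j] == "min") {
        for (i in seq_len(m)) x[i, j] <- scale_max[j] + scale_min[j] - x[i, j]
      }
    }
  }
  p <- matrix(0, m, n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) s <- s + x[i, j]
    for (i in seq_len(m)) p[i, j] <- x[i, j] / s
  }
  e <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (i in seq_len(m)) {
      if (p[i, j] > 0) acc <- acc + p[i, j] * log(p[i, j])
    }
    e[j] <- -acc / log(m)
  }
  d <- numeric(n)
  for (j in seq_len(n)) d[j] <- abs(1 - e[j])
  w <- numeric(n)
  for (j in seq_len(n)) w[j] <- d[j] / sum(d)
  list(p = p, e = e, d = d, w = w)
}

oracle_aras <- function(x, directions, w) {
  m <- nrow(x); n <- ncol(x)
  x0 <- numeric(n)
  for (j in seq_len(n)) {
    x0[j] <- if (directions[j] == "min") min(x[, j]) else max(x[, j])
  }
  ext <- rbind(x0, x)
  nrm <- matrix(0, m + 1L, n)
  for (j in seq_len(n)) {
    col <- ext[, j]
    if (directions[j] == "min") {
      star <- numeric(m + 1L)
      for (i in seq_len(m + 1L)) star[i] <- 1 / col[i]
      col <- star
    }
    s <- 0
    for (i in seq_len(m + 1L)) s <- s + col[i]
    for (i in seq_len(m + 1L)) nrm[i, j] <- col[i] / s
  }
  wtd <- matrix(0, m + 1L, n)
  for (j in seq_len(n)) for (i in seq_len(m + 1L)) wtd[i, j] <- nrm[i, j] * w[j]
  S <- numeric(m + 1L)
  for (i in seq_len(m + 1L)) S[i] <- sum(wtd[i, ])
  K <- numeric(m)
  for (i in seq_len(m)) K[i] <- S[i + 1L] / S[1L]
  list(S_opt = S[1L], S = S[-1L], K = K)
}

# Random small decision problem for property tests.
random_problem <- function(seed, m = NULL, n = NULL) {
  set.seed(seed)
  if (is.null(m)) m <- sample(3:8, 1)
  if (is.null(n)) n <- sample(3:8, 1)
  simulate_decision_problem(m, n, seed = seed + 1L)
}

dm_scales <- function(dm) {
  list(min = vapply(dm$criteria, `[[`, integer(1), "scale_min"),
       max = vapply(dm$criteria, `[[`, integer(1), "scale_max"))
}
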