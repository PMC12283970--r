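# Independent oracles used across test files.

# all permutations of a vector (tiny inputs only)
perms <- function(v) {
  if (length(v) <= 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# exhaustive-enumeration minimum cost of a rectangular assignment:
# every element of the smaller side must be paired
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0 || m == 0) {
    return(0)
  }
  if (n > m) {
    return(brute_assignment_cost(t(cost)))
  }
  best <- Inf
  subsets <- utils::combn(m, n, simplify = FALSE)
  for (s in subsets) {
    for (p in perms(s)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best) best <- tot
    }
  }
  best
}

# lag-1 sample autocorrelation
lag1_cor <- function(z) {
  n <- length(z)
  mean(z[-n] * z[-1]) / stats::var(z)
}

# tiny experiment config used by several suites
tiny_config <- function(model, ...) {
  experiment_config(model, N = 10, seed = 99, ...)
}
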