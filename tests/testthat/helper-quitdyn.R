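# shared fixtures and independent oracles

# truncated power-series matrix exponential: the independent oracle for
# every expm-based computation
series_expm <- function(A, terms = 50) {
  E <- diag(nrow(A)); Tk <- diag(nrow(A))
  for (k in seq_len(terms)) {
    Tk <- Tk %*% A / k
    E <- E + Tk
  }
  E
}

# series oracle with argument halving for large norms (cancellation-free);
# still independent of the Pade implementation under test
oracle_expm <- function(A, terms = 50) {
  nrm <- max(rowSums(abs(A)))
  m <- if (nrm > 0.25) ceiling(log2(nrm / 0.25)) else 0L
  E <- series_expm(A / 2^m, terms)
  for (i in seq_len(m)) E <- E %*% E
  E
}

# random valid generator: all nine arrows, rates uniform on (0, hi)
rand_Q <- function(hi = 0.15) {
  q <- matrix(0, 4, 4)
  q[1:3, ] <- matrix(runif(12, 0, hi), 3, 4)
  diag(q) <- 0
  intensity_matrix(q)
}

# random nonnegative ODE rate set
rand_rates <- function(hi = 0.5) {
  do.call(ode_rates, as.list(setNames(runif(9, 0, hi),
    c("d12", "d13", "d14", "d21", "d23", "d24", "d31", "d32", "d34"))))
}

# small long-format record set: 3 subjects, one missing week 26
records_small <- function() {
  data.frame(
    subject_id = rep(c("a", "b", "c"), each = 3),
    group = "G",
    week = rep(c(0, 12, 26), 3),
    stage = c(1L, 2L, 4L,  1L, 1L, 2L,  2L, 3L, NA),
    stringsAsFactors = FALSE)
}

# counts object for the two-state closed-form MLE check:
# n subjects in stage 1, k absorbed over one interval of delta weeks
two_state_counts <- function(n = 100L, k = 26L, delta = 13) {
  cnt <- matrix(0L, 4, 4)
  cnt[1, 1] <- n - k; cnt[1, 4] <- k
  structure(cnt, interval = delta, n_subjects = n,
            class = c("transition_counts", "matrix"))
}

# the six-arrow recovery generator used in the recovery and coverage checks
recovery_Q <- function() {
  q <- matrix(0, 4, 4)
  q[1, 2] <- 0.06; q[2, 1] <- 0.03; q[2, 3] <- 0.05
  q[3, 2] <- 0.03; q[3, 4] <- 0.05; q[2, 4] <- 0.02
  intensity_matrix(q)
}
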