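#' Matrix exponential by scaling-and-squaring with Pade approximation
#'
#' Dense matrix exponential for the small (4x4 or 3x3) generator and
#' Jacobian matrices used throughout the package. The classic
#' scaling-and-squaring scheme with a diagonal Pade approximant of order 8
#' is accurate to well below 1e-10 on matrices of the scale seen here,
#' including stiff compartmental systems with rates of order 10^3-10^4.
#'
#' @param A square numeric matrix.
#' @return The matrix exponential `exp(A)` as a base matrix.
#' @keywords internal
mat_exp <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), is.numeric(A), all(is.finite(A)))
  n <- nrow(A)
  nrmA <- max(rowSums(abs(A)))  # infinity norm
  s <- if (nrmA > 0.5) ceiling(log2(nrmA / 0.5)) else 0L
  A <- A / 2^s

  # order-8 diagonal Pade: exp(A) ~ (V - U)^{-1} (V + U)
  # coefficients c_k = (2m-k)! m! / ((2m)! k! (m-k)!), m = 8
  m <- 8
  k <- 0:m
  cpade <- exp(lfactorial(2 * m - k) + lfactorial(m) -
               lfactorial(2 * m) - lfactorial(k) - lfactorial(m - k))
  I <- diag(n)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A4 %*% A2
  A8 <- A6 %*% A2
  U <- A %*% (cpade[2] * I + cpade[4] * A2 + cpade[6] * A4 + cpade[8] * A6)
  V <- cpade[1] * I + cpade[3] * A2 + cpade[5] * A4 + cpade[7] * A6 +
    cpade[9] * A8
  E <- solve(V - U, V + U)
  if (s > 0) for (i in seq_len(s)) E <- E %*% E
  E
}
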