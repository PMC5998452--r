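#' Compartmental ODE transition rates
#'
#' The nine nonnegative rates d_ij of the linear compartment model for
#' stage flows: for the transient stages U (unmotivated), I (indecisive),
#' M (motivated),
#' \deqn{U' = d21 I + d31 M - (d12 + d13 + d14) U}
#' \deqn{I' = d12 U - (d21 + d23 + d24) I + d32 M}
#' \deqn{M' = d13 U + d23 I - (d31 + d32 + d34) M}
#' and the former-smoker compartment takes the conservation remainder
#' `F = 100 - (U + I + M)`.
#'
#' @param d12,d13,d14,d21,d23,d24,d31,d32,d34 nonnegative rates (per week
#'   when fitted to weekly curves).
#' @return named numeric vector of class `ode_rates`.
#' @export
ode_rates <- function(d12 = 0, d13 = 0, d14 = 0, d21 = 0, d23 = 0, d24 = 0,
                      d31 = 0, d32 = 0, d34 = 0) {
  r <- c(d12 = d12, d13 = d13, d14 = d14, d21 = d21, d23 = d23, d24 = d24,
         d31 = d31, d32 = d32, d34 = d34)
  if (any(!is.finite(r)) || any(r < 0))
    stop("all nine rates must be finite and nonnegative")
  structure(r, class = "ode_rates")
}

rate_names <- c("d12", "d13", "d14", "d21", "d23", "d24", "d31", "d32", "d34")

as_ode_rates <- function(x) {
  if (inherits(x, "ode_rates")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 9) names(x) <- rate_names
  stopifnot(all(rate_names %in% names(x)))
  do.call(ode_rates, as.list(x[rate_names]))
}

#' Jacobian of the (U, I, M) subsystem
#'
#' The coefficient matrix A of the linear system: diagonal entries are
#' minus the total exit rate of each stage (including the flow into the
#' absorbing former-smoker stage), off-diagonal entry (i, j) is the rate
#' from stage j into stage i. Its trace is therefore exactly minus the sum
#' of all nine rates.
#'
#' @param rates an [ode_rates()] vector.
#' @return 3x3 numeric matrix.
#' @export
ode_jacobian <- function(rates) {
  d <- as_ode_rates(rates)
  A <- matrix(0, 3, 3, dimnames = list(c("U", "I", "M"), c("U", "I", "M")))
  A[1, ] <- c(-(d["d12"] + d["d13"] + d["d14"]), d["d21"], d["d31"])
  A[2, ] <- c(d["d12"], -(d["d21"] + d["d23"] + d["d24"]), d["d32"])
  A[3, ] <- c(d["d13"], d["d23"], -(d["d31"] + d["d32"] + d["d34"]))
  A
}

#' Right-hand side of the compartmental ODE
#'
#' @param state numeric: `(U, I, M)` or `(U, I, M, F)` percentages.
#' @param rates an [ode_rates()] vector.
#' @return derivatives `(dU, dI, dM)`; `dF` is the negated sum by
#'   conservation.
#' @export
ode_rhs <- function(state, rates) {
  x <- as.numeric(state)[1:3]
  as.numeric(ode_jacobian(rates) %*% x)
}

#' Simulate the compartment model
#'
#' The system is linear, so the trajectory is computed exactly as
#' `x(t) = exp(tA) x0` (no step-size or stiffness limitations even at
#' rates of order 10^3-10^4 per week); F takes the conservation remainder.
#'
#' @param rates an [ode_rates()] vector.
#' @param init initial state `(U, I, M, F)` in percent, summing to 100.
#' @param times evaluation times (same unit as the rates; weeks by
#'   convention).
#' @return data.frame `time, U, I, M, F`, class `ode_trajectory`.
#' @export
simulate_ode <- function(rates, init, times = seq(0, 104, by = 1)) {
  d <- as_ode_rates(rates)
  init <- as.numeric(init)
  stopifnot(length(init) == 4, all(is.finite(init)))
  if (abs(sum(init) - 100) > 1e-6)
    stop("init must be percentages summing to 100")
  A <- ode_jacobian(d)
  x0 <- init[1:3]
  tr <- t(vapply(times, function(t) as.numeric(mat_exp(t * A) %*% x0),
                 numeric(3)))
  out <- data.frame(time = times, U = tr[, 1], I = tr[, 2], M = tr[, 3],
                    F = 100 - rowSums(tr))
  class(out) <- c("ode_trajectory", class(out))
  out
}

# trajectory of the (U,I,M) subsystem at several times: one spectral
# decomposition when the eigenbasis is well conditioned, expm fallback
# otherwise (defective or near-defective A)
lin_traj <- function(A, x0, times) {
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(ev) && all(is.finite(ev$vectors)) &&
      abs(det(ev$vectors)) > 1e-10) {
    cc <- solve(ev$vectors, x0)
    tr <- Re(ev$vectors %*% (exp(outer(ev$values, times)) * cc))
    return(t(tr))
  }
  t(vapply(times, function(t) as.numeric(mat_exp(t * A) %*% x0), numeric(3)))
}

# SSE between an ODE solution and target curves at the target's grid
ode_sse <- function(par, A_fun, x0, weeks, target_mat) {
  tr <- lin_traj(A_fun(par), x0, weeks)
  pred <- cbind(tr, 100 - rowSums(tr))
  sum((pred - target_mat)^2)
}

#' Fit the nine compartmental rates to prevalence curves
#'
#' Bounded least squares: minimizes the sum over grid times and all four
#' compartments of squared deviations between the exact linear-ODE
#' solution and the target prevalence curves, with all rates bounded below
#' by zero (the analogue of constrained `fmincon` fitting). The
#' 9-parameter surface is multi-modal, so the optimizer is restarted from
#' seeded log-uniform random initial values.
#'
#' @param target data.frame of target curves: columns `week` (or `time`)
#'   and `stage1..stage4` or `U, I, M, F`, in percent.
#' @param init_state initial state; defaults to the target's first row.
#' @param multistarts number of random restarts (default 20).
#' @param seed integer seed for the restart draws.
#' @param sse_warn warn if the final SSE exceeds this (poor fits happen
#'   when the target is not itself a trajectory of the model).
#' @return list of class `ode_fit`: `rates` ([ode_rates()]), `sse`,
#'   `convergence`, `init_state`.
#' @export
fit_ode_rates <- function(target, init_state = NULL, multistarts = 20,
                          seed = 1, sse_warn = 100) {
  tgt <- as.data.frame(target)
  if ("week" %in% names(tgt)) names(tgt)[names(tgt) == "week"] <- "time"
  if (all(paste0("stage", 1:4) %in% names(tgt)))
    names(tgt)[match(paste0("stage", 1:4), names(tgt))] <- c("U", "I", "M", "F")
  stopifnot(all(c("time", "U", "I", "M", "F") %in% names(tgt)))
  if (nrow(tgt) < 3) stop("target must have at least 3 time points")
  tm <- as.matrix(tgt[, c("U", "I", "M", "F")])
  if (is.null(init_state)) init_state <- as.numeric(tm[1, ])
  x0 <- init_state[1:3]

  # par ordered as rate_names: d12 d13 d14 d21 d23 d24 d31 d32 d34
  A_fun <- function(par) {
    matrix(c(-(par[1] + par[2] + par[3]), par[1], par[2],
             par[4], -(par[4] + par[5] + par[6]), par[5],
             par[7], par[8], -(par[7] + par[8] + par[9])),
           3, 3)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- list(rep(0.05, 9))
  if (multistarts > 1)
    for (i in 2:multistarts)
      starts[[i]] <- exp(stats::runif(9, log(1e-4), log(10)))

  # coarse multistart pass, then a tight polish from the best basin
  run1 <- function(st, factr, maxit) tryCatch(
    stats::optim(st, ode_sse, A_fun = A_fun, x0 = x0, weeks = tgt$time,
                 target_mat = tm, method = "L-BFGS-B",
                 lower = rep(0, 9), upper = rep(1e5, 9),
                 control = list(maxit = maxit, factr = factr,
                                parscale = pmax(st, 1e-3))),
    error = function(e) NULL)
  best <- NULL
  for (st in starts) {
    fit <- run1(st, factr = 1e7, maxit = 300)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("ODE rate fitting failed from every start")
  polish <- run1(pmax(best$par, 1e-8), factr = 10, maxit = 2000)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  if (best$value > sse_warn)
    warning("SSE ", format(best$value, digits = 4),
            " exceeds ", sse_warn, "; the target may not follow the model")
  structure(list(rates = as_ode_rates(stats::setNames(best$par, rate_names)),
                 sse = best$value, convergence = best$convergence,
                 init_state = init_state),
            class = "ode_fit")
}

#' @export
print.ode_fit <- function(x, ...) {
  cat("Compartmental ODE least-squares fit (SSE ",
      format(x$sse, digits = 5), ")\n", sep = "")
  print(round(unclass(x$rates), 5))
  invisible(x)
}

#' Eigenvalue stability analysis of the compartment model
#'
#' Reports the Jacobian of the (U, I, M) subsystem, its eigenvalues
#' (ascending), and the equilibrium structure: when the Jacobian is
#' nonsingular the only equilibrium is the trivial absorbing state
#' (0, 0, 0, 100), globally stable since all eigenvalues are then
#' negative; when it is singular (under-determined system) there is a
#' continuum of equilibria — the null space intersected with the
#' nonnegative simplex — and the trivial equilibrium loses stability in
#' the sense of no longer being the unique attractor.
#'
#' @param rates an [ode_rates()] vector.
#' @param tol eigenvalue magnitude below which the system is declared
#'   under-determined (default 1e-10 relative to the spectral scale).
#' @return list of class `stability_report`: `jacobian`, `eigenvalues`,
#'   `under_determined`, `trivial_stable`, `equilibria` (matrix whose rows
#'   span the equilibrium family as `(U, I, M, F)` percentages; just the
#'   trivial state when nonsingular).
#' @export
eigen_stability <- function(rates, tol = 1e-10) {
  d <- as_ode_rates(rates)
  A <- ode_jacobian(d)
  ev <- eigen(A)
  vals <- ev$values
  scale <- max(abs(vals), 1)
  zero <- abs(vals) < tol * scale
  ord <- order(Re(vals))
  eigenvalues <- Re(vals[ord])  # compartmental: spectrum is real here
  under <- any(zero)
  if (!under) {
    equilibria <- matrix(c(0, 0, 0, 100), 1, 4,
                         dimnames = list(NULL, c("U", "I", "M", "F")))
  } else {
    ns <- MASS::Null(t(A))  # null space of A
    eq <- NULL
    for (j in seq_len(ncol(ns))) {
      v <- Re(ns[, j])
      if (all(v <= 1e-12) ) v <- -v
      if (any(v < -1e-8)) next  # not in the nonnegative cone
      v <- 100 * v / sum(v)     # scale so U+I+M = 100, F = 0 endpoint
      eq <- rbind(eq, c(v, 0))
    }
    equilibria <- rbind(c(0, 0, 0, 100), eq)
    colnames(equilibria) <- c("U", "I", "M", "F")
  }
  structure(list(jacobian = A, eigenvalues = eigenvalues,
                 under_determined = under,
                 trivial_stable = all(eigenvalues < 0),
                 equilibria = equilibria),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Eigenvalues (ascending):",
      paste(format(x$eigenvalues, digits = 5), collapse = ", "), "\n")
  if (x$under_determined) {
    cat("System is under-determined: infinitely many equilibria;",
        "the family is spanned by:\n")
    print(round(x$equilibria, 3))
  } else {
    cat("Unique trivial equilibrium (0, 0, 0, 100); stable:",
        x$trivial_stable, "\n")
  }
  invisible(x)
}

#' Asymptotic state of a trajectory
#'
#' The large-time limit of the trajectory from `init`: the spectral
#' projection of the initial (U, I, M) state onto the zero-eigenvalue
#' subspace of the Jacobian (the origin when all eigenvalues are
#' negative), with F taking the conservation remainder.
#'
#' @param rates an [ode_rates()] vector.
#' @param init initial `(U, I, M, F)` percentages summing to 100.
#' @return named numeric `(U, I, M, F)` limit state.
#' @export
asymptotic_state <- function(rates, init) {
  d <- as_ode_rates(rates)
  init <- as.numeric(init)
  stopifnot(length(init) == 4, abs(sum(init) - 100) < 1e-6)
  A <- ode_jacobian(d)
  ev <- eigen(A)
  scale <- max(abs(ev$values), 1)
  zero <- abs(ev$values) < 1e-10 * scale
  if (!any(zero)) {
    lim <- c(0, 0, 0)
  } else {
    P0 <- tryCatch({
      Vi <- solve(ev$vectors)
      Re(ev$vectors %*% diag(as.numeric(zero), 3) %*% Vi)
    }, error = function(e) NULL)
    if (is.null(P0)) {
      # defective eigenbasis: fall back on long-horizon propagation
      tl <- 1e6 / max(abs(ev$values[!zero]), 1e-6)
      lim <- as.numeric(mat_exp(tl * A) %*% init[1:3])
    } else lim <- as.numeric(P0 %*% init[1:3])
  }
  lim[abs(lim) < 1e-9] <- 0
  out <- c(lim, 100 - sum(lim))
  names(out) <- c("U", "I", "M", "F")
  out
}

#' Time-averaged prevalence over [0, T]
#'
#' Composite-trapezoid average `(1/T) integral_0^T x(t) dt` of each
#' compartment on the trajectory's grid.
#'
#' @param trajectory an `ode_trajectory` (or data.frame `time, U, I, M,
#'   F`) covering `[0, T]`.
#' @param T upper limit; defaults to the trajectory's span.
#' @return named numeric averages `(U, I, M, F)`, summing to 100.
#' @export
average_prevalence <- function(trajectory, T = max(trajectory$time)) {
  tr <- as.data.frame(trajectory)
  stopifnot(all(c("time", "U", "I", "M", "F") %in% names(tr)))
  if (T > max(tr$time) + 1e-9 || T <= min(tr$time))
    stop("T = ", T, " is outside the trajectory span [",
         min(tr$time), ", ", max(tr$time), "]")
  tr <- tr[tr$time <= T + 1e-9, ]
  tt <- tr$time
  trap <- function(y) sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  out <- vapply(c("U", "I", "M", "F"), function(v) trap(tr[[v]]), 0) /
    (max(tt) - min(tt))
  out
}

#' Time to reach the asymptotic state
#'
#' The first time after which every transient compartment stays within
#' `epsilon` percentage points of its asymptotic value. When
#' `full_absorption = TRUE` the question is "when has everyone quit":
#' if the asymptotic former-smoker share is below `100 - epsilon` the
#' answer is `Inf` (full absorption never happens, as in an
#' under-determined system with a nontrivial stable equilibrium).
#'
#' @param rates an [ode_rates()] vector.
#' @param init initial `(U, I, M, F)` percentages.
#' @param epsilon convergence band in percentage points (default 0.5).
#' @param full_absorption ask for convergence to (0, 0, 0, 100) rather
#'   than to the trajectory's own asymptotic state.
#' @param t_max search horizon; defaults to a multiple of the slowest
#'   nonzero timescale.
#' @return time in the rates' time unit (weeks by convention), possibly
#'   `Inf`.
#' @export
time_to_absorption <- function(rates, init, epsilon = 0.5,
                               full_absorption = FALSE, t_max = NULL) {
  d <- as_ode_rates(rates)
  stopifnot(epsilon > 0)
  lim <- asymptotic_state(d, init)
  target <- if (full_absorption) c(0, 0, 0, 100) else lim
  if (full_absorption && lim["F"] < 100 - epsilon) return(Inf)
  dev0 <- max(abs(init[1:3] - target[1:3]))
  if (dev0 <= epsilon) return(0)

  A <- ode_jacobian(d)
  ev <- Re(eigen(A, only.values = TRUE)$values)
  nz <- abs(ev)[abs(ev) > 1e-10 * max(abs(ev), 1)]
  slowest <- if (length(nz)) min(nz) else 1
  if (is.null(t_max)) t_max <- max(50 / slowest, 1)
  dev_at <- function(t) max(abs(as.numeric(mat_exp(t * A) %*% init[1:3]) -
                                  target[1:3]))
  grid <- seq(0, t_max, length.out = 2001)
  devs <- vapply(grid, dev_at, 0)
  while (devs[length(devs)] > epsilon) {
    t_max <- t_max * 4
    if (t_max > 1e12) return(Inf)
    grid <- seq(0, t_max, length.out = 2001)
    devs <- vapply(grid, dev_at, 0)
  }
  last_out <- max(c(0, which(devs > epsilon)))
  if (last_out == 0) return(0)
  # refine by bisection between the last excursion and the next grid point
  lo <- grid[last_out]; hi <- grid[last_out + 1]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (dev_at(mid) > epsilon) lo <- mid else hi <- mid
    if (hi - lo < 1e-9 * max(hi, 1)) break
  }
  (lo + hi) / 2
}
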