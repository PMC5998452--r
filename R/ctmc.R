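#' Construct and validate a CTMC transition intensity matrix
#'
#' The generator Q of the 4-stage chain: off-diagonal entries q_lk >= 0 are
#' per-week transition rates, each diagonal entry is minus its row's
#' off-diagonal sum (rows sum to zero), and stage 4 (former smoker) is
#' absorbing, so its row is all zeros.
#'
#' @param q 4x4 numeric matrix of rates; diagonal entries are recomputed
#'   from the off-diagonals.
#' @return a validated `intensity_matrix` (4x4 matrix).
#' @export
intensity_matrix <- function(q) {
  stopifnot(is.matrix(q), all(dim(q) == c(4, 4)), is.numeric(q))
  diag(q) <- 0
  if (any(q < 0))
    stop("off-diagonal intensities must be nonnegative")
  if (any(q[4, ] != 0))
    stop("stage 4 is absorbing: row 4 must be zero")
  diag(q) <- -rowSums(q)
  dimnames(q) <- list(from = 1:4, to = 1:4)
  structure(q, class = c("intensity_matrix", class(q)))
}

validate_intensity <- function(Q, tol = 1e-10) {
  if (!is.matrix(Q) || !all(dim(Q) == c(4, 4)))
    stop("Q must be a 4x4 matrix")
  off <- Q; diag(off) <- 0
  if (any(off < -tol)) stop("negative off-diagonal intensity in Q")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rows of Q must sum to 0")
  if (any(abs(Q[4, ]) > tol)) stop("absorbing row 4 of Q must be zero")
  invisible(Q)
}

#' Default allowed-transition mask
#'
#' All nine arrows of the stage diagram (every ordered pair among stages
#' 1-3 plus each transient stage into absorbing stage 4).
#' @return 4x4 logical matrix.
#' @export
default_mask <- function() {
  m <- matrix(FALSE, 4, 4, dimnames = list(from = 1:4, to = 1:4))
  m[1:3, ] <- TRUE
  diag(m) <- FALSE
  m[4, ] <- FALSE
  m
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' Solves the Kolmogorov forward equations for a time-homogeneous CTMC:
#' the probability of occupying stage k at time u + t given stage l at
#' time u is entry (l, k) of the matrix exponential of tQ.
#'
#' @param Q an intensity matrix (see [intensity_matrix()]).
#' @param t nonnegative time in weeks.
#' @return 4x4 stochastic matrix.
#' @export
transition_probability <- function(Q, t) {
  validate_intensity(Q)
  stopifnot(length(t) == 1, is.finite(t), t >= 0)
  P <- mat_exp(t * unclass(Q))
  P[P < 0 & P > -1e-12] <- 0   # clip tiny negative round-off
  dimnames(P) <- list(from = 1:4, to = 1:4)
  P
}

# per-interval (from, to, delta) tallies for a panel; the sufficient
# statistic generalized to unequal intervals
interval_tallies <- function(panel, group = NULL) {
  ids <- names(panel$subjects)
  if (!is.null(group)) ids <- ids[panel$groups[ids] == group]
  from <- integer(0); to <- integer(0); delta <- numeric(0)
  for (id in ids) {
    obs <- panel$subjects[[id]]
    if (nrow(obs) < 2) next
    j <- seq_len(nrow(obs) - 1)
    from <- c(from, obs$stage[j]); to <- c(to, obs$stage[j + 1])
    delta <- c(delta, obs$week[j + 1] - obs$week[j])
  }
  out <- list()
  for (d in sort(unique(delta))) {
    cm <- matrix(0L, 4, 4)
    sel <- delta == d
    for (i in which(sel)) cm[from[i], to[i]] <- cm[from[i], to[i]] + 1L
    out[[as.character(d)]] <- cm
  }
  out
}

#' Log-likelihood of panel data under a CTMC generator
#'
#' For equal-interval panel data the log-likelihood is
#' `sum_{l,k} n_lk * log P(Delta)_lk` where `n_lk` are the interval
#' transition counts; unequal intervals contribute one `P(Delta_i)` factor
#' per observation pair. An observed transition with (numerically) zero
#' probability yields `-Inf`.
#'
#' @param Q an intensity matrix.
#' @param data a `transition_counts` matrix or a `stage_panel`.
#' @param group group label when `data` is a panel.
#' @param interval interval length in weeks; defaults to the counts'
#'   `interval` attribute.
#' @return scalar log-likelihood (<= 0).
#' @export
panel_log_likelihood <- function(Q, data, group = NULL, interval = NULL) {
  validate_intensity(Q)
  tallies <-
    if (inherits(data, "transition_counts")) {
      d <- if (is.null(interval)) attr(data, "interval") else interval
      if (is.null(d) || is.na(d)) stop("interval length required for counts")
      stats::setNames(list(unclass(data)[1:4, 1:4]), as.character(d))
    } else if (inherits(data, "stage_panel")) {
      interval_tallies(data, group)
    } else stop("data must be transition_counts or a stage_panel")
  ll <- 0
  for (d in names(tallies)) {
    n <- tallies[[d]]
    P <- transition_probability(Q, as.numeric(d))
    obs <- n > 0
    if (any(obs & P <= 0)) return(-Inf)
    ll <- ll + sum(n[obs] * log(P[obs]))
  }
  ll
}

# internal: negative log-likelihood over log-intensity parameters
ctmc_negll <- function(logpar, mask_idx, tallies) {
  q <- matrix(0, 4, 4)
  q[mask_idx] <- exp(logpar)
  diag(q) <- -rowSums(q)
  ll <- 0
  for (d in names(tallies)) {
    n <- tallies[[d]]
    P <- mat_exp(as.numeric(d) * q)
    obs <- n > 0
    P[obs] <- pmax(P[obs], 1e-300)
    ll <- ll + sum(n[obs] * log(P[obs]))
  }
  -ll
}

#' Fit the CTMC by maximum likelihood
#'
#' Maximizes the panel likelihood over log-intensities (so positivity is
#' automatic), quasi-Newton (L-BFGS-B) with multi-starts from perturbed
#' method-of-moments initial values. The covariance of the log-intensity
#' estimates is the inverse Hessian at the optimum, the basis of the
#' simulated confidence intervals of [ci_simulated()].
#'
#' @param data a `transition_counts` matrix or a `stage_panel`.
#' @param group group label when `data` is a panel.
#' @param mask 4x4 logical matrix of allowed transitions
#'   ([default_mask()]: all nine arrows).
#' @param init optional initial `intensity_matrix`.
#' @param multistarts number of optimizer starts (first from the
#'   method-of-moments value, the rest log-normally perturbed).
#' @param seed integer seed for the perturbations.
#' @param interval interval length override for count-matrix input.
#' @param rate_cap upper bound on each intensity (per week); keeps the
#'   likelihood surface bounded.
#' @return an object of class `ctmc_fit` with elements `Q`
#'   (intensity_matrix), `logpar`, `mask`, `cov` (of logpar), `loglik`,
#'   `convergence`, `boundary` (rates at the cap), `interval`.
#' @export
fit_ctmc <- function(data, group = NULL, mask = default_mask(), init = NULL,
                     multistarts = 5, seed = 1, interval = NULL,
                     rate_cap = 1e4) {
  tallies <-
    if (inherits(data, "transition_counts")) {
      d <- if (is.null(interval)) attr(data, "interval") else interval
      if (is.null(d) || is.na(d)) stop("interval length required for counts")
      stats::setNames(list(unclass(data)[1:4, 1:4]), as.character(d))
    } else if (inherits(data, "stage_panel")) {
      interval_tallies(data, group)
    } else stop("data must be transition_counts or a stage_panel")
  total <- Reduce(`+`, tallies)
  offdiag <- total; diag(offdiag) <- 0
  if (sum(offdiag[mask]) == 0 && sum(offdiag) == 0)
    stop("no observed off-diagonal transitions; nothing to fit")

  mask_idx <- which(mask)
  npar <- length(mask_idx)
  mean_delta <- sum(vapply(names(tallies), function(d)
    as.numeric(d) * sum(tallies[[d]]), 0)) / sum(total)

  # method-of-moments: crude rate = count / (row exposure), floored
  exposure <- rowSums(total) * mean_delta
  q0 <- matrix(1e-3, 4, 4)
  for (l in 1:3) if (exposure[l] > 0)
    q0[l, ] <- pmax(offdiag[l, ] / exposure[l], 1e-3)
  start0 <- log(pmin(pmax(q0[mask_idx], 1e-6), rate_cap / 10))

  lower <- rep(log(1e-10), npar)
  upper <- rep(log(rate_cap), npar)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- list(start0)
  if (multistarts > 1)
    for (i in 2:multistarts)
      starts[[i]] <- start0 + stats::rnorm(npar, 0, 0.5)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, ctmc_negll, mask_idx = mask_idx, tallies = tallies,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, pgtol = 1e-8, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("CTMC fit failed to converge from any start; check the data")

  # rates collapsed to (numerically) zero carry no curvature in log space;
  # the covariance is computed over the active parameters only, with
  # degenerate zero rows/cols for the vanished arrows
  active <- exp(best$par) > 1e-8
  covm <- matrix(0, npar, npar)
  if (any(active)) {
    H <- tryCatch(
      stats::optimHess(best$par, ctmc_negll, mask_idx = mask_idx,
                       tallies = tallies),
      error = function(e) matrix(NA_real_, npar, npar))
    Ha <- H[active, active, drop = FALSE]
    ca <- tryCatch(solve(Ha), error = function(e) MASS::ginv(Ha))
    if (!anyNA(ca)) covm[active, active] <- (ca + t(ca)) / 2
  }

  q <- matrix(0, 4, 4)
  q[mask_idx] <- exp(best$par)
  boundary <- exp(best$par) >= rate_cap * (1 - 1e-6)
  if (any(boundary))
    warning(sum(boundary), " rate(s) at the cap ", rate_cap, "/week")
  structure(list(Q = intensity_matrix(q), logpar = best$par,
                 mask = mask, mask_idx = mask_idx, cov = covm,
                 loglik = -best$value, convergence = best$convergence,
                 boundary = boundary, interval = mean_delta,
                 n_transitions = sum(total)),
            class = "ctmc_fit")
}

#' @export
print.ctmc_fit <- function(x, ...) {
  cat("CTMC maximum likelihood fit (", x$n_transitions,
      " transitions, log-likelihood ", format(x$loglik, digits = 6),
      ")\n", sep = "")
  cat("Transition intensity matrix Q (per week):\n")
  print(round(unclass(x$Q)[1:4, 1:4], 5))
  st <- sojourn_times(x)
  cat("Mean sojourn times (weeks):",
      paste(sprintf("stage %d: %.3f", 1:3, st[1:3]), collapse = ", "), "\n")
  invisible(x)
}

#' Mean sojourn times of the transient stages
#'
#' The expected duration of a single visit to transient stage l is
#' `-1/q_ll`; the absorbing stage has infinite sojourn.
#'
#' @param x an `intensity_matrix` or `ctmc_fit`.
#' @return numeric length 4 (weeks); `Inf` for stages with no exit.
#' @export
sojourn_times <- function(x) {
  Q <- if (inherits(x, "ctmc_fit")) x$Q else x
  validate_intensity(Q)
  d <- diag(unclass(Q))
  out <- ifelse(d < 0, -1 / d, Inf)
  names(out) <- paste0("stage", 1:4)
  out
}

#' Simulated confidence intervals for rates and sojourn times
#'
#' Draws from the asymptotic multivariate normal distribution of the
#' maximum likelihood estimates of the log transition intensities,
#' transforms each draw to rates and sojourn times, and reports percentile
#' bounds — the standard parametric simulation scheme for multi-state
#' model summaries.
#'
#' @param fit a `ctmc_fit`.
#' @param draws number of random vectors (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with data.frames `rates` (from, to, estimate, lower,
#'   upper) and `sojourn` (stage, estimate, se, lower, upper).
#' @export
ci_simulated <- function(fit, draws = 1000, level = 0.95, seed = 1) {
  stopifnot(inherits(fit, "ctmc_fit"))
  covm <- fit$cov
  ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning("covariance not positive semi-definite; nearest-PSD repair applied")
    ed <- eigen(covm, symmetric = TRUE)
    covm <- ed$vectors %*% diag(pmax(ed$values, 0)) %*% t(ed$vectors)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sims <- MASS::mvrnorm(draws, mu = fit$logpar, Sigma = covm)
  if (draws == 1) sims <- matrix(sims, nrow = 1)
  rates <- exp(sims)                       # draws x npar
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  qr_ <- apply(rates, 2, stats::quantile, probs = probs)
  ij <- arrayInd(fit$mask_idx, c(4, 4))
  rates_df <- data.frame(from = ij[, 1], to = ij[, 2],
                         estimate = exp(fit$logpar),
                         lower = qr_[1, ], upper = qr_[2, ])

  # per-draw sojourn: -1/q_ll from the row sums of each simulated Q
  soj <- matrix(NA_real_, draws, 3)
  for (s in seq_len(draws)) {
    q <- matrix(0, 4, 4); q[fit$mask_idx] <- rates[s, ]
    ex <- rowSums(q)[1:3]
    soj[s, ] <- ifelse(ex > 0, 1 / ex, Inf)
  }
  est <- sojourn_times(fit)[1:3]
  qs <- apply(soj, 2, stats::quantile, probs = probs)
  sojourn_df <- data.frame(stage = 1:3, estimate = est,
                           se = apply(soj, 2, stats::sd),
                           lower = qs[1, ], upper = qs[2, ],
                           row.names = NULL)
  list(rates = rates_df, sojourn = sojourn_df, draws = draws, level = level)
}

#' Model-based stage prevalence curves
#'
#' Prevalence at time t of each stage is the initial stage distribution
#' propagated through P(t): `prev(t) = 100 * init %*% exp(tQ)`.
#'
#' @param fit a `ctmc_fit` or `intensity_matrix`.
#' @param init initial distribution over the 4 stages (proportions summing
#'   to 1, or percentages summing to 100).
#' @param grid time grid in weeks (default weekly over 0..26).
#' @return data.frame `week, stage1..stage4` (percent), class
#'   `prevalence_curves`.
#' @export
model_prevalence <- function(fit, init, grid = 0:26) {
  Q <- if (inherits(fit, "ctmc_fit")) fit$Q else fit
  validate_intensity(Q)
  init <- as.numeric(init)
  stopifnot(length(init) == 4, all(init >= 0))
  s <- sum(init)
  if (abs(s - 1) > 1e-6 && abs(s - 100) > 1e-4)
    stop("init must sum to 1 (proportions) or 100 (percent)")
  init <- init / s
  out <- t(vapply(grid, function(t)
    100 * as.numeric(init %*% transition_probability(Q, t)),
    numeric(4)))
  df <- data.frame(week = grid, out)
  names(df) <- c("week", paste0("stage", 1:4))
  class(df) <- c("prevalence_curves", class(df))
  df
}

#' Probability of having reached the absorbing stage
#'
#' The cumulative probability `p_l4(t)` that a subject starting in
#' transient stage l has quit (reached former-smoker stage 4) by time t.
#'
#' @param fit a `ctmc_fit` or `intensity_matrix`.
#' @param from_stage starting stage (1, 2 or 3; 4 returns constant 1).
#' @param grid time grid in weeks.
#' @return data.frame `week, prob`.
#' @export
absorption_probability <- function(fit, from_stage, grid = 0:26) {
  Q <- if (inherits(fit, "ctmc_fit")) fit$Q else fit
  validate_intensity(Q)
  stopifnot(from_stage %in% 1:4)
  if (from_stage == 4) {
    message("from_stage 4 is the absorbing stage; probability is constant 1")
    return(data.frame(week = grid, prob = 1))
  }
  prob <- vapply(grid, function(t)
    transition_probability(Q, t)[from_stage, 4], 0)
  data.frame(week = grid, prob = prob)
}
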