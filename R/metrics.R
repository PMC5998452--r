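#' Metric configuration for efficacy/effectiveness
#'
#' @param alpha penalty weight on adverse motivational shifts, in (0, 1);
#'   default 0.20.
#' @param baseline_week reference week for the change terms (default 0).
#' @param normalization `"global"`: one scalar normalizer over all groups
#'   and times (curves comparable across time); `"per-time"`: normalize at
#'   each time point separately.
#' @return list of class `metric_config`.
#' @export
metric_config <- function(alpha = 0.20, baseline_week = 0,
                          normalization = c("global", "per-time")) {
  normalization <- match.arg(normalization)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0 && alpha < 1))
    stop("alpha must be a single number in [0, 1)")
  structure(list(alpha = alpha, baseline_week = baseline_week,
                 normalization = normalization),
            class = "metric_config")
}

#' Combine per-group prevalence curves into long form
#'
#' @param curves named list of `prevalence_curves` (one per group).
#' @return data.frame `week, group, stage1..stage4`.
#' @export
bind_curves <- function(curves) {
  stopifnot(is.list(curves), !is.null(names(curves)))
  out <- NULL
  for (g in names(curves)) {
    cc <- as.data.frame(curves[[g]])
    cc$group <- g
    out <- rbind(out, cc[, c("week", "group", paste0("stage", 1:4))])
  }
  rownames(out) <- NULL
  out
}

as_long_curves <- function(curves) {
  if (is.data.frame(curves) && "group" %in% names(curves)) return(curves)
  if (is.list(curves) && !is.data.frame(curves)) return(bind_curves(curves))
  stop("curves must be a long data.frame with a group column or a named list")
}

#' Relative efficacy sigma(t)
#'
#' The efficacy of a group at time t is its former-smoker prevalence F(t)
#' divided by `F_max`, the maximum former-smoker prevalence attained by
#' any group at any time on the grid. The best group at its peak thus has
#' efficacy exactly 1.
#'
#' @param curves long prevalence data.frame (`week, group, stage1..4`) or
#'   named list of per-group curves.
#' @param config a [metric_config()].
#' @return data.frame `week, group, sigma` with attribute `F_max`.
#' @export
efficacy <- function(curves, config = metric_config()) {
  curves <- as_long_curves(curves)
  F_max <- max(curves$stage4)
  if (F_max <= 0)
    stop("F_max is 0: no former smokers in any group; efficacy undefined")
  out <- data.frame(week = curves$week, group = curves$group,
                    sigma = curves$stage4 / F_max)
  attr(out, "F_max") <- F_max
  out
}

#' Penalized relative effectiveness rho(t)
#'
#' Effectiveness discounts the gain in former smokers by the adverse
#' motivational shifts: with changes Delta taken relative to the baseline
#' week, the numerator is `dF(t) - alpha * (dU(t) - dM(t))` — growth of
#' the unmotivated pool is penalized, growth of the motivated pool is
#' credited — and is normalized by `N_max`, the maximum numerator among
#' the groups (over the whole grid in global mode, at each time in
#' per-time mode). Unlike efficacy, rho can be negative.
#'
#' @inheritParams efficacy
#' @return data.frame `week, group, rho, numerator, dF, dU, dM` with
#'   attribute `N_max` (scalar, or per-week vector in per-time mode).
#' @export
effectiveness <- function(curves, config = metric_config()) {
  curves <- as_long_curves(curves)
  if (!config$baseline_week %in% curves$week)
    stop("baseline week ", config$baseline_week, " is not on the curve grid")
  out <- NULL
  for (g in unique(curves$group)) {
    cg <- curves[curves$group == g, ]
    base <- cg[cg$week == config$baseline_week, ]
    dU <- cg$stage1 - base$stage1
    dM <- cg$stage3 - base$stage3
    dF <- cg$stage4 - base$stage4
    num <- dF - config$alpha * (dU - dM)
    out <- rbind(out, data.frame(week = cg$week, group = g, numerator = num,
                                 dF = dF, dU = dU, dM = dM))
  }
  if (config$normalization == "global") {
    N_max <- max(out$numerator)
    if (N_max <= 0)
      stop("N_max <= 0 under global normalization (alpha = ", config$alpha,
           ", baseline week ", config$baseline_week,
           "): no group improves; effectiveness undefined")
    out$rho <- out$numerator / N_max
  } else {
    N_max <- stats::ave(out$numerator, out$week, FUN = max)
    if (any(N_max <= 0 & out$week != config$baseline_week))
      warning("per-time N_max <= 0 at some weeks; rho set to NA there")
    out$rho <- ifelse(N_max > 0, out$numerator / N_max, NA_real_)
    N_max <- tapply(out$numerator, out$week, max)
  }
  out <- out[, c("week", "group", "rho", "numerator", "dF", "dU", "dM")]
  attr(out, "N_max") <- N_max
  attr(out, "alpha") <- config$alpha
  out
}
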