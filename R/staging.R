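#' Assign a stage of readiness from questionnaire items
#'
#' Stages follow the standard stage-of-change binning of a 0-10 motivation
#' item combined with 7-day point-prevalence abstinence: a respondent who
#' has not smoked even part of a cigarette in the past 7 days is a former
#' smoker (stage 4) regardless of the motivation item; otherwise motivation
#' 0-3 is unmotivated (stage 1), 4-7 indecisive (stage 2) and 8-10
#' motivated (stage 3).
#'
#' @param motivation integer 0-10, or `NA`. May be missing only when
#'   `smoked_past7` is `"no"`.
#' @param smoked_past7 `"yes"`/`"no"` (case-insensitive) or logical
#'   (`TRUE` = smoked).
#' @param bins cut points of the motivation bins: stage 1 is
#'   `0..bins[1]`, stage 2 is `bins[1]+1..bins[2]`, stage 3 the rest.
#' @return integer stage in 1:4 (vectorized).
#' @examples
#' assign_stage(2, "yes")   # 1
#' assign_stage(7, "yes")   # 2
#' assign_stage(9, "no")    # 4
#' @export
assign_stage <- function(motivation, smoked_past7, bins = c(3L, 7L)) {
  smoked <- parse_yes_no(smoked_past7)
  if (anyNA(smoked))
    stop("smoked_past7 must be yes/no (or logical), got missing/unparsable values")
  motivation <- as.numeric(motivation)
  needs_mot <- smoked
  bad <- needs_mot & is.na(motivation)
  if (any(bad))
    stop("missing motivation for current smokers at ", sum(bad), " record(s)")
  ok <- is.na(motivation) |
    (motivation == round(motivation) & motivation >= 0 & motivation <= 10)
  if (!all(ok))
    stop("motivation must be an integer in [0, 10]; offending value(s): ",
         paste(utils::head(motivation[!ok], 5), collapse = ", "))
  stage <- ifelse(!smoked, 4L,
           ifelse(motivation <= bins[1], 1L,
           ifelse(motivation <= bins[2], 2L, 3L)))
  as.integer(stage)
}

parse_yes_no <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("yes", "y", "1", "true")] <- TRUE
  out[x %in% c("no", "n", "0", "false")] <- FALSE
  out
}

#' Assemble a stage panel from long-format records
#'
#' Builds a validated panel of per-subject (week, stage) sequences from
#' long-format records, one row per subject-visit. Stages may be supplied
#' directly (`stage` column) or derived from the questionnaire items
#' (`motivation`, `smoked_past7`) via [assign_stage()].
#'
#' In complete-case mode (the default, mirroring the usual handling of
#' 3-wave trial panels) subjects missing any grid week are dropped and
#' recorded in the exclusion log; otherwise partial sequences are kept,
#' since the panel likelihood handles unequal observation intervals.
#'
#' @param records data.frame with columns `subject_id`, `group`, `week`,
#'   and either `stage` or both `motivation` and `smoked_past7`.
#' @param grid observation weeks; default `c(0, 12, 26)`.
#' @param complete_case drop subjects with any missing grid wave?
#' @param bins motivation cut points passed to [assign_stage()].
#' @return an object of class `stage_panel`: a list with `subjects` (named
#'   list of data.frames `week`, `stage`), `groups` (named character of
#'   group per subject), `grid`, and `exclusions` (data.frame of dropped
#'   subjects and reasons).
#' @export
build_panel <- function(records, grid = c(0, 12, 26), complete_case = TRUE,
                        bins = c(3L, 7L)) {
  stopifnot(is.data.frame(records), length(grid) >= 2)
  req <- c("subject_id", "group", "week")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  grid <- sort(unique(as.numeric(grid)))

  if (!"stage" %in% names(records)) {
    if (!all(c("motivation", "smoked_past7") %in% names(records)))
      stop("records needs either a stage column or motivation + smoked_past7")
    keep <- !(is.na(records$smoked_past7) & is.na(records$motivation))
    records$stage <- NA_integer_
    records$stage[keep] <- assign_stage(records$motivation[keep],
                                        records$smoked_past7[keep], bins)
  }
  stg <- records$stage
  if (!all(is.na(stg) | stg %in% 1:4))
    stop("stage values must be in 1..4")

  key <- paste(records$subject_id, records$week, sep = "@")
  if (anyDuplicated(key)) {
    dup <- records$subject_id[duplicated(key)][1]
    stop("duplicate (subject, week) observation for subject ", dup)
  }

  id_chr <- as.character(records$subject_id)
  ids <- unique(id_chr)
  rows_by_id <- split(seq_len(nrow(records)), factor(id_chr, levels = ids))
  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  keep <- logical(length(ids))
  groups <- character(0)
  excl_id <- character(0); excl_reason <- character(0)
  for (k in seq_along(ids)) {
    id <- ids[k]
    rows <- records[rows_by_id[[k]], , drop = FALSE]
    rows <- rows[order(rows$week), , drop = FALSE]
    obs <- rows[rows$week %in% grid & !is.na(rows$stage),
                c("week", "stage"), drop = FALSE]
    if ((complete_case && nrow(obs) < length(grid)) || nrow(obs) == 0) {
      excl_id <- c(excl_id, id)
      excl_reason <- c(excl_reason,
                       if (nrow(obs) == 0) "no usable observations"
                       else paste0("missing wave(s): ",
                                   paste(setdiff(grid, obs$week),
                                         collapse = ",")))
      next
    }
    rownames(obs) <- NULL
    obs$stage <- as.integer(obs$stage)
    subjects[[k]] <- obs
    keep[k] <- TRUE
    groups[id] <- as.character(rows$group[1])
  }
  subjects <- subjects[keep]
  excl <- data.frame(subject_id = excl_id, reason = excl_reason,
                     stringsAsFactors = FALSE)
  if (length(subjects) == 0)
    stop("no subjects retained after exclusions")
  structure(list(subjects = subjects, groups = groups, grid = grid,
                 exclusions = excl),
            class = "stage_panel")
}

#' @export
print.stage_panel <- function(x, ...) {
  cat("Stage panel:", length(x$subjects), "subjects in",
      length(unique(x$groups)), "group(s);",
      "grid weeks:", paste(x$grid, collapse = ", "), "\n")
  tab <- table(x$groups)
  for (g in names(tab)) cat("  ", g, ": n = ", tab[[g]], "\n", sep = "")
  if (nrow(x$exclusions))
    cat("  excluded:", nrow(x$exclusions), "subject(s)",
        sprintf("(%.1f%%)", 100 * nrow(x$exclusions) /
                  (nrow(x$exclusions) + length(x$subjects))), "\n")
  invisible(x)
}

#' Censor relapse transitions out of the absorbing stage
#'
#' Stage 4 (7-day abstinence) is treated as absorbing; every sequence is
#' truncated at its first stage-4 observation, which removes the rare
#' observed relapses (and the uninformative 4-to-4 pairs, which have
#' probability 1 under the model and so leave the likelihood unchanged).
#' The number of relapse transitions removed is recorded in
#' `attr(, "relapses_removed")`.
#'
#' @param panel a `stage_panel`.
#' @param mode `"truncate"` keeps each sequence up to first absorption
#'   (default); `"drop_subject"` additionally removes relapsing subjects
#'   entirely.
#' @return the censored `stage_panel`.
#' @export
censor_relapse <- function(panel, mode = c("truncate", "drop_subject")) {
  stopifnot(inherits(panel, "stage_panel"))
  mode <- match.arg(mode)
  removed <- 0L
  drop_ids <- character(0)
  for (id in names(panel$subjects)) {
    obs <- panel$subjects[[id]]
    first4 <- match(4L, obs$stage)
    if (!is.na(first4) && first4 < nrow(obs)) {
      later <- obs$stage[(first4 + 1):nrow(obs)]
      n_rel <- sum(later != 4L)
      removed <- removed + n_rel
      if (n_rel > 0 && mode == "drop_subject") {
        drop_ids <- c(drop_ids, id)
      } else {
        panel$subjects[[id]] <- obs[seq_len(first4), , drop = FALSE]
      }
    }
  }
  if (length(drop_ids)) {
    panel$subjects[drop_ids] <- NULL
    panel$groups <- panel$groups[setdiff(names(panel$groups), drop_ids)]
    panel$exclusions <- rbind(panel$exclusions, data.frame(
      subject_id = drop_ids, reason = "relapse from absorbing stage",
      stringsAsFactors = FALSE))
  }
  attr(panel, "relapses_removed") <- removed
  panel
}

#' Interval transition counts for one intervention group
#'
#' Tallies consecutive observation pairs (stage l then stage k) into a 4x4
#' count matrix, the sufficient statistic for the equal-interval panel
#' likelihood.
#'
#' If the wave spacing is mixed (e.g. the 0/12/26 design, whose intervals
#' are 12 and 14 weeks but which the equal-interval likelihood treats as
#' nominally 13-week follow-ups), the nominal interval is the mean spacing
#' and the result is flagged via attribute `nominal_interval` and a
#' message; pass `interval` to override.
#'
#' @param panel a `stage_panel`.
#' @param group group label; `NULL` pools all subjects.
#' @param interval interval length override in weeks.
#' @return an object of class `transition_counts`: the 4x4 integer matrix
#'   with attributes `interval` (weeks), `nominal_interval` (TRUE if the
#'   spacing was mixed and idealized) and `n_subjects`.
#' @export
transition_counts <- function(panel, group = NULL, interval = NULL) {
  stopifnot(inherits(panel, "stage_panel"))
  ids <- names(panel$subjects)
  if (!is.null(group)) {
    ids <- ids[panel$groups[ids] == group]
    if (!length(ids)) stop("no subjects in group '", group, "'")
  }
  counts <- matrix(0L, 4, 4, dimnames = list(from = 1:4, to = 1:4))
  deltas <- numeric(0)
  for (id in ids) {
    obs <- panel$subjects[[id]]
    if (nrow(obs) < 2) next
    for (j in seq_len(nrow(obs) - 1)) {
      counts[obs$stage[j], obs$stage[j + 1]] <-
        counts[obs$stage[j], obs$stage[j + 1]] + 1L
      deltas <- c(deltas, obs$week[j + 1] - obs$week[j])
    }
  }
  nominal <- FALSE
  if (is.null(interval)) {
    if (length(unique(deltas)) == 1) {
      interval <- deltas[1]
    } else {
      interval <- mean(diff(panel$grid))  # nominal wave spacing
      nominal <- TRUE
      message("mixed observation intervals (",
              paste(sort(unique(deltas)), collapse = ", "),
              " weeks); using nominal interval ", interval, " weeks")
    }
  }
  structure(counts, interval = interval, nominal_interval = nominal,
            n_subjects = length(ids),
            class = c("transition_counts", class(counts)))
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Interval transition counts (", sum(x), " transitions, ",
      attr(x, "n_subjects"), " subjects, interval ",
      attr(x, "interval"), " weeks):\n", sep = "")
  print(unclass(x)[1:4, 1:4])
  invisible(x)
}

#' Observed stage prevalence per group and grid week
#'
#' Per-group stage counts and percentages at each grid week, plus a
#' baseline-to-final change row, reproducing the usual descriptive summary
#' of a 3-wave stage panel.
#'
#' @param panel a `stage_panel` (complete-case: each subject observed at
#'   every reported week).
#' @return data.frame with columns `group`, `week` (final row per group is
#'   `"change"`), `n`, `count1..count4`, `pct1..pct4`.
#' @export
observed_prevalence <- function(panel) {
  stopifnot(inherits(panel, "stage_panel"))
  out <- NULL
  for (g in unique(panel$groups)) {
    ids <- names(panel$subjects)[panel$groups == g]
    weeks <- sort(unique(unlist(lapply(panel$subjects[ids], `[[`, "week"))))
    tab <- matrix(0L, length(weeks), 4,
                  dimnames = list(weeks, paste0("count", 1:4)))
    for (id in ids) {
      obs <- panel$subjects[[id]]
      for (j in seq_len(nrow(obs)))
        tab[as.character(obs$week[j]), obs$stage[j]] <-
          tab[as.character(obs$week[j]), obs$stage[j]] + 1L
    }
    n <- length(ids)
    pct <- 100 * tab / rowSums(tab)
    block <- data.frame(group = g, week = as.character(weeks), n = n,
                        tab, pct, row.names = NULL, check.names = FALSE)
    names(block)[8:11] <- paste0("pct", 1:4)
    chg <- block[nrow(block), ]
    chg$week <- "change"
    chg[, 4:11] <- block[nrow(block), 4:11] - block[1, 4:11]
    out <- rbind(out, block, chg)
  }
  rownames(out) <- NULL
  out
}

#' Read a long-format panel CSV
#'
#' Expects columns `subject_id, group, week, motivation, smoked_past7`
#' (header required; `smoked_past7` case-insensitive yes/no/NA), or a
#' pre-staged file with a `stage` column.
#'
#' @param path CSV path.
#' @inheritParams build_panel
#' @return a `stage_panel`.
#' @export
read_panel_csv <- function(path, grid = c(0, 12, 26), complete_case = TRUE,
                           bins = c(3L, 7L)) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", "", "na"))
  build_panel(records, grid = grid, complete_case = complete_case, bins = bins)
}
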