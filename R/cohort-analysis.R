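# Cohort-level statistics: quartile summaries (the violin-plot numbers),
# one-way ANOVA with Tukey HSD pairwise correction, and per-patient
# longitudinal trajectories.

#' Summarize one group of activity scores
#'
#' Median, first/third quartile (linear interpolation between order
#' statistics, i.e. `quantile` type 7 -- the convention is recorded in the
#' output), min, max and n.
#'
#' @param scores non-empty numeric vector.
#' @return one-row data.frame `n`, `median`, `q1`, `q3`, `min`, `max` with
#'   attribute `quartileMethod`.
#' @export
summarizeGroup <- function(scores) {
  if (!length(scores) || !is.numeric(scores))
    stop("'scores' must be a non-empty numeric vector")
  if (!all(is.finite(scores))) stop("'scores' must be finite")
  q <- unname(quantile(scores, c(0.25, 0.5, 0.75), type = 7))
  out <- data.frame(n = length(scores), median = q[2], q1 = q[1], q3 = q[3],
                    min = min(scores), max = max(scores))
  attr(out, "quartileMethod") <- "linear interpolation (quantile type 7)"
  out
}

#' Compare score distributions across groups
#'
#' Classical one-way fixed-effects ANOVA (equal-variance form) with Tukey
#' HSD adjusted pairwise p-values; unequal group sizes are handled by the
#' Tukey-Kramer harmonic-mean adjustment (as in [stats::TukeyHSD()]). The
#' 0.05 significance threshold is reported alongside but never baked into
#' the returned values.
#'
#' @param groups named list of numeric score vectors, one per group;
#'   at least 2 groups with at least 2 observations each.
#' @return object of class `GroupComparisonResult`: list with `summary`
#'   (per-group data.frame of [summarizeGroup()] rows), `fStatistic`,
#'   `pValue`, `df` (numerator, denominator), `pairwise` (data.frame
#'   `group1`, `group2`, `diff`, `lwr`, `upr`, `pAdj`), `alpha`.
#' @export
compareGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)))
    stop("'groups' must be a named list of at least 2 score vectors")
  small <- names(groups)[vapply(groups, length, 1L) < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  df <- data.frame(
    score = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- aov(score ~ group, data = df)
  tab <- anova(fit)
  tk <- TukeyHSD(fit)$group
  # TukeyHSD rows follow combn(levels, 2) with each pair printed as
  # "second-first"; reconstruct the pair labels instead of parsing the
  # rownames (group labels may themselves contain '-').
  cmb <- utils::combn(names(groups), 2)
  summary <- do.call(rbind, lapply(groups, summarizeGroup))
  summary <- cbind(group = names(groups), summary)
  rownames(summary) <- NULL
  structure(list(
    summary = summary,
    fStatistic = unname(tab[["F value"]][1]),
    pValue = unname(tab[["Pr(>F)"]][1]),
    df = unname(tab[["Df"]]),
    pairwise = data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                          diff = unname(tk[, "diff"]),
                          lwr = unname(tk[, "lwr"]),
                          upr = unname(tk[, "upr"]),
                          pAdj = unname(tk[, "p adj"]),
                          row.names = NULL, stringsAsFactors = FALSE),
    alpha = 0.05), class = "GroupComparisonResult")
}

#' @export
print.GroupComparisonResult <- function(x, ...) {
  cat("One-way ANOVA across", nrow(x$summary), "groups\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g (alpha = %.2g)\n",
              x$df[1], x$df[2], x$fStatistic, x$pValue, x$alpha))
  cat("Tukey HSD adjusted pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Per-patient longitudinal score trajectories
#'
#' Orders each patient's scores by the declared timepoint order and reports
#' the sign of (last - first), so a claim like "a consistent increase at
#' relapse" is assertable as all signs positive. Patients may miss interior
#' timepoints (ragged panels are common in longitudinal series).
#'
#' @param scores data.frame with columns `patient_id`, `timepoint`,
#'   `score`.
#' @param timepointOrder character vector giving the study's timepoint
#'   order; every annotated timepoint must appear in it.
#' @return object of class `TrajectorySet`: list with `trajectories`
#'   (named list of per-patient data.frames ordered by timepoint) and
#'   `summary` (data.frame `patient_id`, `n`, `first`, `last`, `delta`,
#'   `sign`).
#' @export
longitudinalTrajectories <- function(scores, timepointOrder) {
  need <- c("patient_id", "timepoint", "score")
  if (!all(need %in% names(scores)))
    stop("'scores' must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(scores$timepoint), timepointOrder)
  if (length(unknown))
    stop("timepoint(s) not in timepointOrder: ",
         paste(unknown, collapse = ", "))
  dup <- duplicated(scores[c("patient_id", "timepoint")])
  if (any(dup))
    stop("duplicate (patient, timepoint) rows: ",
         paste(unique(paste(scores$patient_id[dup], scores$timepoint[dup],
                            sep = "/")), collapse = ", "))
  scores$timepoint <- factor(scores$timepoint, levels = timepointOrder)
  traj <- lapply(split(scores, scores$patient_id), function(d) {
    d <- d[order(d$timepoint), c("timepoint", "score")]
    d$timepoint <- as.character(d$timepoint)
    rownames(d) <- NULL
    d
  })
  summary <- do.call(rbind, lapply(names(traj), function(p) {
    s <- traj[[p]]$score
    data.frame(patient_id = p, n = length(s), first = s[1],
               last = s[length(s)], delta = s[length(s)] - s[1],
               sign = sign(s[length(s)] - s[1]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(trajectories = traj, summary = summary),
            class = "TrajectorySet")
}

#' @export
print.TrajectorySet <- function(x, ...) {
  cat("Longitudinal trajectories for", length(x$trajectories), "patients\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
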