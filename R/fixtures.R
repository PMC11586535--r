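# Published frequency tables encoded as in-package fixtures.
#
# These are the murmur-grade / maximal-intensity-location cross-tabulation of
# the full study cohort by diagnosis, and the characteristics of the staged
# MMVD dogs.  Counts are stored exactly as printed; percentages are always
# recomputed from the counts.

.TABLE2 <- local({
  diseases <- c("normal", "MMVD", "PS", "AS", "PDA", "DCM")
  grades <- c("none", "soft", "moderate", "loud", "thrilling")
  max_int <- rbind(
    normal = c(94, 37, 3, 0, 0),
    MMVD   = c(7, 87, 114, 139, 64),
    PS     = c(0, 3, 11, 10, 25),
    AS     = c(0, 9, 9, 11, 3),
    PDA    = c(2, 8, 2, 3, 19),
    DCM    = c(4, 11, 7, 2, 0))
  sites <- c("none", "left_base", "left_apex", "right_side")
  pmi <- rbind(
    normal = c(94, 21, 17, 2),
    MMVD   = c(7, 3, 384, 15),
    PS     = c(0, 41, 8, 0),
    AS     = c(0, 23, 8, 1),
    PDA    = c(2, 23, 8, 1),
    DCM    = c(4, 3, 17, 0))
  rbind(
    data.frame(group = rep(diseases, each = 5),
               variable = "max_intensity",
               level = rep(grades, times = 6),
               count = as.integer(t(max_int))),
    data.frame(group = rep(diseases, each = 4),
               variable = "point_of_max",
               level = rep(sites, times = 6),
               count = as.integer(t(pmi))))
})

.TABLE3 <- local({
  stages <- c("A", "B1", "B2", "CD")
  row <- function(variable, level, counts) {
    data.frame(group = stages, variable = variable, level = level,
               count = as.integer(counts))
  }
  rbind(
    row("n", "total", c(62, 225, 131, 51)),
    row("bcs", "lt5", c(44, 129, 71, 39)),
    row("bcs", "5to9", c(16, 85, 52, 8)),
    row("breed", "CKCS", c(2, 38, 33, 11)),
    row("sex", "female_entire", c(11, 18, 9, 2)),
    row("sex", "female_neutered", c(22, 80, 59, 24)),
    row("sex", "male_entire", c(15, 48, 16, 6)),
    row("sex", "male_neutered", c(14, 78, 45, 18)),
    row("pimobendan", "yes", c(0, 16, 50, 37)),
    row("arrhythmia", "yes", c(14, 57, 38, 22)),
    row("apex_grade", "none", c(50, 7, 0, 0)),
    row("apex_grade", "soft", c(12, 88, 2, 1)),
    row("apex_grade", "moderate", c(0, 79, 33, 3)),
    row("apex_grade", "loud", c(0, 47, 64, 25)),
    row("apex_grade", "thrilling", c(0, 4, 32, 22)))
})

# Published medians (IQR) for the continuous characteristics of staged MMVD
# dogs; these parameterize the synthetic cohort generator.
.TABLE3_CONT <- list(
  age = list(A = c(4.4, 2.1, 8.2), B1 = c(9.5, 7.8, 11),
             B2 = c(10, 8.6, 12), CD = c(10, 9.2, 12)),
  body_weight = list(A = c(8.8, 5.3, 11), B1 = c(9.8, 6.9, 15),
                     B2 = c(8.7, 6.0, 12), CD = c(9.3, 5.2, 13)),
  la_ao = list(A = c(1.40, 1.30, 1.43), B1 = c(1.42, 1.35, 1.50),
               B2 = c(1.80, 1.70, 1.98), CD = c(2.29, 1.96, 2.69)),
  lviddn = list(A = c(1.52, 1.42, 1.59), B1 = c(1.57, 1.44, 1.66),
                B2 = c(1.88, 1.77, 1.99), CD = c(2.20, 1.95, 2.38)))

#' Load a published frequency-table fixture
#'
#' Returns the frequency counts of the study's cohort cross-tabulations
#' exactly as printed: `"table2"` is the distribution of maximal murmur
#' intensity and point of maximal intensity by diagnosis over the full
#' cohort; `"table3"` is the breakdown of staged MMVD dogs (stage groups A,
#' B1, B2, and pooled C/D).
#'
#' @param table_id `"table2"` or `"table3"`.
#' @return Data frame with columns `group`, `variable`, `level`, `count`.
#' @export
load_table_fixtures <- function(table_id) {
  switch(table_id,
         table2 = .TABLE2,
         table3 = .TABLE3,
         stop("unknown table_id: ", table_id))
}

#' Cross-tabulate a cohort (or table fixture) with integer percentages
#'
#' For a fixture data frame the printed counts are used directly; for a
#' synthetic cohort the same cross-tabulations are computed from the records
#' (maximal reduced grade over sites and point of maximal intensity by
#' disease; left-apex grade by MMVD stage).  Percentages are rounded to
#' integers, as conventionally reported.
#'
#' @param x A fixture from [load_table_fixtures()] or a cohort data frame
#'   from [synthesize_cohort()].
#' @return Data frame with columns `group`, `variable`, `level`, `count`,
#'   `pct`.  Percentages are relative to the group total: the number of dogs
#'   in the group (for fixtures, the total of the `max_intensity` /
#'   `apex_grade` rows, or the `n` row when present).
#' @export
cohort_summary <- function(x) {
  if (is.data.frame(x) && all(c("group", "variable", "level", "count")
                              %in% names(x))) {
    tab <- x
  } else if (is.data.frame(x) && "disease" %in% names(x)) {
    tab <- .cohort_crosstab(x)
  } else {
    stop("x must be a table fixture or a cohort data frame")
  }
  if (nrow(tab) == 0) stop("empty input")
  totals <- .group_totals(tab)
  tab$pct <- as.integer(round(100 * tab$count / totals[tab$group]))
  tab
}

.group_totals <- function(tab) {
  groups <- unique(tab$group)
  out <- vapply(groups, function(g) {
    sub <- tab[tab$group == g, ]
    if (any(sub$variable == "n")) {
      sub$count[sub$variable == "n"][1]
    } else if (any(sub$variable == "max_intensity")) {
      sum(sub$count[sub$variable == "max_intensity"])
    } else if (any(sub$variable == "apex_grade")) {
      sum(sub$count[sub$variable == "apex_grade"])
    } else {
      sum(sub$count)
    }
  }, numeric(1))
  names(out) <- groups
  out
}

# cross-tabulations of a synthetic cohort mirroring the fixture layout
.cohort_crosstab <- function(cohort) {
  grades <- grade_levels()
  gmax <- pmax(cohort$levine_left_apex, cohort$levine_left_base,
               cohort$levine_right_side)
  max_grade <- factor(reduce_levine(gmax), levels = grades)
  out <- list()
  for (d in unique(cohort$disease)) {
    sel <- cohort$disease == d
    cnt <- table(max_grade[sel])
    out[[length(out) + 1L]] <- data.frame(
      group = d, variable = "max_intensity", level = grades,
      count = as.integer(cnt))
    pmi <- table(factor(cohort$point_of_maximal_intensity[sel],
                        levels = c("none", "left_base", "left_apex",
                                   "right_side")))
    out[[length(out) + 1L]] <- data.frame(
      group = d, variable = "point_of_max",
      level = names(pmi), count = as.integer(pmi))
  }
  mm <- cohort[cohort$disease == "MMVD" | cohort$mmvd_stage == "A", ]
  if (nrow(mm) > 0) {
    mm$stage_group <- ifelse(mm$mmvd_stage %in% c("C", "D"), "CD",
                             mm$mmvd_stage)
    for (s in unique(mm$stage_group)) {
      sel <- mm$stage_group == s
      apex <- factor(reduce_levine(mm$levine_left_apex[sel]), levels = grades)
      cnt <- table(apex)
      out[[length(out) + 1L]] <- data.frame(
        group = s, variable = "apex_grade", level = grades,
        count = as.integer(cnt))
    }
  }
  do.call(rbind, out)
}

#' Proportion of a fixture group above/at a set of levels
#'
#' Convenience accessor for derived percentages such as the proportion of
#' dogs in a diagnosis group with any murmur, or with a loud-or-thrilling
#' left-apex murmur.
#'
#' @param summary Output of [cohort_summary()].
#' @param group Group label (disease or stage group).
#' @param variable Variable name within the table.
#' @param levels Levels whose counts are summed in the numerator.
#' @return Integer percentage (rounded as printed).
#' @export
summary_pct <- function(summary, group, variable, levels) {
  sub <- summary[summary$group == group & summary$variable == variable &
                   summary$level %in% levels, ]
  if (nrow(sub) == 0) stop("no matching rows")
  totals <- .group_totals(summary[summary$group == group, ])
  as.integer(round(100 * sum(sub$count) / totals[[group]]))
}
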