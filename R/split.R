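# Covariate-minimization cohort splitting (Pocock-Simon).
#
# Patients are processed in a seeded random order and each is assigned to
# the arm (train/test) that minimizes the summed marginal imbalance over the
# balancing variables plus a weighted arm-size term.  The 50/50 ratio is
# guaranteed by a hard capacity bound (no arm may exceed ceil(n/2)); the
# soft size term keeps interim drift small while still letting covariates
# decide, which is what allows identical covariate pairs to end up on
# opposite arms regardless of arrival order.  The processing order and
# tie-break coins are derived per patient from hash(seed, patient_id), so
# each patient's assignment depends only on the patients ordered before it
# (online in the processing order, for a fixed capacity).

.DEFAULT_SPLIT_VARS <- c("site_of_recruitment", "disease_group",
                         "heart_rate", "max_murmur_grade", "bcs",
                         "body_weight")

# Derive the stratification levels for each balancing variable.  Continuous
# variables are binned into terciles computed on the full cohort; BCS is
# dichotomized at 5; disease is grouped MMVD / normal / other; missing
# values form their own stratum.
.split_strata <- function(cohort, variables) {
  tercile <- function(x) {
    br <- unique(stats::quantile(x, c(0, 1 / 3, 2 / 3, 1), na.rm = TRUE))
    lev <- as.character(cut(x, br, include.lowest = TRUE))
    lev[is.na(lev)] <- "missing"
    lev
  }
  out <- lapply(variables, function(v) {
    switch(v,
      disease_group = {
        d <- cohort$disease
        ifelse(d == "MMVD", "MMVD", ifelse(d == "normal", "normal", "other"))
      },
      max_murmur_grade = {
        g <- pmax(cohort$levine_left_apex, cohort$levine_left_base,
                  cohort$levine_right_side)
        reduce_levine(g)
      },
      heart_rate = tercile(cohort$heart_rate),
      body_weight = tercile(cohort$body_weight),
      bcs = ifelse(is.na(cohort$bcs), "missing",
                   ifelse(cohort$bcs < 5, "<5", ">=5")),
      {
        if (!v %in% names(cohort)) stop("unknown balancing variable: ", v)
        x <- as.character(cohort[[v]])
        x[is.na(x)] <- "missing"
        x
      })
  })
  names(out) <- variables
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Split a cohort by stratified minimization
#'
#' @param cohort Cohort data frame (one row per patient, with
#'   `patient_id`).
#' @param variables Balancing variables; the default six are recruitment
#'   site, disease group (MMVD/normal/other), heart rate, maximum murmur
#'   intensity over sites, body condition score, and body weight.
#' @param ratio Target proportion in the training arm (0.5).
#' @param seed Integer seed.
#' @param size_weight Weight of the soft arm-size balance term relative to
#'   the unit-weighted covariates.  Equal arm sizes are guaranteed
#'   separately by a hard capacity bound of ceil(n/2) per arm.
#' @return A `split_assignment`: data frame `assignment` (`patient_id`,
#'   `arm`), per-variable `imbalance_report`, and the `seed`.
#' @export
minimization_split <- function(cohort, variables = .DEFAULT_SPLIT_VARS,
                               ratio = 0.5, seed = 1L, size_weight = 2) {
  stopifnot(nrow(cohort) > 0, ratio == 0.5)
  strata <- .split_strata(cohort, variables)
  n <- nrow(cohort)
  cap <- ceiling(n / 2)
  keys <- vapply(cohort$patient_id, function(id) {
    derive_seed(seed, "order", id)
  }, integer(1))
  ord <- order(keys)
  arm <- character(n)
  # counts[[v]][level, arm]
  counts <- lapply(strata, function(col) {
    m <- matrix(0L, nrow = length(unique(col)), ncol = 2,
                dimnames = list(unique(col), c("train", "test")))
    m
  })
  sizes <- c(train = 0L, test = 0L)
  for (i in ord) {
    open <- names(sizes)[sizes < cap]
    if (length(open) == 1L) {
      a <- open
    } else {
      score <- c(train = 0, test = 0)
      for (a in c("train", "test")) {
        s <- size_weight * abs((sizes[[a]] + 1L) -
                                 sizes[[setdiff(c("train", "test"), a)]])
        for (v in variables) {
          lev <- strata[i, v]
          cnt <- counts[[v]][lev, ]
          cnt[[a]] <- cnt[[a]] + 1L
          s <- s + abs(cnt[["train"]] - cnt[["test"]])
        }
        score[[a]] <- s
      }
      a <- if (score[["train"]] < score[["test"]]) {
        "train"
      } else if (score[["test"]] < score[["train"]]) {
        "test"
      } else {
        coin <- with_seed(derive_seed(seed, "coin", cohort$patient_id[i]),
                          stats::runif(1))
        if (coin < 0.5) "train" else "test"
      }
    }
    arm[i] <- a
    sizes[[a]] <- sizes[[a]] + 1L
    for (v in variables) {
      lev <- strata[i, v]
      counts[[v]][lev, a] <- counts[[v]][lev, a] + 1L
    }
  }
  report <- data.frame(
    variable = variables,
    imbalance = vapply(variables, function(v) {
      sum(abs(counts[[v]][, "train"] - counts[[v]][, "test"]))
    }, numeric(1)),
    row.names = NULL)
  structure(list(assignment = data.frame(patient_id = cohort$patient_id,
                                         arm = arm,
                                         stringsAsFactors = FALSE),
                 imbalance_report = report, seed = as.integer(seed)),
            class = "split_assignment")
}

#' Per-variable imbalance of an arbitrary assignment
#'
#' Computes the same summed level-wise |train - test| imbalance scores that
#' minimization optimizes, for any assignment (e.g., simple randomization),
#' enabling like-for-like comparisons.
#'
#' @param cohort Cohort data frame.
#' @param arm Character vector (`"train"`/`"test"`) aligned with `cohort`.
#' @param variables Balancing variables.
#' @return Data frame `variable`, `imbalance`.
#' @export
split_imbalance <- function(cohort, arm, variables = .DEFAULT_SPLIT_VARS) {
  strata <- .split_strata(cohort, variables)
  data.frame(
    variable = variables,
    imbalance = vapply(variables, function(v) {
      tab <- table(strata[[v]], factor(arm, c("train", "test")))
      sum(abs(tab[, "train"] - tab[, "test"]))
    }, numeric(1)),
    row.names = NULL)
}
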