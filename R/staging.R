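# Clinical rules: Levine-to-reduced grade mapping, body-weight-normalized
# left ventricular diameter, ACVIM echocardiographic staging of MMVD, the
# preclinical clean/confounded partition, and the B1-vs-B2 classification
# layer driven by the loud-or-greater murmur probability.

#' Collapse a Levine murmur grade (0-VI) to the reduced scale
#'
#' Levine grades I/II map to soft, III to moderate, IV to loud, and V/VI to
#' thrilling; 0 encodes the absence of a murmur and maps to none.
#'
#' @param levine Integer vector with values in 0-6.
#' @return Character vector of reduced grade labels (see [grade_levels()]).
#' @export
reduce_levine <- function(levine) {
  if (any(is.na(levine)) || any(levine < 0 | levine > 6) ||
      any(levine != round(levine))) {
    stop("Levine grade must be an integer in 0-6")
  }
  map <- c("none", "soft", "soft", "moderate", "loud", "thrilling",
           "thrilling")
  map[as.integer(levine) + 1L]
}

#' Body-weight-normalized left ventricular internal diameter in diastole
#'
#' LVIDDN = LVIDD (cm) / weight (kg)^0.294, the allometric normalization
#' used by the ACVIM B2 criterion.
#'
#' @param lvidd Left ventricular internal diameter in diastole, cm.
#' @param weight Body weight, kg.
#' @return Dimensionless normalized diameter.
#' @export
compute_lviddn <- function(lvidd, weight) {
  if (any(lvidd <= 0) || any(weight <= 0)) {
    stop("lvidd and weight must be positive")
  }
  lvidd / weight^0.294
}

#' Stage a dog under the ACVIM echocardiographic criteria
#'
#' MMVD dogs without congestive heart failure are staged B2 when both
#' LA/Ao >= 1.6 and LVIDDN >= 1.7 (inclusive thresholds), else B1.  CHF
#' (stage C/D) is an input label assigned clinically, passed through
#' unchanged.  Dogs with a normal heart and body weight < 15 kg are stage A
#' (at risk); larger normal dogs receive stage `"none"`.
#'
#' @param record A one-row data frame (or list) with fields `disease`,
#'   `la_ao`, `lvidd`, `body_weight`, and optional `chf` (logical) or
#'   `mmvd_stage` giving a clinical C/D label.
#' @return Stage label: one of `"none"`, `"A"`, `"B1"`, `"B2"`, `"C"`, `"D"`.
#' @export
stage_mmvd <- function(record) {
  disease <- record$disease
  if (disease == "normal") {
    if (is.na(record$body_weight)) stop("missing body weight")
    return(if (record$body_weight < 15) "A" else "none")
  }
  if (disease != "MMVD") return("none")
  chf <- isTRUE(record$chf) ||
    (!is.null(record$mmvd_stage) && !is.na(record$mmvd_stage) &&
       record$mmvd_stage %in% c("C", "D"))
  if (chf) {
    if (!is.null(record$mmvd_stage) && record$mmvd_stage %in% c("C", "D")) {
      return(record$mmvd_stage)
    }
    return("C")
  }
  if (is.na(record$la_ao) || is.na(record$lvidd) ||
      is.na(record$body_weight)) {
    stop("missing echocardiographic values for MMVD dog ",
         record$patient_id %||% "")
  }
  lviddn <- compute_lviddn(record$lvidd, record$body_weight)
  if (record$la_ao >= 1.6 && lviddn >= 1.7) "B2" else "B1"
}

#' Partition a staged cohort into preclinical clean / confounded samples
#'
#' Dogs that are not preclinical MMVD (normal hearts, other cardiac disease,
#' stage C/D congestive heart failure) or that receive loop diuretics
#' (furosemide or torasemide) are excluded.  The remaining B1/B2 dogs form
#' the preclinical sample, split into a confounded subsample (body weight
#' outside 2-25 kg, age < 6 years, or on pimobendan) and a clean subsample
#' (all gates passed).
#'
#' @param cohort Cohort data frame with columns `patient_id`, `disease`,
#'   `mmvd_stage`, `age`, `body_weight`, `pimobendan_flag`,
#'   `loop_diuretic_flag`.
#' @return Data frame with `patient_id`, `partition` (`"clean"`,
#'   `"confounded"`, `"excluded"`), and `exclusion_reason` (NA for included
#'   dogs).
#' @export
partition_preclinical <- function(cohort) {
  if (any(is.na(cohort$mmvd_stage))) stop("cohort contains unstaged records")
  one <- function(i) {
    r <- cohort[i, ]
    if (r$disease != "MMVD") {
      return(c("excluded", if (r$disease == "normal") "normal_heart"
               else "other_disease"))
    }
    if (r$mmvd_stage %in% c("C", "D")) return(c("excluded", "chf"))
    if (isTRUE(r$loop_diuretic_flag)) return(c("excluded", "loop_diuretic"))
    if (!r$mmvd_stage %in% c("B1", "B2")) return(c("excluded", "not_stage_b"))
    if (is.na(r$body_weight) || r$body_weight < 2 || r$body_weight > 25) {
      return(c("confounded", "weight_outside_2_25kg"))
    }
    if (is.na(r$age) || r$age < 6) return(c("confounded", "age_lt_6y"))
    if (isTRUE(r$pimobendan_flag)) return(c("confounded", "pimobendan"))
    c("clean", NA_character_)
  }
  res <- t(vapply(seq_len(nrow(cohort)), one, character(2)))
  data.frame(patient_id = cohort$patient_id, partition = res[, 1],
             exclusion_reason = res[, 2], stringsAsFactors = FALSE)
}

#' Probability-based B1-vs-B2 classification from a left-apex grade
#' distribution
#'
#' The continuous score is the predicted probability that the left-apex
#' murmur is loud or greater, `P(loud) + P(thrilling)`; the dog is called B2
#' when the score reaches the threshold.  The default threshold 0.5
#' corresponds to the specific operating point where a predicted loud or
#' thrilling murmur decides stage B2.
#'
#' @param dist Length-5 probability vector over the reduced grades
#'   (left-apex prediction), or a matrix with 5 columns (one row per dog).
#' @param threshold Decision threshold on the loud-or-greater probability.
#' @return List with `stage` (`"B1"`/`"B2"`) and `score`.
#' @export
classify_b1_b2 <- function(dist, threshold = 0.5) {
  score <- loud_or_greater_probability(dist)
  list(stage = ifelse(score >= threshold, "B2", "B1"), score = score)
}

#' Expert rule: stage B2 iff the left-apex reduced grade is loud or thrilling
#'
#' @param grade Reduced grade label(s) at the left apex.
#' @return `"B1"` or `"B2"` per element.
#' @export
expert_rule_b1_b2 <- function(grade) {
  g <- as_grade(grade)
  ifelse(g %in% c("loud", "thrilling"), "B2", "B1")
}
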