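# Synthetic cohort generator.
#
# Emulates the joint structure of the study population: diseases and MMVD
# stages in the published proportions, per-site Levine grades drawn from the
# printed grade distributions (left-apex grade conditional on MMVD stage;
# maximal grade conditional on diagnosis for other diseases),
# echocardiographic measurements drawn from log-normal distributions matched
# to the printed medians and interquartile ranges and constrained to the
# ACVIM stage criteria, and one synthetic phonocardiogram per auscultation
# site whose murmur grade matches the site's reduced Levine grade.

.tab_prop <- function(tab, group, variable) {
  sub <- tab[tab$group == group & tab$variable == variable, ]
  p <- sub$count / sum(sub$count)
  names(p) <- sub$level
  p
}

#' Default cohort marginal distributions
#'
#' Marginals mirror the published cohort: disease mix over the 756 dogs,
#' MMVD stage mix (B1 225, B2 131, C 44, D 7), per-stage left-apex grade
#' distributions, per-diagnosis maximal-grade and point-of-maximal-intensity
#' distributions, and per-stage medication/arrhythmia rates.  Grade and
#' stage distributions for diagnoses that the published tables do not break
#' down (mitral valve dysplasia, pooled "other") are chosen to resemble the
#' closest tabulated diagnosis.
#'
#' @return Named list of named probability vectors / lists, suitable for the
#'   `marginals` argument of [synthesize_cohort()].
#' @export
default_cohort_marginals <- function() {
  t2 <- .TABLE2
  t3 <- .TABLE3
  grades <- grade_levels()
  max_grade <- lapply(c(normal = "normal", MMVD = "MMVD", PS = "PS",
                        AS = "AS", PDA = "PDA", DCM = "DCM"),
                      function(d) .tab_prop(t2, d, "max_intensity"))
  max_grade$MVD_dysplasia <- stats::setNames(c(0.05, 0.25, 0.3, 0.3, 0.1),
                                             grades)
  max_grade$other <- stats::setNames(c(0.35, 0.35, 0.2, 0.08, 0.02), grades)
  pmi <- lapply(c(normal = "normal", MMVD = "MMVD", PS = "PS", AS = "AS",
                  PDA = "PDA", DCM = "DCM"),
                function(d) {
                  p <- .tab_prop(t2, d, "point_of_max")
                  p <- p[names(p) != "none"]
                  if (sum(p) == 0) p[] <- c(1, 1, 1) / 3 else p <- p / sum(p)
                  p
                })
  pmi$MVD_dysplasia <- c(left_base = 0.1, left_apex = 0.85, right_side = 0.05)
  pmi$other <- c(left_base = 0.5, left_apex = 0.35, right_side = 0.15)
  apex_grade_by_stage <- lapply(c(A = "A", B1 = "B1", B2 = "B2", CD = "CD"),
                                function(s) .tab_prop(t3, s, "apex_grade"))
  list(
    disease = c(normal = 134, MMVD = 407, PS = 49, AS = 32, PDA = 34,
                DCM = 24, MVD_dysplasia = 13, other = 63) / 756,
    mmvd_stage = c(B1 = 225, B2 = 131, C = 44, D = 7) / 407,
    site_of_recruitment = stats::setNames(rep(0.25, 4),
                                          paste0("centre", 1:4)),
    sex = c(female_entire = 18, female_neutered = 80, male_entire = 48,
            male_neutered = 78) / 224,
    max_grade_by_disease = max_grade,
    pmi_by_disease = pmi,
    apex_grade_by_stage = apex_grade_by_stage,
    pimobendan_by_stage = c(A = 0, B1 = 16 / 225, B2 = 50 / 131,
                            CD = 37 / 51),
    arrhythmia_by_stage = c(A = 14 / 62, B1 = 57 / 225, B2 = 38 / 131,
                            CD = 22 / 51),
    loop_diuretic_by_stage = c(A = 0, B1 = 0.037, B2 = 0.037, CD = 0.85)
  )
}

.validate_marginals <- function(m) {
  for (nm in c("disease", "mmvd_stage", "site_of_recruitment", "sex")) {
    check_probs(m[[nm]], nm)
  }
  for (d in names(m$max_grade_by_disease)) {
    check_probs(m$max_grade_by_disease[[d]], paste0("max_grade[", d, "]"))
  }
  for (s in names(m$apex_grade_by_stage)) {
    check_probs(m$apex_grade_by_stage[[s]], paste0("apex_grade[", s, "]"))
  }
  for (d in names(m$pmi_by_disease)) {
    check_probs(m$pmi_by_disease[[d]], paste0("pmi[", d, "]"))
  }
  invisible(TRUE)
}

# Levine grade within a reduced class (uniform over the class's Levine range)
.levine_from_reduced <- function(grade) {
  switch(grade,
         none = 0L,
         soft = sample(1:2, 1L),
         moderate = 3L,
         loud = 4L,
         thrilling = sample(5:6, 1L))
}

# stage group key for parameter lookup
.stage_group <- function(stage) {
  if (stage %in% c("C", "D")) "CD" else if (stage %in% c("A", "B1", "B2")) {
    stage
  } else "A"   # normal-heart-like echo for unstaged dogs
}

# Draw echo measures consistent with a stage group; B1/B2 constrained to the
# ACVIM criteria (B2: both thresholds met; B1: at least one failed).
.draw_echo <- function(stage_group, weight) {
  la <- .TABLE3_CONT$la_ao[[stage_group]]
  lv <- .TABLE3_CONT$lviddn[[stage_group]]
  for (i in 1:50) {
    la_ao <- rlnorm_median_iqr(1, la[1], la[2], la[3])
    lviddn <- rlnorm_median_iqr(1, lv[1], lv[2], lv[3])
    b2 <- la_ao >= 1.6 && lviddn >= 1.7
    if (stage_group == "B2" && b2) break
    if (stage_group == "B1" && !b2) break
    if (!stage_group %in% c("B1", "B2")) break
  }
  if (stage_group == "B2") {
    la_ao <- max(la_ao, 1.6)
    lviddn <- max(lviddn, 1.7)
  }
  if (stage_group == "B1" && la_ao >= 1.6 && lviddn >= 1.7) {
    la_ao <- 1.55
  }
  c(la_ao = la_ao, lviddn = lviddn, lvidd = lviddn * weight^0.294)
}

#' Generate a synthetic cohort of dogs with per-site phonocardiograms
#'
#' @param n Number of dogs.
#' @param marginals Marginal distribution specification; see
#'   [default_cohort_marginals()].
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param audio If `TRUE` (default) synthesize one recording per auscultation
#'   site per dog; `FALSE` generates metadata only (useful for large
#'   marginal-distribution checks).
#' @param duration,sample_rate,ambient_noise_rms Passed to the
#'   phonocardiogram synthesizer for every recording.
#' @return A `pcg_cohort`: list with `cohort` (one row per dog) and
#'   `recordings` (named list of `pcg_recording`, names
#'   `<patient_id>_<site>`), plus the generation parameters.
#' @export
synthesize_cohort <- function(n, marginals = default_cohort_marginals(),
                              seed = 1L, audio = TRUE, duration = 15,
                              sample_rate = 4000, ambient_noise_rms = 0.02) {
  stopifnot(n > 0)
  .validate_marginals(marginals)
  grades <- grade_levels()
  sites <- site_levels()
  rows <- with_seed(derive_seed(seed, "cohort"), {
    lapply(seq_len(n), function(i) {
      disease <- sample_level(marginals$disease)
      stage <- "none"
      if (disease == "MMVD") stage <- sample_level(marginals$mmvd_stage)
      sg <- .stage_group(stage)
      # demographics
      if (disease == "MMVD") {
        ag <- .TABLE3_CONT$age[[sg]]
        wt <- .TABLE3_CONT$body_weight[[sg]]
      } else if (disease == "normal") {
        ag <- c(4.4, 2.1, 8.2); wt <- c(10, 5.5, 18)
      } else {
        ag <- c(3.5, 1.5, 7); wt <- c(12, 6, 22)
      }
      age <- rlnorm_median_iqr(1, ag[1], ag[2], ag[3])
      weight <- rlnorm_median_iqr(1, wt[1], wt[2], wt[3])
      if (disease == "normal" && stage == "none" && weight < 15) stage <- "A"
      # murmur grades per site
      if (disease == "MMVD" && stage != "none") {
        apex_grade <- sample_level(marginals$apex_grade_by_stage[[sg]])
        max_grade <- apex_grade
        pmi_site <- "left_apex"
        if (max_grade != "none") {
          pmi_site <- sample_level(marginals$pmi_by_disease$MMVD)
        }
      } else {
        max_grade <- sample_level(marginals$max_grade_by_disease[[disease]])
        pmi_site <- if (max_grade == "none") "left_apex" else {
          sample_level(marginals$pmi_by_disease[[disease]])
        }
        apex_grade <- if (pmi_site == "left_apex") max_grade else NA
      }
      gidx <- grade_index(max_grade)
      site_grade <- stats::setNames(rep("none", 3), sites)
      if (max_grade != "none") {
        for (s in sites) {
          if (s == pmi_site || (disease == "MMVD" && s == "left_apex")) {
            site_grade[s] <- max_grade
          } else {
            drop <- sample(1:2, 1L, prob = c(0.6, 0.4))
            site_grade[s] <- grades[max(gidx - drop, 0L) + 1L]
          }
        }
        if (disease == "MMVD" && !is.na(apex_grade)) {
          site_grade["left_apex"] <- apex_grade
        }
      }
      levine <- vapply(site_grade, .levine_from_reduced, integer(1))
      echo <- .draw_echo(sg, weight)
      pmed <- marginals$pimobendan_by_stage
      amed <- marginals$arrhythmia_by_stage
      dmed <- marginals$loop_diuretic_by_stage
      key <- if (sg %in% names(pmed)) sg else "A"
      loop_p <- if (disease == "DCM") 0.3 else dmed[[key]]
      data.frame(
        patient_id = sprintf("P%04d", i),
        site_of_recruitment = sample_level(marginals$site_of_recruitment),
        disease = disease, mmvd_stage = stage,
        age = round(age, 1), body_weight = round(weight, 1),
        bcs = as.integer(pmin(pmax(round(stats::rnorm(1, 5, 1.3)), 1), 9)),
        sex = sample_level(marginals$sex),
        heart_rate = as.integer(pmin(pmax(round(stats::rnorm(1, 115, 25)),
                                          60), 220)),
        arrhythmia_flag = stats::runif(1) < amed[[key]],
        levine_left_apex = levine[["left_apex"]],
        levine_left_base = levine[["left_base"]],
        levine_right_side = levine[["right_side"]],
        point_of_maximal_intensity =
          if (max_grade == "none") "none" else pmi_site,
        la_ao = round(echo[["la_ao"]], 2),
        lvidd = round(echo[["lvidd"]], 2),
        pimobendan_flag = stats::runif(1) < pmed[[key]],
        loop_diuretic_flag = stats::runif(1) < loop_p,
        stringsAsFactors = FALSE)
    })
  })
  cohort <- do.call(rbind, rows)
  recordings <- list()
  if (audio) {
    for (i in seq_len(n)) {
      r <- cohort[i, ]
      for (s in sites) {
        g <- reduce_levine(r[[paste0("levine_", s)]])
        cfg <- synthesis_config(
          heart_rate = r$heart_rate, sample_rate = sample_rate,
          duration = duration, murmur_grade = g,
          murmur_timing = if (r$disease == "PDA" && g != "none")
            "continuous" else "systolic",
          ambient_noise_rms = ambient_noise_rms,
          seed = derive_seed(seed, "audio", r$patient_id, s))
        recordings[[paste(r$patient_id, s, sep = "_")]] <-
          synthesize_pcg(cfg, patient_id = r$patient_id, site = s)
      }
    }
  }
  structure(list(cohort = cohort, recordings = recordings, seed = seed,
                 duration = duration, sample_rate = sample_rate,
                 ambient_noise_rms = ambient_noise_rms),
            class = "pcg_cohort")
}

#' Per-site reduced grade labels of a cohort, in long format
#'
#' @param cohort Cohort data frame (the `cohort` element of a `pcg_cohort`).
#' @return Data frame with `patient_id`, `site`, `recording_id`, `grade`
#'   (reduced grade label at that site).
#' @export
cohort_recording_labels <- function(cohort) {
  out <- do.call(rbind, lapply(site_levels(), function(s) {
    data.frame(patient_id = cohort$patient_id, site = s,
               recording_id = paste(cohort$patient_id, s, sep = "_"),
               grade = reduce_levine(cohort[[paste0("levine_", s)]]),
               stringsAsFactors = FALSE)
  }))
  out[order(out$patient_id, out$site), ]
}

#' @export
print.pcg_cohort <- function(x, ...) {
  cat(sprintf("<pcg_cohort> %d dogs, %d recordings (seed %d)\n",
              nrow(x$cohort), length(x$recordings), x$seed))
  print(table(x$cohort$disease))
  invisible(x)
}
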