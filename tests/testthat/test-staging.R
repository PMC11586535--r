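test_that("Levine grades collapse onto the reduced scale, order-preserving", {
  expect_equal(reduce_levine(0), "none")
  expect_equal(reduce_levine(2), "soft")
  expect_equal(reduce_levine(3), "moderate")
  expect_equal(reduce_levine(4), "loud")
  expect_equal(reduce_levine(c(1, 5, 6)), c("soft", "thrilling",
                                            "thrilling"))
  # surjective and monotone over the full domain
  all_levels <- reduce_levine(0:6)
  expect_setequal(all_levels, grade_levels())
  expect_true(!is.unsorted(grade_index(all_levels)))
  expect_error(reduce_levine(7), "0-6")
  expect_error(reduce_levine(-1), "0-6")
})

test_that("LVIDDN follows the allometric formula and its monotonicities", {
  expect_equal(compute_lviddn(1, 1), 1)
  expect_equal(compute_lviddn(2, 1), 2)
  expect_equal(compute_lviddn(3, 9.8), 3 / exp(0.294 * log(9.8)),
               tolerance = 1e-12)
  expect_true(compute_lviddn(2.5, 8) > compute_lviddn(2.4, 8))
  expect_true(compute_lviddn(2.5, 9) < compute_lviddn(2.5, 8))
  expect_error(compute_lviddn(0, 5), "positive")
})

test_that("ACVIM staging applies the echo thresholds inclusively", {
  mk <- function(la_ao, lviddn, weight = 10, disease = "MMVD",
                 stage = NA_character_) {
    list(patient_id = "X", disease = disease, la_ao = la_ao,
         lvidd = lviddn * weight^0.294, body_weight = weight,
         mmvd_stage = stage)
  }
  expect_equal(stage_mmvd(mk(1.80, 1.88)), "B2")
  expect_equal(stage_mmvd(mk(1.42, 1.57)), "B1")
  expect_equal(stage_mmvd(mk(1.6, 1.7)), "B2")       # inclusive thresholds
  expect_equal(stage_mmvd(mk(1.59, 1.9)), "B1")
  expect_equal(stage_mmvd(mk(1.9, 1.69)), "B1")
  expect_equal(stage_mmvd(mk(2.3, 2.2, stage = "C")), "C")
  expect_equal(stage_mmvd(list(disease = "normal", body_weight = 10)), "A")
  expect_equal(stage_mmvd(list(disease = "normal", body_weight = 20)),
               "none")
  expect_error(stage_mmvd(list(patient_id = "X", disease = "MMVD",
                               la_ao = NA, lvidd = 2, body_weight = 8,
                               mmvd_stage = NA)),
               "missing echocardiographic")
  # monotone: raising either measurement never demotes B2 to B1
  set.seed(6)
  for (i in 1:25) {
    la <- runif(1, 1.2, 2.2)
    lv <- runif(1, 1.3, 2.2)
    s0 <- stage_mmvd(mk(la, lv))
    s1 <- stage_mmvd(mk(la + runif(1, 0, 0.5), lv + runif(1, 0, 0.5)))
    expect_false(s0 == "B2" && s1 == "B1")
  }
})

test_that("preclinical partition applies the exclusion and confounder gates", {
  mk <- function(id, disease = "MMVD", stage = "B1", age = 8, weight = 10,
                 pimo = FALSE, loop = FALSE) {
    data.frame(patient_id = id, disease = disease, mmvd_stage = stage,
               age = age, body_weight = weight, pimobendan_flag = pimo,
               loop_diuretic_flag = loop, stringsAsFactors = FALSE)
  }
  co <- rbind(mk("p1", loop = TRUE),
              mk("p2", stage = "B2", age = 4),
              mk("p3"),
              mk("p4", disease = "normal", stage = "A"),
              mk("p5", stage = "C"),
              mk("p6", weight = 30),
              mk("p7", pimo = TRUE),
              mk("p8", weight = 1.5))
  part <- partition_preclinical(co)
  got <- stats::setNames(part$partition, part$patient_id)
  expect_equal(got[["p1"]], "excluded")
  expect_equal(part$exclusion_reason[part$patient_id == "p1"],
               "loop_diuretic")
  expect_equal(got[["p2"]], "confounded")
  expect_equal(got[["p3"]], "clean")
  expect_equal(got[["p4"]], "excluded")
  expect_equal(got[["p5"]], "excluded")
  expect_equal(got[["p6"]], "confounded")
  expect_equal(got[["p7"]], "confounded")
  expect_equal(got[["p8"]], "confounded")
})

test_that("partition covers a synthetic cohort and clean dogs pass all gates", {
  co <- synthesize_cohort(300, seed = 44, audio = FALSE)$cohort
  part <- partition_preclinical(co)
  expect_equal(nrow(part), nrow(co))
  expect_setequal(part$partition,
                  intersect(c("clean", "confounded", "excluded"),
                            part$partition))
  clean <- co[part$partition == "clean", ]
  expect_true(all(clean$disease == "MMVD"))
  expect_true(all(clean$mmvd_stage %in% c("B1", "B2")))
  expect_true(all(clean$body_weight >= 2 & clean$body_weight <= 25))
  expect_true(all(clean$age >= 6))
  expect_true(!any(clean$pimobendan_flag) && !any(clean$loop_diuretic_flag))
})

test_that("B1/B2 classification thresholds the loud-or-greater score", {
  hi <- c(0, 0, 0.1, 0.7, 0.2)
  lo <- c(0.5, 0.4, 0.1, 0, 0)
  expect_equal(classify_b1_b2(hi, 0.5)$stage, "B2")
  expect_equal(classify_b1_b2(hi, 0.5)$score, 0.9)
  expect_equal(classify_b1_b2(lo, 1e-9)$stage, "B1")
  expect_equal(classify_b1_b2(lo, 0.5)$score, 0)
  # threshold 0 calls everything B2: the sensitivity-1 ROC endpoint
  m <- rbind(hi, lo, rep(0.2, 5))
  expect_true(all(classify_b1_b2(m, 0)$stage == "B2"))
})

test_that("the expert staging rule keys on loud-or-thrilling apex grades", {
  expect_equal(expert_rule_b1_b2("loud"), "B2")
  expect_equal(expert_rule_b1_b2("thrilling"), "B2")
  expect_equal(expert_rule_b1_b2("moderate"), "B1")
  expect_equal(expert_rule_b1_b2("none"), "B1")
})
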