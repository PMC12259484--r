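test_that("categorize uses lower-inclusive half-open intervals", {
  expect_equal(categorize(0, c(33, 66)), "low")
  expect_equal(categorize(66, c(33, 66)), "high")
  expect_equal(categorize(c(32.9, 33, 65.9, 100), c(33, 66)),
               c("low", "moderate", "moderate", "high"))
  expect_error(categorize(50, c(66, 33)), "strictly increasing")

  # against a linear-scan oracle over arbitrary cut lists
  set.seed(7)
  for (rep in 1:20) {
    cuts <- sort(runif(sample(1:4, 1), 1, 99))
    labels <- c("low",
                if (length(cuts) == 2) "moderate"
                else if (length(cuts) > 2) paste0("moderate_",
                                                  seq_len(length(cuts) - 1)),
                "high")[seq_len(length(cuts) + 1)]
    scores <- runif(50, 0, 100)
    scan <- vapply(scores, function(s) {
      i <- 1L
      for (ct in cuts) if (s >= ct) i <- i + 1L else break
      labels[i]
    }, character(1))
    expect_equal(categorize(scores, cuts), scan)
  }
})

test_that("uniform weights reduce to the fraction of risk answers selected", {
  # brute force over every subset of a 4-answer toy exposure domain
  w <- default_risk_weights()
  w$exposure$work_contexts[] <- 0
  w$exposure$distance_frequency[] <- 0
  w$exposure_modifiers$isolation_triggers[] <- 1
  w$exposure_modifiers$behaviours_would_stop[] <- 1
  toy <- c("food_medicine_healthcare", "outdoor_exercise",
           "other_shops_services", "visit_friends")
  w$exposure$isolation_behaviours[] <- 0
  w$exposure$isolation_behaviours[toy] <- 1
  w$factor_scale_max$exposure <- length(toy)
  w <- risktailor:::validate_risk_weights(unclass(w))
  for (mask in 0:15) {
    subset <- toy[as.logical(bitwAnd(mask, 2^(0:3)))]
    rec <- make_record(isolation_behaviours = subset,
                       distance_frequency = "almost_always")
    est <- score_risk(rec, w)
    expect_equal(est$exposure_risk, 100 * length(subset) / length(toy))
  }
})

test_that("a maximally protective respondent sits at the configured minima", {
  rec <- make_record(
    work_contexts = "from_home",
    isolation_behaviours = "mostly_home",
    distance_frequency = "almost_always",
    handwash_situations = c("public_surfaces", "entering_building",
                            "before_food", "after_contact",
                            "after_sneeze_cough", "touching_face"),
    handwash_thoroughness = c("soap_or_sanitiser", "twenty_seconds",
                              "nails_and_fingers"),
    age_band = "20_29", gender = "female"
  )
  est <- score_risk(rec)
  expect_equal(est$exposure_risk, 0)
  expect_equal(est$hygiene_risk, 0)
  expect_equal(est$uncontrollable_risk, 0)
  expect_equal(est$exposure_category, "low")
  expect_equal(est$hygiene_category, "low")
})

test_that("adding risk answers is monotone; protective answers never raise risk", {
  w <- default_risk_weights()
  base_sets <- list(
    character(0), "food_medicine_healthcare",
    c("food_medicine_healthcare", "outdoor_exercise"),
    c("visit_family", "mostly_home")
  )
  for (base in base_sets) {
    rec0 <- make_record(isolation_behaviours = base)
    est0 <- score_risk(rec0, w)
    for (extra in setdiff(risktailor:::rt_isolation_behaviours, base)) {
      rec1 <- make_record(isolation_behaviours = c(base, extra))
      est1 <- score_risk(rec1, w)
      if (w$exposure$isolation_behaviours[[extra]] > 0) {
        expect_gte(est1$exposure_risk, est0$exposure_risk)
      } else {
        expect_lte(est1$exposure_risk, est0$exposure_risk)
      }
    }
  }
  # two respondents identical except one additional visit
  quiet <- make_record(isolation_behaviours = "food_medicine_healthcare")
  social <- make_record(
    isolation_behaviours = c("food_medicine_healthcare", "visit_friends"))
  expect_gte(score_risk(social)$exposure_risk,
             score_risk(quiet)$exposure_risk)
})

test_that("each answer family touches exactly one factor", {
  # exhaustive over all subsets of handwashing situations (2^7) against a
  # fixed exposure profile: hygiene may move, exposure and uncontrollable
  # may not
  sits <- risktailor:::rt_handwash_situations
  base <- make_record()
  base_est <- score_risk(base)
  for (mask in 0:(2^7 - 1)) {
    subset <- sits[as.logical(bitwAnd(mask, 2^(0:6)))]
    est <- score_risk(make_record(handwash_situations = subset))
    expect_equal(est$exposure_risk, base_est$exposure_risk)
    expect_equal(est$uncontrollable_risk, base_est$uncontrollable_risk)
  }
  # and symmetrically: exposure answers never move hygiene/uncontrollable
  for (subset in list(character(0), "visit_friends",
                      c("food_medicine_healthcare", "visit_family"),
                      risktailor:::rt_isolation_behaviours)) {
    est <- score_risk(make_record(isolation_behaviours = subset))
    expect_equal(est$hygiene_risk, base_est$hygiene_risk)
    expect_equal(est$uncontrollable_risk, base_est$uncontrollable_risk)
  }
  # demographics only move the uncontrollable factor
  for (age in c("under_20", "40_49", "70_plus")) {
    est <- score_risk(make_record(age_band = age))
    expect_equal(est$exposure_risk, base_est$exposure_risk)
    expect_equal(est$hygiene_risk, base_est$hygiene_risk)
  }
})

test_that("scores are invariant to answer order within a set", {
  a <- make_record(isolation_behaviours = c("visit_friends", "visit_family",
                                            "outdoor_exercise"))
  b <- make_record(isolation_behaviours = c("outdoor_exercise",
                                            "visit_family",
                                            "visit_friends"))
  expect_equal(score_risk(a)[-1], score_risk(b)[-1])
})

test_that("an answer without a configured weight is a configuration error", {
  w <- default_risk_weights()
  w$exposure$isolation_behaviours <-
    w$exposure$isolation_behaviours[-which(names(
      w$exposure$isolation_behaviours) == "visit_friends")]
  expect_error(risktailor:::validate_risk_weights(unclass(w)),
               "visit_friends")
})

test_that("risk weights round-trip through JSON", {
  w <- default_risk_weights()
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_weights(w, path)
  reread <- load_risk_weights(path)
  rec <- make_record(isolation_behaviours = c("visit_friends",
                                              "outdoor_exercise"),
                     distance_frequency = "rarely")
  expect_equal(score_risk(rec, reread), score_risk(rec, w))
  # the packaged fixture matches the in-code default configuration
  packaged <- load_risk_weights(system.file("extdata", "risk_weights.json",
                                            package = "risktailor"))
  expect_equal(score_risk(rec, packaged), score_risk(rec, w))
})
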