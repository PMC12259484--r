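# Three-factor risk engine. Each factor aggregates the non-negative weights
# of the risk-conferring answers actually given, normalised to 0-100 by a
# configurable per-factor ceiling. Protective answers carry weight zero: they
# reduce risk only by displacing risk-conferring answers, never by subtracting.

#' Default risk-weight configuration
#'
#' The deployed weights of the original tool were expert-elicited and are not
#' part of this package; the configuration object is the reproducible
#' contract. The documented default is uniform within each factor: every
#' risk-conferring multi-select answer weighs 1, every protective answer 0,
#' and the ordinal distance item is graded 4 ("almost never") down to
#' 0 ("almost always"; "never in public" also 0 - no exposure). Endorsed
#' self-isolation triggers act as exposure multipliers at or below 1
#' (reported willingness to retreat slightly lowers expected exposure);
#' answers about which behaviours would stop act likewise.
#'
#' @return A `risk_weights` list with components `exposure`,
#'   `exposure_modifiers`, `hygiene`, `uncontrollable`, `factor_scale_max`
#'   and `cuts`.
#' @export
default_risk_weights <- function() {
  w <- list(
    exposure = list(
      work_contexts = c(
        patients_vulnerable = 1, children = 1, coworkers = 1,
        general_public = 1, from_home = 0, not_working = 0
      ),
      isolation_behaviours = c(
        food_medicine_healthcare = 1, outdoor_exercise = 1,
        other_shops_services = 1, mostly_home = 0, visit_family = 1,
        visit_friends = 1
      ),
      distance_frequency = c(
        almost_never = 4, rarely = 3, sometimes = 2, often = 1,
        almost_always = 0, never_in_public = 0
      )
    ),
    exposure_modifiers = list(
      isolation_triggers = c(
        own_symptoms = 0.95, contact_with_sick = 0.95,
        government_restrictions = 0.95, never = 1, other = 1
      ),
      behaviours_would_stop = c(
        food_medicine_healthcare = 0.99, outdoor_exercise = 0.99,
        other_shops_services = 0.99, mostly_home = 1, visit_family = 0.99,
        visit_friends = 0.99, other = 1
      )
    ),
    hygiene = list(
      handwash_situations = c(
        public_surfaces = 0, entering_building = 0, before_food = 0,
        after_contact = 0, after_sneeze_cough = 0, touching_face = 0,
        never_or_occasionally = 1
      ),
      handwash_thoroughness = c(
        soap_or_sanitiser = 0, twenty_seconds = 0, nails_and_fingers = 0,
        none_of_above = 1
      )
    ),
    uncontrollable = list(
      age_band = c(
        under_20 = 0, `20_29` = 0, `30_39` = 0, `40_49` = 1, `50_59` = 1,
        `60_69` = 2, `70_plus` = 3, declined = 1
      ),
      gender = c(
        female = 0, male = 1, nonbinary_or_self_specified = 0, declined = 0
      )
    ),
    factor_scale_max = list(exposure = 13, hygiene = 2, uncontrollable = 4),
    cuts = c(33, 66)
  )
  validate_risk_weights(w)
}

validate_risk_weights <- function(w) {
  needed <- c("exposure", "exposure_modifiers", "hygiene", "uncontrollable",
              "factor_scale_max", "cuts")
  missing_parts <- setdiff(needed, names(w))
  if (length(missing_parts) > 0) {
    abort(paste0("risk weights missing component(s): ",
                 paste(missing_parts, collapse = ", ")))
  }
  domains <- list(
    c("exposure", "work_contexts"), c("exposure", "isolation_behaviours"),
    c("exposure", "distance_frequency"),
    c("exposure_modifiers", "isolation_triggers"),
    c("exposure_modifiers", "behaviours_would_stop"),
    c("hygiene", "handwash_situations"), c("hygiene", "handwash_thoroughness"),
    c("uncontrollable", "age_band"), c("uncontrollable", "gender")
  )
  full_domains <- c(rt_set_fields,
                    list(distance_frequency = rt_distance_levels,
                         age_band = rt_age_bands, gender = rt_genders))
  for (d in domains) {
    vec <- w[[d[1]]][[d[2]]]
    if (is.null(vec)) abort(paste0("risk weights missing map: ", d[2]))
    missing_codes <- setdiff(full_domains[[d[2]]], names(vec))
    if (length(missing_codes) > 0) {
      abort(paste0("no weight configured for ", d[2], " code(s): ",
                   paste(missing_codes, collapse = ", ")))
    }
    if (d[1] != "exposure_modifiers" && any(vec < 0)) {
      abort(paste0("negative weight in ", d[2]))
    }
    if (d[1] == "exposure_modifiers" && any(vec < 0 | vec > 1)) {
      abort(paste0("exposure modifiers must lie in [0, 1]: ", d[2]))
    }
  }
  sm <- w$factor_scale_max
  if (any(unlist(sm) <= 0)) abort("factor_scale_max must be positive")
  validate_cuts(w$cuts)
  structure(w, class = "risk_weights")
}

validate_cuts <- function(cuts) {
  if (length(cuts) < 1 || any(diff(cuts) <= 0) ||
      any(cuts <= 0 | cuts >= 100)) {
    abort("category cut points must be strictly increasing within (0, 100)")
  }
  invisible(cuts)
}

#' Read risk weights from JSON
#'
#' @param path JSON file mirroring the structure of
#'   [default_risk_weights()].
#' @return A validated `risk_weights` object.
#' @export
load_risk_weights <- function(path) {
  if (!file.exists(path)) abort(paste0("weights file not found: ", path))
  raw <- jsonlite::fromJSON(path)
  for (part in c("exposure", "exposure_modifiers", "hygiene",
                 "uncontrollable")) {
    raw[[part]] <- lapply(raw[[part]], unlist)
  }
  raw$cuts <- as.numeric(unlist(raw$cuts))
  validate_risk_weights(raw)
}

#' @rdname load_risk_weights
#' @param weights A `risk_weights` object.
#' @export
write_risk_weights <- function(weights, path) {
  stopifnot(inherits(weights, "risk_weights"))
  out <- unclass(weights)
  out[c("exposure", "exposure_modifiers", "hygiene", "uncontrollable")] <-
    lapply(out[c("exposure", "exposure_modifiers", "hygiene",
                 "uncontrollable")], function(part) lapply(part, as.list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

sum_weights <- function(answers, weight_map, field) {
  if (length(answers) == 0) return(0)
  missing_codes <- setdiff(answers, names(weight_map))
  if (length(missing_codes) > 0) {
    abort(paste0("no weight configured for ", field, " code(s): ",
                 paste(missing_codes, collapse = ", ")))
  }
  sum(weight_map[answers])
}

#' Score a cohort with the three-factor risk model
#'
#' For each respondent, three scores in 0-100 are computed independently:
#' *exposure risk* ("risk of getting the virus") from work contexts,
#' self-isolation behaviours and the distance-keeping frequency, scaled by
#' the trigger modifiers; *hygiene risk* ("risk from not removing the
#' virus") from handwashing answers; and *uncontrollable risk* from
#' demographics. Each factor is the weighted sum of its risk-conferring
#' answers, times `100 / factor_scale_max`, clamped to `[0, 100]`, and then
#' mapped to a `low`/`moderate`/`high` category by [categorize()].
#'
#' @param responses A validated cohort tibble (or a single record as a
#'   one-row tibble).
#' @param weights A `risk_weights` configuration.
#' @return A tibble with one row per respondent: `respondent_id`,
#'   `exposure_risk`, `hygiene_risk`, `uncontrollable_risk` and the three
#'   `_category` columns.
#' @export
score_risk <- function(responses, weights = default_risk_weights()) {
  weights <- validate_risk_weights(unclass(weights))
  n <- nrow(responses)
  exposure <- hygiene <- uncontrollable <- numeric(n)
  for (i in seq_len(n)) {
    expo <- sum_weights(responses$work_contexts[[i]],
                        weights$exposure$work_contexts, "work_contexts") +
      sum_weights(responses$isolation_behaviours[[i]],
                  weights$exposure$isolation_behaviours,
                  "isolation_behaviours") +
      sum_weights(responses$distance_frequency[i],
                  weights$exposure$distance_frequency, "distance_frequency")
    mod <- prod(c(
      weights$exposure_modifiers$isolation_triggers[
        responses$isolation_triggers[[i]]],
      weights$exposure_modifiers$behaviours_would_stop[
        responses$behaviours_would_stop[[i]]]
    ), na.rm = FALSE)
    if (is.na(mod)) {
      abort(sprintf("row %d: trigger answer without configured modifier", i))
    }
    exposure[i] <- expo * mod
    hygiene[i] <- sum_weights(responses$handwash_situations[[i]],
                              weights$hygiene$handwash_situations,
                              "handwash_situations") +
      sum_weights(responses$handwash_thoroughness[[i]],
                  weights$hygiene$handwash_thoroughness,
                  "handwash_thoroughness")
    uncontrollable[i] <- sum_weights(responses$age_band[i],
                                     weights$uncontrollable$age_band,
                                     "age_band") +
      sum_weights(responses$gender[i], weights$uncontrollable$gender,
                  "gender")
  }
  clamp01 <- function(x, scale_max) pmin(pmax(100 * x / scale_max, 0), 100)
  exposure <- clamp01(exposure, weights$factor_scale_max$exposure)
  hygiene <- clamp01(hygiene, weights$factor_scale_max$hygiene)
  uncontrollable <- clamp01(uncontrollable,
                            weights$factor_scale_max$uncontrollable)
  tibble::tibble(
    respondent_id = responses$respondent_id,
    exposure_risk = exposure,
    hygiene_risk = hygiene,
    uncontrollable_risk = uncontrollable,
    exposure_category = categorize(exposure, weights$cuts),
    hygiene_category = categorize(hygiene, weights$cuts),
    uncontrollable_category = categorize(uncontrollable, weights$cuts)
  )
}

#' Map a 0-100 risk score to an ordinal category
#'
#' Intervals are half-open and lower-inclusive: a score below the first cut
#' is `low`, a score at or above the last cut is `high`, anything between is
#' `moderate`. With more than two cuts the intermediate labels are
#' `moderate_1`, `moderate_2`, ...
#'
#' @param score Numeric vector of scores in `[0, 100]`.
#' @param cuts Strictly increasing cut points within `(0, 100)`.
#' @return Character vector of category labels.
#' @export
#' @examples
#' categorize(c(0, 33, 65.9, 66, 100), cuts = c(33, 66))
categorize <- function(score, cuts = c(33, 66)) {
  validate_cuts(cuts)
  if (any(score < 0 | score > 100, na.rm = TRUE)) {
    abort("scores must lie in [0, 100]")
  }
  n_mid <- length(cuts) - 1
  labels <- c("low",
              if (n_mid == 1) "moderate"
              else if (n_mid > 1) paste0("moderate_", seq_len(n_mid)),
              "high")
  idx <- findInterval(score, cuts, left.open = FALSE) + 1L
  labels[idx]
}
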