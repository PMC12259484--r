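# Answer domains of the risk-estimation questionnaire. These are the closed
# vocabularies every other module validates against; order matters for ordinal
# fields (distance_frequency) and for stable serialisation.

rt_behaviours <- c("social_distancing", "self_isolation", "hand_washing")

rt_constructs <- c("attitude", "perceived_norm", "perceived_behavioural_control")

rt_age_bands <- c(
  "under_20", "20_29", "30_39", "40_49", "50_59", "60_69", "70_plus",
  "declined"
)

rt_genders <- c("female", "male", "nonbinary_or_self_specified", "declined")

rt_work_contexts <- c(
  "patients_vulnerable", "children", "coworkers", "general_public",
  "from_home", "not_working"
)

rt_isolation_behaviours <- c(
  "food_medicine_healthcare", "outdoor_exercise", "other_shops_services",
  "mostly_home", "visit_family", "visit_friends"
)

rt_isolation_triggers <- c(
  "own_symptoms", "contact_with_sick", "government_restrictions", "never",
  "other"
)

rt_behaviours_would_stop <- c(rt_isolation_behaviours, "other")

# Ordinal 1-5 plus a special level meaning "I am never in public places";
# the special level is kept in the record but coded missing when the item is
# used as the behaviour measure (no exposure means the rating is undefined).
rt_distance_levels <- c(
  "almost_never", "rarely", "sometimes", "often", "almost_always",
  "never_in_public"
)

rt_handwash_situations <- c(
  "public_surfaces", "entering_building", "before_food", "after_contact",
  "after_sneeze_cough", "touching_face", "never_or_occasionally"
)

rt_handwash_thoroughness <- c(
  "soap_or_sanitiser", "twenty_seconds", "nails_and_fingers", "none_of_above"
)

# Multi-select (set-valued) response fields and their admissible options.
rt_set_fields <- list(
  work_contexts = rt_work_contexts,
  isolation_behaviours = rt_isolation_behaviours,
  isolation_triggers = rt_isolation_triggers,
  behaviours_would_stop = rt_behaviours_would_stop,
  handwash_situations = rt_handwash_situations,
  handwash_thoroughness = rt_handwash_thoroughness
)

rt_scalar_fields <- c(
  "respondent_id", "country", "age_band", "gender", "distance_frequency",
  "n_items_opted"
)

#' Code the distance-keeping item as the numeric behaviour measure
#'
#' Maps the ordinal distance-frequency answer to 1 ("almost never") through
#' 5 ("almost always"). The special answer `never_in_public` is coded `NA`:
#' a respondent who is never in public has no defined distance-keeping
#' frequency, so the value is excluded from determinant analysis rather than
#' treated as an extreme.
#'
#' @param x Character vector of distance-frequency answer codes.
#' @return Numeric vector in 1..5 with `NA` for `never_in_public` or missing.
#' @export
#' @examples
#' distance_to_numeric(c("almost_never", "almost_always", "never_in_public"))
distance_to_numeric <- function(x) {
  idx <- match(x, rt_distance_levels[1:5])
  as.numeric(idx)
}
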