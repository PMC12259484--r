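# Determinant item bank: every item measures one sub-determinant of one
# Reasoned Action Approach construct (attitude, perceived norm, perceived
# behavioural control) for one of the three target behaviours.

# Sub-determinant labels per construct. 9 + 7 + 7 = 23 per behaviour; with
# four phrasing variants each, 3 behaviours x 23 x 4 = 276 items.
rt_sub_determinants <- list(
  attitude = c(
    "expected_effectiveness", "expected_personal_risk",
    "expected_risk_to_others", "expected_effort", "expected_comfort",
    "affective_reassurance", "affective_frustration", "perceived_importance",
    "expected_social_cost"
  ),
  perceived_norm = c(
    "injunctive_family", "injunctive_friends", "injunctive_experts",
    "descriptive_household", "descriptive_friends", "descriptive_community",
    "motivation_to_comply"
  ),
  perceived_behavioural_control = c(
    "perceived_capability", "perceived_autonomy", "skills_knowledge",
    "environmental_constraints", "habit_automaticity",
    "resisting_social_pressure", "confidence_when_busy"
  )
)

rt_behaviour_phrases <- c(
  social_distancing = "keeping at least 1.5 metres from others in public",
  self_isolation = "staying at home as much as possible",
  hand_washing = "washing or sanitising my hands thoroughly and often"
)

abbrev_construct <- c(
  attitude = "att", perceived_norm = "pn",
  perceived_behavioural_control = "pbc"
)
abbrev_behaviour <- c(
  social_distancing = "dist", self_isolation = "iso", hand_washing = "hw"
)

#' Construct the packaged default determinant item bank
#'
#' Builds the 276-item bank used throughout the package: for each of the
#' three target behaviours, 23 sub-determinants (9 attitude, 7 perceived
#' norm, 7 perceived behavioural control) are each measured by four phrasing
#' variants on a 1-7 bipolar scale. Item texts are generated English
#' placeholders; the structure (counts, construct coverage, identifiers,
#' scales) is what downstream analysis depends on.
#'
#' @param scale_min,scale_max Integer response-scale bounds applied to every
#'   generated item (default 1-7, the usual bipolar convention for
#'   Reasoned-Action-Approach items).
#' @return An `item_bank`: a tibble with columns `item_id`, `behaviour`,
#'   `construct`, `sub_determinant`, `text`, `scale_min`, `scale_max` and a
#'   `version` attribute.
#' @export
#' @examples
#' bank <- default_item_bank()
#' nrow(bank) # 276
default_item_bank <- function(scale_min = 1L, scale_max = 7L) {
  rows <- list()
  for (beh in rt_behaviours) {
    for (con in rt_constructs) {
      for (sub in rt_sub_determinants[[con]]) {
        for (v in 1:4) {
          id <- paste(abbrev_behaviour[[beh]], abbrev_construct[[con]],
                      sub, v, sep = "_")
          txt <- sprintf(
            "Thinking about %s: rate your %s (%s), phrasing variant %d.",
            rt_behaviour_phrases[[beh]], gsub("_", " ", sub),
            gsub("_", " ", con), v
          )
          rows[[length(rows) + 1L]] <- tibble::tibble(
            item_id = id, behaviour = beh, construct = con,
            sub_determinant = sub, text = txt,
            scale_min = as.integer(scale_min),
            scale_max = as.integer(scale_max)
          )
        }
      }
    }
  }
  bank <- do.call(rbind, rows)
  new_item_bank(bank, version = "default-1")
}

new_item_bank <- function(items, version) {
  validate_item_bank(items)
  structure(items, class = c("item_bank", class(tibble::tibble())),
            version = version)
}

validate_item_bank <- function(items) {
  required <- c("item_id", "behaviour", "construct", "sub_determinant",
                "text", "scale_min", "scale_max")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("item bank is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(items) == 0) {
    abort("bank must contain at least one item")
  }
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate item_id in bank: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad_beh <- setdiff(unique(items$behaviour), rt_behaviours)
  if (length(bad_beh) > 0) {
    abort(paste0("unknown behaviour: ", paste(bad_beh, collapse = ", ")))
  }
  bad_con <- setdiff(unique(items$construct), rt_constructs)
  if (length(bad_con) > 0) {
    abort(paste0("unknown construct: ", paste(bad_con, collapse = ", ")))
  }
  bad_scale <- items$item_id[items$scale_min >= items$scale_max]
  if (length(bad_scale) > 0) {
    abort(paste0("scale_min must be < scale_max for item(s): ",
                 paste(bad_scale, collapse = ", ")))
  }
  invisible(items)
}

#' Read a determinant item bank from JSON
#'
#' The on-disk format is a JSON object `{version, items: [...]}` where each
#' item carries `item_id`, `behaviour`, `construct`, `sub_determinant`,
#' `text`, `scale_min`, `scale_max`. Duplicate identifiers, unknown
#' behaviours/constructs and inverted scale bounds are rejected with an error
#' naming the offending item.
#'
#' @param path Path to the JSON file.
#' @return A validated `item_bank`.
#' @seealso [write_item_bank()], [default_item_bank()]
#' @export
load_item_bank <- function(path) {
  if (!file.exists(path)) abort(paste0("item bank file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(raw$items) || (is.data.frame(raw$items) && nrow(raw$items) == 0) ||
      (!is.data.frame(raw$items) && length(raw$items) == 0)) {
    abort("bank must contain at least one item")
  }
  items <- tibble::as_tibble(raw$items)
  items$scale_min <- as.integer(items$scale_min)
  items$scale_max <- as.integer(items$scale_max)
  new_item_bank(items, version = raw$version %||% "unversioned")
}

#' Write an item bank to JSON
#'
#' @param bank An `item_bank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  validate_item_bank(bank)
  out <- list(
    version = attr(bank, "version") %||% "unversioned",
    items = as.data.frame(bank)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
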