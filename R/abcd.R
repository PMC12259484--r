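# ABCD message table and the tailoring rule engine. An acyclic behaviour
# change diagram row links a behaviour change principle (BCP), via its
# conditions for effectiveness and a concrete application (the message text),
# to the sub-determinant and (sub-)behaviour it is assumed to influence.

abcd_columns <- c(
  "behaviour", "sub_behaviour", "determinant", "sub_determinant", "bcp",
  "conditions_for_effectiveness", "application", "locale"
)

#' Read an ABCD message table from TSV
#'
#' The table is tab-separated with the columns `behaviour`, `sub_behaviour`,
#' `determinant`, `sub_determinant`, `bcp`, `conditions_for_effectiveness`,
#' `application`, `locale`, in that order. Row order is preserved: it is the
#' stable tie-break order used by [select_messages()]. Entries must name a
#' non-empty application and be unique on
#' (behaviour, sub_determinant, application, locale).
#'
#' @param path TSV path.
#' @return An `abcd_table` tibble with an `abcd_row` provenance column.
#' @export
load_abcd <- function(path) {
  if (!file.exists(path)) abort(paste0("ABCD table not found: ", path))
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
  if (nrow(raw) == 0) abort("ABCD table is empty")
  missing_cols <- setdiff(abcd_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("ABCD table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_abcd(tibble::as_tibble(raw[abcd_columns]))
}

validate_abcd <- function(entries) {
  bad_beh <- setdiff(unique(entries$behaviour), rt_behaviours)
  if (length(bad_beh) > 0) {
    abort(paste0("ABCD entry with unknown behaviour: ",
                 paste(bad_beh, collapse = ", ")))
  }
  bad_det <- setdiff(unique(entries$determinant), rt_constructs)
  if (length(bad_det) > 0) {
    abort(paste0("ABCD entry with unknown determinant: ",
                 paste(bad_det, collapse = ", ")))
  }
  if (any(!nzchar(entries$application))) {
    abort("every ABCD entry must name a non-empty application")
  }
  key <- paste(entries$behaviour, entries$sub_determinant,
               entries$application, entries$locale, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate ABCD entry (behaviour, sub_determinant, application, locale)")
  }
  entries$abcd_row <- seq_len(nrow(entries))
  structure(entries, class = c("abcd_table", class(tibble::tibble())))
}

#' @rdname load_abcd
#' @param entries An `abcd_table`.
#' @return `write_abcd()` returns `path`, invisibly.
#' @export
write_abcd <- function(entries, path) {
  out <- as.data.frame(entries)[abcd_columns]
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged English ABCD message fixture
#'
#' A small English-language message table covering all three behaviours,
#' shipped in `inst/extdata/abcd_messages_en.tsv`.
#'
#' @return An `abcd_table`.
#' @export
default_abcd <- function() {
  load_abcd(system.file("extdata", "abcd_messages_en.tsv",
                        package = "risktailor", mustWork = TRUE))
}

#' Default reinforcement message set
#'
#' Shown when no tailoring rule fires, i.e. the respondent reports fully
#' protective behaviour on all three fronts: one positive-reinforcement
#' message per behaviour, encouraging maintenance rather than change.
#'
#' @param locale Language tag of the messages (only `"en"` ships).
#' @return An `abcd_table` of three entries.
#' @export
default_reinforcement_messages <- function(locale = "en") {
  validate_abcd(tibble::tibble(
    behaviour = rt_behaviours,
    sub_behaviour = "maintaining_current_behaviour",
    determinant = "attitude",
    sub_determinant = "perceived_importance",
    bcp = "positive reinforcement",
    conditions_for_effectiveness = "reinforcement follows the behaviour and is valued",
    application = c(
      "You are doing a great job keeping your distance from others - keep it up!",
      "You are doing a great job limiting your trips outside your home - keep it up!",
      "You are doing a great job washing your hands often and thoroughly - keep it up!"
    ),
    locale = locale
  ))
}

# ---- Tailoring rules -------------------------------------------------------

rt_rule_ops <- c("contains", "not_contains", "eq", "ne", "le", "ge", "lt",
                 "gt")

#' Load tailoring rules from JSON
#'
#' Rules are declarative: a JSON list of
#' `{rule_id, behaviour, trigger: {field, op, value}, priority}`. The trigger
#' predicate references one respondent field; set-valued fields support
#' `contains` / `not_contains`, scalar fields support the comparison
#' operators, and comparisons on `distance_frequency` are ordinal over its
#' five frequency levels (`never_in_public` never satisfies an ordinal
#' comparison, since no exposure means no defined frequency).
#'
#' @param path JSON path.
#' @return A `tailoring_rules` tibble.
#' @export
load_tailoring_rules <- function(path) {
  if (!file.exists(path)) abort(paste0("rules file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rules <- tibble::tibble(
    rule_id = raw$rule_id,
    behaviour = raw$behaviour,
    field = raw$trigger$field,
    op = raw$trigger$op,
    value = as.character(raw$trigger$value),
    priority = as.integer(raw$priority)
  )
  validate_rules(rules)
}

validate_rules <- function(rules) {
  needed <- c("rule_id", "behaviour", "field", "op", "value", "priority")
  missing_cols <- setdiff(needed, names(rules))
  if (length(missing_cols) > 0) {
    abort(paste0("rules missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(rules$rule_id)) abort("rule_id must be unique")
  bad_beh <- setdiff(unique(rules$behaviour), rt_behaviours)
  if (length(bad_beh) > 0) {
    abort(paste0("rule with unknown behaviour: ",
                 paste(bad_beh, collapse = ", ")))
  }
  known_fields <- c(rt_scalar_fields, names(rt_set_fields))
  bad_field <- setdiff(unique(rules$field), known_fields)
  if (length(bad_field) > 0) {
    abort(paste0("rule references unknown respondent field: ",
                 paste(bad_field, collapse = ", ")))
  }
  bad_op <- setdiff(unique(rules$op), rt_rule_ops)
  if (length(bad_op) > 0) {
    abort(paste0("unknown rule operator: ", paste(bad_op, collapse = ", ")))
  }
  structure(rules, class = c("tailoring_rules", class(tibble::tibble())))
}

#' Packaged default tailoring rules
#'
#' Loads the rule set shipped in `inst/extdata/tailoring_rules.json`:
#' risk-conferring answers (infrequent distance keeping, visits to friends
#' and family, not mostly staying home, poor hand hygiene) trigger messages
#' for the corresponding behaviour.
#'
#' @return A `tailoring_rules` tibble.
#' @export
default_tailoring_rules <- function() {
  load_tailoring_rules(system.file("extdata", "tailoring_rules.json",
                                   package = "risktailor", mustWork = TRUE))
}

# Evaluate one rule's trigger against one respondent row. Returns TRUE/FALSE.
rule_fires <- function(rule, record) {
  field <- rule$field
  op <- rule$op
  value <- rule$value
  if (field %in% names(rt_set_fields)) {
    answers <- record[[field]][[1]]
    if (op == "contains") return(value %in% answers)
    if (op == "not_contains") return(!(value %in% answers))
    abort(paste0("operator '", op, "' not defined for set field ", field))
  }
  x <- record[[field]][[1]]
  if (field == "distance_frequency") {
    x <- distance_to_numeric(x)
    v <- distance_to_numeric(value)
    if (op %in% c("eq", "ne")) {
      x <- record[[field]][[1]]
      v <- value
    } else if (is.na(x) || is.na(v)) {
      return(FALSE)
    }
  } else {
    v <- value
    if (field == "n_items_opted") {
      x <- as.numeric(x)
      v <- as.numeric(v)
    }
  }
  switch(op,
    eq = identical(as.character(x), as.character(v)),
    ne = !identical(as.character(x), as.character(v)),
    le = x <= v, ge = x >= v, lt = x < v, gt = x > v,
    abort(paste0("operator '", op, "' not defined for scalar field ", field))
  )
}

# Behaviour -> risk factor driving its priority (D11-style ordering).
behaviour_factor <- c(
  social_distancing = "exposure_risk",
  self_isolation = "exposure_risk",
  hand_washing = "hygiene_risk"
)

# Fixed tie-break order between behaviours with equal factor risk.
behaviour_tie_order <- c(self_isolation = 1, social_distancing = 2,
                         hand_washing = 3)

#' Select tailored messages for one respondent
#'
#' Implements the tailoring contract: a behaviour's messages are eligible
#' only if at least one of its rules fires on the respondent's answers.
#' Eligible ABCD entries are ordered by the risk score of the factor behind
#' their behaviour (highest first; ties broken in the fixed order
#' self-isolation, distance keeping, hand washing), then by the priority of
#' the strongest fired rule, then by stable ABCD row order, and truncated to
#' `max_messages`. A respondent for whom no rule fires receives the
#' reinforcement set instead. Every returned message carries provenance: the
#' ABCD row and the rule that made it eligible.
#'
#' @param response One respondent (a one-row cohort tibble).
#' @param risk The respondent's [score_risk()] row.
#' @param abcd An `abcd_table` of candidate messages.
#' @param rules A `tailoring_rules` tibble.
#' @param max_messages Maximum number of messages returned (default 6, two
#'   per behaviour).
#' @param reinforcement `abcd_table` used when no rule fires.
#' @return A tibble of selected entries with columns `application`,
#'   `behaviour`, `sub_determinant`, `bcp`, `abcd_row`, `rule_id`,
#'   `rule_priority` and `factor_score` (`rule_id` is `NA` for the
#'   reinforcement set).
#' @export
select_messages <- function(response, risk, abcd,
                            rules = default_tailoring_rules(),
                            max_messages = 6,
                            reinforcement = default_reinforcement_messages()) {
  if (max_messages < 1) abort("max_messages must be at least 1")
  stopifnot(nrow(response) == 1, nrow(risk) == 1)
  missing_beh <- setdiff(rt_behaviours, unique(abcd$behaviour))
  if (length(missing_beh) > 0) {
    abort(paste0("ABCD table lacks entries for behaviour(s): ",
                 paste(missing_beh, collapse = ", ")))
  }
  fired <- vapply(seq_len(nrow(rules)), function(j) {
    rule_fires(rules[j, ], response)
  }, logical(1))
  provenance_cols <- c("behaviour", "sub_behaviour", "determinant",
                       "sub_determinant", "bcp", "application", "locale",
                       "abcd_row")
  if (!any(fired)) {
    out <- reinforcement[provenance_cols]
    out$rule_id <- NA_character_
    out$rule_priority <- NA_integer_
    out$factor_score <- unlist(risk[behaviour_factor[out$behaviour]],
                               use.names = FALSE)
    out$reinforcement <- TRUE
    return(utils::head(out, max_messages))
  }
  fired_rules <- rules[fired, ]
  # strongest fired rule per behaviour
  best <- lapply(split(fired_rules, fired_rules$behaviour), function(g) {
    g[order(-g$priority, g$rule_id), ][1, ]
  })
  eligible <- abcd[abcd$behaviour %in% names(best), ]
  if (nrow(eligible) == 0) {
    abort("no ABCD entry available for the behaviours whose rules fired")
  }
  eligible$rule_id <- vapply(eligible$behaviour,
                             function(b) best[[b]]$rule_id, character(1))
  eligible$rule_priority <- vapply(eligible$behaviour,
                                   function(b) best[[b]]$priority,
                                   integer(1))
  eligible$factor_score <- vapply(eligible$behaviour, function(b) {
    risk[[behaviour_factor[[b]]]][1]
  }, numeric(1))
  ord <- order(-eligible$factor_score,
               behaviour_tie_order[eligible$behaviour],
               -eligible$rule_priority,
               eligible$abcd_row)
  out <- eligible[ord, c(provenance_cols, "rule_id", "rule_priority",
                         "factor_score")]
  out$reinforcement <- FALSE
  utils::head(out, max_messages)
}
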