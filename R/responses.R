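# Respondent records. A cohort is a tibble with one row per respondent;
# multi-select questions are list-columns of answer-code character vectors and
# the sparse determinant answers are a list-column of named integer vectors
# (names are item_ids, kept in bank order so serialisation is stable).

#' Validate a cohort of respondent records
#'
#' Checks every field against the questionnaire's closed answer domains and
#' every determinant score against its item's scale, and enforces the opt-in
#' contract: the number of answered determinant items never exceeds
#' `n_items_opted`, which must be an even number in 0..20.
#'
#' @param responses A cohort tibble (see [read_responses()] for the schema).
#' @param bank The `item_bank` the determinant answers refer to.
#' @return `responses`, invisibly, if valid; otherwise an error naming the
#'   first offending row and field.
#' @export
validate_responses <- function(responses, bank) {
  validate_item_bank(bank)
  required <- c(rt_scalar_fields, names(rt_set_fields), "determinant_scores")
  missing_cols <- setdiff(required, names(responses))
  if (length(missing_cols) > 0) {
    abort(paste0("responses missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(responses$respondent_id)) {
    abort("respondent_id must be unique")
  }
  check_enum <- function(values, domain, field) {
    bad <- which(!is.na(values) & !(values %in% domain))
    if (length(bad) > 0) {
      abort(sprintf("row %d: invalid %s '%s'", bad[1], field, values[bad[1]]))
    }
  }
  check_enum(responses$age_band, rt_age_bands, "age_band")
  check_enum(responses$gender, rt_genders, "gender")
  check_enum(responses$distance_frequency, rt_distance_levels,
             "distance_frequency")
  for (field in names(rt_set_fields)) {
    domain <- rt_set_fields[[field]]
    for (i in seq_len(nrow(responses))) {
      vals <- responses[[field]][[i]]
      bad <- setdiff(vals, domain)
      if (length(bad) > 0) {
        abort(sprintf("row %d: invalid %s '%s'", i, field, bad[1]))
      }
    }
  }
  n_opt <- responses$n_items_opted
  bad_opt <- which(is.na(n_opt) | n_opt < 0 | n_opt > 20 | n_opt %% 2 != 0)
  if (length(bad_opt) > 0) {
    abort(sprintf("row %d: n_items_opted must be even in [0,20], got %s",
                  bad_opt[1], n_opt[bad_opt[1]]))
  }
  scale_min <- stats::setNames(bank$scale_min, bank$item_id)
  scale_max <- stats::setNames(bank$scale_max, bank$item_id)
  for (i in seq_len(nrow(responses))) {
    sc <- responses$determinant_scores[[i]]
    if (length(sc) == 0) next
    unknown <- setdiff(names(sc), bank$item_id)
    if (length(unknown) > 0) {
      abort(sprintf("row %d: score for unknown item '%s'", i, unknown[1]))
    }
    if (length(sc) > responses$n_items_opted[i]) {
      abort(sprintf(
        "row %d: %d determinant scores exceed n_items_opted = %d",
        i, length(sc), responses$n_items_opted[i]
      ))
    }
    out_of_range <- names(sc)[sc < scale_min[names(sc)] |
                              sc > scale_max[names(sc)]]
    if (length(out_of_range) > 0) {
      abort(sprintf("row %d: score for item '%s' outside its scale",
                    i, out_of_range[1]))
    }
  }
  invisible(responses)
}

set_to_cell <- function(x) paste(x, collapse = ";")
cell_to_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Write a cohort to CSV
#'
#' Serialises a cohort as comma-separated UTF-8 with a header row.
#' Multi-select answers are joined with `";"`; determinant answers become one
#' wide column per item (in bank order), with an empty cell meaning "not
#' presented / not answered". Only items answered by at least one respondent
#' get a column, so files stay compact under planned missingness.
#'
#' @param responses A validated cohort tibble.
#' @param path Output path.
#' @param bank The item bank (fixes the column order of determinant items).
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, bank) {
  validate_responses(responses, bank)
  answered <- unique(unlist(lapply(responses$determinant_scores, names)))
  item_cols <- bank$item_id[bank$item_id %in% answered]
  out <- data.frame(
    respondent_id = responses$respondent_id,
    country = responses$country,
    age_band = responses$age_band,
    gender = responses$gender,
    stringsAsFactors = FALSE
  )
  for (field in names(rt_set_fields)) {
    out[[field]] <- vapply(responses[[field]], set_to_cell, character(1))
  }
  out$distance_frequency <- responses$distance_frequency
  out$n_items_opted <- responses$n_items_opted
  for (id in item_cols) {
    out[[id]] <- vapply(responses$determinant_scores, function(sc) {
      if (id %in% names(sc)) as.character(sc[[id]]) else ""
    }, character(1))
  }
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_responses()]: parses the documented CSV dialect
#' (comma-separated, UTF-8, header row, `";"`-joined multi-select cells, wide
#' determinant-score columns named by item id, empty cell = not answered) and
#' validates every record against the bank. Columns that are neither part of
#' the questionnaire schema nor item ids in the bank are an error, as are
#' scores outside their item's scale.
#'
#' @param path CSV path.
#' @param bank The `item_bank` to validate determinant columns against.
#' @return A validated cohort tibble.
#' @export
read_responses <- function(path, bank) {
  validate_item_bank(bank)
  if (!file.exists(path)) abort(paste0("responses file not found: ", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  schema_cols <- c(rt_scalar_fields, names(rt_set_fields))
  missing_cols <- setdiff(schema_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("responses CSV missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), schema_cols)
  unknown <- setdiff(extra, bank$item_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown column(s) in responses CSV: ",
                 paste(unknown, collapse = ", ")))
  }
  item_cols <- bank$item_id[bank$item_id %in% extra]
  n <- nrow(raw)
  n_opt_num <- suppressWarnings(as.numeric(raw$n_items_opted))
  bad_opt <- which(is.na(n_opt_num) | n_opt_num %% 1 != 0 |
                   n_opt_num < 0 | n_opt_num > 20 | n_opt_num %% 2 != 0)
  if (length(bad_opt) > 0) {
    abort(sprintf("row %d: n_items_opted must be even in [0,20], got '%s'",
                  bad_opt[1], raw$n_items_opted[bad_opt[1]]))
  }
  scores <- vector("list", n)
  if (length(item_cols) > 0) {
    score_mat <- vapply(item_cols, function(id) {
      cell <- raw[[id]]
      val <- suppressWarnings(as.integer(cell))
      bad <- which(nzchar(cell) & is.na(val))
      if (length(bad) > 0) {
        abort(sprintf("row %d: non-integer score '%s' for item '%s'",
                      bad[1], cell[bad[1]], id))
      }
      ifelse(nzchar(cell), val, NA_integer_)
    }, integer(n))
    score_mat <- matrix(score_mat, nrow = n,
                        dimnames = list(NULL, item_cols))
    for (i in seq_len(n)) {
      row_scores <- score_mat[i, ]
      row_scores <- row_scores[!is.na(row_scores)]
      scores[[i]] <- row_scores
    }
  } else {
    scores <- replicate(n, stats::setNames(integer(0), character(0)),
                        simplify = FALSE)
  }
  responses <- tibble::tibble(
    respondent_id = raw$respondent_id,
    country = raw$country,
    age_band = raw$age_band,
    gender = raw$gender,
    work_contexts = lapply(raw$work_contexts, cell_to_set),
    isolation_behaviours = lapply(raw$isolation_behaviours, cell_to_set),
    isolation_triggers = lapply(raw$isolation_triggers, cell_to_set),
    behaviours_would_stop = lapply(raw$behaviours_would_stop, cell_to_set),
    distance_frequency = raw$distance_frequency,
    handwash_situations = lapply(raw$handwash_situations, cell_to_set),
    handwash_thoroughness = lapply(raw$handwash_thoroughness, cell_to_set),
    n_items_opted = as.integer(n_opt_num),
    determinant_scores = scores
  )
  validate_responses(responses, bank)
  responses
}

#' Usage-funnel counts
#'
#' Container for the tool-usage funnel: everyone who opened the tool is
#' either a first-page-only visitor, started the assessment without
#' completing it, or completed it; the three must sum to the total.
#'
#' @param total_opened,opened_first_page_only,started_not_completed,completed
#'   Non-negative counts.
#' @return A `funnel_counts` list.
#' @export
#' @examples
#' funnel_counts(102909, 27424, 11635, 63850)
funnel_counts <- function(total_opened, opened_first_page_only,
                          started_not_completed, completed) {
  counts <- list(
    total_opened = total_opened,
    opened_first_page_only = opened_first_page_only,
    started_not_completed = started_not_completed,
    completed = completed
  )
  if (any(vapply(counts, function(x) x < 0, logical(1)))) {
    abort("funnel counts must be non-negative")
  }
  if (total_opened != opened_first_page_only + started_not_completed +
      completed) {
    abort("funnel counts must satisfy total = first_page_only + started_not_completed + completed")
  }
  structure(counts, class = "funnel_counts")
}

#' Drop-out percentage of the usage funnel
#'
#' The drop-out rate is computed among people who went past the first page:
#' `100 * started_not_completed / (total_opened - opened_first_page_only)`.
#' First-page-only visitors never engaged with the assessment and are
#' excluded from the denominator.
#'
#' @param counts A [funnel_counts()] object.
#' @return Drop-out percentage in `[0, 100]`.
#' @export
#' @examples
#' funnel_stats(funnel_counts(102909, 27424, 11635, 63850)) # ~15.4
funnel_stats <- function(counts) {
  stopifnot(inherits(counts, "funnel_counts"))
  denom <- counts$total_opened - counts$opened_first_page_only
  if (denom == 0) {
    abort("drop-out undefined: nobody went past the first page")
  }
  100 * counts$started_not_completed / denom
}

#' Read or write funnel counts as JSON
#'
#' @param path JSON path.
#' @return `load_funnel_counts()` returns a `funnel_counts` object;
#'   `write_funnel_counts()` returns `path` invisibly.
#' @export
load_funnel_counts <- function(path) {
  raw <- jsonlite::fromJSON(path)
  funnel_counts(raw$total_opened, raw$opened_first_page_only,
                raw$started_not_completed, raw$completed)
}

#' @rdname load_funnel_counts
#' @param counts A `funnel_counts` object.
#' @export
write_funnel_counts <- function(counts, path) {
  stopifnot(inherits(counts, "funnel_counts"))
  jsonlite::write_json(unclass(counts), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
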