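# Independent oracle implementations used to cross-check the package. These
# are written directly from the statistical definitions and deliberately
# share no code with the implementation under test.

# Pearson r from first principles (no stats::cor).
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  dx <- x - mx
  dy <- y - my
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Linear-interpolation quantile between order statistics (type-7 convention),
# written out by hand.
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Potential for Change indices straight from their verbal definitions.
oracle_pdelta1 <- function(scores, behaviour) {
  r <- oracle_pearson(scores, behaviour)
  if (is.na(r)) return(NA_real_)
  m <- sum(scores) / length(scores)
  if (r > 0) (sort(scores)[length(scores)] - m) * r
  else if (r < 0) (sort(scores)[1] - m) * r
  else 0
}

oracle_pdelta2 <- function(scores, behaviour, upper_q = 0.95,
                           lower_q = 0.05) {
  r <- oracle_pearson(scores, behaviour)
  if (is.na(r)) return(NA_real_)
  m <- sum(scores) / length(scores)
  if (r > 0) (oracle_quantile(scores, upper_q) - m) * r * r
  else if (r < 0) (oracle_quantile(scores, lower_q) - m) * r * r
  else 0
}

# Fisher-z interval written out by hand (used against correlation_ci).
oracle_fisher_ci <- function(r, n, level = 0.95) {
  z <- 0.5 * log((1 + r) / (1 - r))
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(low = (exp(2 * (z - half)) - 1) / (exp(2 * (z - half)) + 1),
    high = (exp(2 * (z + half)) - 1) / (exp(2 * (z + half)) + 1))
}

# Independent tailoring-rule evaluator: tests every rule against a record
# using the documented predicate semantics, then rebuilds the expected
# selection from the documented ordering contract.
oracle_rule_fires <- function(rule, record) {
  set_fields <- c("work_contexts", "isolation_behaviours",
                  "isolation_triggers", "behaviours_would_stop",
                  "handwash_situations", "handwash_thoroughness")
  value <- rule$value
  if (rule$field %in% set_fields) {
    members <- record[[rule$field]][[1]]
    return(switch(rule$op,
                  contains = value %in% members,
                  not_contains = !(value %in% members)))
  }
  x <- record[[rule$field]][[1]]
  if (rule$op == "eq") return(x == value)
  if (rule$op == "ne") return(x != value)
  if (rule$field == "distance_frequency") {
    ord <- c(almost_never = 1, rarely = 2, sometimes = 3, often = 4,
             almost_always = 5)
    xi <- ord[x]; vi <- ord[value]
    if (is.na(xi) || is.na(vi)) return(FALSE)
    x <- xi; value <- vi
  } else if (rule$field == "n_items_opted") {
    x <- as.numeric(x); value <- as.numeric(value)
  }
  switch(rule$op, le = x <= value, ge = x >= value, lt = x < value,
         gt = x > value)
}

oracle_select <- function(record, risk, abcd, rules, max_messages = 6) {
  fired <- vapply(seq_len(nrow(rules)),
                  function(j) oracle_rule_fires(rules[j, ], record),
                  logical(1))
  if (!any(fired)) return(NULL) # reinforcement case, checked separately
  fr <- rules[fired, ]
  factor_of <- c(social_distancing = "exposure_risk",
                 self_isolation = "exposure_risk",
                 hand_washing = "hygiene_risk")
  tie <- c(self_isolation = 1, social_distancing = 2, hand_washing = 3)
  behs <- unique(fr$behaviour)
  best_priority <- vapply(behs, function(b) max(fr$priority[fr$behaviour == b]),
                          numeric(1))
  cand <- abcd[abcd$behaviour %in% behs, ]
  fs <- vapply(cand$behaviour, function(b) risk[[factor_of[[b]]]][1],
               numeric(1))
  pr <- best_priority[cand$behaviour]
  ord <- order(-fs, tie[cand$behaviour], -pr, cand$abcd_row)
  head(cand$abcd_row[ord], max_messages)
}

# Small handmade fixtures -----------------------------------------------

tiny_bank <- function(n_items = 4, scale_min = 1, scale_max = 7) {
  risktailor:::new_item_bank(tibble::tibble(
    item_id = paste0("it", seq_len(n_items)),
    behaviour = rep("social_distancing", n_items),
    construct = rep("attitude", n_items),
    sub_determinant = paste0("facet_", seq_len(n_items)),
    text = paste0("placeholder item ", seq_len(n_items)),
    scale_min = as.integer(scale_min),
    scale_max = as.integer(scale_max)
  ), version = "test")
}

# A single handmade respondent; override any field with ...
make_record <- function(...) {
  rec <- tibble::tibble(
    respondent_id = "p1",
    country = "NL",
    age_band = "30_39",
    gender = "female",
    work_contexts = list("from_home"),
    isolation_behaviours = list("mostly_home"),
    isolation_triggers = list(c("own_symptoms", "contact_with_sick")),
    behaviours_would_stop = list(character(0)),
    distance_frequency = "almost_always",
    handwash_situations = list(c("public_surfaces", "entering_building",
                                 "before_food", "after_contact",
                                 "after_sneeze_cough", "touching_face")),
    handwash_thoroughness = list(c("soap_or_sanitiser", "twenty_seconds",
                                   "nails_and_fingers")),
    n_items_opted = 0L,
    determinant_scores = list(stats::setNames(integer(0), character(0)))
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    value <- overrides[[nm]]
    if (is.list(rec[[nm]])) rec[[nm]] <- list(value) else rec[[nm]] <- value
  }
  rec
}

random_cohort <- function(n, bank, seed) {
  cfg <- simulation_config(
    n_respondents = n, seed = seed,
    dropout = c(first_page_only = 0, started_not_completed = 0,
                completed = 1)
  )
  simulate_cohort(cfg, bank)$responses
}
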