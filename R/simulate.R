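# Synthetic respondent generator. A latent Gaussian (copula-style) model
# realises the statistical structure the determinant analysis assumes:
# each respondent has a latent behaviour tendency; each determinant item is a
# latent normal correlated with it at the planted level, discretised to the
# item's ordinal scale; respondents answer a uniformly random subset of items
# of their opted-in size, so missingness is ignorable by construction.

# Default answer prevalences for the multi-select questions. These mirror
# the response structure reported for the field deployment and are the fixed
# study conditions of the simulator.
rt_default_prevalences <- list(
  work_contexts = c(
    patients_vulnerable = 0.067, children = 0.061, coworkers = 0.20,
    general_public = 0.282, from_home = 0.40, not_working = 0.25
  ),
  isolation_behaviours = c(
    food_medicine_healthcare = 0.758, outdoor_exercise = 0.701,
    other_shops_services = 0.522, mostly_home = 0.451, visit_family = 0.359,
    visit_friends = 0.271
  ),
  isolation_triggers = c(
    own_symptoms = 0.854, contact_with_sick = 0.733,
    government_restrictions = 0.658, never = 0.044, other = 0.004
  ),
  behaviours_would_stop = c(
    other_shops_services = 0.434, food_medicine_healthcare = 0.406,
    outdoor_exercise = 0.346, visit_family = 0.319, visit_friends = 0.25,
    mostly_home = 0, other = 0.032
  ),
  handwash_situations = c(
    public_surfaces = 0.834, entering_building = 0.774, before_food = 0.766,
    after_contact = 0.652, after_sneeze_cough = 0.41, touching_face = 0.289,
    never_or_occasionally = 0.039
  ),
  handwash_thoroughness = c(
    soap_or_sanitiser = 0.911, twenty_seconds = 0.698,
    nails_and_fingers = 0.47, none_of_above = 0.012
  )
)

rt_default_age_probs <- c(
  under_20 = 0.045, `20_29` = 0.176, `30_39` = 0.195, `40_49` = 0.201,
  `50_59` = 0.194, `60_69` = 0.143, `70_plus` = 0.045, declined = 0.001
)

rt_default_gender_probs <- c(
  female = 0.541, male = 0.452, nonbinary_or_self_specified = 0.0031,
  declined = 0.0039
)

# Distance-keeping marginal: five ordinal frequencies plus "never in public".
rt_default_behaviour_marginal <- c(
  almost_never = 0.009, rarely = 0.019, sometimes = 0.087, often = 0.236,
  almost_always = 0.615, never_in_public = 0.034
)

# Opt-in distribution over 0, 2, ..., 20 determinant items: a large
# no-thanks group, a long middle, and a motivated tail answering all 20.
rt_default_opt_in <- c(
  `0` = 0.35, `2` = 0.10, `4` = 0.08, `6` = 0.07, `8` = 0.06, `10` = 0.08,
  `12` = 0.05, `14` = 0.04, `16` = 0.04, `18` = 0.03, `20` = 0.10
)

# Funnel state probabilities (first-page-only / started-not-completed /
# completed), matching the deployment's observed proportions.
rt_default_dropout <- c(
  first_page_only = 27424 / 102909,
  started_not_completed = 11635 / 102909,
  completed = 63850 / 102909
)

rt_default_countries <- c(
  NL = 0.36, NZ = 0.23, BE = 0.11, GB = 0.11, RO = 0.10, US = 0.05,
  IT = 0.04
)

#' Build a simulation configuration
#'
#' Defaults emulate the response structure of the field deployment: the
#' distance-keeping marginal, multi-select answer prevalences, demographic
#' margins and funnel proportions follow the reported percentages; the
#' opt-in distribution and item latents are the package's documented
#' defaults. Planted correlations are specified per item on the latent
#' scale; unlisted items default to 0.
#'
#' @param n_respondents Number of individuals who open the tool (each is
#'   assigned a funnel state; only completers yield response records).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param planted_r Named numeric vector, item_id -> latent correlation in
#'   (-1, 1) with the behaviour tendency.
#' @param item_mean_sd Named list, item_id -> `c(mean, sd)` of the latent
#'   item score on the raw scale before discretisation. Items not listed use
#'   mean at 70% of the scale range (the usual positive skew of endorsement
#'   items) and sd 1.2.
#' @param behaviour_marginal Probabilities over the five distance levels
#'   plus `never_in_public`; must sum to 1.
#' @param opt_in_distribution Probabilities over 0, 2, ..., 20; must sum
#'   to 1.
#' @param answer_prevalences Per-option endorsement probabilities for the
#'   multi-select questions.
#' @param dropout Probabilities over the three funnel states; must sum to 1.
#' @param age_probs,gender_probs,country_probs Demographic margins.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_respondents = 1000, seed = 1,
                              planted_r = numeric(0),
                              item_mean_sd = list(),
                              behaviour_marginal = rt_default_behaviour_marginal,
                              opt_in_distribution = rt_default_opt_in,
                              answer_prevalences = rt_default_prevalences,
                              dropout = rt_default_dropout,
                              age_probs = rt_default_age_probs,
                              gender_probs = rt_default_gender_probs,
                              country_probs = rt_default_countries) {
  cfg <- list(
    n_respondents = as.integer(n_respondents), seed = as.integer(seed),
    planted_r = planted_r, item_mean_sd = item_mean_sd,
    behaviour_marginal = behaviour_marginal,
    opt_in_distribution = opt_in_distribution,
    answer_prevalences = answer_prevalences, dropout = dropout,
    age_probs = age_probs, gender_probs = gender_probs,
    country_probs = country_probs
  )
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0(what, " must be non-negative and sum to 1"))
    }
  }
  check_probs(cfg$behaviour_marginal, "behaviour_marginal")
  check_probs(cfg$opt_in_distribution, "opt_in_distribution")
  check_probs(cfg$dropout, "dropout")
  check_probs(cfg$age_probs, "age_probs")
  check_probs(cfg$gender_probs, "gender_probs")
  check_probs(cfg$country_probs, "country_probs")
  if (length(cfg$planted_r) > 0 && any(abs(cfg$planted_r) >= 1)) {
    abort("planted_r must lie strictly inside (-1, 1)")
  }
  if (length(cfg$behaviour_marginal) != 6) {
    abort("behaviour_marginal needs 6 probabilities (5 levels + never_in_public)")
  }
  if (!identical(names(cfg$opt_in_distribution),
                 as.character(seq(0, 20, by = 2)))) {
    abort("opt_in_distribution must be named '0','2',...,'20'")
  }
  if (cfg$n_respondents < 0) abort("n_respondents must be non-negative")
  structure(cfg, class = "simulation_config")
}

#' Read or write a simulation configuration as JSON
#'
#' @param path JSON path.
#' @export
load_simulation_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$planted_r <- unlist(raw$planted_r) %||% numeric(0)
  raw$item_mean_sd <- lapply(raw$item_mean_sd %||% list(), unlist)
  for (f in c("behaviour_marginal", "opt_in_distribution", "dropout",
              "age_probs", "gender_probs", "country_probs",
              "answer_prevalences")) {
    if (!is.null(raw[[f]])) {
      raw[[f]] <- if (f == "answer_prevalences") {
        lapply(raw[[f]], unlist)
      } else {
        unlist(raw[[f]])
      }
    }
  }
  defaults <- simulation_config()
  cfg <- modifyList(unclass(defaults), raw[!vapply(raw, is.null, logical(1))])
  validate_simulation_config(cfg)
}

#' @rdname load_simulation_config
#' @param config A `simulation_config`.
#' @export
config_to_json_list <- function(config) {
  out <- unclass(config)
  # named vectors must become JSON objects, not arrays
  for (f in names(out)) {
    if (is.numeric(out[[f]]) && !is.null(names(out[[f]]))) {
      out[[f]] <- as.list(out[[f]])
    }
  }
  out$answer_prevalences <- lapply(out$answer_prevalences, as.list)
  out$item_mean_sd <- lapply(out$item_mean_sd, as.list)
  out
}

write_simulation_config <- function(config, path) {
  jsonlite::write_json(config_to_json_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

draw_set <- function(domain, prevalence) {
  p <- prevalence[domain]
  p[is.na(p)] <- 0
  domain[stats::runif(length(domain)) < p]
}

#' Simulate a respondent cohort with known structure
#'
#' Each of `n_respondents` tool openers is assigned a funnel state; each
#' completer receives demographics and multi-select answers drawn from the
#' configured margins, a latent behaviour tendency `b ~ N(0,1)` discretised
#' to the distance item via thresholds matching the behaviour marginal
#' (`never_in_public` is drawn independently of `b`), and determinant scores
#' `round(mu + sigma * (r*b + sqrt(1-r^2)*e))` clamped to the item scale,
#' for a uniformly random without-replacement item subset of the opted-in
#' size. The returned truth record stores every planted parameter.
#'
#' @param config A [simulation_config()].
#' @param bank The `item_bank` items are drawn from.
#' @return A list with `responses` (validated cohort tibble of completers),
#'   `funnel` (a [funnel_counts()]), and `truth` (planted parameters).
#' @export
simulate_cohort <- function(config, bank = default_item_bank()) {
  config <- validate_simulation_config(unclass(config))
  validate_item_bank(bank)
  unknown <- setdiff(names(config$planted_r), bank$item_id)
  if (length(unknown) > 0) {
    abort(paste0("planted_r given for unknown item(s): ",
                 paste(unknown, collapse = ", ")))
  }
  unknown_ms <- setdiff(names(config$item_mean_sd), bank$item_id)
  if (length(unknown_ms) > 0) {
    abort(paste0("item_mean_sd given for unknown item(s): ",
                 paste(unknown_ms, collapse = ", ")))
  }
  set.seed(config$seed)
  n_items <- nrow(bank)
  planted <- stats::setNames(rep(0, n_items), bank$item_id)
  planted[names(config$planted_r)] <- config$planted_r
  mu <- bank$scale_min + 0.7 * (bank$scale_max - bank$scale_min)
  sigma <- rep(1.2, n_items)
  names(mu) <- names(sigma) <- bank$item_id
  for (id in names(config$item_mean_sd)) {
    mu[id] <- config$item_mean_sd[[id]][1]
    sigma[id] <- config$item_mean_sd[[id]][2]
  }

  states <- sample(names(config$dropout), config$n_respondents,
                   replace = TRUE, prob = config$dropout)
  funnel <- funnel_counts(
    total_opened = config$n_respondents,
    opened_first_page_only = sum(states == "first_page_only"),
    started_not_completed = sum(states == "started_not_completed"),
    completed = sum(states == "completed")
  )
  n <- funnel$completed
  if (n == 0) {
    empty <- tibble::tibble(
      respondent_id = character(0), country = character(0),
      age_band = character(0), gender = character(0),
      work_contexts = list(), isolation_behaviours = list(),
      isolation_triggers = list(), behaviours_would_stop = list(),
      distance_frequency = character(0),
      handwash_situations = list(), handwash_thoroughness = list(),
      n_items_opted = integer(0), determinant_scores = list()
    )
    return(list(responses = empty, funnel = funnel,
                truth = list(planted_r = planted, item_mean = mu,
                             item_sd = sigma, config = unclass(config))))
  }

  # latent behaviour tendency and its ordinal discretisation
  b <- rnorm(n)
  pub <- stats::runif(n) < config$behaviour_marginal[["never_in_public"]]
  cond <- config$behaviour_marginal[rt_distance_levels[1:5]]
  cond <- cond / sum(cond)
  thresholds <- qnorm(cumsum(cond))[1:4]
  level_idx <- findInterval(b, thresholds) + 1L
  distance <- rt_distance_levels[level_idx]
  distance[pub] <- "never_in_public"

  opt_sizes <- as.integer(sample(names(config$opt_in_distribution), n,
                                 replace = TRUE,
                                 prob = config$opt_in_distribution))
  scores <- vector("list", n)
  bank_order <- stats::setNames(seq_len(n_items), bank$item_id)
  for (i in seq_len(n)) {
    k <- min(opt_sizes[i], n_items)
    if (k == 0) {
      scores[[i]] <- stats::setNames(integer(0), character(0))
      next
    }
    ids <- bank$item_id[sort(sample.int(n_items, k))]
    r <- planted[ids]
    latent <- r * b[i] + sqrt(1 - r^2) * rnorm(k)
    raw_score <- round(mu[ids] + sigma[ids] * latent)
    raw_score <- pmin(pmax(raw_score, bank$scale_min[bank_order[ids]]),
                      bank$scale_max[bank_order[ids]])
    scores[[i]] <- stats::setNames(as.integer(raw_score), ids)
  }

  responses <- tibble::tibble(
    respondent_id = sprintf("r%05d", seq_len(n)),
    country = sample(names(config$country_probs), n, replace = TRUE,
                     prob = config$country_probs),
    age_band = sample(names(config$age_probs), n, replace = TRUE,
                      prob = config$age_probs),
    gender = sample(names(config$gender_probs), n, replace = TRUE,
                    prob = config$gender_probs),
    work_contexts = replicate(n, draw_set(
      rt_work_contexts, config$answer_prevalences$work_contexts),
      simplify = FALSE),
    isolation_behaviours = replicate(n, draw_set(
      rt_isolation_behaviours,
      config$answer_prevalences$isolation_behaviours), simplify = FALSE),
    isolation_triggers = replicate(n, draw_set(
      rt_isolation_triggers, config$answer_prevalences$isolation_triggers),
      simplify = FALSE),
    behaviours_would_stop = replicate(n, draw_set(
      rt_behaviours_would_stop,
      config$answer_prevalences$behaviours_would_stop), simplify = FALSE),
    distance_frequency = distance,
    handwash_situations = replicate(n, draw_set(
      rt_handwash_situations,
      config$answer_prevalences$handwash_situations), simplify = FALSE),
    handwash_thoroughness = replicate(n, draw_set(
      rt_handwash_thoroughness,
      config$answer_prevalences$handwash_thoroughness), simplify = FALSE),
    n_items_opted = opt_sizes,
    determinant_scores = scores
  )
  validate_responses(responses, bank)
  list(
    responses = responses,
    funnel = funnel,
    truth = list(planted_r = planted, item_mean = mu, item_sd = sigma,
                 latent_behaviour = b, config = unclass(config))
  )
}

#' Compare planted and recovered determinant structure
#'
#' For every item with a planted parameter, reports the planted latent
#' correlation next to the estimate recovered by [correlation_ci()] from the
#' discretised, partially missing data, whether the CI covers the planted
#' value, and the Kendall rank agreement between the planted-correlation
#' ordering and the PΔ2 ordering. Discretisation attenuates correlations, so
#' at large n the CI concentrates slightly below a strong planted value;
#' the coverage flag is reported against the planted (latent) value and
#' should be read together with the attenuation inherent in ordinal data.
#'
#' @param cohort The list returned by [simulate_cohort()].
#' @param bank The item bank used for the simulation.
#' @param min_pairs Minimum pairwise-complete n per item.
#' @return A list with `items` (per-item tibble) and `kendall_tau`
#'   (`NA` when fewer than two items have defined statistics).
#' @export
recoverability_report <- function(cohort, bank = default_item_bank(),
                                  min_pairs = 10) {
  truth <- cohort$truth
  ct <- ciber_table(cohort$responses, bank, min_pairs = min_pairs)
  s <- ct$summaries
  planted_items <- names(truth$planted_r)
  rows <- lapply(planted_items, function(id) {
    est <- if (nrow(s) > 0 && id %in% s$item_id) s[s$item_id == id, ] else NULL
    tibble::tibble(
      item_id = id,
      planted_r = truth$planted_r[[id]],
      estimated_r = if (is.null(est)) NA_real_ else est$r,
      r_ci_low = if (is.null(est)) NA_real_ else est$r_ci_low,
      r_ci_high = if (is.null(est)) NA_real_ else est$r_ci_high,
      n_pairs = if (is.null(est)) 0L else est$n_pairs,
      ci_covers_truth = if (is.null(est)) NA else
        est$r_ci_low <= truth$planted_r[[id]] &
        truth$planted_r[[id]] <= est$r_ci_high,
      pdelta2 = if (is.null(est)) NA_real_ else est$pdelta2
    )
  })
  items <- do.call(rbind, rows)
  defined <- items[!is.na(items$pdelta2), ]
  tau <- if (nrow(defined) >= 2 && sd(defined$planted_r) > 0 &&
             sd(defined$pdelta2) > 0) {
    cor(defined$planted_r, defined$pdelta2, method = "kendall")
  } else {
    NA_real_
  }
  list(items = items, kendall_tau = tau)
}
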