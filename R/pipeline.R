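# Pipeline commands: file-in/file-out wrappers around the package functions,
# each writing a run manifest so any output can be reproduced bit-for-bit
# from its inputs and seed.

write_manifest <- function(out_dir, command, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    package = "risktailor",
    version = as.character(utils::packageVersion("risktailor")),
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Writes `responses.csv`, `funnel.json`, `truth.json` and a run manifest.
#'
#' @param config A [simulation_config()] or a path to its JSON form.
#' @param out_dir Output directory (created if needed).
#' @param bank Item bank used for the simulation.
#' @param seed Optional integer overriding the seed in `config`.
#' @return Named character vector of written files, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, bank = default_item_bank(),
                         seed = NULL) {
  if (is.character(config)) config <- load_simulation_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- validate_simulation_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config, bank)
  paths <- c(
    responses = file.path(out_dir, "responses.csv"),
    funnel = file.path(out_dir, "funnel.json"),
    truth = file.path(out_dir, "truth.json")
  )
  write_responses(sim$responses, paths[["responses"]], bank)
  write_funnel_counts(sim$funnel, paths[["funnel"]])
  truth <- sim$truth
  truth$latent_behaviour <- NULL # per-respondent latents stay in memory only
  truth$planted_r <- as.list(truth$planted_r)
  truth$item_mean <- as.list(truth$item_mean)
  truth$item_sd <- as.list(truth$item_sd)
  truth$config <- config_to_json_list(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_manifest(out_dir, "simulate", config$seed,
                 inputs = list(n_respondents = config$n_respondents),
                 outputs = as.list(paths))
  invisible(paths)
}

#' Score a cohort and select tailored messages
#'
#' Reads a cohort CSV, scores every respondent with the three-factor risk
#' model, runs the tailoring engine, and writes `risk_estimates.csv` plus a
#' per-respondent `messages.json` (each message with full provenance: ABCD
#' row, fired rule, factor score) and a manifest.
#'
#' @param responses_path Cohort CSV path.
#' @param out_dir Output directory.
#' @param bank Item bank for response validation.
#' @param weights A `risk_weights` object or path to its JSON form.
#' @param rules A `tailoring_rules` tibble or path to its JSON form.
#' @param abcd An `abcd_table` or path to its TSV form.
#' @param max_messages Per-respondent message cap.
#' @return Named character vector of written files, invisibly.
#' @export
cmd_score <- function(responses_path, out_dir, bank = default_item_bank(),
                      weights = default_risk_weights(),
                      rules = default_tailoring_rules(),
                      abcd = default_abcd(), max_messages = 6) {
  if (is.character(weights)) weights <- load_risk_weights(weights)
  if (is.character(rules)) rules <- load_tailoring_rules(rules)
  if (is.character(abcd)) abcd <- load_abcd(abcd)
  responses <- read_responses(responses_path, bank)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  risk <- score_risk(responses, weights)
  messages <- lapply(seq_len(nrow(responses)), function(i) {
    sel <- select_messages(responses[i, ], risk[i, ], abcd, rules,
                           max_messages = max_messages)
    list(respondent_id = responses$respondent_id[i],
         messages = as.data.frame(sel))
  })
  paths <- c(
    risk = file.path(out_dir, "risk_estimates.csv"),
    messages = file.path(out_dir, "messages.json")
  )
  write.csv(as.data.frame(risk), paths[["risk"]], row.names = FALSE)
  jsonlite::write_json(messages, paths[["messages"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  write_manifest(out_dir, "score", NA,
                 inputs = list(responses = responses_path,
                               max_messages = max_messages),
                 outputs = as.list(paths))
  invisible(paths)
}

#' Run the determinant analysis on a cohort
#'
#' Reads a cohort CSV, computes the CIBER table, writes the three orderings
#' (by PΔ1, by PΔ2, by correlation) and the insufficient-data listing as
#' CSVs, renders the two-panel CIBER plot to PNG, reports the usage funnel
#' (when a funnel JSON is supplied) and writes a manifest. With zero
#' completed records only the funnel report is produced, with a warning.
#'
#' @param responses_path Cohort CSV path.
#' @param out_dir Output directory.
#' @param bank Item bank.
#' @param funnel_path Optional path to a funnel-counts JSON.
#' @param behaviour_field,min_pairs,upper_q,lower_q Passed to
#'   [ciber_table()].
#' @param plot_seed Seed for the plot jitter.
#' @return Named character vector of written files, invisibly.
#' @export
cmd_analyze <- function(responses_path, out_dir, bank = default_item_bank(),
                        funnel_path = NULL,
                        behaviour_field = "distance_frequency",
                        min_pairs = 10, upper_q = 0.95, lower_q = 0.05,
                        plot_seed = 1) {
  responses <- read_responses(responses_path, bank)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(funnel_path)) {
    funnel <- load_funnel_counts(funnel_path)
    report <- c(unclass(funnel), list(dropout_pct = funnel_stats(funnel)))
    funnel_out <- file.path(out_dir, "funnel_report.json")
    jsonlite::write_json(report, funnel_out, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, funnel = funnel_out)
  }
  if (nrow(responses) == 0) {
    warn("cohort has no completed records; writing funnel report only")
    write_manifest(out_dir, "analyze", plot_seed,
                   inputs = list(responses = responses_path),
                   outputs = as.list(paths))
    return(invisible(paths))
  }
  ct <- ciber_table(responses, bank, behaviour_field = behaviour_field,
                    min_pairs = min_pairs, upper_q = upper_q,
                    lower_q = lower_q)
  table_paths <- write_ciber_tables(ct, out_dir)
  paths <- c(paths, table_paths)
  if (nrow(ct$summaries) > 0) {
    plot_path <- file.path(out_dir, "ciber_plot.png")
    p <- ciber_plot(ct, responses, behaviour_field = behaviour_field,
                    seed = plot_seed)
    ggplot2::ggsave(plot_path, p, width = 9, height = 6, dpi = 150)
    paths <- c(paths, plot = plot_path)
  }
  write_manifest(out_dir, "analyze", plot_seed,
                 inputs = list(responses = responses_path,
                               behaviour_field = behaviour_field,
                               min_pairs = min_pairs),
                 outputs = as.list(paths))
  invisible(paths)
}
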