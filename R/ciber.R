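# Confidence Interval-Based Estimation of Relevance (CIBER) and the two
# Potential for Change indices. CIBER is an estimation approach, not a
# testing one: sub-determinants are judged by an ultra-wide (99.99%) CI for
# their mean (room for improvement) next to a 95% CI for their zero-order
# correlation with behaviour (association). No multiplicity correction is
# applied, by design.

#' t-based confidence interval for a mean
#'
#' Two-sided interval `mean +/- t(1-(1-level)/2, n-1) * sd / sqrt(n)`. The
#' default level is the deliberately conservative 99.99% used in CIBER plots,
#' chosen so that many means can be displayed together without the usual
#' per-comparison optimism. A zero-variance vector yields a zero-width
#' interval.
#'
#' @param scores Numeric vector, `n >= 2`, finite.
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(mean, low, high)`.
#' @export
#' @examples
#' mean_ci(c(1, 2, 3, 4, 5), level = 0.95)
mean_ci <- function(scores, level = 0.9999) {
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 2) abort("mean_ci needs at least 2 non-missing values")
  if (any(!is.finite(scores))) abort("mean_ci needs finite values")
  m <- mean(scores)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(scores) / sqrt(n)
  c(mean = m, low = m - half, high = m + half)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Computes the zero-order correlation on pairwise-complete observations and
#' its two-sided CI via the Fisher z transform
#' (`tanh(atanh(r) +/- z * (n - 3)^(-1/2))`). Constant input makes the
#' correlation undefined; it is flagged as such (`r = NA`,
#' `undefined = TRUE`), never silently zero.
#'
#' @param x,y Paired numeric vectors.
#' @param level Confidence level (default 0.95, the CIBER convention for the
#'   association panel).
#' @return A list with `r`, `low`, `high`, `n` (pairwise-complete count) and
#'   `undefined`.
#' @export
#' @examples
#' correlation_ci(1:10, (1:10) + rnorm(10))
correlation_ci <- function(x, y, level = 0.95) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("correlation_ci needs at least 4 pairwise-complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, low = NA_real_, high = NA_real_, n = n,
                undefined = TRUE))
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = r, low = r, high = r, n = n, undefined = FALSE))
  }
  z <- atanh(r)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  list(r = r, low = tanh(z - half), high = tanh(z + half), n = n,
       undefined = FALSE)
}

pairwise_complete <- function(scores, behaviour) {
  keep <- complete.cases(scores, behaviour)
  list(scores = scores[keep], behaviour = behaviour[keep],
       n = sum(keep))
}

#' Potential for Change index, variant 1
#'
#' Combines room for improvement with strength of association: for a
#' positive zero-order correlation with behaviour,
#' `(max(scores) - mean(scores)) * r`; for a negative correlation,
#' `(min(scores) - mean(scores)) * r`. Extremes are the *observed* sample
#' extremes, not the theoretical scale bounds. Both branches yield
#' non-negative values; `r = 0` (or constant scores) gives 0, and a constant
#' behaviour vector leaves the index undefined (`NA`).
#'
#' @param scores Numeric vector of item scores.
#' @param behaviour Paired numeric behaviour measure.
#' @return A single numeric value (`NA` if the correlation is undefined
#'   because behaviour is constant).
#' @export
#' @examples
#' potential_for_change_1(c(1, 1, 5, 3), c(1, 1, 5, 3)) # r = 1
potential_for_change_1 <- function(scores, behaviour) {
  pc <- pairwise_complete(scores, behaviour)
  if (pc$n < 4) abort("potential_for_change_1 needs at least 4 pairs")
  if (sd(pc$behaviour) == 0) return(NA_real_)
  if (sd(pc$scores) == 0) return(0)
  r <- cor(pc$scores, pc$behaviour)
  if (r > 0) (max(pc$scores) - mean(pc$scores)) * r
  else if (r < 0) (min(pc$scores) - mean(pc$scores)) * r
  else 0
}

#' Potential for Change index, variant 2
#'
#' As [potential_for_change_1()], but the observed extreme is replaced by the
#' 0.95 (positive r) or 0.05 (negative r) sample quantile - effectively a 5%
#' trimmed extreme - and the correlation enters squared (the proportion of
#' explained variance). Trimming and squaring both damp sample
#' idiosyncrasies, making this variant more robust across samples and more
#' punishing of weak associations. Quantiles use linear interpolation
#' between order statistics (R's default type 7), which the index value
#' depends on.
#'
#' Note the sign behaviour of the negative branch: because the squared
#' correlation is positive while the 0.05 quantile lies at or below the
#' mean, a negatively associated item gets a value at or below zero. This
#' follows the index's published definition literally; under a descending
#' sort such items rank below unassociated ones.
#'
#' @inheritParams potential_for_change_1
#' @param upper_q,lower_q Quantiles standing in for the trimmed maximum and
#'   minimum.
#' @return A single numeric value (`NA` if behaviour is constant).
#' @export
potential_for_change_2 <- function(scores, behaviour, upper_q = 0.95,
                                   lower_q = 0.05) {
  pc <- pairwise_complete(scores, behaviour)
  if (pc$n < 4) abort("potential_for_change_2 needs at least 4 pairs")
  if (sd(pc$behaviour) == 0) return(NA_real_)
  if (sd(pc$scores) == 0) return(0)
  r <- cor(pc$scores, pc$behaviour)
  if (r > 0) {
    (quantile(pc$scores, upper_q, names = FALSE, type = 7) -
       mean(pc$scores)) * r^2
  } else if (r < 0) {
    (quantile(pc$scores, lower_q, names = FALSE, type = 7) -
       mean(pc$scores)) * r^2
  } else {
    0
  }
}

item_score_matrix <- function(responses, item_ids) {
  n <- nrow(responses)
  mat <- matrix(NA_real_, nrow = n, ncol = length(item_ids),
                dimnames = list(NULL, item_ids))
  for (i in seq_len(n)) {
    sc <- responses$determinant_scores[[i]]
    if (length(sc) > 0) {
      hit <- intersect(names(sc), item_ids)
      mat[i, hit] <- sc[hit]
    }
  }
  mat
}

#' CIBER summary table for every determinant item
#'
#' For each item with at least `min_pairs` pairwise-complete observations
#' against the behaviour measure, computes the sample mean with its 99.99%
#' CI, the zero-order correlation with its 95% Fisher-z CI, both Potential
#' for Change indices, and the target-selection flag of [select_targets()].
#' All statistics for an item are computed on the same pairwise-complete
#' subset, so mean, extremes and correlation describe the same respondents.
#' Items below the threshold (or with undefined correlations) are reported
#' in a separate `insufficient` table, never silently dropped.
#'
#' @param responses A validated cohort tibble.
#' @param bank The `item_bank`.
#' @param behaviour_field Respondent field used as the behaviour measure
#'   (default the distance-keeping item, coded 1-5 with `never_in_public`
#'   missing).
#' @param min_pairs Minimum pairwise-complete n (default 10).
#' @param mean_level,r_level CI levels for the mean and the association.
#' @param upper_q,lower_q Trimmed-extreme quantiles for the second index.
#' @param r_rule,room_rule Selection thresholds, see [select_targets()].
#' @return A `ciber_table` list: `summaries` plus the three orderings
#'   `by_pdelta1`, `by_pdelta2`, `by_r` (each descending), and
#'   `insufficient`.
#' @export
ciber_table <- function(responses, bank,
                        behaviour_field = "distance_frequency",
                        min_pairs = 10, mean_level = 0.9999,
                        r_level = 0.95, upper_q = 0.95, lower_q = 0.05,
                        r_rule = list(direction = "positive"),
                        room_rule = list(ceiling = 0.9)) {
  validate_item_bank(bank)
  behaviour <- behaviour_vector(responses, behaviour_field)
  mat <- item_score_matrix(responses, bank$item_id)
  rows <- vector("list", nrow(bank))
  insufficient <- list()
  for (k in seq_len(nrow(bank))) {
    id <- bank$item_id[k]
    pc <- pairwise_complete(mat[, id], behaviour)
    if (pc$n < max(min_pairs, 4)) {
      insufficient[[length(insufficient) + 1L]] <- tibble::tibble(
        item_id = id, n_pairs = pc$n, reason = "insufficient data"
      )
      next
    }
    if (sd(pc$behaviour) == 0 || sd(pc$scores) == 0) {
      insufficient[[length(insufficient) + 1L]] <- tibble::tibble(
        item_id = id, n_pairs = pc$n, reason = "correlation undefined"
      )
      next
    }
    mci <- mean_ci(pc$scores, level = mean_level)
    rci <- correlation_ci(pc$scores, pc$behaviour, level = r_level)
    rows[[k]] <- tibble::tibble(
      item_id = id,
      sub_determinant = bank$sub_determinant[k],
      construct = bank$construct[k],
      scale_min = bank$scale_min[k],
      scale_max = bank$scale_max[k],
      n_pairs = pc$n,
      mean = mci[["mean"]],
      mean_ci_low = mci[["low"]],
      mean_ci_high = mci[["high"]],
      r = rci$r,
      r_ci_low = rci$low,
      r_ci_high = rci$high,
      pdelta1 = potential_for_change_1(pc$scores, pc$behaviour),
      pdelta2 = potential_for_change_2(pc$scores, pc$behaviour,
                                       upper_q = upper_q, lower_q = lower_q)
    )
  }
  summaries <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  insufficient <- if (length(insufficient) > 0) {
    do.call(rbind, insufficient)
  } else {
    tibble::tibble(item_id = character(0), n_pairs = integer(0),
                   reason = character(0))
  }
  if (is.null(summaries) || nrow(summaries) == 0) {
    warn("no item meets the pairwise-complete threshold; table is empty")
    summaries <- tibble::tibble()
    return(structure(list(summaries = summaries, by_pdelta1 = summaries,
                          by_pdelta2 = summaries, by_r = summaries,
                          insufficient = insufficient),
                     class = "ciber_table"))
  }
  summaries <- select_targets(summaries, r_rule = r_rule,
                              room_rule = room_rule)
  structure(list(
    summaries = summaries,
    by_pdelta1 = summaries[order(-summaries$pdelta1, summaries$item_id), ],
    by_pdelta2 = summaries[order(-summaries$pdelta2, summaries$item_id), ],
    by_r = summaries[order(-summaries$r, summaries$item_id), ],
    insufficient = insufficient
  ), class = "ciber_table")
}

behaviour_vector <- function(responses, behaviour_field) {
  if (!behaviour_field %in% names(responses)) {
    abort(paste0("behaviour field not found in responses: ", behaviour_field))
  }
  x <- responses[[behaviour_field]]
  if (behaviour_field == "distance_frequency") distance_to_numeric(x)
  else as.numeric(x)
}

#' Flag intervention targets among CIBER summaries
#'
#' A sub-determinant is selected when (association criterion) its
#' correlation CI excludes zero in the favourable direction, and (room
#' criterion) its mean lies below the configured ceiling fraction of its
#' scale range - a strongly associated item whose mean already sits at the
#' scale ceiling offers no room for improvement and is not selected.
#'
#' @param summaries The `summaries` tibble of a [ciber_table()].
#' @param r_rule List with `direction` (`"positive"`: CI entirely above 0;
#'   `"negative"`: entirely below; `"either"`).
#' @param room_rule List with `ceiling`, the fraction of the scale range
#'   (above `scale_min`) the mean must stay below (default 0.9).
#' @return `summaries` with a logical `selected` column.
#' @export
select_targets <- function(summaries, r_rule = list(direction = "positive"),
                           room_rule = list(ceiling = 0.9)) {
  direction <- r_rule$direction %||% "positive"
  ceiling_frac <- room_rule$ceiling %||% 0.9
  assoc <- switch(direction,
    positive = summaries$r_ci_low > 0,
    negative = summaries$r_ci_high < 0,
    either = summaries$r_ci_low > 0 | summaries$r_ci_high < 0,
    abort("r_rule$direction must be 'positive', 'negative' or 'either'")
  )
  room_ceiling <- summaries$scale_min +
    ceiling_frac * (summaries$scale_max - summaries$scale_min)
  summaries$selected <- assoc & summaries$mean < room_ceiling
  summaries
}

#' Two-panel CIBER plot
#'
#' Left panel: each item's raw score distribution (seeded jittered points)
#' with a diamond at the mean and a bar spanning the 99.99% mean CI on the
#' item's scale. Right panel: a diamond at the correlation with a bar for
#' its 95% CI on a fixed [-1, 1] axis with a zero reference line. Items are
#' stacked in bank order, top first; the jitter is deterministic given
#' `seed`.
#'
#' @param ct A `ciber_table`.
#' @param responses The cohort the table was computed from (for the raw
#'   points).
#' @param behaviour_field As in [ciber_table()].
#' @param seed Integer seed for the jitter.
#' @return A patchwork object (left | right).
#' @export
ciber_plot <- function(ct, responses,
                       behaviour_field = "distance_frequency", seed = 1) {
  stopifnot(inherits(ct, "ciber_table"))
  s <- ct$summaries
  if (is.null(s) || nrow(s) == 0) abort("nothing to plot")
  s$item <- factor(s$item_id, levels = rev(s$item_id))
  behaviour <- behaviour_vector(responses, behaviour_field)
  mat <- item_score_matrix(responses, s$item_id)
  raw <- do.call(rbind, lapply(s$item_id, function(id) {
    keep <- complete.cases(mat[, id], behaviour)
    if (!any(keep)) return(NULL)
    data.frame(item = id, score = mat[keep, id])
  }))
  raw$item <- factor(raw$item, levels = rev(s$item_id))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  raw$score_j <- raw$score + stats::runif(nrow(raw), -0.18, 0.18)
  raw$item_j <- as.numeric(raw$item) + stats::runif(nrow(raw), -0.25, 0.25)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  left <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = raw,
      ggplot2::aes(x = .data$score_j, y = .data$item_j),
      alpha = 0.25, size = 0.6, colour = "grey40"
    ) +
    ggplot2::geom_errorbarh(
      data = s,
      ggplot2::aes(xmin = .data$mean_ci_low, xmax = .data$mean_ci_high,
                   y = as.numeric(.data$item)),
      height = 0.25, colour = "#2166ac", linewidth = 0.8
    ) +
    ggplot2::geom_point(
      data = s,
      ggplot2::aes(x = .data$mean, y = as.numeric(.data$item)),
      shape = 18, size = 3, colour = "#2166ac"
    ) +
    ggplot2::scale_y_continuous(breaks = seq_len(nrow(s)),
                                labels = levels(s$item)) +
    ggplot2::labs(x = "score", y = NULL,
                  title = "Scores (99.99% CI of the mean)") +
    ggplot2::theme_minimal(base_size = 9)
  right <- ggplot2::ggplot(s) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$r_ci_low, xmax = .data$r_ci_high,
                   y = as.numeric(.data$item)),
      height = 0.25, colour = "#b2182b", linewidth = 0.8
    ) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$r, y = as.numeric(.data$item)),
      shape = 18, size = 3, colour = "#b2182b"
    ) +
    ggplot2::scale_y_continuous(breaks = seq_len(nrow(s)), labels = NULL) +
    ggplot2::coord_cartesian(xlim = c(-1, 1)) +
    ggplot2::labs(x = "correlation with behaviour", y = NULL,
                  title = "Association (95% CI)") +
    ggplot2::theme_minimal(base_size = 9)
  patchwork::wrap_plots(left, right, nrow = 1, widths = c(2, 1))
}

#' Write the three CIBER orderings to CSV
#'
#' @param ct A `ciber_table`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_ciber_tables <- function(ct, dir) {
  stopifnot(inherits(ct, "ciber_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    by_pdelta1 = file.path(dir, "ciber_by_pdelta1.csv"),
    by_pdelta2 = file.path(dir, "ciber_by_pdelta2.csv"),
    by_r = file.path(dir, "ciber_by_r.csv"),
    insufficient = file.path(dir, "ciber_insufficient.csv")
  )
  for (nm in names(paths)) {
    write.csv(as.data.frame(ct[[nm]]), paths[[nm]], row.names = FALSE)
  }
  invisible(paths)
}
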