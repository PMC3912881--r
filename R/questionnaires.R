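#' Conventional reverse-keyed items of STAI Form Y1
#'
#' The state form scores 20 items rated 1–4; positively worded (anxiety-
#' absent) items are inverted before summation. The instrument is under
#' copyright and keying is not enumerable from the study description, so
#' the reverse set is a configuration input everywhere in this package;
#' this default is the conventional set of ten positively worded Y1 items.
#'
#' @return Integer vector of 1-based item indices.
#' @export
stai_reverse_items <- function() {
  c(1L, 2L, 5L, 8L, 10L, 11L, 15L, 16L, 19L, 20L)
}

#' Score STAI Form Y1 state-anxiety responses
#'
#' Each reverse-keyed response `r` is mapped to `5 - r`; the cumulative
#' score is the sum of the 20 transformed items and ranges 20 (low state
#' anxiety) to 80 (high). Missing or out-of-range items are an error —
#' no imputation.
#'
#' @param responses Either a long tibble with columns `item`, `response`
#'   and optional grouping columns (`participant_id`, `condition`, ...), or
#'   a bare numeric vector of 20 responses.
#' @param reverse_items 1-based indices of reverse-keyed items (default
#'   [stai_reverse_items()]).
#' @return For a vector input, a single integer score. For a tibble, one
#'   row per group with a `stai_score` column.
#' @examples
#' score_stai(c(rep(1, 10), rep(4, 10)), reverse_items = 11:20) # minimum: 20
#' @export
score_stai <- function(responses, reverse_items = stai_reverse_items()) {
  if (!all(reverse_items %in% 1:20)) {
    abort("`reverse_items` must be 1-based indices in 1..20.")
  }
  if (is.numeric(responses)) {
    return(score_stai_one(responses, reverse_items))
  }
  groups <- intersect(c("participant_id", "condition"), names(responses))
  responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      stai_score = score_stai_one(.data$response[order(.data$item)], reverse_items,
        items = sort(.data$item)
      ),
      .groups = "drop"
    )
}

score_stai_one <- function(v, reverse_items, items = seq_along(v)) {
  if (length(v) != 20 || !identical(as.integer(items), 1:20)) {
    abort("a STAI-Y1 response set must contain exactly items 1..20 (no imputation).")
  }
  if (anyNA(v) || any(v < 1 | v > 4) || any(v != round(v))) {
    abort("STAI responses must be integers in 1..4.")
  }
  v <- as.integer(v)
  v[reverse_items] <- 5L - v[reverse_items]
  sum(v)
}

#' Per-item descriptive statistics for a Likert battery
#'
#' For each item answered under `condition`: the sample median (midpoint of
#' the two central order statistics for even n, reproducing half-point
#' medians such as 4.5), mean, sample SD (n-1 denominator) and n.
#'
#' @param table Long tibble with columns `condition`, `item`, `response`.
#' @param condition Condition label to summarise.
#' @return A tibble with one row per item: `item`, `n`, `median`, `mean`,
#'   `sd`.
#' @export
seq_descriptives <- function(table, condition) {
  rows <- dplyr::filter(table, .data$condition == !!condition)
  if (nrow(rows) == 0) {
    abort(sprintf("no responses for condition '%s'.", condition))
  }
  if (any(rows$response < 1 | rows$response > 5)) {
    abort("responses must lie in 1..5.")
  }
  rows |>
    dplyr::group_by(item = .data$item) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$response),
      mean = mean(.data$response),
      sd = sd(.data$response),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$item)
}

#' Packaged simulation-evaluation questionnaire summary table
#'
#' Loads the published per-item descriptive table for the two simulation
#' conditions (recital, audition): median, mean, SD and the Wilcoxon
#' p-value column, where non-significant entries are recorded as the
#' literal `"ns"`. Used by [count_significant()] and the acceptance tests.
#'
#' @return A tibble: `item`, `label`, `condition`, `median`, `mean`, `sd`,
#'   `p` (character; numeric string or `"ns"`).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_fixture.csv",
    package = "hrvstress", mustWork = TRUE
  )
  readr::read_csv(path, col_types = readr::cols(
    item = readr::col_integer(), label = readr::col_character(),
    condition = readr::col_character(), median = readr::col_double(),
    mean = readr::col_double(), sd = readr::col_double(),
    p = readr::col_character()
  ))
}

#' Count items whose medians test significantly above the midpoint
#'
#' Applies the reported-significance rule to a summary table with a `p`
#' column: an item counts when its recorded p is numeric and below `alpha`
#' (`"ns"` literals are non-significant). Returns the count and the
#' percentage of the item range, rounded to one decimal.
#'
#' @param summaries A table shaped like [table1_fixture()].
#' @param condition Condition label.
#' @param alpha Significance level (default 0.05).
#' @param items Item index range to count over (default 1:19).
#' @return A one-row tibble: `condition`, `n_significant`, `n_items`,
#'   `percent`.
#' @export
count_significant <- function(summaries, condition, alpha = 0.05,
                              items = 1:19) {
  rows <- dplyr::filter(
    summaries, .data$condition == !!condition, .data$item %in% items
  )
  if (nrow(rows) == 0) abort(sprintf("unknown condition '%s'.", condition))
  p_num <- suppressWarnings(as.numeric(rows$p))
  sig <- !is.na(p_num) & p_num < alpha
  tibble(
    condition = condition,
    n_significant = sum(sig),
    n_items = length(items),
    percent = round(100 * sum(sig) / length(items), 1)
  )
}
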