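#' Generate 5-point Likert batteries with per-item location shifts
#'
#' Each response is produced by discretizing a logistic latent variable
#' centred at the item's shift into five symmetric bins (cut points at
#' -1.5, -0.5, 0.5, 1.5 latent units). A zero shift therefore gives a
#' response distribution symmetric about the scale midpoint 3, and a larger
#' shift gives stochastically larger responses.
#'
#' @param n Number of respondents (>= 1).
#' @param item_shifts Numeric vector of latent location shifts, one per
#'   item (default 19 zeros, the simulation-evaluation battery length).
#' @param seed Integer seed.
#' @param participant_id Optional vector of `n` participant labels.
#' @return A long tibble (`likert_table`): `participant_id`, `item`,
#'   `response` with responses integer in 1..5.
#' @export
generate_likert <- function(n, item_shifts = rep(0, 19), seed = 1L,
                            participant_id = NULL) {
  if (n < 1) abort("`n` must be at least 1.")
  n_items <- length(item_shifts)
  if (is.null(participant_id)) participant_id <- sprintf("P%02d", seq_len(n))
  cuts <- c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf)
  withr::with_seed(as.integer(seed), {
    latent <- rlogis(n * n_items) +
      rep(item_shifts, each = n) # item varies slowest
  })
  resp <- findInterval(latent, cuts, rightmost.closed = TRUE)
  out <- tibble(
    participant_id = rep(participant_id, times = n_items),
    item = rep(seq_len(n_items), each = n),
    response = as.integer(resp)
  )
  dplyr::arrange(out, .data$participant_id, .data$item)
}

#' Generate STAI Form Y1 response sets with a target score distribution
#'
#' The state-anxiety score is the sum of 20 items on a 1–4 scale after
#' reverse-keyed items are inverted, so totals range 20 (minimal anxiety)
#' to 80 (maximal). Each respondent's target total is drawn from
#' `Normal(target_mean, target_sd)`, rounded and clamped to `[20, 80]`; the
#' excess over 20 is then spread uniformly at random across the 20
#' (score-keyed) items, each capped at 4. Raw responses for reverse-keyed
#' items are stored inverted (`5 - v`) so that [score_stai()] with the same
#' `reverse_items` recovers the intended totals exactly. The quantity being
#' matched is the score mean/SD, not any per-item structure.
#'
#' @param n Number of respondents.
#' @param target_mean,target_sd Target mean and SD of the scored totals;
#'   `target_mean` must lie in `[20, 80]`.
#' @param seed Integer seed.
#' @param reverse_items Reverse-keyed item indices (default
#'   [stai_reverse_items()]).
#' @param participant_id Optional vector of `n` participant labels.
#' @return A long tibble: `participant_id`, `item` (1..20), `response`
#'   (integer 1..4), carrying `reverse_items` as an attribute.
#' @export
generate_stai <- function(n, target_mean, target_sd = 0, seed = 1L,
                          reverse_items = stai_reverse_items(),
                          participant_id = NULL) {
  if (n < 1) abort("`n` must be at least 1.")
  if (target_mean < 20 || target_mean > 80) {
    abort("`target_mean` is unattainable: STAI-Y1 totals range 20 to 80.")
  }
  if (is.null(participant_id)) participant_id <- sprintf("P%02d", seq_len(n))
  withr::with_seed(as.integer(seed), {
    totals <- round(pmin(80, pmax(20, rnorm(n, target_mean, target_sd))))
    rows <- purrr::map2(seq_len(n), totals, function(i, total) {
      # keyed values in 1..4 summing to `total`: spread total-20 increments
      keyed <- rep(1L, 20L)
      excess <- total - 20L
      while (excess > 0L) {
        open <- which(keyed < 4L)
        take <- open[sample.int(length(open), min(excess, length(open)))]
        keyed[take] <- keyed[take] + 1L
        excess <- excess - length(take)
      }
      raw <- keyed
      raw[reverse_items] <- 5L - raw[reverse_items]
      tibble(
        participant_id = participant_id[i],
        item = 1:20, response = as.integer(raw)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "reverse_items") <- reverse_items
  out
}
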