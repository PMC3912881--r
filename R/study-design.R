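#' Describe a within-subjects performance-stress study design
#'
#' The default design mirrors a two-condition (simulated vs real audition),
#' three-segment (baseline, pre-performance, performance) within-subjects
#' study with 7 participants: 5-minute baseline and pre-performance
#' segments and a performance segment of the same order (a short solo
#' piece), with every participant measured in every cell.
#'
#' `effect_matrix` holds the target LF/HF ratio per (segment, condition)
#' cell. The default reproduces the qualitative stress pattern of such
#' studies: elevated pre-performance sympatho-vagal balance in both
#' conditions, markedly higher before the real audition.
#'
#' @param n_participants Number of participants (>= 2; default 7).
#' @param conditions Condition labels (default simulated/real audition).
#' @param segments Segment labels in temporal order.
#' @param segment_durations Seconds per segment (default 300 each).
#' @param effect_matrix Numeric matrix, segments x conditions, of target
#'   LF/HF ratios (all positive).
#' @param questionnaire_shifts Named list, one numeric vector of per-item
#'   latent shifts per condition, for [generate_likert()].
#' @param stai_targets Tibble with `condition`, `mean`, `sd`: target STAI
#'   score distribution per condition.
#' @param mean_rr,amp_hf,freq_lf,freq_hf,noise_sd RR model parameters
#'   shared across cells: the HF modulation amplitude is held at `amp_hf`
#'   (ms) and the LF amplitude set per cell to `amp_hf * sqrt(target)`, so
#'   the analytic LF/HF power ratio equals the cell target.
#' @param ratio_jitter_sd SD (log scale) of per-participant-per-cell
#'   lognormal jitter applied to the target ratios; 0 gives identical
#'   targets in every cell of a row.
#' @param ectopic_rate,ectopic_magnitude Artifact corruption applied to
#'   every recording (default: none).
#' @param seed Integer master seed; all sub-streams derive from it.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_participants = 7,
                         conditions = c("simulated_audition", "real_audition"),
                         segments = c("baseline", "pre_performance", "performance"),
                         segment_durations = c(300, 300, 300),
                         effect_matrix = default_effect_matrix(segments, conditions),
                         questionnaire_shifts = list(
                           simulated_audition = rep(0.8, 19),
                           real_audition = rep(0.8, 19)
                         ),
                         stai_targets = tibble(
                           condition = conditions,
                           mean = c(32.29, 37.43), sd = c(7.39, 7.09)
                         ),
                         mean_rr = 800, amp_hf = 20, freq_lf = 0.095,
                         freq_hf = 0.25, noise_sd = 10,
                         ratio_jitter_sd = 0.2,
                         ectopic_rate = 0, ectopic_magnitude = 0.3,
                         seed = 1L) {
  if (n_participants < 2) abort("`n_participants` must be at least 2.")
  if (length(segment_durations) != length(segments)) {
    abort("one duration per segment, please.")
  }
  if (any(segment_durations <= 0)) abort("segment durations must be positive.")
  effect_matrix <- as.matrix(effect_matrix)
  if (!all(dim(effect_matrix) == c(length(segments), length(conditions)))) {
    abort("`effect_matrix` must be segments x conditions.")
  }
  if (any(effect_matrix <= 0)) {
    abort("every (segment, condition) cell needs a positive target ratio.")
  }
  dimnames(effect_matrix) <- list(segments, conditions)
  structure(
    list(
      n_participants = as.integer(n_participants), conditions = conditions,
      segments = segments, segment_durations = segment_durations,
      effect_matrix = effect_matrix,
      questionnaire_shifts = questionnaire_shifts,
      stai_targets = stai_targets,
      mean_rr = mean_rr, amp_hf = amp_hf, freq_lf = freq_lf,
      freq_hf = freq_hf, noise_sd = noise_sd,
      ratio_jitter_sd = ratio_jitter_sd,
      ectopic_rate = ectopic_rate, ectopic_magnitude = ectopic_magnitude,
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

#' @rdname study_design
#' @export
default_effect_matrix <- function(segments = c("baseline", "pre_performance", "performance"),
                                  conditions = c("simulated_audition", "real_audition")) {
  m <- matrix(c(1.5, 3.0, 2.0, 1.5, 6.0, 2.0),
    nrow = 3, ncol = 2,
    dimnames = list(segments, conditions)
  )
  m
}

#' Generate a complete synthetic study dataset
#'
#' Produces, per participant and condition, one RR series per segment whose
#' LF amplitude is chosen so the analytic LF/HF power ratio matches the
#' design's target for that cell (optionally jittered per participant), a
#' 19-item Likert battery per condition, and STAI Form Y1 responses per
#' condition. All randomness derives deterministically from `design$seed`.
#'
#' @param design A [study_design()].
#' @return A list of class `study_dataset`: `rr` (tibble with list-column
#'   `rr` of [rr_series()]), `likert`, `stai` (long tibbles with a
#'   `condition` column), `design`.
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  grid <- tidyr::expand_grid(
    participant_id = sprintf("P%02d", seq_len(design$n_participants)),
    condition = design$conditions,
    segment = design$segments
  )
  withr::with_seed(design$seed, {
    jitter <- if (design$ratio_jitter_sd > 0) {
      exp(rnorm(nrow(grid), 0, design$ratio_jitter_sd))
    } else {
      rep(1, nrow(grid))
    }
  })
  rows <- purrr::pmap(
    list(grid$participant_id, grid$condition, grid$segment,
      seq_len(nrow(grid))),
    function(pid, cond, seg, k) {
      target <- design$effect_matrix[seg, cond] * jitter[k]
      spec <- rr_modulation_spec(
        mean_rr = design$mean_rr,
        amp_lf = design$amp_hf * sqrt(target), freq_lf = design$freq_lf,
        amp_hf = design$amp_hf, freq_hf = design$freq_hf,
        noise_sd = design$noise_sd,
        duration = design$segment_durations[match(seg, design$segments)],
        seed = derive_seed(design$seed, k)
      )
      rr <- generate_rr(spec)
      if (design$ectopic_rate > 0) {
        rr <- inject_ectopics(rr, design$ectopic_rate,
          design$ectopic_magnitude,
          seed = derive_seed(design$seed, k + 100000L)
        )
      }
      tibble(
        participant_id = pid, condition = cond, segment = seg,
        target_ratio = target, rr = list(rr)
      )
    }
  )
  rr_tbl <- dplyr::bind_rows(rows)

  likert <- purrr::imap(design$questionnaire_shifts, function(shifts, cond) {
    dplyr::mutate(
      generate_likert(design$n_participants, shifts,
        seed = derive_seed(design$seed, 200000L + match(cond, design$conditions))
      ),
      condition = cond, .after = "participant_id"
    )
  }) |> dplyr::bind_rows()

  stai <- purrr::pmap(design$stai_targets, function(condition, mean, sd) {
    dplyr::mutate(
      generate_stai(design$n_participants, mean, sd,
        seed = derive_seed(design$seed, 300000L + match(condition, design$conditions))
      ),
      condition = condition, .after = "participant_id"
    )
  }) |> dplyr::bind_rows()

  structure(
    list(rr = rr_tbl, likert = likert, stai = stai, design = design),
    class = "study_dataset"
  )
}

#' Write a study dataset to CSV files
#'
#' RR series go to `rr_<participant>_<condition>_<segment>.csv` in the RR
#' dialect; questionnaires to `likert.csv` and `stai.csv`
#' (`participant_id, condition, item, response`).
#'
#' @param dataset A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::pwalk(
    dataset$rr[c("participant_id", "condition", "segment", "rr")],
    function(participant_id, condition, segment, rr) {
      write_rr_csv(rr, file.path(
        dir, sprintf("rr_%s_%s_%s.csv", participant_id, condition, segment)
      ))
    }
  )
  readr::write_csv(dataset$likert, file.path(dir, "likert.csv"))
  readr::write_csv(dataset$stai, file.path(dir, "stai.csv"))
  invisible(dir)
}
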