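#' Configure the end-to-end study analysis
#'
#' Bundles the synthetic design (or on-disk data directory) with HRV and
#' inference parameters. Unknown options are errors — no silent typos.
#'
#' @param design A [study_design()] describing the synthetic dataset.
#' @param window,hop Band-power window length and hop, s.
#' @param kernel Median-filter kernel (odd beats), or `NULL` for automatic:
#'   apply kernel 5 only when the design injects ectopic artifacts.
#' @param resample_rate Tachogram resampling rate, Hz.
#' @param lf_band,hf_band Analysis bands, Hz.
#' @param order Butterworth order.
#' @param trim_transients Drop filter edge-transient windows.
#' @param mu0 Hypothesized questionnaire median (scale midpoint).
#' @param alpha Significance level for reported counts.
#' @param alternative Sidedness for the per-item Wilcoxon tests.
#' @param ... Unknown options (an error, by design).
#' @return A list of class `study_config`.
#' @export
study_config <- function(design = study_design(), window = 60, hop = 30,
                         kernel = NULL, resample_rate = 4,
                         lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                         order = 4L, trim_transients = TRUE,
                         mu0 = 3, alpha = 0.05,
                         alternative = "two_sided", ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(paste0("unknown config option(s): ", paste(names(extra), collapse = ", ")))
  }
  structure(
    list(
      design = design, window = window, hop = hop, kernel = kernel,
      resample_rate = resample_rate, lf_band = lf_band, hf_band = hf_band,
      order = order, trim_transients = trim_transients,
      mu0 = mu0, alpha = alpha, alternative = alternative
    ),
    class = "study_config"
  )
}

#' Run the full study analysis
#'
#' Executes the complete pipeline: synthetic data generation, per-recording
#' HRV analysis (optional median-filter repair, 4 Hz spline resampling,
#' band filtering, windowed LF/HF), per-segment ratio means, questionnaire
#' scoring and descriptives, and the inference battery (per-item Wilcoxon
#' vs the scale midpoint, paired t on STAI scores, 3x2 within-subjects
#' ANOVA on segment-mean ratios). Deterministic given the design seed.
#'
#' @param config A [study_config()].
#' @return A list of class `study_report`: `ratios` (per participant x
#'   condition x segment), `ratio_summary` (condition x segment grand mean
#'   and SD), `anova`, `stai_scores`, `stai_ttest`, `seq_summary` (per-item
#'   descriptives + Wilcoxon p per condition), `seq_significance`,
#'   `provenance`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  design <- config$design
  dataset <- generate_study(design)

  kernel <- config$kernel
  if (is.null(kernel)) kernel <- if (design$ectopic_rate > 0) 5L else NA
  ratios <- purrr::pmap(
    dataset$rr[c("participant_id", "condition", "segment", "rr")],
    function(participant_id, condition, segment, rr) {
      res <- tryCatch(
        {
          if (!is.na(kernel)) rr <- median_filter_rr(rr, kernel)
          track <- band_power_track(
            resample_rr(rr, config$resample_rate),
            window = config$window, hop = config$hop,
            lf_band = config$lf_band, hf_band = config$hf_band,
            order = config$order, trim_transients = config$trim_transients
          )
          segment_mean_ratio(track, -Inf, Inf, segment = segment)
        },
        error = function(e) {
          abort(sprintf(
            "HRV stage failed for %s / %s / %s: %s",
            participant_id, condition, segment, conditionMessage(e)
          ))
        }
      )
      dplyr::mutate(res,
        participant_id = participant_id, condition = condition,
        .before = 1
      )
    }
  ) |> dplyr::bind_rows()

  ratio_summary <- ratios |>
    dplyr::group_by(.data$condition, .data$segment) |>
    dplyr::summarise(
      sd_ratio = sd(.data$mean_ratio),
      mean_ratio = mean(.data$mean_ratio),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::relocate("mean_ratio", .before = "sd_ratio")

  anova <- rm_anova_3x2(
    tibble(
      participant = ratios$participant_id,
      time = factor(ratios$segment, levels = design$segments),
      audition = factor(ratios$condition, levels = design$conditions),
      value = ratios$mean_ratio
    )
  )

  stai_scores <- score_stai(dataset$stai)
  wide <- tidyr::pivot_wider(stai_scores,
    names_from = "condition", values_from = "stai_score"
  )
  stai_ttest <- paired_t(
    wide[[design$conditions[1]]], wide[[design$conditions[2]]]
  )

  seq_summary <- purrr::map(design$conditions, function(cond) {
    desc <- seq_descriptives(dataset$likert, cond)
    p <- vapply(desc$item, function(it) {
      vals <- dataset$likert$response[
        dataset$likert$condition == cond & dataset$likert$item == it
      ]
      tryCatch(
        wilcoxon_one_sample(vals, config$mu0, config$alternative)$p_value,
        error = function(e) NA_real_ # all responses at the midpoint
      )
    }, numeric(1))
    dplyr::mutate(desc, condition = cond, p = p, .after = "item")
  }) |> dplyr::bind_rows()

  seq_significance <- purrr::map(
    design$conditions,
    function(cond) count_significant(seq_summary, cond, config$alpha,
      items = unique(seq_summary$item)
    )
  ) |> dplyr::bind_rows()

  structure(
    list(
      ratios = ratios, ratio_summary = ratio_summary, anova = anova,
      stai_scores = stai_scores, stai_ttest = stai_ttest,
      seq_summary = seq_summary, seq_significance = seq_significance,
      provenance = list(
        seed = design$seed, n_participants = design$n_participants,
        window = config$window, hop = config$hop, kernel = kernel,
        package_version = as.character(utils::packageVersion("hrvstress"))
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "Study report (n = %d participants, seed %d)\n\nSegment-mean LF/HF:\n",
    x$provenance$n_participants, x$provenance$seed
  ))
  print(x$ratio_summary)
  cat("\nWithin-subjects ANOVA on LF/HF:\n")
  print(x$anova$table[, c("effect", "df_effect", "df_error", "f", "p_value")])
  cat("\nState anxiety paired t: ")
  print(x$stai_ttest)
  cat("\nQuestionnaire medians above midpoint:\n")
  print(x$seq_significance)
  invisible(x)
}

#' Write a study report to CSV files
#'
#' Each table is written with a leading `#` provenance comment line
#' (seed, window/hop, package version).
#'
#' @param report A [run_study()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf(
    "# hrvstress %s | seed %d | window %gs hop %gs",
    report$provenance$package_version, report$provenance$seed,
    report$provenance$window, report$provenance$hop
  )
  tables <- list(
    ratios = report$ratios, ratio_summary = report$ratio_summary,
    anova = report$anova$table, stai_scores = report$stai_scores,
    stai_ttest = tidy(report$stai_ttest),
    seq_summary = report$seq_summary,
    seq_significance = report$seq_significance
  )
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    writeLines(prov, path)
    readr::write_csv(as_tibble(tables[[nm]]), path, append = TRUE,
      col_names = TRUE
    )
  }
  invisible(dir)
}

#' Recompute the in-study checkable quantities
#'
#' Computes, at run time, every quantity of the study that is recomputable
#' from packaged material or analytically: the counts of questionnaire
#' items testing significantly above the midpoint (from the packaged
#' published summary table), the STAI extreme scores, and the ANOVA
#' degrees-of-freedom structure at n = 7.
#'
#' @param reverse_items STAI reverse-keyed set (default
#'   [stai_reverse_items()]).
#' @return A tibble with `target`, `computed` and `expected` columns.
#' @export
acceptance_report <- function(reverse_items = stai_reverse_items()) {
  fixture <- table1_fixture()
  rec <- count_significant(fixture, "recital")
  aud <- count_significant(fixture, "audition")
  rec_skill <- count_significant(fixture, "recital", items = 12:19)

  max_raw <- rep(4L, 20)
  max_raw[reverse_items] <- 1L
  min_raw <- rep(1L, 20)
  min_raw[reverse_items] <- 4L
  stai_min <- score_stai(min_raw, reverse_items)
  stai_max <- score_stai(max_raw, reverse_items)

  aov_df <- rm_anova_3x2(tibble(
    participant = rep(sprintf("P%d", 1:7), each = 6),
    time = rep(rep(c("baseline", "pre", "perf"), each = 2), 7),
    audition = rep(c("sim", "real"), 21),
    value = withr::with_seed(42L, rnorm(42))
  ))$table

  tibble(
    target = c(
      "recital items significant (of 19)", "recital percent",
      "audition items significant (of 19)", "audition percent",
      "recital skill items significant (of 8)",
      "stai minimum score", "stai maximum score",
      "anova df time", "anova df audition", "anova df interaction"
    ),
    computed = c(
      as.character(c(
        rec$n_significant, rec$percent, aud$n_significant, aud$percent,
        rec_skill$n_significant, stai_min, stai_max
      )),
      sprintf("(%d, %d)", aov_df$df_effect[1], aov_df$df_error[1]),
      sprintf("(%d, %d)", aov_df$df_effect[2], aov_df$df_error[2]),
      sprintf("(%d, %d)", aov_df$df_effect[3], aov_df$df_error[3])
    ),
    expected = c(
      "12", "63.2", "13", "68.4", "7", "20", "80",
      "(2, 12)", "(1, 6)", "(2, 12)"
    )
  )
}
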