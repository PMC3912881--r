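#' Tidy and glance methods for test results
#'
#' Broom-style accessors: `tidy()` returns one row per statistic (or per
#' ANOVA effect), `glance()` a one-row model summary.
#'
#' @param x A `wilcoxon_result`, `ttest_result` or `rm_anova_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name hrvstress-tidiers
NULL

#' @rdname hrvstress-tidiers
#' @method tidy wilcoxon_result
#' @export
tidy.wilcoxon_result <- function(x, ...) {
  tibble(
    statistic = x$w_statistic, n_effective = x$n_effective,
    p_value = x$p_value, method = paste0("wilcoxon_signed_rank_", x$method),
    alternative = x$alternative, mu0 = x$mu0
  )
}

#' @rdname hrvstress-tidiers
#' @method glance wilcoxon_result
#' @export
glance.wilcoxon_result <- function(x, ...) tidy(x)

#' @rdname hrvstress-tidiers
#' @method tidy ttest_result
#' @export
tidy.ttest_result <- function(x, ...) {
  tibble(
    statistic = x$t, df = x$df, p_value = x$p_value,
    mean_diff = x$mean_diff, method = "paired_t"
  )
}

#' @rdname hrvstress-tidiers
#' @method glance ttest_result
#' @export
glance.ttest_result <- function(x, ...) tidy(x)

#' @rdname hrvstress-tidiers
#' @method tidy rm_anova_result
#' @export
tidy.rm_anova_result <- function(x, ...) x$table

#' @rdname hrvstress-tidiers
#' @method glance rm_anova_result
#' @export
glance.rm_anova_result <- function(x, ...) {
  tibble(
    n_participants = x$n_participants,
    levels_a = x$levels[1], levels_b = x$levels[2],
    ss_total = x$ss_total, ss_participant = x$ss_participant
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "One-sample Wilcoxon signed-rank (%s, %s)\n  W = %g, n_eff = %d, p = %.4g (mu0 = %g)\n",
    x$method, x$alternative, x$w_statistic, x$n_effective, x$p_value, x$mu0
  ))
  invisible(x)
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    "Paired t-test\n  t(%d) = %.3f, p = %.4g, mean diff = %.3f\n",
    x$df, x$t, x$p_value, x$mean_diff
  ))
  invisible(x)
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf(
    "Within-subjects ANOVA (%d x %d, n = %d participants)\n",
    x$levels[1], x$levels[2], x$n_participants
  ))
  print(x$table)
  invisible(x)
}
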