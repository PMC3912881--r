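#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around the standard Shapiro-Wilk routine returning a tidy
#' result; used to screen variables before choosing parametric vs
#' non-parametric tests.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A one-row tibble: `w`, `p_value`, `n`, `method`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  if (sd(values) == 0) abort("constant input: zero variance, W undefined.")
  ht <- shapiro.test(values)
  tibble(
    w = unname(ht$statistic), p_value = ht$p.value, n = n,
    method = "shapiro_wilk"
  )
}

# Exact null distribution of the one-sample signed-rank statistic W+ for a
# given rank vector (average ranks allowed). Equivalent to enumerating all
# 2^n sign assignments: ranks are doubled to integers and the distribution
# built by convolution, so tied (fractional) ranks are handled exactly.
# Returns list(support_w2, counts) with counts summing to 2^n.
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  list(w2 = 0:total, counts = counts)
}

#' One-sample Wilcoxon signed-rank test against a hypothesized median
#'
#' The non-parametric analogue of the one-sample t-test: differences from
#' `mu0` are ranked by absolute value (average ranks for ties, zeros
#' removed under the Wilcoxon convention) and W is the sum of ranks of the
#' positive differences. The p-value is exact — computed from the full
#' 2^n-assignment null distribution — whenever `n_effective <= 25` and
#' either there are no ties or `n_effective <= 12`; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' The two-sided exact p doubles the smaller tail (capped at 1).
#'
#' @param values Numeric vector.
#' @param mu0 Hypothesized median (e.g. 3, a 5-point scale midpoint).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @param exact_max,exact_max_ties Thresholds switching to the normal
#'   approximation.
#' @return An object of class `wilcoxon_result`; see [tidy()].
#' @examples
#' wilcoxon_one_sample(c(4, 4, 4, 4, 4, 4), mu0 = 3, alternative = "greater")
#' @export
wilcoxon_one_sample <- function(values, mu0 = 0,
                                alternative = c("two_sided", "greater", "less"),
                                exact_max = 25L, exact_max_ties = 12L) {
  alternative <- match.arg(alternative)
  d <- values[!is.na(values)] - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("all values equal mu0: no information against the hypothesized median.")
  }
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  has_ties <- any(ranks != round(ranks)) || anyDuplicated(abs(d)) > 0
  use_exact <- n <= exact_max_ties || (n <= exact_max && !has_ties)

  if (use_exact) {
    null <- signed_rank_null(ranks)
    w2 <- round(2 * w)
    tot <- sum(null$counts)
    p_ge <- sum(null$counts[null$w2 >= w2]) / tot
    p_le <- sum(null$counts[null$w2 <= w2]) / tot
    p <- switch(alternative,
      greater = p_ge, less = p_le,
      two_sided = min(1, 2 * min(p_ge, p_le))
    )
    method <- "exact"
  } else {
    mu_w <- n * (n + 1) / 4
    tie_sizes <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_sizes^3 - tie_sizes) / 48
    z <- function(cc) (w - mu_w - cc) / sqrt(sigma2)
    p <- switch(alternative,
      greater = pnorm(z(0.5), lower.tail = FALSE),
      less = pnorm(z(-0.5)),
      two_sided = min(1, 2 * pnorm(abs(w - mu_w) - 0.5,
        sd = sqrt(sigma2), lower.tail = FALSE
      ))
    )
    method <- "normal_approx"
  }
  structure(
    list(
      w_statistic = w, n_effective = n, p_value = p, method = method,
      alternative = alternative, mu0 = mu0
    ),
    class = "wilcoxon_result"
  )
}

#' Paired-samples t-test
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the paired differences `d = a - b`,
#' with `n - 1` degrees of freedom and a two-sided p-value.
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @return An object of class `ttest_result`; see [tidy()].
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must be paired (equal length).")
  d <- a - b
  n <- length(d)
  if (n < 2) abort("paired t needs at least 2 pairs.")
  if (sd(d) == 0) abort("zero-variance differences: t undefined.")
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  structure(
    list(
      t = t_stat, df = n - 1L, p_value = 2 * pt(-abs(t_stat), n - 1),
      mean_diff = mean(d), n = n
    ),
    class = "ttest_result"
  )
}

#' Two-factor fully within-subjects (repeated-measures) ANOVA
#'
#' Classical decomposition for a complete balanced design with one
#' observation per participant x factor-A level x factor-B level cell (the
#' study shape is 3 time points x 2 audition types). Each within-subjects
#' effect is tested against its own participant-by-effect error stratum:
#' `F_A = MS_A / MS_{participant x A}`, and so on, with uncorrected degrees
#' of freedom by default; Greenhouse-Geisser epsilon-corrected p-values are
#' available with `gg = TRUE`.
#'
#' @param data Long tibble with columns `participant`, two factor columns,
#'   and `value`.
#' @param factors Character vector naming the two within-subject factor
#'   columns (default `c("time", "audition")`).
#' @param gg Also report Greenhouse-Geisser corrected p-values.
#' @return An object of class `rm_anova_result`; its `table` element has a
#'   row per effect (`time`, `audition`, `time:audition`) with `df_effect`,
#'   `df_error`, `ss_effect`, `ss_error`, `ms_effect`, `ms_error`, `f`,
#'   `p_value` (and `epsilon`, `p_gg` when `gg = TRUE`). F is `NA`,
#'   flagged degenerate, when the matching error mean square is zero.
#' @export
rm_anova_within <- function(data, factors = c("time", "audition"), gg = FALSE) {
  fa <- factors[1]
  fb <- factors[2]
  need <- c("participant", fa, fb, "value")
  if (!all(need %in% names(data))) {
    abort(paste0("`data` needs columns: ", paste(need, collapse = ", "), "."))
  }
  data <- dplyr::mutate(
    data,
    participant = factor(.data$participant),
    .a = factor(.data[[fa]]), .b = factor(.data[[fb]])
  )
  ns <- nlevels(data$participant)
  a <- nlevels(data$.a)
  b <- nlevels(data$.b)
  if (ns < 2) abort("need at least 2 participants.")
  counts <- dplyr::count(data, .data$participant, .data$.a, .data$.b)
  if (nrow(counts) != ns * a * b || any(counts$n != 1)) {
    abort("design must be complete and balanced: exactly one value per participant x cell (no imputation).")
  }

  y <- data$value
  grand <- mean(y)
  m_s <- tapply(y, data$participant, mean)
  m_a <- tapply(y, data$.a, mean)
  m_b <- tapply(y, data$.b, mean)
  m_ab <- tapply(y, list(data$.a, data$.b), mean)
  m_sa <- tapply(y, list(data$participant, data$.a), mean)
  m_sb <- tapply(y, list(data$participant, data$.b), mean)

  ss_a <- ns * b * sum((m_a - grand)^2)
  ss_b <- ns * a * sum((m_b - grand)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, b)) -
    outer(rep(1, a), m_b) + grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
    outer(rep(1, ns), m_a) + grand)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
    outer(rep(1, ns), m_b) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ia <- as.integer(data$.a)
  ib <- as.integer(data$.b)
  is_ <- as.integer(data$participant)
  resid3 <- y - m_sa[cbind(is_, ia)] - m_sb[cbind(is_, ib)] -
    m_ab[cbind(ia, ib)] + m_s[is_] + m_a[ia] + m_b[ib] - grand
  ss_sab <- sum(resid3^2)

  eff <- tibble(
    effect = c(fa, fb, paste0(fa, ":", fb)),
    df_effect = c(a - 1L, b - 1L, (a - 1L) * (b - 1L)),
    df_error = c((a - 1L) * (ns - 1L), (b - 1L) * (ns - 1L),
      (a - 1L) * (b - 1L) * (ns - 1L)),
    ss_effect = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_sa, ss_sb, ss_sab)
  )
  eff <- dplyr::mutate(
    eff,
    ms_effect = .data$ss_effect / .data$df_effect,
    ms_error = .data$ss_error / .data$df_error,
    f = ifelse(.data$ms_error > 0, .data$ms_effect / .data$ms_error, NA_real_),
    p_value = ifelse(is.na(.data$f), NA_real_,
      pf(.data$f, .data$df_effect, .data$df_error, lower.tail = FALSE)
    )
  )
  if (any(is.na(eff$f))) {
    warn("degenerate data (zero error mean square): F flagged NA for some effects.")
  }

  if (gg) {
    # participant x cell matrix; array dims (s, a, b) flatten with a fastest
    arr <- tapply(y, list(data$participant, data$.a, data$.b), mean)
    cells <- matrix(arr, nrow = ns, ncol = a * b)
    orthonorm <- function(m) sweep(m, 2, sqrt(colSums(m^2)), "/")
    contr_a <- orthonorm(stats::contr.helmert(a))
    contr_b <- orthonorm(stats::contr.helmert(b))
    one_a <- matrix(1 / a, a, 1)
    one_b <- matrix(1 / b, b, 1)
    eps <- c(
      gg_epsilon(cells %*% kronecker(one_b, contr_a)),
      gg_epsilon(cells %*% kronecker(contr_b, one_a)),
      gg_epsilon(cells %*% kronecker(contr_b, contr_a))
    )
    eff$epsilon <- eps
    eff$p_gg <- ifelse(is.na(eff$f), NA_real_,
      pf(eff$f, eff$df_effect * eps, eff$df_error * eps, lower.tail = FALSE)
    )
  }

  structure(
    list(
      table = eff, n_participants = ns, levels = c(a, b),
      ss_total = ss_tot, ss_participant = ss_s
    ),
    class = "rm_anova_result"
  )
}

# Greenhouse-Geisser epsilon from a matrix of within-subject contrast scores
gg_epsilon <- function(z) {
  s <- stats::cov(z)
  k <- ncol(s)
  if (k == 1) return(1)
  (sum(diag(s)))^2 / (k * sum(s^2))
}

#' @rdname rm_anova_within
#' @param ... Passed to [rm_anova_within()].
#' @export
rm_anova_3x2 <- function(data, ...) {
  res <- rm_anova_within(data, ...)
  if (!identical(res$levels, c(3L, 2L))) {
    abort("expected a 3-level x 2-level within-subjects design.")
  }
  res
}
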