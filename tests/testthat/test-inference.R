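test_that("exact signed-rank p-values match spec-level hand enumerations", {
  # six ratings of 4 against midpoint 3: only the all-positive assignment
  # is as extreme, so the one-sided p is 1/64
  res <- wilcoxon_one_sample(rep(4, 6), mu0 = 3, alternative = "greater")
  expect_equal(res$p_value, 1 / 64)
  expect_equal(res$w_statistic, 21)
  expect_equal(res$n_effective, 6L)
  expect_equal(res$method, "exact")
  # {2, 4} about 3 is perfectly symmetric
  expect_equal(wilcoxon_one_sample(c(2, 4), mu0 = 3)$p_value, 1)
  expect_error(wilcoxon_one_sample(rep(3, 5), mu0 = 3), "no information")
})

test_that("exact p equals brute-force enumeration over all sign patterns", {
  withr::with_seed(101, {
    for (rep_i in 1:200) {
      n <- sample(3:12, 1)
      vals <- if (runif(1) < 0.5) {
        round(runif(n, -3, 5)) # integers: ties and zeros likely
      } else {
        runif(n, -2, 4)
      }
      mu0 <- 0
      if (all(vals == mu0)) next
      alt <- sample(c("two_sided", "greater", "less"), 1)
      got <- wilcoxon_one_sample(vals, mu0, alt)
      expect_equal(got$p_value, brute_wilcoxon_p(vals, mu0, alt),
        tolerance = 1e-12,
        info = paste("rep", rep_i)
      )
    }
  })
})

test_that("tie-free exact p agrees with the reference implementation", {
  withr::with_seed(202, {
    for (i in 1:50) {
      vals <- rnorm(sample(6:20, 1))
      got <- wilcoxon_one_sample(vals, 0)$p_value
      ref <- stats::wilcox.test(vals, mu = 0, exact = TRUE)$p.value
      expect_equal(got, ref, tolerance = 1e-12)
    }
  })
})

test_that("adding a positive constant never increases the greater-p", {
  withr::with_seed(303, {
    for (i in 1:50) {
      vals <- rnorm(10)
      p1 <- wilcoxon_one_sample(vals, 0, "greater")$p_value
      p2 <- wilcoxon_one_sample(vals + abs(rnorm(1)), 0, "greater")$p_value
      expect_lte(p2, p1 + 1e-12)
    }
  })
})

test_that("normal approximation is consistent with exact at n = 25", {
  withr::with_seed(404, {
    for (i in 1:30) {
      vals <- rnorm(25, mean = runif(1, -0.3, 0.3))
      exact <- wilcoxon_one_sample(vals, 0)$p_value
      approx <- wilcoxon_one_sample(vals, 0, exact_max = 0)$p_value
      expect_equal(wilcoxon_one_sample(vals, 0, exact_max = 0)$method,
        "normal_approx")
      expect_lt(abs(exact - approx), 0.01)
    }
  })
})

test_that("paired t matches hand computation and the reference routine", {
  res <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t, 2 / (1 / sqrt(3)))
  expect_equal(res$df, 2L)
  expect_equal(res$mean_diff, 2)
  withr::with_seed(11, {
    a <- rnorm(11)
    b <- rnorm(11)
  })
  got <- paired_t(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  expect_equal(got$df, 10L) # n = 11 pairs
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(c(1, 2), c(0, 1)), "zero-variance")
})

test_that("within-subjects anova reproduces the 3x2 df structure at n = 7", {
  withr::with_seed(7, d <- null_anova_data(7))
  res <- rm_anova_3x2(d)
  expect_equal(res$table$df_effect, c(2L, 1L, 2L))
  expect_equal(res$table$df_error, c(12L, 6L, 12L))
})

test_that("anova sums of squares decompose the total exactly", {
  withr::with_seed(8, d <- null_anova_data(9))
  res <- rm_anova_within(d)
  recomposed <- sum(res$table$ss_effect) + sum(res$table$ss_error) +
    res$ss_participant
  expect_lt(abs(recomposed - res$ss_total) / res$ss_total, 1e-8)
})

test_that("anova F and p agree with the reference aov error strata", {
  withr::with_seed(9, d <- null_anova_data(6))
  res <- rm_anova_3x2(d)
  d2 <- dplyr::mutate(d,
    participant = factor(participant),
    time = factor(time), audition = factor(audition)
  )
  ref <- summary(stats::aov(
    value ~ time * audition + Error(participant / (time * audition)),
    data = d2
  ))
  ref_time <- ref[["Error: participant:time"]][[1]]
  ref_aud <- ref[["Error: participant:audition"]][[1]]
  ref_int <- ref[["Error: participant:time:audition"]][[1]]
  expect_equal(res$table$f[1], ref_time["time", "F value"], tolerance = 1e-10)
  expect_equal(res$table$f[2], ref_aud["audition", "F value"], tolerance = 1e-10)
  expect_equal(res$table$f[3], ref_int["time:audition", "F value"],
    tolerance = 1e-10
  )
  expect_equal(res$table$p_value[1], ref_time["time", "Pr(>F)"],
    tolerance = 1e-10
  )
})

test_that("collapsing to two levels makes F equal the squared paired t", {
  withr::with_seed(10, {
    n <- 8
    a <- rnorm(n)
    b <- rnorm(n) + 0.5
  })
  # a 2 (time) x 2 (pseudo-factor) design replicating each pair: the time
  # effect tested against participant x time equals t^2 on the pairs
  d <- tidyr::expand_grid(
    participant = sprintf("P%d", 1:n),
    time = c("t1", "t2"), audition = c("x", "y")
  )
  pair_vals <- rbind(a, b)
  d$value <- pair_vals[cbind(
    match(d$time, c("t1", "t2")),
    match(d$participant, sprintf("P%d", 1:n))
  )]
  # duplicating across the pseudo-factor zeroes its strata: expected here
  expect_warning(res <- rm_anova_within(d), "degenerate")
  tt <- paired_t(a, b)
  expect_equal(res$table$f[1], tt$t^2, tolerance = 1e-8)
  expect_equal(res$table$p_value[1], tt$p_value, tolerance = 1e-8)
})

test_that("degenerate constant cells are flagged rather than reported", {
  d <- tidyr::expand_grid(
    participant = sprintf("P%d", 1:4),
    time = c("t1", "t2", "t3"), audition = c("x", "y")
  )
  d$value <- 1
  expect_warning(res <- rm_anova_3x2(d), "degenerate")
  expect_true(all(res$table$ss_effect == 0))
  expect_true(all(is.na(res$table$f)))
})

test_that("incomplete or unbalanced designs are refused", {
  withr::with_seed(12, d <- null_anova_data(5))
  expect_error(rm_anova_3x2(d[-1, ]), "complete and balanced")
  expect_error(rm_anova_3x2(rbind(d, d[1, ])), "complete and balanced")
  one <- dplyr::filter(d, participant == "P1")
  expect_error(rm_anova_3x2(one), "at least 2 participants")
})

test_that("greenhouse-geisser epsilon is sane and unity for 1-df effects", {
  withr::with_seed(13, d <- null_anova_data(10))
  res <- rm_anova_within(d, gg = TRUE)
  expect_equal(res$table$epsilon[2], 1) # 2-level factor: epsilon is exactly 1
  expect_true(all(res$table$epsilon >= 0.5 - 1e-9 & res$table$epsilon <= 1 + 1e-9))
  # the correction is conservative where it matters: for F > 1 shrinking both
  # df can only raise the p-value (for F < 1 the direction is not guaranteed)
  big <- !is.na(res$table$f) & res$table$f > 1
  expect_true(all(res$table$p_gg[big] >= res$table$p_value[big] - 1e-12))
})

test_that("shapiro-wilk screen flags bimodal data and passes normal grids", {
  bimodal <- rep(c(0, 10), each = 10)
  expect_lt(shapiro_wilk(bimodal)$p_value, 0.05)
  grid <- stats::qnorm((1:10) / 11)
  expect_gt(shapiro_wilk(grid)$w, 0.98)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})
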