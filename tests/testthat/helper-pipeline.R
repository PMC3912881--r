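# Shared helpers for building small analytic inputs.

# uniform series holding a pure sinusoid (plus optional DC offset)
sinusoid_series <- function(freq, amp = 1, duration = 600, rate = 4,
                            offset = 0) {
  t <- seq(0, duration, by = 1 / rate)
  uniform_series(t, offset + amp * sin(2 * pi * freq * t), rate)
}

# clean RR series through resampling and band-power tracking
rr_to_track <- function(rr, ...) {
  band_power_track(resample_rr(rr, 4), ...)
}

# brute-force one-sample signed-rank p-value by explicit enumeration of all
# 2^n sign assignments (independent of the package's convolution path)
brute_wilcoxon_p <- function(values, mu0, alternative) {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(ranks[s]))
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
}

# null 3x2 within-subjects dataset of iid normal cell values
null_anova_data <- function(n = 7) {
  tidyr::expand_grid(
    participant = sprintf("P%d", seq_len(n)),
    time = c("baseline", "pre", "perf"),
    audition = c("sim", "real")
  ) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
}
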