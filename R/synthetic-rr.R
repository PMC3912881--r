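#' Specify sinusoidal RR modulation with known spectral ground truth
#'
#' Describes a beat-domain RR model: each interval is the mean RR plus one
#' sinusoid in the LF band (0.04–0.15 Hz), one in the HF band (0.15–0.4 Hz),
#' and Gaussian noise, all evaluated at the previous beat's time. The model
#' acts on interval values sampled at beat times rather than on a continuous
#' integral-pulse train, which keeps the band powers analytic: a sinusoid of
#' amplitude `a` ms contributes `a^2/2` ms^2 to its band.
#'
#' @param mean_rr Mean interval, ms (default 800, i.e. 75 bpm).
#' @param amp_lf,freq_lf LF modulation amplitude (ms) and frequency (Hz);
#'   frequency must lie in 0.04–0.15 Hz whenever the amplitude is positive.
#' @param amp_hf,freq_hf HF modulation amplitude (ms) and frequency (Hz);
#'   frequency must lie in 0.15–0.4 Hz whenever the amplitude is positive.
#' @param noise_sd SD of additive white Gaussian interval noise, ms.
#' @param duration Recording length to cover, s.
#' @param seed Integer seed; every generator here is a pure function of its
#'   arguments including the seed.
#'
#' @return A list of class `rr_modulation_spec`.
#' @export
rr_modulation_spec <- function(mean_rr = 800, amp_lf = 30, freq_lf = 0.095,
                               amp_hf = 20, freq_hf = 0.25, noise_sd = 0,
                               duration = 300, seed = 1L) {
  if (mean_rr <= 0) abort("`mean_rr` must be positive.")
  if (duration <= 0) abort("`duration` must be positive.")
  if (amp_lf < 0 || amp_hf < 0 || noise_sd < 0) {
    abort("amplitudes and `noise_sd` must be nonnegative.")
  }
  if (amp_lf > 0 && (freq_lf < 0.04 || freq_lf > 0.15)) {
    abort("`freq_lf` must lie in the LF band [0.04, 0.15] Hz.")
  }
  if (amp_hf > 0 && (freq_hf < 0.15 || freq_hf > 0.4)) {
    abort("`freq_hf` must lie in the HF band [0.15, 0.4] Hz.")
  }
  if (amp_lf + amp_hf + noise_sd >= mean_rr) {
    abort(paste0(
      "amplitude budget too large: amp_lf + amp_hf + noise_sd (",
      amp_lf + amp_hf + noise_sd, " ms) must stay below mean_rr (", mean_rr,
      " ms) so no interval can be nonpositive."
    ))
  }
  structure(
    list(
      mean_rr = mean_rr, amp_lf = amp_lf, freq_lf = freq_lf,
      amp_hf = amp_hf, freq_hf = freq_hf, noise_sd = noise_sd,
      duration = duration, seed = as.integer(seed)
    ),
    class = "rr_modulation_spec"
  )
}

#' Generate an RR-interval series from a modulation spec
#'
#' Beat times are laid down iteratively: the interval starting at beat time
#' `t` is `mean_rr + amp_lf*sin(2*pi*freq_lf*t) + amp_hf*sin(2*pi*freq_hf*t)
#' + N(0, noise_sd)` ms, and the next beat follows that many milliseconds
#' later. Generation continues until the series covers at least `duration`
#' seconds. The analytic per-band modulation powers (`amp^2/2` ms^2) are
#' attached as the `ground_truth` attribute.
#'
#' @param spec An [rr_modulation_spec()].
#' @return An [rr_series()] tibble with attributes `ground_truth`
#'   (list of `lf_power`, `hf_power`, ms^2) and `spec`.
#' @examples
#' rr <- generate_rr(rr_modulation_spec(amp_lf = 30, amp_hf = 20, seed = 7))
#' attr(rr, "ground_truth")
#' @export
generate_rr <- function(spec) {
  stopifnot(inherits(spec, "rr_modulation_spec"))
  withr::with_seed(spec$seed, {
    # over-allocate: mean rate gives ~duration*1000/mean_rr beats
    n_max <- ceiling(spec$duration * 1000 / spec$mean_rr * 1.5) + 10L
    noise <- if (spec$noise_sd > 0) rnorm(n_max, 0, spec$noise_sd) else numeric(n_max)
    t <- 0
    rr <- numeric(n_max)
    tt <- numeric(n_max)
    k <- 0L
    while (t < spec$duration && k < n_max) {
      k <- k + 1L
      r <- spec$mean_rr +
        spec$amp_lf * sin(2 * pi * spec$freq_lf * t) +
        spec$amp_hf * sin(2 * pi * spec$freq_hf * t) +
        noise[k]
      if (r <= 0) {
        abort(paste0(
          "generated a nonpositive interval; the amplitude budget ",
          "(amp_lf + amp_hf + noise draws) exceeded mean_rr at beat ", k, "."
        ))
      }
      t <- t + r / 1000
      rr[k] <- r
      tt[k] <- t
    }
    out <- suppressWarnings(rr_series(tt[seq_len(k)], rr[seq_len(k)]))
    attr(out, "ground_truth") <- list(
      lf_power = spec$amp_lf^2 / 2,
      hf_power = spec$amp_hf^2 / 2
    )
    attr(out, "spec") <- spec
    out
  })
}

#' Inject ectopic-beat artifacts into an RR series
#'
#' Emulates premature (ectopic) beats as shorten/lengthen couplets: each
#' selected interval is shortened by `magnitude` of its value and the
#' following interval lengthened by the same absolute amount, so total
#' elapsed time is preserved exactly. This is the canonical corruption a
#' median filter removes.
#'
#' @param rr An [rr_series()].
#' @param rate Per-beat corruption probability, in `[0, 0.2)`.
#' @param magnitude Fraction of the interval removed, in `(0, 1)`.
#' @param seed Integer seed.
#' @return An [rr_series()] with attribute `corrupted_beats`: the indices of
#'   the shortened intervals.
#' @export
inject_ectopics <- function(rr, rate, magnitude = 0.3, seed = 1L) {
  if (nrow(rr) == 0) abort("cannot inject ectopics into an empty series.")
  if (rate < 0 || rate >= 0.2) abort("`rate` must lie in [0, 0.2).")
  if (magnitude <= 0 || magnitude >= 1) abort("`magnitude` must lie in (0, 1).")
  n <- nrow(rr)
  withr::with_seed(as.integer(seed), {
    hit <- which(rbinom(n - 1L, 1L, rate) == 1L) # last interval has no follower
  })
  new_rr <- rr$rr_ms
  delta <- magnitude * rr$rr_ms[hit] # from original values
  new_rr[hit] <- new_rr[hit] - delta
  new_rr[hit + 1L] <- new_rr[hit + 1L] + delta
  out <- suppressWarnings(
    rr_series(rr_origin(rr) + cumsum(new_rr) / 1000, new_rr)
  )
  attr(out, "corrupted_beats") <- hit
  attr(out, "ground_truth") <- attr(rr, "ground_truth")
  out
}

#' Synthesize a spiky single-lead ECG trace from beat times
#'
#' Places a narrow Gaussian "R-wave" template at each beat time on a uniform
#' grid, for driving [detect_r_peaks()] with inputs whose true beat times
#' are known. No morphological realism (P/T waves, baseline wander) is
#' attempted.
#'
#' @param beat_times Beat times, s.
#' @param rate Sampling rate, Hz (nominally 250).
#' @param spike_width SD of the Gaussian template, s.
#' @return A tibble of class `ecg_trace` with columns `t_s`, `amplitude`
#'   and attribute `rate`.
#' @export
synthesize_ecg <- function(beat_times, rate = 250, spike_width = 0.01) {
  t_grid <- seq(0, max(beat_times) + 0.5, by = 1 / rate)
  amp <- numeric(length(t_grid))
  for (bt in beat_times) {
    idx <- which(abs(t_grid - bt) < 5 * spike_width)
    amp[idx] <- amp[idx] + exp(-(t_grid[idx] - bt)^2 / (2 * spike_width^2))
  }
  structure(
    tibble(t_s = t_grid, amplitude = amp),
    class = c("ecg_trace", class(tibble())),
    rate = rate
  )
}
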