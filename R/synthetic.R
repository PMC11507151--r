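#' One channel's voltage series plus its clinical metadata
#'
#' Lightweight container tying a voltage series to the sampling rate and the
#' patient-level annotations (sex, age, brain region, hemisphere) that the
#' cohort stage groups on.
#'
#' @param x numeric voltage series.
#' @param fs sampling rate in Hz.
#' @param channel_id unique channel label.
#' @param patient_id patient label.
#' @param sex `"F"` or `"M"`.
#' @param age age in years.
#' @param region brain-region label.
#' @param hemisphere `"L"` or `"R"`.
#' @return Object of class `signal_record`.
#' @export
signal_record <- function(x, fs, channel_id, patient_id = NA_character_,
                          sex = NA_character_, age = NA_real_,
                          region = NA_character_, hemisphere = NA_character_) {
  stopifnot(is.numeric(x), length(x) >= 1L, fs > 0)
  structure(
    list(x = as.numeric(x), fs = fs, channel_id = as.character(channel_id),
         patient_id = as.character(patient_id), sex = as.character(sex),
         age = as.numeric(age), region = as.character(region),
         hemisphere = as.character(hemisphere)),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("signal_record %s: %d samples @ %g Hz (%.1f s), patient %s [%s, %s %s]\n",
              x$channel_id, length(x$x), x$fs, length(x$x) / x$fs,
              x$patient_id, x$sex, x$hemisphere, x$region))
  invisible(x)
}

# Run expr under a private RNG stream; caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derived sub-seed for (patient, channel) streams, kept below 2^31.
derive_seed <- function(seed, patient, channel) {
  ((seed %% 2147483647) * 1009 + patient * 131071 + channel * 8191) %% 2147483629
}

# Stationary Gaussian signal with expected power spectrum shape(f)^2:
# inverse FFT of shape(f) times an i.i.d. complex-Gaussian spectrum
# (Rayleigh amplitudes, uniform phases), standardized to sd 1. Randomizing
# amplitudes as well as phases matters: a deterministic amplitude spectrum
# would couple disjoint windows of one realization through a shared energy
# constraint and bias window-level statistics.
spectral_synthesis <- function(n, fs, shape, seed) {
  m <- n %/% 2L
  f <- (1:m) * fs / n
  amp <- shape(f)
  amp[!is.finite(amp)] <- 0
  z <- with_seed(seed, complex(real = rnorm(m), imaginary = rnorm(m)))
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  spec[2:(m + 1L)] <- amp * z
  if (n %% 2L == 0L) spec[m + 1L] <- 0  # real signal: drop the Nyquist bin
  idx <- 2:ceiling((n + 1L) / 2)
  spec[n + 2L - idx] <- Conj(spec[idx])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

#' Colored (power-law) noise
#'
#' Zero-mean unit-variance Gaussian noise whose power spectrum decays as
#' `f^(-beta)`, generated by spectral synthesis: inverse FFT of `f^(-beta/2)`
#' amplitudes with i.i.d. uniform random phases. `beta = 0` gives white
#' noise, `beta = 1` pink (1/f, the canonical broadband background of field
#' potentials), `beta = 2` brown noise. Deterministic for a fixed seed.
#'
#' @param n number of samples, `>= 2`.
#' @param fs sampling rate in Hz.
#' @param beta spectral exponent, `>= 0`.
#' @param seed integer seed.
#' @return Numeric series of length `n`.
#' @examples
#' x <- gen_colored_noise(2^12, fs = 200, beta = 1, seed = 1)
#' @export
gen_colored_noise <- function(n, fs, beta, seed) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  if (!is.numeric(beta) || beta < 0) stop("beta must be >= 0")
  n <- as.integer(n)
  spectral_synthesis(n, fs, function(f) f^(-beta / 2), seed)
}

#' Colored noise with a narrow-band oscillatory peak
#'
#' A colored-noise background (exponent `beta`) plus a band-limited
#' oscillation centred at `peak_freq`, emulating the theta/alpha spectral
#' peaks of wake iEEG. The peak is a Gaussian bump of width `peak_bw` (Hz,
#' standard deviation) in the amplitude spectrum, scaled so that the fraction
#' `peak_amplitude` of total signal variance sits in the oscillatory
#' component. With `peak_amplitude = 0` the output is identical to
#' [gen_colored_noise()] under the same seed.
#'
#' @inheritParams gen_colored_noise
#' @param peak_freq peak centre frequency in Hz, `0 < peak_freq < fs/2`.
#' @param peak_amplitude fraction of total variance in the peak, in `[0, 1)`.
#' @param peak_bw spectral width (sd) of the peak in Hz.
#' @return Numeric series of length `n`.
#' @export
gen_oscillatory_channel <- function(n, fs, beta, peak_freq, peak_amplitude,
                                    seed, peak_bw = 0.5) {
  if (!is.numeric(peak_freq) || peak_freq <= 0 || peak_freq >= fs / 2)
    stop("peak_freq must lie in (0, fs/2)")
  if (peak_amplitude < 0 || peak_amplitude >= 1)
    stop("peak_amplitude must lie in [0, 1)")
  if (peak_amplitude == 0) return(gen_colored_noise(n, fs, beta, seed))
  if (!is.numeric(beta) || beta < 0) stop("beta must be >= 0")
  n <- as.integer(n)
  shape <- function(f) {
    bg2 <- f^(-beta)
    bg2 <- bg2 / sum(bg2)
    pk2 <- exp(-(f - peak_freq)^2 / (2 * peak_bw^2))
    pk2 <- pk2 / sum(pk2)
    sqrt((1 - peak_amplitude) * bg2 + peak_amplitude * pk2)
  }
  spectral_synthesis(n, fs, shape, seed)
}

#' Logistic-map series
#'
#' Iterates `x_{t+1} = r * x_t * (1 - x_t)` from `x0`, discarding `burn_in`
#' initial samples. At `r = 4` the map is fully chaotic; its ordinal
#' structure (e.g. the forbidden strictly-decreasing triple at `D = 3`) makes
#' it the standard deterministic fixture for ordinal-pattern analysis.
#'
#' @param n samples returned after burn-in.
#' @param r map parameter, `0 < r <= 4`.
#' @param x0 initial value in `(0, 1)`.
#' @param burn_in samples discarded before recording.
#' @return Numeric series of length `n`.
#' @examples
#' gen_logistic_map(5, r = 4, x0 = 0.3)
#' @export
gen_logistic_map <- function(n, r = 4, x0 = 0.3, burn_in = 0L) {
  if (!is.numeric(x0) || x0 <= 0 || x0 >= 1) stop("x0 must lie in (0, 1)")
  if (!is.numeric(r) || r <= 0 || r > 4) stop("r must lie in (0, 4]")
  if (n < 1) stop("n must be >= 1")
  burn_in <- as.integer(burn_in)
  total <- as.integer(n) + burn_in
  x <- numeric(total)
  x[1] <- x0
  for (t in seq_len(total - 1L)) x[t + 1L] <- r * x[t] * (1 - x[t])
  x[(burn_in + 1L):total]
}

#' Controlled group effect for a synthetic cohort
#'
#' Per-sex generative parameters: spectral exponent of the 1/f-like
#' background, centre frequency of the oscillatory peak, the variance
#' fraction carried by the peak, and the length of the trailing zero-pad
#' (emulating records zero-padded to a fixed length). Identical female/male
#' values (the default) encode the null of no sex difference.
#'
#' @param beta_female,beta_male spectral exponents, `>= 0`.
#' @param peak_freq_female,peak_freq_male peak frequencies in Hz.
#' @param peak_amplitude variance fraction of the peak, `[0, 1)`.
#' @param pad_tail_s trailing seconds of exact zeros.
#' @return Object of class `group_effect`.
#' @export
group_effect <- function(beta_female = 1, beta_male = 1,
                         peak_freq_female = 8, peak_freq_male = 8,
                         peak_amplitude = 0.3, pad_tail_s = 8) {
  if (beta_female < 0 || beta_male < 0) stop("beta must be >= 0")
  if (peak_amplitude < 0 || peak_amplitude >= 1)
    stop("peak_amplitude must lie in [0, 1)")
  if (pad_tail_s < 0) stop("pad_tail_s must be >= 0")
  structure(
    list(beta_female = beta_female, beta_male = beta_male,
         peak_freq_female = peak_freq_female, peak_freq_male = peak_freq_male,
         peak_amplitude = peak_amplitude, pad_tail_s = pad_tail_s),
    class = "group_effect"
  )
}

#' Specification of a synthetic iEEG cohort
#'
#' Describes one region/hemisphere cell of a cohort: patient counts per sex,
#' channels per patient, record length and sampling rate, per-sex age laws,
#' and the generative [group_effect()]. Defaults mirror the structure of a
#' wake iEEG atlas record: 68 s at 200 Hz with an 8 s zero-padded tail
#' (13,600 samples per channel), five patients per sex (the minimum cohort
#' eligibility), two channels per patient, and ages drawn from normal laws
#' truncated to 18-65 years and rounded to whole years.
#'
#' @param n_female_patients,n_male_patients patient counts, `>= 0`.
#' @param channels_per_patient channels recorded per patient, `>= 1`.
#' @param region_label brain-region label.
#' @param hemisphere `"L"` or `"R"`.
#' @param duration_s record length in seconds (including any zero-pad tail).
#' @param fs sampling rate in Hz.
#' @param age_law_female,age_law_male `c(mean, sd)` of the age law in years.
#' @param effect a [group_effect()].
#' @param seed integer master seed; each (patient, channel) gets a derived
#'   private stream so generation is independent of insertion order.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_female_patients = 5, n_male_patients = 5,
                        channels_per_patient = 2,
                        region_label = "supramarginal gyrus",
                        hemisphere = "L", duration_s = 68, fs = 200,
                        age_law_female = c(30, 10), age_law_male = c(35, 10),
                        effect = group_effect(), seed = 1L) {
  stopifnot(n_female_patients >= 0, n_male_patients >= 0,
            channels_per_patient >= 1, duration_s > 0, fs > 0,
            hemisphere %in% c("L", "R"), inherits(effect, "group_effect"))
  if (effect$pad_tail_s >= duration_s) stop("pad_tail_s must be < duration_s")
  if (effect$peak_freq_female >= fs / 2 || effect$peak_freq_male >= fs / 2)
    stop("peak frequencies must be < fs/2")
  structure(
    list(n_female_patients = as.integer(n_female_patients),
         n_male_patients = as.integer(n_male_patients),
         channels_per_patient = as.integer(channels_per_patient),
         region_label = region_label, hemisphere = hemisphere,
         duration_s = duration_s, fs = fs,
         age_law_female = age_law_female, age_law_male = age_law_male,
         effect = effect, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Truncated-normal age, rounded to whole years.
draw_age <- function(law, seed) {
  with_seed(seed, {
    repeat {
      a <- rnorm(1, law[1], law[2])
      if (a >= 18 && a <= 65) return(round(a))
    }
  })
}

#' Generate a synthetic iEEG cohort
#'
#' Realizes a [cohort_spec()]: for every patient and channel, a colored-noise
#' background with a narrow-band oscillatory peak (parameters from the
#' per-sex [group_effect()]), followed by `pad_tail_s` seconds of exact
#' zeros, plus one metadata row per channel. Patient ids are `F01, F02, ...`
#' and `M01, ...`; every (patient, channel) pair draws from a private RNG
#' stream derived from the master seed, so results are reproducible and
#' insertion-order independent.
#'
#' @param spec a [cohort_spec()].
#' @return List with `records` (list of [signal_record()]) and `metadata`
#'   (`data.frame` with columns `patient_id`, `sex`, `age`, `region`,
#'   `hemisphere`, `channel_id`, `fs_hz`).
#' @examples
#' coh <- gen_cohort(cohort_spec(seed = 7))
#' length(coh$records)   # 5 F + 5 M patients x 2 channels = 20
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  eff <- spec$effect
  n_total <- as.integer(round(spec$duration_s * spec$fs))
  n_pad <- as.integer(round(eff$pad_tail_s * spec$fs))
  n_active <- n_total - n_pad
  records <- list()
  meta <- list()
  k <- 0L
  for (sex in c("F", "M")) {
    n_pat <- if (sex == "F") spec$n_female_patients else spec$n_male_patients
    beta <- if (sex == "F") eff$beta_female else eff$beta_male
    pfreq <- if (sex == "F") eff$peak_freq_female else eff$peak_freq_male
    law <- if (sex == "F") spec$age_law_female else spec$age_law_male
    p_off <- if (sex == "F") 0L else 1000L
    for (p in seq_len(n_pat)) {
      pid <- sprintf("%s%02d", sex, p)
      age <- draw_age(law, derive_seed(spec$seed, p_off + p, 0L))
      for (ch in seq_len(spec$channels_per_patient)) {
        cid <- sprintf("%s_ch%02d", pid, ch)
        x <- gen_oscillatory_channel(
          n_active, spec$fs, beta, pfreq, eff$peak_amplitude,
          seed = derive_seed(spec$seed, p_off + p, ch))
        if (n_pad > 0L) x <- c(x, rep(0, n_pad))
        k <- k + 1L
        records[[k]] <- signal_record(
          x, spec$fs, channel_id = cid, patient_id = pid, sex = sex,
          age = age, region = spec$region_label, hemisphere = spec$hemisphere)
        meta[[k]] <- data.frame(
          patient_id = pid, sex = sex, age = age, region = spec$region_label,
          hemisphere = spec$hemisphere, channel_id = cid, fs_hz = spec$fs,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(records = records, metadata = do.call(rbind, meta))
}
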