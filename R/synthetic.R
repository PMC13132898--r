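# Synthetic cohort generator: multi-channel EEG-like recordings plus
# subjective fatigue scores with the statistical structure the downstream
# analysis assumes (band-limited oscillations on a 1/f background, fatigue-
# dependent theta/alpha power increase and complexity decrease, scores that
# rise with task intensity and per-subject susceptibility).

#' Construct a subject profile for the synthetic generator
#'
#' A profile fixes everything subject-specific: baseline relative band powers,
#' susceptibility to physically and mentally induced fatigue, measurement
#' noise, and which channels carry the fatigue signature.
#'
#' @param subject_id Character subject identifier.
#' @param baseline_band_weights Named non-negative numeric vector of relative
#'   band powers for `delta`, `theta`, `alpha`, `beta`; must sum to a positive
#'   finite value.
#' @param fatigue_gain_physical,fatigue_gain_mental Unitless gains `>= 0`
#'   scaling the spectral/complexity shift injected during the physical (s2)
#'   and mental (s3) task events.
#' @param noise_scale Unitless `> 0`; scales both the 1/f + white signal noise
#'   and the subjective-score noise.
#' @param channel_gains Named positive numeric vector over exactly
#'   `TP9, AF7, AF8, TP10`: per-channel gain on the fatigue signature
#'   (informative channels get gain near 1, uninformative ones near 0).
#' @param channel_gains_mental Optional separate channel-gain map for the
#'   mental-task signature; defaults to `channel_gains`. Lets a cohort place
#'   the physical and mental signatures on different electrodes.
#' @param score_baseline Subjective fatigue score in the non-fatigued state,
#'   on the 0-100 scale the generator uses (see vignette).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            baseline_band_weights = c(delta = 1, theta = 0.6,
                                                      alpha = 0.8, beta = 0.4),
                            fatigue_gain_physical = 1,
                            fatigue_gain_mental = 1,
                            noise_scale = 1,
                            channel_gains = c(TP9 = 1, AF7 = 1,
                                              AF8 = 0.2, TP10 = 0.2),
                            channel_gains_mental = NULL,
                            score_baseline = 15) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  bands <- c("delta", "theta", "alpha", "beta")
  if (!setequal(names(baseline_band_weights), bands)) {
    stop_ef("baseline_band_weights must be named over %s", paste(bands, collapse = ", "))
  }
  baseline_band_weights <- baseline_band_weights[bands]
  if (any(!is.finite(baseline_band_weights)) || any(baseline_band_weights < 0) ||
      sum(baseline_band_weights) <= 0) {
    stop_ef("band weights must be finite, non-negative, with positive sum")
  }
  check_number(fatigue_gain_physical, "fatigue_gain_physical", lower = 0)
  check_number(fatigue_gain_mental, "fatigue_gain_mental", lower = 0)
  check_number(noise_scale, "noise_scale", lower = 0, strict = TRUE)
  if (!setequal(names(channel_gains), eeg_channels())) {
    stop_ef("channel_gains must be named over exactly %s",
            paste(eeg_channels(), collapse = ", "))
  }
  channel_gains <- channel_gains[eeg_channels()]
  if (any(!is.finite(channel_gains)) || any(channel_gains <= 0)) {
    stop_ef("channel_gains must be finite and > 0")
  }
  if (is.null(channel_gains_mental)) {
    channel_gains_mental <- channel_gains
  } else {
    if (!setequal(names(channel_gains_mental), eeg_channels())) {
      stop_ef("channel_gains_mental must be named over exactly %s",
              paste(eeg_channels(), collapse = ", "))
    }
    channel_gains_mental <- channel_gains_mental[eeg_channels()]
    if (any(!is.finite(channel_gains_mental)) || any(channel_gains_mental <= 0)) {
      stop_ef("channel_gains_mental must be finite and > 0")
    }
  }
  check_number(score_baseline, "score_baseline", lower = 0)
  structure(
    list(subject_id = subject_id,
         baseline_band_weights = baseline_band_weights,
         fatigue_gain_physical = fatigue_gain_physical,
         fatigue_gain_mental = fatigue_gain_mental,
         noise_scale = noise_scale,
         channel_gains = channel_gains,
         channel_gains_mental = channel_gains_mental,
         score_baseline = score_baseline),
    class = "subject_profile"
  )
}

#' Construct a session plan
#'
#' One session is the ordered event schedule s1, m1, s2, m2, s3, m3 with the
#' fixed durations 180, 120, 180, 120, `s3_duration_s`, 120 seconds at 256 Hz.
#' The s3 (mental task) block is the only variable-length event, up to 900 s.
#'
#' @param session_index Integer 1..3.
#' @param intensity Physical-task intensity for this session, one of
#'   `"low"`, `"medium"`, `"high"` (sessions are run on three days at
#'   increasing treadmill intensity).
#' @param s3_duration_s Duration of the mental task event in seconds
#'   (0 to 900; default 540).
#' @return An object of class `session_plan` with the event schedule.
#' @export
session_plan <- function(session_index,
                         intensity = c("low", "medium", "high"),
                         s3_duration_s = 540) {
  intensity <- match.arg(intensity)
  session_index <- as.integer(session_index)
  if (is.na(session_index) || session_index < 1L || session_index > 3L) {
    stop_ef("session_index must be 1, 2 or 3")
  }
  check_number(s3_duration_s, "s3_duration_s", lower = 0)
  if (s3_duration_s > 900) stop_ef("s3_duration_s must be <= 900 s")
  schedule <- data.frame(
    event = c("s1", "m1", "s2", "m2", "s3", "m3"),
    duration_s = c(180, 120, 180, 120, s3_duration_s, 120),
    stringsAsFactors = FALSE
  )
  structure(
    list(session_index = session_index,
         intensity = intensity,
         event_schedule = schedule,
         sampling_rate = EEG_FS),
    class = "session_plan"
  )
}

#' Default three-session plan set (low, medium, high intensity)
#'
#' @param s3_duration_s Mental-task duration shared by all sessions (default
#'   540 s, i.e. 9 minutes of the "up to 15 min" block).
#' @return List of three `session_plan` objects.
#' @export
default_session_plans <- function(s3_duration_s = 540) {
  list(session_plan(1L, "low", s3_duration_s),
       session_plan(2L, "medium", s3_duration_s),
       session_plan(3L, "high", s3_duration_s))
}

intensity_level <- function(intensity) {
  c(low = 1, medium = 2, high = 3)[[intensity]]
}

plan_total_samples <- function(plan) {
  as.integer(round(sum(plan$event_schedule$duration_s) * plan$sampling_rate))
}

# Sample ranges (0-based half-open) of each scheduled event.
plan_event_ranges <- function(plan) {
  dur <- plan$event_schedule$duration_s
  if (any(!is.finite(dur)) || any(dur < 0) || plan$sampling_rate <= 0) {
    stop_ef("schedule error: durations must be finite and >= 0, sampling rate > 0")
  }
  ends <- cumsum(dur) * plan$sampling_rate
  starts <- c(0, ends[-length(ends)])
  data.frame(event = plan$event_schedule$event,
             start_sample = as.integer(round(starts)),
             end_sample = as.integer(round(ends)),
             stringsAsFactors = FALSE)
}

# Synthesize unit-variance Gaussian noise with a prescribed spectral amplitude
# profile directly in the frequency domain (complex Gaussian coefficients on
# the positive-frequency bins, Hermitian completion, one inverse FFT).
spectral_noise <- function(n, amp_at) {
  half <- (n - 1L) %/% 2L # strictly positive, non-Nyquist bins
  freqs <- (seq_len(half)) * 1 # bin indices; caller converts to Hz
  spec <- complex(n)
  a <- amp_at(freqs)
  nz <- which(a > 0)
  if (length(nz)) {
    z <- complex(real = rnorm(length(nz)), imaginary = rnorm(length(nz))) * a[nz]
    spec[nz + 1L] <- z
    spec[n + 1L - nz] <- Conj(z)
  }
  y <- Re(fft(spec, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# Unit-variance band-limited Gaussian noise, or a pure tone at the band centre
# (tone mode underpins the spectral-placement checks).
band_component <- function(n, f_lo, f_hi, fs, mode = "noise") {
  if (mode == "tone") {
    fc <- (f_lo + f_hi) / 2
    phase <- runif(1, 0, 2 * pi)
    return(sqrt(2) * sin(2 * pi * fc * seq_len(n) / fs + phase))
  }
  spectral_noise(n, function(bins) {
    f <- bins * fs / n
    as.numeric(f >= f_lo & f < f_hi)
  })
}

# Unit-variance 1/f (pink) noise via spectral shaping.
pink_noise <- function(n, fs) {
  spectral_noise(n, function(bins) 1 / sqrt(bins * fs / n))
}

moving_average <- function(x, k) {
  # centred moving average, edges padded by replication
  n <- length(x)
  xp <- c(rep(x[1], k %/% 2), x, rep(x[n], k %/% 2))
  stats::filter(xp, rep(1 / k, k), sides = 2)[(k %/% 2 + 1):(k %/% 2 + n)]
}

BAND_EDGES <- list(delta = c(0.4, 4), theta = c(4, 8),
                   alpha = c(8, 12), beta = c(12, 30))

#' Generate one synthetic subject-session EEG recording
#'
#' Each channel is a sum of four band-limited oscillations (delta, theta,
#' alpha, beta) on a pink + white noise background. During the physical task
#' (s2) the theta and alpha weights are raised and a moving-average smoothing
#' is blended in, both in proportion to
#' `fatigue_gain_physical x intensity x channel_gain`; during the mental task
#' (s3) likewise with `fatigue_gain_mental`. Identical
#' `(profile, plan, seed)` give bit-identical samples.
#'
#' @param profile A [subject_profile()].
#' @param plan A [session_plan()].
#' @param seed Integer seed.
#' @param band_mode `"noise"` (band-limited Gaussian noise, default) or
#'   `"tone"` (one pure sinusoid at each band centre; used for spectral
#'   calibration checks).
#' @return An object of class `eeg_recording`: list with `subject_id`,
#'   `session_index`, `sampling_rate`, `total_duration_s` and `channels`
#'   (named list of equal-length numeric vectors).
#' @export
generate_recording <- function(profile, plan, seed, band_mode = c("noise", "tone")) {
  stopifnot(inherits(profile, "subject_profile"), inherits(plan, "session_plan"))
  band_mode <- match.arg(band_mode)
  ranges <- plan_event_ranges(plan)
  n <- plan_total_samples(plan)
  if (n <= 0) stop_ef("schedule error: total duration must be positive")
  fs <- plan$sampling_rate
  ilev <- intensity_level(plan$intensity)
  idx_of <- function(ev) {
    r <- ranges[ranges$event == ev, ]
    if (r$end_sample > r$start_sample) (r$start_sample + 1L):r$end_sample else integer(0)
  }
  s2_idx <- idx_of("s2")
  s3_idx <- idx_of("s3")

  channels <- lapply(eeg_channels(), function(ch) {
    g_ch <- profile$channel_gains[[ch]]
    g_ch_m <- profile$channel_gains_mental[[ch]]
    with_seed(derive_seed(seed, "chan", ch), {
      comp <- lapply(names(BAND_EDGES), function(b) {
        e <- BAND_EDGES[[b]]
        band_component(n, e[1], e[2], fs, mode = band_mode)
      })
      names(comp) <- names(BAND_EDGES)
      w <- profile$baseline_band_weights
      x <- numeric(n)
      for (b in names(comp)) {
        wt <- rep(w[[b]], n)
        if (b %in% c("theta", "alpha")) {
          wt[s2_idx] <- wt[s2_idx] *
            (1 + 0.6 * profile$fatigue_gain_physical * ilev * g_ch)
          wt[s3_idx] <- wt[s3_idx] *
            (1 + 0.6 * profile$fatigue_gain_mental * g_ch_m)
        }
        x <- x + sqrt(wt) * comp[[b]]
      }
      if (profile$noise_scale > 0) {
        x <- x + profile$noise_scale *
          (sqrt(0.8) * pink_noise(n, fs) + sqrt(0.2) * rnorm(n))
      }
      # complexity reduction: blend towards a smoothed copy during task events
      sm <- moving_average(x, 5L)
      lam_p <- min(0.9, 0.2 * profile$fatigue_gain_physical * ilev * g_ch)
      lam_m <- min(0.9, 0.2 * profile$fatigue_gain_mental * g_ch_m)
      if (length(s2_idx)) x[s2_idx] <- (1 - lam_p) * x[s2_idx] + lam_p * sm[s2_idx]
      if (length(s3_idx)) x[s3_idx] <- (1 - lam_m) * x[s3_idx] + lam_m * sm[s3_idx]
      x
    })
  })
  names(channels) <- eeg_channels()

  structure(
    list(subject_id = profile$subject_id,
         session_index = plan$session_index,
         sampling_rate = fs,
         total_duration_s = n / fs,
         channels = channels),
    class = "eeg_recording"
  )
}

#' Generate subjective fatigue scores for one subject-session
#'
#' Scores live on a 0-100 scale. The baseline (s1) score is the profile's
#' `score_baseline`; the physical (s2) score adds
#' `12 x intensity x fatigue_gain_physical`; the mental (s3) score adds
#' `25 x fatigue_gain_mental` (the mental task protocol does not change across
#' sessions). Gaussian noise with sd `3 x noise_scale` is added to each score
#' and results are clamped at 0.
#'
#' @inheritParams generate_recording
#' @return A data.frame with columns `subject`, `session`, `event`
#'   (`s1`, `s2`, `s3`) and `score`.
#' @export
generate_scores <- function(profile, plan, seed) {
  stopifnot(inherits(profile, "subject_profile"), inherits(plan, "session_plan"))
  plan_event_ranges(plan) # validates schedule
  ilev <- intensity_level(plan$intensity)
  mu <- c(
    s1 = profile$score_baseline,
    s2 = profile$score_baseline + 12 * ilev * profile$fatigue_gain_physical,
    s3 = profile$score_baseline + 25 * profile$fatigue_gain_mental
  )
  noise <- with_seed(derive_seed(seed, "scores"), rnorm(3, 0, 3 * profile$noise_scale))
  data.frame(
    subject = profile$subject_id,
    session = plan$session_index,
    event = names(mu),
    score = pmax(0, unname(mu) + noise),
    stringsAsFactors = FALSE
  )
}

#' Draw a cohort of heterogeneous subject profiles
#'
#' Per-subject fatigue gains are lognormal around `gain_mean` with log-sd
#' `gain_sd`, and band weights get mild lognormal jitter, so that subjects
#' differ both in susceptibility (which drives their subjective scores) and in
#' the strength of the EEG signature (which drives the features) - the
#' between-subject structure leave-one-subject-out validation exercises.
#'
#' @param n_subjects Number of subjects (`>= 2`).
#' @param seed Integer seed.
#' @param gain_mean,gain_sd Lognormal location/scale of the per-subject
#'   physical and mental fatigue gains.
#' @param noise_scale Shared noise scale passed to each profile.
#' @param channel_gains Shared channel-gain map (which channels are
#'   informative); see [subject_profile()].
#' @return List of `subject_profile` objects with ids `"S01"`, `"S02"`, ...
#' @export
cohort_profiles <- function(n_subjects, seed,
                            gain_mean = 1, gain_sd = 0.4, noise_scale = 1,
                            channel_gains = c(TP9 = 1, AF7 = 1,
                                              AF8 = 0.2, TP10 = 0.2)) {
  lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("S%02d", i)
    with_seed(derive_seed(seed, "profile", sid), {
      gains <- gain_mean * exp(rnorm(2, 0, gain_sd))
      jitter <- exp(rnorm(4, 0, 0.1))
      subject_profile(
        subject_id = sid,
        baseline_band_weights = c(delta = 1, theta = 0.6,
                                  alpha = 0.8, beta = 0.4) * jitter,
        fatigue_gain_physical = gains[1],
        fatigue_gain_mental = gains[2],
        noise_scale = noise_scale,
        channel_gains = channel_gains
      )
    })
  })
}

#' Generate a full synthetic cohort
#'
#' Builds `n_subjects` profiles, derives one seed per subject-session from the
#' master seed, generates all subjective scores, and returns a self-describing
#' cohort whose recordings are regenerated deterministically on demand with
#' [cohort_recording()] (recordings are large; holding a full default cohort
#' in memory would be wasteful).
#'
#' @param n_subjects Number of subjects, `>= 2` (subject-independent
#'   validation needs at least two); default 12.
#' @param plans List of [session_plan()]s, default the three-session
#'   low/medium/high set.
#' @param master_seed Integer master seed; every random consumer receives a
#'   seed derived from it via [derive_seed()].
#' @param ... Passed to [cohort_profiles()] (`gain_mean`, `gain_sd`,
#'   `noise_scale`, `channel_gains`).
#' @param profiles Optional explicit list of profiles (overrides `...`).
#' @return Object of class `eeg_cohort`: `profiles`, `plans`, `scores`
#'   (data.frame over all subject-session-events), `manifest`, `master_seed`.
#' @export
generate_cohort <- function(n_subjects = 12, plans = default_session_plans(),
                            master_seed = 1, ..., profiles = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) {
    stop_ef("configuration error: n_subjects must be >= 2 (LOSO needs >= 2 subjects)")
  }
  stopifnot(length(plans) >= 1L, all(vapply(plans, inherits, TRUE, "session_plan")))
  if (is.null(profiles)) {
    profiles <- cohort_profiles(n_subjects, derive_seed(master_seed, "profiles"), ...)
  }
  stopifnot(length(profiles) == n_subjects)
  scores <- do.call(rbind, lapply(profiles, function(pr) {
    do.call(rbind, lapply(plans, function(pl) {
      generate_scores(pr, pl, derive_seed(master_seed, "scores", pr$subject_id,
                                          pl$session_index))
    }))
  }))
  manifest <- list(
    n_subjects = n_subjects,
    subjects = vapply(profiles, `[[`, character(1), "subject_id"),
    sampling_rate = EEG_FS,
    master_seed = master_seed,
    sessions = lapply(plans, function(pl) {
      list(session_index = pl$session_index, intensity = pl$intensity,
           durations_s = pl$event_schedule$duration_s,
           total_duration_s = sum(pl$event_schedule$duration_s))
    })
  )
  structure(
    list(profiles = profiles, plans = plans, scores = scores,
         manifest = manifest, master_seed = master_seed),
    class = "eeg_cohort"
  )
}

#' Regenerate one recording of a cohort
#'
#' @param cohort An [generate_cohort()] object.
#' @param subject_id Subject identifier (e.g. `"S03"`).
#' @param session_index Session 1..3 (must be one of the cohort's plans).
#' @param band_mode Passed to [generate_recording()].
#' @return An `eeg_recording`.
#' @export
cohort_recording <- function(cohort, subject_id, session_index,
                             band_mode = "noise") {
  stopifnot(inherits(cohort, "eeg_cohort"))
  ids <- vapply(cohort$profiles, `[[`, character(1), "subject_id")
  i <- match(subject_id, ids)
  if (is.na(i)) stop_ef("unknown subject '%s'", subject_id)
  sess <- vapply(cohort$plans, `[[`, integer(1), "session_index")
  j <- match(as.integer(session_index), sess)
  if (is.na(j)) stop_ef("unknown session %s", session_index)
  generate_recording(cohort$profiles[[i]], cohort$plans[[j]],
                     derive_seed(cohort$master_seed, "rec", subject_id, session_index),
                     band_mode = band_mode)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Per-session recordings as CSV (`timestamp_s, TP9, AF7, AF8, TP10`), scores
#' as one `scores.csv`, the manifest as `manifest.json`.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if needed).
#' @param recordings Write the (large) per-session signal CSVs too? Default
#'   TRUE; set FALSE to write only scores and manifest.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir, recordings = TRUE) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (recordings) {
    for (sid in cohort$manifest$subjects) {
      for (pl in cohort$plans) {
        rec <- cohort_recording(cohort, sid, pl$session_index)
        write_recording(rec, file.path(dir, sprintf("%s_session%d.csv", sid,
                                                    pl$session_index)))
      }
    }
  }
  invisible(dir)
}

#' Write a single recording as CSV
#'
#' @param recording An `eeg_recording`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- length(recording$channels[[1]])
  df <- data.frame(timestamp_s = (seq_len(n) - 1) / recording$sampling_rate)
  for (ch in names(recording$channels)) df[[ch]] <- recording$channels[[ch]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects x %d sessions (master_seed %d)\n",
              x$manifest$n_subjects, length(x$plans), x$master_seed))
  invisible(x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s session %d: %d channels x %d samples (%.0f s @ %d Hz)\n",
              x$subject_id, x$session_index, length(x$channels),
              length(x$channels[[1]]), x$total_duration_s, x$sampling_rate))
  invisible(x)
}
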