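# Shared fixtures, all generated in code. Simulation sizes are scaled down
# relative to the full default cohort (12 x 3 sessions, 540 s mental task)
# to fit the test-time budget; the scaling is in session count, mental-task
# duration and windows-per-event only, never in the event layout or the
# feature definitions.

quick_plan <- function(s3 = 60, intensity = "high", session = 3L) {
  session_plan(session, intensity, s3_duration_s = s3)
}

# A bare recording object with known-length channels (for segmentation tests
# that only need lengths, not realistic signals).
fake_recording <- function(duration_s, fill = 0) {
  n <- as.integer(duration_s * 256)
  channels <- lapply(eeg_channels(), function(ch) rep(fill, n))
  names(channels) <- eeg_channels()
  structure(list(subject_id = "SX", session_index = 1L, sampling_rate = 256L,
                 total_duration_s = duration_s, channels = channels),
            class = "eeg_recording")
}

# Strong-effect cohort profiles: a two-level susceptibility mixture
# (alternating high/low responders). See the vignette for why "strong
# effects" is a gain split rather than a uniform gain raise: labels derive
# from thresholds at the cohort score mean, so scaling all gains together
# recentres the threshold and leaves borderline subjects borderline.
strong_profiles <- function(n, seed, hi = 3.2, lo = 0.8, noise = 0.3,
                            channel_gains = c(TP9 = 1, AF7 = 1,
                                              AF8 = 0.2, TP10 = 0.2),
                            channel_gains_mental = NULL) {
  lapply(seq_len(n), function(i) {
    g <- if (i %% 2 == 1) hi else lo
    eegfatigue:::with_seed(derive_seed(seed, "prof", i), {
      jit <- exp(rnorm(4, 0, 0.1))
      subject_profile(sprintf("S%02d", i),
        baseline_band_weights = c(delta = 1, theta = 0.6,
                                  alpha = 0.8, beta = 0.4) * jit,
        fatigue_gain_physical = g, fatigue_gain_mental = g,
        noise_scale = noise, channel_gains = channel_gains,
        channel_gains_mental = channel_gains_mental)
    })
  })
}

# The channel-recovery world: the physical signature lives on TP9, the mental
# signature on AF7, nothing informative elsewhere - so no single channel can
# detect all fatigued rows and the top-ranked combination must contain both.
# Cross-gains must be truly inert (0.003 => <2% band-power shift, below the
# window-averaged feature noise); at 0.05 the high-intensity product
# 0.6 x 3.2 x 3 x 0.05 still shifts power by ~30%, which is learnable.
split_signature_profiles <- function(n, seed, ...) {
  eps <- 0.003
  strong_profiles(
    n, seed, ...,
    channel_gains = c(TP9 = 1, AF7 = eps, AF8 = eps, TP10 = eps),
    channel_gains_mental = c(TP9 = eps, AF7 = 1, AF8 = eps, TP10 = eps))
}

strong_cohort <- function(n = 12, seed = 1, s3 = 60, ...) {
  generate_cohort(n, list(quick_plan(s3)), master_seed = seed,
                  profiles = strong_profiles(n, seed, ...))
}

# A modelling-shaped random feature table + scores without any signal
# generation (fast path for labelling/modelling/evaluation unit tests).
random_feature_table <- function(n_subjects, sessions = 1:3, seed = 1,
                                 channels = eeg_channels(),
                                 events = c("s1", "s2", "s3")) {
  eegfatigue:::with_seed(seed, {
    keys <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                        session = sessions, channel = channels,
                        event = events, stringsAsFactors = FALSE)
    feats <- matrix(rnorm(nrow(keys) * 16), nrow(keys), 16,
                    dimnames = list(NULL, feature_names()))
    cbind(keys, as.data.frame(feats))
  })
}

random_scores <- function(n_subjects, sessions = 1:3, seed = 1, mean = 40, sd = 15) {
  eegfatigue:::with_seed(seed, {
    keys <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                        session = sessions, event = c("s1", "s2", "s3"),
                        stringsAsFactors = FALSE)
    keys$score <- pmax(0, rnorm(nrow(keys), mean, sd))
    keys
  })
}

# A small labelled table whose features carry the label signal (separable up
# to `noise`); used for classifier-behaviour and pipeline-property tests.
separable_table <- function(n_subjects = 6, sessions = 1:2, seed = 1,
                            channels = c("TP9", "AF7"), noise = 0.1) {
  ft <- random_feature_table(n_subjects, sessions, seed, channels)
  sc <- random_scores(n_subjects, sessions, seed + 1)
  tab <- build_modelling_table(ft, sc, label_policy(physical_threshold = 40,
                                                    mental_threshold = 40),
                               channels = channels)
  cols <- feature_columns(channels)
  eegfatigue:::with_seed(seed + 2, {
    shift <- matrix(rnorm(nrow(tab) * length(cols), sd = noise),
                    nrow(tab), length(cols))
    tab[, cols] <- shift + 3 * tab$label
  })
  tab
}
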