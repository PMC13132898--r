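# The 16-feature battery computed on each 2560-sample window:
# statistical moments (Mean, SD, Kur, SK), seven entropies (SE, FE, SnE, RE,
# PE, DE, SVDE) and five spectral quantities (four band powers + SpE).

#' Canonical feature names, in their fixed order
#' @return Character vector of length 16.
#' @export
feature_names <- function() {
  c("Mean", "SD", "Kur", "SK",
    "SE", "FE", "SnE", "RE", "PE", "DE", "SVDE",
    "delta_power", "theta_power", "alpha_power", "beta_power", "SpE")
}

#' The three feature groups
#'
#' @return Named list: `statistical` (4 features), `entropy` (7),
#'   `frequency` (5).
#' @export
feature_groups <- function() {
  list(
    statistical = c("Mean", "SD", "Kur", "SK"),
    entropy = c("SE", "FE", "SnE", "RE", "PE", "DE", "SVDE"),
    frequency = c("delta_power", "theta_power", "alpha_power", "beta_power", "SpE")
  )
}

#' Feature-extraction parameters
#'
#' Hyperparameters of the entropy and spectral estimators. Defaults follow
#' the common choices of the driver-fatigue EEG literature; every value is
#' overridable. Tolerances for SE/FE are expressed as a fraction `r` of the
#' segment's (population) standard deviation.
#'
#' @param m Embedding dimension for sample/fuzzy entropy (`>= 1`).
#' @param r Tolerance fraction (`> 0`); tolerance = `r * SD(segment)`.
#' @param pe_order,pe_delay Ordinal-pattern order and delay for permutation
#'   entropy.
#' @param renyi_alpha Renyi order `alpha > 0`, `!= 1`.
#' @param histogram_bins Equal-width amplitude histogram bins (`>= 2`) for
#'   SnE/RE/DE.
#' @param svd_embed_dim,svd_delay Delay-embedding dimension and delay for SVD
#'   entropy.
#' @param bands Named list of `c(f_low, f_high)` band edges in Hz
#'   (half-open `[f_low, f_high)`).
#' @param welch_nperseg,welch_overlap Welch estimator settings: per-window
#'   length in samples and fractional overlap.
#' @param spectral_range Analysis range (Hz) over which the PSD is normalised
#'   for spectral entropy.
#' @return Object of class `feature_params`.
#' @export
feature_params <- function(m = 2L, r = 0.2, pe_order = 3L, pe_delay = 1L,
                           renyi_alpha = 2, histogram_bins = 64L,
                           svd_embed_dim = 10L, svd_delay = 1L,
                           bands = list(delta = c(0.4, 4), theta = c(4, 8),
                                        alpha = c(8, 12), beta = c(12, 30)),
                           welch_nperseg = 256L, welch_overlap = 0.5,
                           spectral_range = c(0.4, 30)) {
  check_number(m, "m", lower = 1)
  check_number(r, "r", lower = 0, strict = TRUE)
  check_number(pe_order, "pe_order", lower = 2)
  check_number(pe_delay, "pe_delay", lower = 1)
  check_number(renyi_alpha, "renyi_alpha", lower = 0, strict = TRUE)
  if (abs(renyi_alpha - 1) < 1e-12) stop_ef("renyi_alpha must differ from 1")
  check_number(histogram_bins, "histogram_bins", lower = 2)
  check_number(svd_embed_dim, "svd_embed_dim", lower = 2)
  check_number(svd_delay, "svd_delay", lower = 1)
  edges <- do.call(rbind, bands)
  if (any(edges[, 1] >= edges[, 2]) || is.unsorted(as.vector(t(edges)))) {
    stop_ef("band edges must be strictly increasing and non-overlapping")
  }
  structure(
    list(m = as.integer(m), r = r, pe_order = as.integer(pe_order),
         pe_delay = as.integer(pe_delay), renyi_alpha = renyi_alpha,
         histogram_bins = as.integer(histogram_bins),
         svd_embed_dim = as.integer(svd_embed_dim),
         svd_delay = as.integer(svd_delay), bands = bands,
         welch_nperseg = as.integer(welch_nperseg),
         welch_overlap = welch_overlap, spectral_range = spectral_range,
         log_bases = c(SE = "e", FE = "e", SnE = "e", RE = "e",
                       PE = "2", DE = "2", SVDE = "2", SpE = "e")),
    class = "feature_params"
  )
}

#' Statistical moments of a segment
#'
#' Population-denominator moments (divide by N): mean, standard deviation,
#' raw fourth standardised moment (kurtosis, not excess) and skewness. A
#' zero-variance segment has no shape information: Kur and SK are set to 0 and
#' flagged via the `"flags"` attribute.
#'
#' @param x Numeric segment (`N >= 2`).
#' @return Named numeric vector `Mean, SD, Kur, SK` (with optional `flags`
#'   attribute).
#' @export
compute_moments <- function(x) {
  n <- length(x)
  if (n < 2L) stop_ef("segment must have at least 2 samples")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  if (s == 0) {
    out <- c(Mean = mu, SD = 0, Kur = 0, SK = 0)
    attr(out, "flags") <- "degenerate_moments"
    return(out)
  }
  c(Mean = mu, SD = s,
    Kur = mean((x - mu)^4) / v^2,
    SK = mean((x - mu)^3) / s^3)
}

#' Sample and fuzzy entropy of a segment
#'
#' Sample entropy: negative log ratio of the counts of template pairs
#' (self-matches excluded) matching at length `m + 1` versus length `m` under
#' Chebyshev distance `<= r * SD(x)`. When either count is zero the estimate
#' is undefined and is capped at the maximum observable value
#' `-log(2 / ((N - m - 1)(N - m)))`. Fuzzy entropy replaces the hard match
#' with the membership degree `exp(-(d / r_tol)^2)` averaged over pairs.
#'
#' @param x Numeric segment.
#' @param params A [feature_params()].
#' @return Named numeric vector `SE, FE` (optionally flagged).
#' @export
compute_regularity_entropies <- function(x, params = feature_params()) {
  n <- length(x)
  m <- params$m
  if (n <= m + 1L) stop_ef("segment too short for embedding dimension m = %d", m)
  r_tol <- params$r * sqrt(mean((x - mean(x))^2))
  st <- pair_match_stats(x, m, r_tol)
  cap <- -log(2 / ((n - m - 1) * (n - m)))
  flags <- character(0)
  if (st[["A_m"]] > 0 && st[["A_m1"]] > 0) {
    se <- -log(st[["A_m1"]] / st[["A_m"]])
  } else {
    se <- cap
    flags <- c(flags, "se_capped")
  }
  if (st[["C_m"]] > 0 && st[["C_m1"]] > 0) {
    fe <- -log(st[["C_m1"]] / st[["C_m"]])
  } else {
    fe <- cap
    flags <- c(flags, "fe_capped")
  }
  out <- c(SE = se, FE = fe)
  if (length(flags)) attr(out, "flags") <- flags
  out
}

# Ordinal pattern codes of the delay embedding. Ties resolve by index order
# (stable): within a pattern, the rank of element k counts elements strictly
# smaller plus earlier equal elements. Vectorised over all patterns.
ordinal_patterns <- function(x, order_m, delay) {
  nt <- length(x) - (order_m - 1L) * delay
  if (nt < 1L) stop_ef("segment too short for pe_order %d, pe_delay %d", order_m, delay)
  cols <- lapply(seq_len(order_m) - 1L, function(k) x[seq_len(nt) + k * delay])
  code <- numeric(nt)
  for (k in seq_len(order_m)) {
    rk <- numeric(nt)
    for (l in seq_len(order_m)) {
      if (l == k) next
      rk <- rk + (cols[[l]] < cols[[k]]) + (l < k) * (cols[[l]] == cols[[k]])
    }
    code <- code * order_m + rk
  }
  code
}

#' Permutation and SVD entropy of a segment
#'
#' Permutation entropy: base-2 Shannon entropy of the ordinal-pattern
#' distribution of order `pe_order` at delay `pe_delay` (bounded by
#' `log2(pe_order!)`). SVD entropy: base-2 Shannon entropy of the squared
#' singular values of the delay-embedding trajectory matrix, normalised to
#' sum to one (bounded by `log2(svd_embed_dim)`).
#'
#' @inheritParams compute_regularity_entropies
#' @return Named numeric vector `PE, SVDE`.
#' @export
compute_symbolic_entropies <- function(x, params = feature_params()) {
  pat <- ordinal_patterns(x, params$pe_order, params$pe_delay)
  p <- tabulate(factor(pat)) / length(pat)
  pe <- -sum(p * log2(p))

  d <- params$svd_embed_dim
  tau <- params$svd_delay
  nt <- length(x) - (d - 1L) * tau
  if (nt < 1L) stop_ef("segment too short for svd_embed_dim %d", d)
  emb <- sapply(seq_len(d) - 1L, function(k) x[seq_len(nt) + k * tau])
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1L)
  # squared singular values of emb = eigenvalues of the d x d Gram matrix
  ev <- eigen(crossprod(emb), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  p2 <- ev / sum(ev)
  p2 <- p2[p2 > .Machine$double.eps]
  svde <- -sum(p2 * log2(p2))
  c(PE = pe, SVDE = max(svde, 0))
}

# Amplitude histogram probabilities: equal-width bins over [min, max],
# empty bins excluded. A constant segment occupies a single bin.
amplitude_histogram <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(1)
  idx <- pmin(bins, 1L + floor((x - lo) / (hi - lo) * bins))
  p <- tabulate(idx, nbins = bins) / length(x)
  p[p > 0]
}

#' Distribution entropies of a segment
#'
#' Shannon (natural log), Renyi of order `alpha` (natural log) and base-2
#' "distribution entropy", all computed from the same equal-width amplitude
#' histogram over `[min(x), max(x)]` with empty bins excluded. A constant
#' segment occupies one bin, so all three are 0.
#'
#' @inheritParams compute_regularity_entropies
#' @return Named numeric vector `SnE, RE, DE`.
#' @export
compute_distribution_entropies <- function(x, params = feature_params()) {
  p <- amplitude_histogram(x, params$histogram_bins)
  a <- params$renyi_alpha
  c(SnE = -sum(p * log(p)),
    RE = log(sum(p^a)) / (1 - a),
    DE = -sum(p * log2(p)))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: Hann-windowed segments of
#' `welch_nperseg` samples with `welch_overlap` fractional overlap, mean
#' removed per segment, one-sided density scaling (power / Hz).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param params A [feature_params()].
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = EEG_FS, params = feature_params()) {
  L <- min(params$welch_nperseg, length(x))
  step <- max(1L, as.integer(round(L * (1 - params$welch_overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / L)) # periodic Hann
  denom <- fs * sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(nf)])^2 / denom
    # one-sided: double everything except DC (and Nyquist when L even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (L %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + sp * dbl
  }
  list(freq = (seq_len(nf) - 1L) * fs / L, psd = acc / length(starts))
}

#' Band powers and spectral entropy of a segment
#'
#' Band power is the integral of the Welch PSD over the half-open band
#' `[f_low, f_high)`; spectral entropy is the Shannon entropy (natural log) of
#' the PSD normalised to a probability distribution over the analysis range.
#'
#' @inheritParams compute_regularity_entropies
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector
#'   `delta_power, theta_power, alpha_power, beta_power, SpE`.
#' @export
compute_spectral <- function(x, params = feature_params(), fs = EEG_FS) {
  ps <- welch_psd(x, fs, params)
  df <- ps$freq[2] - ps$freq[1]
  bp <- vapply(params$bands, function(edge) {
    sel <- ps$freq >= edge[1] & ps$freq < edge[2]
    sum(ps$psd[sel]) * df
  }, numeric(1))
  names(bp) <- paste0(names(params$bands), "_power")
  rng <- params$spectral_range
  sel <- ps$freq >= rng[1] & ps$freq < rng[2]
  pk <- ps$psd[sel]
  spe <- if (sum(pk) > 0) {
    p <- pk / sum(pk)
    p <- p[p > 0]
    -sum(p * log(p))
  } else 0
  c(bp, SpE = spe)
}

#' Full 16-feature vector of one segment
#'
#' Concatenation of [compute_moments()], [compute_regularity_entropies()],
#' [compute_distribution_entropies()], [compute_symbolic_entropies()] and
#' [compute_spectral()] in the canonical [feature_names()] order. Degenerate
#' segments are handled by each sub-operation's sentinel policy; no NaN leaks
#' downstream.
#'
#' @inheritParams compute_spectral
#' @return Named numeric vector of length 16 (with optional `flags`
#'   attribute).
#' @export
compute_feature_vector <- function(x, params = feature_params(), fs = EEG_FS) {
  parts <- list(
    compute_moments(x),
    compute_regularity_entropies(x, params),
    compute_distribution_entropies(x, params),
    compute_symbolic_entropies(x, params),
    compute_spectral(x, params, fs)
  )
  flags <- unlist(lapply(parts, attr, "flags"))
  out <- unlist(lapply(parts, function(p) {
    attributes(p)$flags <- NULL
    p
  }))
  out <- out[feature_names()]
  stopifnot(!anyNA(out))
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Average feature vectors into one event representative
#'
#' Element-wise arithmetic mean of the per-window feature vectors of one
#' channel-event, yielding the single representative row per event the models
#' consume.
#'
#' @param vectors List of 16-element feature vectors (or a matrix with one
#'   row per vector).
#' @return Named numeric vector of length 16.
#' @export
aggregate_event_features <- function(vectors) {
  if (is.matrix(vectors)) vectors <- asplit(vectors, 1)
  if (!length(vectors)) stop_ef("aggregation error: no feature vectors to average")
  mat <- do.call(rbind, lapply(vectors, as.numeric))
  out <- colMeans(mat)
  names(out) <- names(vectors[[1]])
  out
}

#' Per-event feature table of one recording
#'
#' Segments the recording, computes the 16 features for every window and
#' averages windows into one representative per (channel, event).
#'
#' @param recording An `eeg_recording`.
#' @param params A [feature_params()].
#' @param windows_per_event Cap on windows per event (compute-budget
#'   subsample; default all). See [segment_recording()].
#' @param events Optional subset of events (e.g. `c("s1", "s2", "s3")` when
#'   only the modelled task events are needed).
#' @return data.frame: one row per (subject, session, channel, event) with 16
#'   feature columns.
#' @export
recording_features <- function(recording, params = feature_params(),
                               windows_per_event = Inf, events = NULL) {
  segs <- segment_recording(recording, windows_per_event = windows_per_event,
                            events = events)
  if (!nrow(segs)) stop_ef("recording produced no segments")
  key <- interaction(segs$channel, segs$event, drop = TRUE)
  out <- lapply(split(seq_len(nrow(segs)), key), function(ix) {
    fv <- aggregate_event_features(lapply(segs$samples[ix], compute_feature_vector,
                                          params = params,
                                          fs = recording$sampling_rate))
    cbind(
      data.frame(subject = segs$subject[ix[1]], session = segs$session[ix[1]],
                 channel = segs$channel[ix[1]], event = segs$event[ix[1]],
                 n_windows = length(ix), stringsAsFactors = FALSE),
      as.data.frame(as.list(fv))
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$channel, out$event), ]
}

#' Feature table for a whole cohort
#'
#' Streams recordings one at a time (regenerating them from the cohort's
#' seeds), so memory stays flat in cohort size.
#'
#' @param cohort An `eeg_cohort`.
#' @inheritParams recording_features
#' @return data.frame: one row per (subject, session, channel, event).
#' @export
cohort_feature_table <- function(cohort, params = feature_params(),
                                 windows_per_event = Inf, events = NULL) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  rows <- list()
  for (sid in cohort$manifest$subjects) {
    for (pl in cohort$plans) {
      rec <- cohort_recording(cohort, sid, pl$session_index)
      rows[[length(rows) + 1L]] <-
        recording_features(rec, params, windows_per_event, events = events)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
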