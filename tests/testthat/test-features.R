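params <- feature_params()

test_that("moments match the population formulas", {
  # alternating +1, -1: Mean 0, SD 1, SK 0, Kur 1
  m <- compute_moments(rep(c(1, -1), 10))
  expect_equal(m[["Mean"]], 0)
  expect_equal(m[["SD"]], 1)
  expect_equal(m[["Kur"]], 1)
  expect_equal(m[["SK"]], 0)
  # random vectors vs textbook oracle
  for (seed in 1:5) {
    x <- eegfatigue:::with_seed(seed, rnorm(20, sd = 3))
    expect_equal(compute_moments(x), oracle_moments(x), tolerance = 1e-12)
  }
  # degenerate: constant segment flagged, Kur/SK sentinel 0
  m0 <- compute_moments(rep(7, 10))
  expect_equal(as.numeric(m0), c(7, 0, 0, 0))
  expect_equal(attr(m0, "flags"), "degenerate_moments")
})

test_that("sample and fuzzy entropy match the brute-force oracle exactly", {
  # short printed series, m = 2, r = 0.2 * SD
  x12 <- c(1.2, -0.4, 0.8, 2.1, -1.3, 0.5, 0.9, -0.2, 1.7, -0.8, 0.3, 1.1)
  r <- 0.2 * pop_sd(x12)
  st <- eegfatigue:::pair_match_stats(x12, 2L, r)
  or <- oracle_pair_stats(x12, 2, r)
  expect_identical(unname(st[c("A_m", "A_m1")]), unname(or[c("A_m", "A_m1")]))
  expect_equal(unname(st[c("C_m", "C_m1")]), unname(or[c("C_m", "C_m1")]),
               tolerance = 1e-12)
  # and on random <= 50-point series, including the entropy values
  for (seed in 1:8) {
    x <- eegfatigue:::with_seed(seed, rnorm(50))
    r <- params$r * pop_sd(x)
    got <- compute_regularity_entropies(x, params)
    expect_equal(got[["SE"]], oracle_sampen(x, params$m, r), tolerance = 1e-12)
    expect_equal(got[["FE"]], oracle_fuzzen(x, params$m, r), tolerance = 1e-12)
  }
})

test_that("regularity entropies order periodic below noise", {
  hits <- 0
  for (seed in 1:100) {
    per <- rep(c(0, 1, -1, 0.5), length.out = 60)
    noise <- eegfatigue:::with_seed(seed, runif(60, -1, 1))
    se_p <- compute_regularity_entropies(per + 0, params)[["SE"]]
    se_n <- compute_regularity_entropies(noise, params)[["SE"]]
    hits <- hits + (se_p < se_n)
  }
  expect_gte(hits, 95)
})

test_that("degenerate and capped regularity cases", {
  cst <- compute_regularity_entropies(rep(3, 40), params)
  expect_equal(cst[["FE"]], 0)
  expect_equal(cst[["SE"]], 0)
  # no matches at all: strictly exploding series with tiny tolerance -> cap
  x <- 2^(1:30)
  got <- compute_regularity_entropies(x, feature_params(r = 1e-9))
  n <- 30; m <- 2
  expect_equal(got[["SE"]], -log(2 / ((n - m - 1) * (n - m))))
})

test_that("permutation entropy: limits, bound, oracle equivalence", {
  expect_equal(compute_symbolic_entropies(1:100, params)[["PE"]], 0) # ramp
  bound <- log2(factorial(params$pe_order))
  for (seed in 1:10) {
    x <- eegfatigue:::with_seed(seed, rnorm(40))
    pe <- compute_symbolic_entropies(x, params)[["PE"]]
    expect_lte(pe, bound)
    expect_equal(pe, oracle_pe(x, params$pe_order, params$pe_delay),
                 tolerance = 1e-12)
  }
  # long iid noise approaches the bound
  x <- eegfatigue:::with_seed(99, runif(5000))
  expect_gt(compute_symbolic_entropies(x, params)[["PE"]], 0.99 * bound)
  # ties resolved stably: all-tied samples give a single pattern
  expect_equal(compute_symbolic_entropies(rep(1, 50), params)[["PE"]], 0)
})

test_that("SVD entropy: rank-1 trajectories and the log2(d) bound", {
  # geometric sequence: embedding columns proportional -> rank 1 -> SVDE 0
  expect_equal(compute_symbolic_entropies(1.1^(1:60), params)[["SVDE"]], 0,
               tolerance = 1e-8)
  expect_equal(compute_symbolic_entropies(rep(2, 60), params)[["SVDE"]], 0,
               tolerance = 1e-8)
  for (seed in 1:5) {
    x <- eegfatigue:::with_seed(seed, rnorm(200))
    expect_lte(compute_symbolic_entropies(x, params)[["SVDE"]],
               log2(params$svd_embed_dim))
  }
})

test_that("distribution entropies: uniform histograms and the Renyi limit", {
  # k equally occupied bins -> SnE = ln k, DE = log2 k
  for (k in c(2, 4, 8)) {
    x <- rep(seq_len(k), each = 16)
    got <- compute_distribution_entropies(x, params)
    expect_equal(got[["SnE"]], log(k), tolerance = 1e-12)
    expect_equal(got[["DE"]], log2(k), tolerance = 1e-12)
  }
  # alpha -> 1: Renyi approaches Shannon
  x <- eegfatigue:::with_seed(4, rnorm(2560))
  sne <- compute_distribution_entropies(x, params)[["SnE"]]
  for (a in c(1 - 1e-4, 1 + 1e-4)) {
    re <- compute_distribution_entropies(x, feature_params(renyi_alpha = a))[["RE"]]
    expect_equal(re, sne, tolerance = 1e-3)
  }
  # constant segment: one occupied bin, all three zero
  expect_equal(unname(compute_distribution_entropies(rep(5, 100), params)),
               c(0, 0, 0))
})

test_that("spectral features localise power and flag flat spectra", {
  t <- (0:2559) / 256
  tone <- sin(2 * pi * 10 * t) # pure 10 Hz
  sp <- compute_spectral(tone, params)
  total <- sum(sp[c("delta_power", "theta_power", "alpha_power", "beta_power")])
  expect_gt(sp[["alpha_power"]], 0.95 * total)
  # white noise: SpE within 5% of the flat-spectrum maximum
  nbins <- sum(seq(0, 128) >= 0.4 & seq(0, 128) < 30)
  for (seed in 1:10) {
    x <- eegfatigue:::with_seed(seed, rnorm(2560))
    expect_gt(compute_spectral(x, params)[["SpE"]], 0.95 * log(nbins))
  }
  # constant segment: mean removal leaves nothing
  sp0 <- compute_spectral(rep(1, 2560), params)
  expect_equal(unname(sp0), rep(0, 5))
})

test_that("the full feature vector composes its sub-operations", {
  x <- eegfatigue:::with_seed(11, rnorm(2560))
  v <- compute_feature_vector(x, params)
  expect_length(v, 16)
  expect_named(v, feature_names())
  expect_equal(v[c("Mean", "SD", "Kur", "SK")], compute_moments(x))
  expect_equal(v[c("SE", "FE")], compute_regularity_entropies(x, params))
  expect_equal(v[c("SnE", "RE", "DE")], compute_distribution_entropies(x, params))
  expect_equal(v[c("PE", "SVDE")], compute_symbolic_entropies(x, params))
  expect_equal(v[c("delta_power", "theta_power", "alpha_power", "beta_power", "SpE")],
               compute_spectral(x, params))
  # constant segment: sentinels applied, no NaN leaks
  v0 <- compute_feature_vector(rep(1, 2560), params)
  expect_false(anyNA(v0))
  expect_true(all(is.finite(v0)))
})

test_that("scale behaviour: c * x changes only what it should", {
  x <- eegfatigue:::with_seed(21, rnorm(400))
  v1 <- compute_feature_vector(x, params)
  v2 <- compute_feature_vector(5 * x, params)
  expect_equal(v2[["SD"]], 5 * v1[["SD"]])
  expect_equal(v2[["Mean"]], 5 * v1[["Mean"]])
  inv <- c("Kur", "SK", "SE", "FE", "SnE", "RE", "PE", "DE", "SVDE", "SpE")
  expect_equal(v2[inv], v1[inv], tolerance = 1e-10)
  bands <- c("delta_power", "theta_power", "alpha_power", "beta_power")
  expect_equal(unname(v2[bands]), unname(25 * v1[bands]), tolerance = 1e-10)
})

test_that("event aggregation is an element-wise mean", {
  v <- eegfatigue:::with_seed(3, rnorm(16))
  names(v) <- feature_names()
  expect_equal(aggregate_event_features(list(v)), v)
  expect_equal(aggregate_event_features(list(v, v, v)), v)
  vs <- lapply(1:4, function(i) {
    out <- eegfatigue:::with_seed(i, rnorm(16)); names(out) <- feature_names(); out
  })
  manual <- Reduce(`+`, vs) / 4
  expect_equal(aggregate_event_features(vs), manual, tolerance = 1e-12)
  expect_error(aggregate_event_features(list()), "aggregation error")
})

test_that("entropies are nonnegative on generated segments", {
  ent <- c("SE", "FE", "SnE", "RE", "PE", "DE", "SVDE", "SpE")
  for (seed in 1:5) {
    x <- eegfatigue:::with_seed(seed, cumsum(rnorm(2560)) + rnorm(2560))
    v <- compute_feature_vector(x, params)
    expect_true(all(v[ent] >= 0))
    expect_true(all(v[c("delta_power", "theta_power", "alpha_power",
                        "beta_power")] >= 0))
  }
})
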