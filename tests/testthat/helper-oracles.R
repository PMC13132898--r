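# Independent reference implementations (naive, O(N^2)/enumeration) used to
# freeze expected values. Deliberately written without reusing any package
# internals.

# Template-pair counts and fuzzy membership sums by explicit double loop.
oracle_pair_stats <- function(x, m, r) {
  nt <- length(x) - m
  A_m <- A_m1 <- C_m <- C_m1 <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      dm1 <- max(dm, abs(x[i + m] - x[j + m]))
      if (dm <= r) A_m <- A_m + 1
      if (dm1 <= r) A_m1 <- A_m1 + 1
      if (r > 0) {
        C_m <- C_m + exp(-(dm / r)^2)
        C_m1 <- C_m1 + exp(-(dm1 / r)^2)
      } else {
        C_m <- C_m + (dm == 0)
        C_m1 <- C_m1 + (dm1 == 0)
      }
    }
  }
  c(A_m = A_m, A_m1 = A_m1, C_m = C_m, C_m1 = C_m1)
}

# Undefined ratios (zero matches) fall back to the same finite-sample cap
# convention the operation specifies: -log(2 / ((N - m - 1)(N - m))).
oracle_sampen <- function(x, m, r) {
  st <- oracle_pair_stats(x, m, r)
  n <- length(x)
  if (st[["A_m"]] == 0 || st[["A_m1"]] == 0) {
    return(-log(2 / ((n - m - 1) * (n - m))))
  }
  -log(st[["A_m1"]] / st[["A_m"]])
}

oracle_fuzzen <- function(x, m, r) {
  st <- oracle_pair_stats(x, m, r)
  n <- length(x)
  if (st[["C_m"]] == 0 || st[["C_m1"]] == 0) {
    return(-log(2 / ((n - m - 1) * (n - m))))
  }
  -log(st[["C_m1"]] / st[["C_m"]])
}

# Permutation entropy by explicit pattern enumeration (order() is stable).
oracle_pe <- function(x, m, tau) {
  nt <- length(x) - (m - 1) * tau
  pats <- character(nt)
  for (i in seq_len(nt)) {
    w <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(w), collapse = "-")
  }
  p <- table(pats) / nt
  -sum(p * log2(p))
}

# Textbook population moments.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  c(Mean = mu, SD = sqrt(v),
    Kur = (sum((x - mu)^4) / n) / v^2,
    SK = (sum((x - mu)^3) / n) / v^(3 / 2))
}

# Confusion tally by explicit loop.
oracle_confusion <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Population SD (the tolerance convention used for SE/FE).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
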