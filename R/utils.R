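# Internal helpers: seed plumbing, argument checks, logging.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and a label
#'
#' Deterministic, platform-independent fan-out of one master seed to the
#' pipeline's random consumers (one per subject, per stage, ...). The scheme is
#' a 31-bit multiplicative hash over the label's bytes, so the same
#' (master seed, label) pair yields the same child seed on any platform.
#'
#' @param master_seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the consumer, e.g.
#'   `derive_seed(1, "subject", 3)`.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(as.integer(master_seed)) %% m
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  for (b in utf8ToInt(label)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

stop_ef <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_ef("`%s` must be a single finite number", name)
  }
  if ((strict && x <= lower) || (!strict && x < lower)) {
    stop_ef("`%s` must be %s %s", name, if (strict) ">" else ">=", lower)
  }
  invisible(x)
}

# stderr logging with level prefix; quiet unless option set higher than level
ef_log <- function(level = c("info", "warn"), fmt, ...) {
  level <- match.arg(level)
  message(sprintf("[eegfatigue:%s] %s", level, sprintf(fmt, ...)))
}

.log_seen <- new.env(parent = emptyenv())

# Per-session deduplicated warning (fold loops would otherwise repeat the
# same message hundreds of times).
log_once <- function(key, fmt, ...) {
  msg <- sprintf(fmt, ...)
  id <- paste(key, msg)
  if (is.null(.log_seen[[id]])) {
    .log_seen[[id]] <- TRUE
    ef_log("warn", "%s", msg)
  }
  invisible(NULL)
}
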