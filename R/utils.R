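# Internal helpers shared across modules.

#' @importFrom stats qnorm pnorm pchisq qchisq rnorm runif rbinom plogis
#'   uniroot median sd cor optimize ks.test t.test coef predict
#' @importFrom utils head tail
NULL

# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards. All package randomness funnels through this
# so that library calls never perturb user seeds.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Derive a named substream seed from a base seed; keeps results reproducible
# per pipeline stage while staying below 2^31.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("%s must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("%s must lie in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  as.numeric(x)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
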