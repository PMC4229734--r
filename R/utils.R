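# Internal helpers shared across modules.

# Run `code` under a temporarily-seeded RNG, restoring the caller's RNG state.
# A NULL seed leaves the current RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Derive a stream-specific child seed so independent stages of a pipeline
# driven by one master seed do not share RNG streams. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.double(seed) * 48271 + stream * 9973) %% 2147483647
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "pmaxnet_config_error")
}

stop_parse <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "pmaxnet_parse_error")
}

#' Format a count as a percentage of a total
#'
#' Presentation helper used by composition summaries and reports: `k` out of
#' `n`, as a percentage rounded to `digits` decimal places (half up, so
#' 2.491 prints as "2.5" at one decimal).
#'
#' @param k Numerator count(s).
#' @param n Denominator count(s).
#' @param digits Decimal places to keep (default 1).
#' @return Numeric vector of rounded percentages.
#' @examples
#' percent_of(14, 562)   # 2.5
#' percent_of(615, 11963) # 5.1
#' @export
percent_of <- function(k, n, digits = 1) {
  stopifnot(all(n > 0))
  p <- 100 * k / n
  # round half up at the printed precision (matches tabulated percentages)
  scale <- 10^digits
  floor(p * scale + 0.5) / scale
}
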