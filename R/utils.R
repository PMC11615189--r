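# Internal helpers shared across modules.

# Deterministic sub-seed for a named random substream, kept inside 32-bit
# integer range so set.seed() never overflows.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never disturbs user-level streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

config_error <- function(msg, field = NULL) {
  abort(msg, class = "nbd_config_error", field = field)
}

input_error <- function(msg, ...) {
  abort(msg, class = "nbd_input_error", ...)
}

#' Percentage of a count pair, rounded to the nearest percent
#'
#' Cohort summaries report proportions as integer percentages of count pairs
#' (e.g. 44 of 115 whole-genome-doubled tumors -> 38%). This helper applies
#' that convention: `round(100 * numerator / denominator)`.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @return Integer-valued percentage.
#' @examples
#' percent_of(44, 115)
#' @export
percent_of <- function(numerator, denominator) {
  stopifnot(denominator > 0)
  round(100 * numerator / denominator)
}

# Clamp a probability strictly inside (0, 1) for binomial draws.
clamp01 <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)
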