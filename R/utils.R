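#' Round half away from zero
#'
#' Decimal rounding as printed in analytical tables: exact halves round away
#' from zero (base `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(2.805, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Fan a root seed out to per-generator child seeds by fixed offsets, so that
# adding a generator never perturbs the streams of the others. Kept below
# 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + offset * 104729) %% 2147483647)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

stop_config <- function(msg) abort(msg, class = "phytonet_config_error")
stop_validation <- function(msg) abort(msg, class = "phytonet_validation_error")

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop_config(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
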