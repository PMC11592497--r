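#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rlnorm rbinom rweibull runif rgamma rpois quantile
#'   sd cor predict lm glm binomial coef model.matrix setNames complete.cases
#'   aggregate var dnorm
#' @importFrom utils head write.csv read.csv str modifyList
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds derived from a master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

assert_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

assert_number <- function(x, field, lower = -Inf, upper = Inf,
                          integer = FALSE, open_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) && x <= upper &&
    (!integer || x == round(x))
  if (!ok) {
    stop_field(field, sprintf(
      "must be a %s in %s%s, %s]", if (integer) "whole number" else "number",
      if (open_lower) "(" else "[", lower, upper
    ))
  }
  invisible(x)
}
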