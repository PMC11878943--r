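# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. Seeds are explicit arguments throughout the package; nothing relies
# on ambient .Random.seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "foalwatch_contract_error")
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Deterministic child seed so that independent draws inside one seeded
# operation do not reuse the same stream. Kept below 2^31 - 1.
child_seed <- function(seed, k) {
  (as.double(seed) * 1000003 + 7919 * k) %% 2147483647
}
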