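# internal helpers: seeded evaluation, child-seed derivation, validation

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# deterministic per-artifact child streams from one master seed;
# kept below 2^31 - 1
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1048573) * 1021 + offset)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_fmt("`%s` must be a single finite number", name)
  }
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name)
  if (x < min || x != floor(x)) {
    stop_fmt("`%s` must be an integer >= %d", name, min)
  }
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_fmt("`%s` must lie in [0, 1]", name)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
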