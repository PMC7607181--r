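# Internal validation / RNG helpers.

abort <- function(msg, class) {
  stop(structure(class = c(class, "ihcmet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    abort(sprintf("`%s` must be in [0, 1]", name), "ihcmet_param_error")
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && all(if (strict) x > 0 else x >= 0)
  if (!ok)
    abort(sprintf("`%s` must be %s", name,
                  if (strict) "> 0" else ">= 0"), "ihcmet_param_error")
  invisible(x)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`; the global
# RNG state is restored afterwards, so generators never leak RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort("`seed` must be a single integer", "ihcmet_param_error")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round-half-up to integer (Table-1 style percentages)
round_half_up <- function(x) floor(x + 0.5)
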