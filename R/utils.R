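# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed < 2^31 from a base seed and a small offset.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647L)
}

assert_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

assert_number <- function(x, name, lower = -Inf, allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, lower))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
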