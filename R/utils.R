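# internal helpers shared across modules

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched
with_seed <- function(seed, code) {
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
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_simplex <- function(x, name, tol = 1e-9) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric vector with no missing values.", name))
  }
  if (any(x < -tol) || abs(sum(x) - 1) > tol) {
    abort(sprintf("`%s` must lie on the probability simplex (entries >= 0, sum 1).", name))
  }
  invisible(x)
}

# entropy-safe x * log(x) with the 0 log 0 := 0 convention (natural log)
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}
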