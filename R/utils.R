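# internal helpers shared across modules

# run expr with a temporary RNG state seeded by `seed` (NULL = leave RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

# derive a stream-specific child seed from a master seed; stays < 2^31
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + stream * 69621) %% 2147483399 + 1
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

as_date_strict <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(out) || anyNA(out)) {
    abort(sprintf("could not parse %s as ISO-8601 dates", what))
  }
  out
}

# standard error of the mean; 0 for length-1 input
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1) return(0)
  sd(x) / sqrt(length(x))
}
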