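# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls never disturb user RNG.
# seed = NULL means "use the current RNG stream" (no isolation).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive an independent sub-seed for a named stream from one
# global seed, so each generator can be re-run on its own. Stays < 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- sum(utf8ToInt(as.character(stream)) *
               seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(as.double(seed)) * 48271 + key * 8191) %% 2147483629)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0)
    stop("`", name, "` must be a single positive number", call. = FALSE)
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single number in [0, 1]", call. = FALSE)
  invisible(x)
}

check_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}
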