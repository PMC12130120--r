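# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls stay referentially
# transparent.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministically derive a stream seed below 2^31 from a base seed and
# integer tags (e.g. subject, phase). Keeps independent stages decoupled.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) {
    s <- (s * 69069 + as.double(t) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop2("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop2("`%s` must be in [%s, %s]", name, format(lower), format(upper))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop2("`%s` must be a whole number", name)
  invisible(as.integer(x))
}

check_finite_vector <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop2("`%s` must be a finite numeric vector without NA", name)
  }
  invisible(x)
}

# Polynomial rolling hash mod a Mersenne prime, returned as 8 hex chars.
# Used for manifest identity stamps only (reproducibility, not security).
content_hash <- function(x) {
  if (is.character(x)) x <- paste(x, collapse = "\n")
  v <- utf8ToInt(enc2utf8(as.character(x)))
  if (length(v) == 0L) return("00000000")
  m <- 2147483647
  h <- 0
  for (i in seq_along(v)) h <- (h * 131 + v[i]) %% m
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
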