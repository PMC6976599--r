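# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never disturbs user-level
# reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_value <- function(...) stop(sprintf(...), call. = FALSE)

check_prob_vector <- function(p, what = "p_values", allow_one = TRUE) {
  if (length(p) == 0L) stop_value("%s must be nonempty", what)
  if (!is.numeric(p) || anyNA(p)) stop_value("%s must be numeric without NA", what)
  hi_ok <- if (allow_one) all(p <= 1) else all(p < 1)
  if (!all(p > 0) || !hi_ok) {
    bad <- which(p <= 0 | p > 1)[1L]
    stop_value("%s must lie in (0, 1]; element %d is %g", what, bad, p[bad])
  }
  invisible(p)
}

# Canonical undirected edge keys: "u|v" with u <= v lexicographically.
edge_key <- function(u, v) {
  a <- pmin(u, v)
  b <- pmax(u, v)
  paste(a, b, sep = "\r")
}
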