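#' @keywords internal
"_PACKAGE"

# One master seed; every stochastic operation derives its own child seed so
# that adding or reordering stages never perturbs the streams of the others.

#' Derive a child seed from a master seed and a stage tag
#'
#' Deterministic integer hash of (master seed, tag). Keeps every stochastic
#' stage of the pipeline on its own reproducible RNG stream.
#'
#' @param master Integer master seed.
#' @param tag Character stage label.
#' @return A single integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(master)) * 48271 + h + 1) %% 2147483647)
}

# Evaluate expr with a local RNG state seeded at `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
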