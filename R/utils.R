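# Internal helpers: deterministic seed derivation and scoped RNG use.
#
# All randomness in the package flows from a single integer master seed through
# named, ordered substreams: derive_seed() hashes the master seed together with
# a sequence of labels/counters into a new 32-bit seed, and with_seed()
# evaluates an expression under that seed while restoring the caller's RNG
# state afterwards. This makes whole simulated datasets and whole RDM
# timecourses bit-reproducible from one integer without clobbering the user's
# session RNG.

MOD31 <- 2147483647 # 2^31 - 1, keeps derived seeds in R's integer range

derive_seed <- function(master, ...) {
  parts <- list(...)
  s <- as.double(abs(as.integer(master))) %% MOD31
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    s <- (s * 48271 + as.double(p) + 1) %% MOD31
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_fmt("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_fmt("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}
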