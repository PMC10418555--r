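# Internal helpers: seeded RNG scoping and stable seed derivation.

# Polynomial string hash modulo the Mersenne prime 2^31 - 1.  Exact in double
# arithmetic (131 * 2^31 < 2^53).
hash_string <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483647
  h
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Each independently seeded task (one submission x trait bootstrap, one
#' synthetic patient VCF, ...) gets its own seed derived by stable hashing, so
#' adding or removing one task never perturbs the random stream of another.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric labels identifying the task; concatenated
#'   with "/" before hashing.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "/")
  as.integer((hash_string(key) + as.numeric(master) * 48271) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# state.  With seed = NULL the code runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
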