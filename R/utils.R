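# internal helpers: validation, deterministic seed derivation, logging

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))

assertNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary sequence of labels into
#' a 31-bit integer seed. Used to give every (population, individual) and
#' every stochastic stage its own RNG stream, so adding a population or
#' rerunning a single stage never perturbs the draws of another.
#'
#' @param seed Master integer seed.
#' @param ... Character/numeric labels identifying the stream.
#' @return A single integer in \[0, 2^31 - 2\].
#' @examples
#' deriveSeed(1, "lab", "M1")
#' @export
deriveSeed <- function(seed, ...) {
  parts <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (b in utf8ToInt(parts)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# run expr with a local RNG state seeded from `seed`; restores global state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
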