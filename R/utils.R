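# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. No function in the package touches the
# global random state outside this wrapper.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Format numerics for CSV output: decimal point, no scientific notation,
# empty string for NA.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, trim = TRUE, scientific = FALSE, digits = 15)
  }, character(1))
  out
}
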