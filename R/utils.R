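`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All simulator randomness funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed %% .Machine$integer.max)
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying < 2^31.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)
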