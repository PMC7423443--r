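`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar numeric check used by constructors
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state (the global .Random.seed is restored on exit).
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-replicate substream seed: two rounds of a Lehmer LCG
# (multiplier 48271, modulus 2^31 - 1) so replicate k is reproducible in
# isolation. All arithmetic stays below 2^53 so it is exact in doubles.
derive_stream_seed <- function(master_seed, index) {
  m <- 2147483647
  x <- abs(as.numeric(master_seed)) %% m
  x <- (x * 48271) %% m
  x <- ((x + abs(as.numeric(index)) + 1) * 48271) %% m
  as.integer(x)
}
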