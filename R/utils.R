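# Internal helpers: seeded substreams and local RNG scoping.

.MOD31 <- 2147483647

# Deterministic child seed for a named substream. Mixing the stream name into
# the seed keeps generators independent: adding a new generator never perturbs
# the draws of existing ones.
childSeed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% .MOD31
  s <- (abs(as.numeric(seed)) %% .MOD31) * 48271 %% .MOD31
  as.integer((h + s) %% .MOD31)
}

# Evaluate expr under a fixed seed without clobbering the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Vectorised stop() with sprintf formatting.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Structured progress messages; silenced via options(maskDRP.verbose = FALSE).
logMsg <- function(fmt, ...) {
  if (isTRUE(getOption("maskDRP.verbose", TRUE)))
    message(sprintf(paste0("[maskDRP] ", fmt), ...))
  invisible(NULL)
}
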