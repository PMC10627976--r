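## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. Keeps pipeline stages independently
## reproducible without trampling the global stream.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

## Deterministic sub-seed derivation; stays below 2^31 - 1.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + 104729 * offset) %%
               2147483647)
}

## Polynomial rolling hash of a character vector, as 8 hex digits. Used for
## config digests and weight checksums; stability matters, cryptography does
## not.
textDigest <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Digest of an arbitrary R object via its deparsed form (numbers at full
## precision so weight vectors hash faithfully).
objectDigest <- function(x) {
  textDigest(paste(deparse(x, control = c("keepNA", "digits17")),
                   collapse = ""))
}

## Wrap angles to (-pi, pi].
wrapAngle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

## Standard error of the mean over fold-wise values.
semOver <- function(x) stats::sd(x) / sqrt(length(x))

validLabels <- c("TD", "ASD", "unknown")
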