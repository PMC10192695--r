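# internal helpers

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

# deterministic per-item seed derivation from a master seed; all arithmetic
# stays below 2^53 so the result is exact in doubles and fits in a 32-bit int
derive_seed <- function(master_seed, index) {
  m <- as.numeric(master_seed) %% 2147483647
  h <- (m * 48271 + as.numeric(index) * 104729 + 12345) %% 2147483647
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
}

# polynomial rolling hash of a character string, returned as hex;
# used to fingerprint configurations in run manifests (exact in doubles)
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
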