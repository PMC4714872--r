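# Internal helpers: seeding, coordinates, small hashing.

# Deterministic sub-stream seed derived from a master seed and a text tag.
# LCG-style fold kept below 2^31 so it is a valid set.seed() argument.
substream_seed <- function(seed, tag) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(as.character(tag))) {
    h <- (h * 69069 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state; global RNG is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Tiny FNV-1a-style content hash for provenance stamps (hex string).
content_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, give.attr = FALSE)), collapse = "\n")
  h <- 2166136261
  for (c in utf8ToInt(txt)) {
    h <- ((bitwXor(as.integer(h %% 2147483647), c)) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Coordinate conventions: everything internal is 0-based half-open.
pos0_to_1 <- function(p) p + 1L          # point: 0-based -> 1-based
pos1_to_0 <- function(p) p - 1L
interval0_to_human <- function(iv) c(iv[1] + 1, iv[2])  # 1-based inclusive

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

in_interval <- function(p, iv) p >= iv[1] & p < iv[2]

overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]
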