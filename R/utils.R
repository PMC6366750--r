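# Internal helpers: deterministic seed substreams and a small provenance hash.

# Derive a reproducible 31-bit substream seed from a top-level seed and a tag,
# so each stochastic stage of a run draws from its own deterministic stream.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 260000 * 7919 + h) %% 2147483629L)
}

# djb2-style rolling hash of a deparsed object, kept within integer range.
# Weak by cryptographic standards but stable across platforms; used only to
# stamp run provenance with a config fingerprint.
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
             collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 16777213
  sprintf("%07x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
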