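# Internal helpers shared across modules.

# round() in R rounds half to even; printed percentages in population
# reports use conventional half-up rounding.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 31-bit string hash used to derive per-unit random substreams
# so that draws never depend on row order. The polynomial pass alone is
# affine in the characters, which would leave structured (lattice) seed sets
# that R's generator seeding does not scramble well; the iterated quadratic
# map provides the avalanche that breaks such structure.
mulmod31 <- function(a, b, p = 2147483647) {
  a1 <- a %/% 65536
  a0 <- a %% 65536
  (((a1 * b) %% p) * 65536 + a0 * b) %% p
}

stable_hash <- function(x) {
  p <- 2147483647
  vapply(x, function(s) {
    h <- 5381
    for (k in utf8ToInt(as.character(s))) h <- (h * 31 + k) %% p
    for (r in 1:4) {
      h <- (mulmod31(h, h) + mulmod31(h, 48271) + r * 2654435) %% p
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

substream_seed <- function(seed, id) {
  stable_hash(paste0(format(seed, scientific = FALSE), "|", id))
}

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

write_kv <- function(x, path) {
  writeLines(paste(names(x), unlist(lapply(x, format)), sep = "\t"), path)
}
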