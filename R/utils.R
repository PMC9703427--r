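# internal helpers shared across modules

# Derive a reproducible substream seed from a root seed and a stream index.
# Kept strictly below 2^31 so it is always a valid set.seed() input.
derive_seed <- function(seed, index) {
  s <- as.double(seed) %% 2147483647
  as.integer((s + as.double(index) * 1000003) %% 2147483646) + 1L
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_binary <- function(x, what = "states") {
  if (length(x) == 0 || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must be a non-empty vector of 0/1 values with no NA", what),
         call. = FALSE)
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
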