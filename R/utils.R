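# Evaluate `expr` under a fixed RNG state when `seed` is given, without
# disturbing the caller's RNG; fall back to the ambient stream otherwise.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a reproducible child seed from a parent seed and a stream label.
# The label enters through an order-sensitive polynomial rolling hash so
# distinct labels (including permutations like "s12" vs "s21") map to
# distinct streams. Results stay < 2^31, valid R integers.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (c in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + c) %% 2147483563
  }
  x <- (as.double(seed) * 48271 + h) %% 2147483563
  as.integer(x) + 1L
}

# Permute a vector safely: unlike sample(x), never expands a length-1
# integer into 1:x.
shuffle <- function(x) {
  x[sample.int(length(x))]
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_if_not_matrix <- function(x, arg) {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty numeric matrix.", arg))
  }
}
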