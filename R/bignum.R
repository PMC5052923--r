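# Minimal exact non-negative integer arithmetic for combinatorial identity
# checks (class-weight completeness). Numbers are little-endian limb vectors
# in base 1e7 stored as doubles, so every limb operation stays well inside
# the exact-integer range of double precision.

BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x < BIG_BASE)
  as.numeric(x)
}

big_norm <- function(x) {
  carry <- 0
  for (i in seq_along(x)) {
    v <- x[i] + carry
    carry <- floor(v / BIG_BASE)
    x[i] <- v - carry * BIG_BASE
  }
  while (carry > 0) {
    x <- c(x, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# multiply by a small integer (< ~1e8 keeps limb products exact)
big_mul_small <- function(a, k) {
  stopifnot(k >= 0, k < 1e8)
  if (k == 0) return(0)
  big_norm(a * k)
}

big_eq <- function(a, b) {
  length(a) == length(b) && all(a == b)
}

big_pow_small <- function(base, n) {
  out <- big_from_int(1)
  for (i in seq_len(n)) out <- big_mul_small(out, base)
  out
}

big_to_string <- function(a) {
  digits <- sprintf("%07.0f", rev(a))
  digits[1] <- sub("^0+(?=.)", "", digits[1], perl = TRUE)
  paste(digits, collapse = "")
}

# exponent of prime p in n! (Legendre's formula)
legendre_exp <- function(n, p) {
  e <- 0
  q <- p
  while (q <= n) {
    e <- e + n %/% q
    q <- q * p
  }
  e
}

primes_up_to <- function(n) {
  if (n < 2) return(integer())
  sieve <- rep(TRUE, n)
  sieve[1] <- FALSE
  for (p in 2:floor(sqrt(n))) {
    if (sieve[p]) sieve[seq(p * p, n, by = p)] <- FALSE
  }
  which(sieve)
}

# exact value of (a!/prod(bs!)) * (c!/prod(ds!)) as a bignum; every factor
# is a multinomial coefficient so all prime exponents are non-negative
big_multinomial_product <- function(a, bs, c_, ds) {
  ps <- primes_up_to(max(a, c_, 2))
  out <- big_from_int(1)
  for (p in ps) {
    e <- legendre_exp(a, p) - sum(vapply(bs, legendre_exp, numeric(1), p = p)) +
      legendre_exp(c_, p) - sum(vapply(ds, legendre_exp, numeric(1), p = p))
    stopifnot(e >= 0)
    for (i in seq_len(e)) out <- big_mul_small(out, p)
  }
  out
}
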