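# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's class-table machinery: entropies are computed straight
# from enumerated letter columns, and the Gini oracle uses the
# mean-absolute-difference identity rather than the sorted-rank formula.

BASES <- c("A", "C", "G", "T")

random_motif <- function(N, L) {
  motif(apply(matrix(sample(BASES, N * L, replace = TRUE), N, L),
              1, paste, collapse = ""))
}

# Gini via pairwise mean absolute difference: sum |x_i - x_j| / (2 L^2 mean)
gini_mad <- function(x) {
  L <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * L^2 * mean(x))
}

entropy_bits_oracle <- function(letter_col) {
  p <- table(letter_col) / length(letter_col)
  -sum(p * log2(p))
}

# all A^N columns of N letters over an alphabet of size A, as a list
enumerate_columns <- function(N, A = 4) {
  idx <- as.matrix(expand.grid(rep(list(seq_len(A)), N)))
  lapply(seq_len(nrow(idx)), function(i) BASES[idx[i, ]])
}

# direct tilted sums over all A^N columns: log Z, mean and variance of
# column entropy (bits), at tilt lam
brute_force_column_stats <- function(N, lam, A = 4) {
  cols <- enumerate_columns(N, A)
  h <- vapply(cols, entropy_bits_oracle, numeric(1))
  w <- exp(-lam * h)
  z <- sum(w)
  mu <- sum(h * w) / z
  list(log_z = log(z), mean = mu, var = sum((h - mu)^2 * w) / z,
       entropies = h)
}

# exhaustive per-motif ICs for N x L motifs, computed from enumerated
# column entropies (independent of build_oracle's internals)
brute_force_motif_ics <- function(N, L, A = 4) {
  h_col <- vapply(enumerate_columns(N, A), entropy_bits_oracle, numeric(1))
  grids <- as.matrix(expand.grid(rep(list(seq_along(h_col)), L)))
  2 * L - rowSums(matrix(h_col[grids], ncol = L))
}

# a motif with one fully conserved column and the rest nearly flat
high_igc_motif <- function(N = 50, L = 17) {
  stopifnot(N %% 2 == 0)
  cols <- matrix("", N, L)
  cols[, 1] <- "A"
  # remaining columns as balanced as possible: each carries almost no IC,
  # so nearly all information sits in the conserved column
  counts <- rep(N %/% 4, 4) + c(rep(1, N %% 4), rep(0, 4 - N %% 4))
  for (j in 2:L) {
    cols[, j] <- sample(rep(BASES, counts))
  }
  motif(apply(cols, 1, paste, collapse = ""))
}
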