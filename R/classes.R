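# Equivalence classes of single-column count vectors.
#
# A column of N letters maps to its count vector (n_A, n_C, n_G, n_T); two
# columns have equal entropy iff their count vectors are permutations of one
# another. All partition functions, tilted moments and exact samplers reduce
# to sums over the integer partitions of N into at most |alphabet| parts,
# weighted by the number of columns in each class.

#' Enumerate count-vector equivalence classes
#'
#' One class per integer partition of `N` into at most `alphabet_size`
#' parts. Each class carries its canonical representative (counts sorted
#' non-increasing, zero-padded), its plug-in entropy in bits, and the log of
#' its weight: the number of distinct columns in the class,
#' \deqn{w(\bar n) = \frac{A!}{\prod_v m(\bar n)_v!} \cdot
#'       \frac{N!}{\prod_b n_b!},}
#' where `m` counts multiplicities of values within the count tuple. The
#' weights sum to `alphabet_size^N` over all classes.
#'
#' @param N Number of sites per column (positive integer).
#' @param alphabet_size Alphabet cardinality, 2 to 20 (4 for DNA). Partition
#'   counts grow as `O(N^(A-1))`; a warning is issued above 6.
#' @return An object of class `class_table`: a list with elements `N`,
#'   `alphabet_size`, `counts` (k x A integer matrix), `entropy` (bits),
#'   `log_weight` (natural log), `class_count`.
#' @examples
#' ct <- enumerate_classes(4)
#' ct$class_count  # 5 partitions of 4 into at most 4 parts
#' @export
enumerate_classes <- function(N, alphabet_size = 4L) {
  N <- as.integer(N)
  alphabet_size <- as.integer(alphabet_size)
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (alphabet_size < 2L || alphabet_size > 20L) {
    stop("alphabet_size must be between 2 and 20", call. = FALSE)
  }
  if (alphabet_size > 6L) {
    warning("partition enumeration grows as O(N^(A-1)); alphabet_size > 6 ",
            "may be very slow for large N")
  }
  counts <- if (alphabet_size == 4L) partitions_at_most_4(N) else
    partitions_at_most_k(N, alphabet_size)
  entropy <- partition_entropy_bits(counts, N)
  log_weight <- partition_log_weight(counts, N, alphabet_size)
  structure(
    list(N = N, alphabet_size = alphabet_size, counts = counts,
         entropy = entropy, log_weight = log_weight,
         class_count = nrow(counts)),
    class = "class_table"
  )
}

#' @export
print.class_table <- function(x, ...) {
  cat(sprintf("<class_table: N = %d, alphabet = %d, %d classes>\n",
              x$N, x$alphabet_size, x$class_count))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.class_table <- function(x, ...) {
  cts <- as.data.frame(x$counts)
  names(cts) <- paste0("count_", seq_len(x$alphabet_size))
  tibble::as_tibble(cbind(cts, entropy = x$entropy, log_weight = x$log_weight))
}

# partitions of N into at most 4 non-increasing parts; rows sorted by
# construction (n1 >= n2 >= n3 >= n4). Single loop over n1, inner levels
# vectorized with sequence().
partitions_at_most_4 <- function(N) {
  blocks <- vector("list", N)
  for (n1 in seq(ceiling(N / 4), N)) {
    r1 <- N - n1
    a2 <- ceiling(r1 / 3)
    b2 <- min(n1, r1)
    if (a2 > b2) next
    n2s <- a2:b2
    r2 <- r1 - n2s
    lo3 <- ceiling(r2 / 2)
    hi3 <- pmin(n2s, r2)
    k <- pmax(0L, hi3 - lo3 + 1L)
    keep <- k > 0L
    if (!any(keep)) next
    n2 <- rep(n2s[keep], k[keep])
    n3 <- sequence(k[keep], from = lo3[keep])
    n4 <- N - n1 - n2 - n3
    blocks[[n1]] <- cbind(n1, n2, n3, n4, deparse.level = 0)
  }
  out <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  storage.mode(out) <- "integer"
  out
}

# generic recursion for other alphabet sizes
partitions_at_most_k <- function(N, k) {
  res <- list()
  part <- integer(k)
  rec <- function(n, pos, max_part) {
    if (n == 0L) {
      res[[length(res) + 1L]] <<- part
      return(invisible(NULL))
    }
    if (pos > k) return(invisible(NULL))
    lo <- ceiling(n / (k - pos + 1L))
    hi <- min(n, max_part)
    if (hi < lo) return(invisible(NULL))
    for (p in hi:lo) {
      part[pos] <<- p
      rec(n - p, pos + 1L, p)
      part[pos] <<- 0L
    }
  }
  rec(N, 1L, N)
  out <- do.call(rbind, res)
  storage.mode(out) <- "integer"
  out
}

# row-wise plug-in entropy in bits of count matrices
partition_entropy_bits <- function(counts, N) {
  p <- counts / N
  lp <- ifelse(counts > 0, log2(p), 0)
  as.numeric(-rowSums(p * lp))
}

# row-wise natural-log class weights; rows are sorted non-increasing, so the
# multiplicity factorials come from run lengths of equal adjacent values
partition_log_weight <- function(counts, N, A) {
  k <- nrow(counts)
  run <- rep(1, k)
  mult_fact <- rep(1, k)
  if (A >= 2L) {
    for (j in 2:A) {
      eq <- counts[, j] == counts[, j - 1L]
      run <- ifelse(eq, run + 1, 1)
      mult_fact <- mult_fact * ifelse(eq, run, 1)
    }
  }
  perm_term <- lfactorial(A) - log(mult_fact)
  motif_term <- lfactorial(N) - rowSums(lfactorial(counts))
  as.numeric(perm_term + motif_term)
}

#' Closed-form count of equivalence classes (DNA alphabet)
#'
#' Number of integer partitions of `N` into at most 4 parts:
#' `round(((N+4)^3 + 3 (N+4)^2 - 9 (N+4) ((N+4) mod 2)) / 144)`.
#' Equals `enumerate_classes(N, 4)$class_count`.
#'
#' @param N Positive integer (vectorized).
#' @return Integer count(s).
#' @export
class_count_closed_form <- function(N) {
  stopifnot(all(N >= 1))
  M <- N + 4
  as.integer(round((M^3 + 3 * M^2 - 9 * M * (M %% 2)) / 144))
}

#' Weight and entropy of a single count vector
#'
#' `class_weight()` returns the number of distinct columns whose count
#' vector is a permutation of `counts`, as a double together with its
#' natural log in attribute `"log"`; `class_weight_exact()` returns the
#' exact integer as a decimal string (arbitrary precision).
#' `class_entropy()` is the plug-in Shannon entropy of the column in bits.
#'
#' @param counts Non-negative integer vector of per-letter counts (length =
#'   alphabet size; canonical order is non-increasing but any permutation
#'   gives the same result).
#' @return See above.
#' @examples
#' class_weight(c(2, 1, 1, 0))  # 144 of the 256 columns with N = 4
#' @export
class_weight <- function(counts) {
  A <- length(counts)
  N <- sum(counts)
  lw <- lfactorial(A) - sum(lfactorial(table(counts))) +
    lfactorial(N) - sum(lfactorial(counts))
  w <- exp(lw)
  if (w < 2^53) w <- round(w)
  structure(w, log = lw)
}

#' @rdname class_weight
#' @export
class_weight_exact <- function(counts) {
  A <- length(counts)
  N <- sum(counts)
  mult <- as.integer(table(counts))
  big_to_string(big_multinomial_product(A, mult, N, counts))
}

#' @rdname class_weight
#' @export
class_entropy <- function(counts) {
  counts_entropy_bits(counts)
}

# ---- tilted sums over a class table --------------------------------------

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Single-column partition function (log scale)
#'
#' \eqn{\log Z_c(\lambda) = \log \sum_{\bar n} w(\bar n)
#'   e^{-\lambda H(\bar n)}}, with entropy in bits. Computed by
#' log-sum-exp so it neither overflows nor underflows at any practical
#' `lam`. At `lam = 0` this is `N log 4`: the log-count of all columns.
#'
#' @param tbl A `class_table` from [enumerate_classes()].
#' @param lam Conjugate (inverse-temperature-like) parameter; positive
#'   values favor low-entropy (conserved) columns.
#' @return Natural-log partition function (scalar).
#' @export
log_partition_column <- function(tbl, lam) {
  stopifnot(inherits(tbl, "class_table"), is.finite(lam))
  log_sum_exp(tbl$log_weight - lam * tbl$entropy)
}

# normalized class probabilities under the entropy tilt
class_probs <- function(tbl, lam) {
  lt <- tbl$log_weight - lam * tbl$entropy
  p <- exp(lt - max(lt))
  p / sum(p)
}

#' Tilted mean and variance of column entropy
#'
#' Exact mean and variance (and third central moment) of the per-column
#' entropy in bits under the tilted distribution
#' \eqn{p(\bar n) \propto w(\bar n) e^{-\lambda H(\bar n)}}. The mean is
#' strictly decreasing in `lam`; the variance equals minus its derivative.
#'
#' @inheritParams log_partition_column
#' @return A list with `mean` (bits), `var` (bits^2) and `mu3` (bits^3,
#'   third central moment).
#' @export
tilted_moments <- function(tbl, lam) {
  p <- class_probs(tbl, lam)
  h <- tbl$entropy
  mu <- sum(p * h)
  v <- sum(p * (h - mu)^2)
  list(mean = mu, var = v, mu3 = sum(p * (h - mu)^3))
}

# ---- exact column sampling -----------------------------------------------

# all permutations of 1..n as a matrix (n! rows); cached
.perm_cache <- new.env(parent = emptyenv())
permutations_of <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) cbind(v[i], rec(v[-i]))))
  }
  out <- rec(seq_len(n))
  .perm_cache[[key]] <- out
  out
}

# distinct assignments of a count multiset to the alphabet positions:
# unique rows among all permutations of the count tuple
distinct_assignments <- function(counts) {
  P <- permutations_of(length(counts))
  unique(matrix(counts[P], nrow(P), ncol(P)))
}

# Stage (1) of the column sampler: class indices ~ w e^{-lam H} / Z_c.
# The entropy (hence IC) of a column is already determined here, so callers
# that only need ICs (e.g. the rejection sampler) can defer the letter
# stages to materialize_columns() for the columns they keep.
sample_class_indices <- function(tbl, lam, n_col) {
  sample.int(tbl$class_count, n_col, replace = TRUE,
             prob = class_probs(tbl, lam))
}

# Stages (2) and (3): for each class index draw an assignment of the count
# multiset to the alphabet letters — uniform among the distinct assignments,
# or tilted by exp(-mu * g) (g = GC fraction) when mu is non-NULL — then a
# uniform random arrangement of the letter multiset over the N rows.
# Returns an N x length(cls) character matrix.
materialize_columns <- function(tbl, cls, mu = NULL, letters = DNA_BASES) {
  N <- tbl$N
  n_col <- length(cls)
  assigned <- matrix(0L, n_col, tbl$alphabet_size)
  for (ci in unique(cls)) {
    idx <- which(cls == ci)
    asg <- distinct_assignments(tbl$counts[ci, ])
    if (nrow(asg) == 1L) {
      ai <- rep(1L, length(idx))
    } else if (is.null(mu)) {
      ai <- sample.int(nrow(asg), length(idx), replace = TRUE)
    } else {
      g <- (asg[, 2] + asg[, 3]) / N      # C and G positions
      wgt <- exp(-mu * g - max(-mu * g))
      ai <- sample.int(nrow(asg), length(idx), replace = TRUE,
                       prob = wgt / sum(wgt))
    }
    assigned[idx, ] <- asg[ai, , drop = FALSE]
  }

  # base letter matrix: column j holds its letter multiset in fixed order
  B <- matrix(rep.int(rep(letters, n_col), as.vector(t(assigned))), N, n_col)
  # stage (3): independent within-column shuffle via a radix-ordered key
  o <- order(rep(seq_len(n_col), each = N), stats::runif(N * n_col))
  matrix(B[o], N, n_col)
}

# all three stages at once
sample_columns <- function(tbl, lam, n_col, mu = NULL, letters = DNA_BASES) {
  materialize_columns(tbl, sample_class_indices(tbl, lam, n_col),
                      mu = mu, letters = letters)
}

#' Draw one column from the tilted column distribution
#'
#' Exact three-stage draw: class by tilted weight, base assignment uniform
#' within the class, letters arranged uniformly over rows. Every column in a
#' class is equiprobable.
#'
#' @inheritParams log_partition_column
#' @return Character vector of `N` letters.
#' @export
sample_column <- function(tbl, lam) {
  drop(sample_columns(tbl, lam, 1L))
}

# ---- caching and serialization -------------------------------------------

.class_table_cache <- new.env(parent = emptyenv())

#' Cached class table lookup
#'
#' Memoized [enumerate_classes()]; tables are keyed by
#' `(N, alphabet_size)` and built at most once per session.
#' @inheritParams enumerate_classes
#' @return A `class_table`.
#' @export
class_table <- function(N, alphabet_size = 4L) {
  key <- paste(N, alphabet_size, sep = "_")
  if (is.null(.class_table_cache[[key]])) {
    .class_table_cache[[key]] <- enumerate_classes(N, alphabet_size)
  }
  .class_table_cache[[key]]
}

#' Serialize a class table to/from tab-separated text
#'
#' The format is a plain TSV with two `#`-prefixed header lines recording
#' `N` and the alphabet size, then one row per class: the representative
#' counts, entropy in bits, and natural-log weight.
#'
#' @param tbl A `class_table`.
#' @param path File path.
#' @return `write_class_table()` returns `path` invisibly;
#'   `read_class_table()` returns a `class_table`.
#' @export
write_class_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "class_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# N=%d", tbl$N),
               sprintf("# alphabet_size=%d", tbl$alphabet_size)), con)
  df <- as.data.frame(tbl$counts)
  names(df) <- paste0("count_", seq_len(tbl$alphabet_size))
  df$entropy <- sprintf("%.17g", tbl$entropy)
  df$log_weight <- sprintf("%.17g", tbl$log_weight)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_class_table
#' @export
read_class_table <- function(path) {
  hdr <- readLines(path, n = 2L)
  N <- as.integer(sub("# N=", "", hdr[1], fixed = TRUE))
  A <- as.integer(sub("# alphabet_size=", "", hdr[2], fixed = TRUE))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L)
  counts <- as.matrix(df[, seq_len(A)])
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  structure(
    list(N = N, alphabet_size = A, counts = counts,
         entropy = as.numeric(df$entropy),
         log_weight = as.numeric(df$log_weight),
         class_count = nrow(counts)),
    class = "class_table"
  )
}
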