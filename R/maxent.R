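# Maximum-entropy motif distribution with a mean-IC constraint.
#
# P(M) = Z^{-1} exp(-lambda * H(M)) over all N x L motifs, equivalently
# proportional to exp(lambda * IC(M)). The distribution factors over
# columns, so tuning and sampling reduce to the single-column class table.

#' Achievable mean-IC interval for a motif ensemble
#'
#' Open interval of mean ICs attainable by the maximum-entropy family:
#' `(L * (2 - H_max(N)), 2 * L)`, where `H_max(N)` is the entropy of the
#' most balanced column count vector. Any finite tilt parameter yields a
#' mean strictly inside this interval; the endpoints are only reached in the
#' infinite-tilt limits.
#'
#' @param N Sites per motif.
#' @param L Motif width (bp).
#' @return Named numeric vector `c(lower, upper)` in bits.
#' @export
achievable_ic_range <- function(N, L) {
  stopifnot(N >= 1, L >= 1)
  base_counts <- rep(N %/% 4, 4) + c(rep(1, N %% 4), rep(0, 4 - N %% 4))
  h_max <- counts_entropy_bits(base_counts)
  c(lower = L * (2 - h_max), upper = 2 * L)
}

#' Fit the maximum-entropy motif model for a target mean IC
#'
#' Tunes the conjugate parameter `lambda` so that the expected IC of the
#' tilted distribution equals `target_ic`. The expected IC is
#' `L * (2 - <H>_lambda)` with `<H>_lambda` the tilted mean column entropy;
#' it is strictly increasing in `lambda`, so a doubling bracket around
#' `[-1, 1]` followed by Brent root-finding (and a Newton polish using the
#' exact tilted variance) always converges for feasible targets.
#'
#' @param N Sites per motif.
#' @param L Motif width (bp).
#' @param target_ic Desired mean IC in bits; must lie strictly inside
#'   [achievable_ic_range()].
#' @param tol Tolerance on the achieved mean IC, in bits.
#' @return An object of class `maxent_model`: list with `N`, `L`, `lam`,
#'   `target_ic`, `achieved_mean_ic`, `sigma2_ic` (variance of IC in
#'   bits^2), and the class table used.
#' @examples
#' fit_maxent(20, 10, target_ic = 10)
#' @export
fit_maxent <- function(N, L, target_ic, tol = 1e-10) {
  rng <- achievable_ic_range(N, L)
  if (!(target_ic > rng["lower"] && target_ic < rng["upper"])) {
    stop(sprintf(
      "target IC %.6g bits is not achievable for N = %d, L = %d; the open interval of feasible mean ICs is (%.6g, %.6g) bits",
      target_ic, N, L, rng["lower"], rng["upper"]), call. = FALSE)
  }
  tbl <- class_table(N)
  mean_ic <- function(lam) L * (2 - tilted_moments(tbl, lam)$mean)

  lo <- -1; hi <- 1
  while (mean_ic(lo) > target_ic) lo <- lo * 2
  while (mean_ic(hi) < target_ic) hi <- hi * 2
  lam <- stats::uniroot(function(x) mean_ic(x) - target_ic, c(lo, hi),
                        tol = .Machine$double.eps^0.5)$root
  # Newton polish: d<IC>/dlam = L * Var(H) per column
  for (i in 1:100) {
    mom <- tilted_moments(tbl, lam)
    diff <- L * (2 - mom$mean) - target_ic
    if (abs(diff) <= tol || mom$var <= 0) break
    lam <- lam - diff / (L * mom$var)
  }
  mom <- tilted_moments(tbl, lam)
  structure(
    list(N = as.integer(N), L = as.integer(L), lam = lam,
         target_ic = target_ic,
         achieved_mean_ic = L * (2 - mom$mean),
         sigma2_ic = L * mom$var,
         class_table = tbl),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model: N = %d, L = %d, lambda = %.6g, mean IC = %.6g bits>\n",
    x$N, x$L, x$lam, x$achieved_mean_ic))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(term = c("lambda", "mean_ic", "var_ic"),
                 estimate = c(x$lam, x$achieved_mean_ic, x$sigma2_ic))
}

#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(n_sites = x$N, width = x$L, lambda = x$lam,
                 target_ic = x$target_ic, mean_ic = x$achieved_mean_ic,
                 var_ic = x$sigma2_ic,
                 n_classes = x$class_table$class_count)
}

# fast untrusted-input-free motif constructor for sampler output
new_motif <- function(sequences, N, L) {
  structure(sequences, N = N, L = L, class = "motif")
}

# per-motif ICs from an N x (n*L) sampled letter matrix
columns_ic <- function(B, N, L, n) {
  counts <- vapply(DNA_BASES, function(b) colSums(B == b), numeric(ncol(B)))
  if (is.null(dim(counts))) counts <- matrix(counts, 1L)
  p <- counts / N
  lp <- ifelse(counts > 0, log2(p), 0)
  h_col <- -rowSums(p * lp)
  as.numeric(rowsum(2 - h_col, rep(seq_len(n), each = L)))
}

# assemble all n motifs from an N x (n*L) letter matrix (vectorized reshape)
assemble_all_motifs <- function(B, N, L, n) {
  C <- matrix(aperm(array(B, c(N, L, n)), c(1, 3, 2)), N * n, L)
  seqs <- do.call(paste0, lapply(seq_len(L), function(j) C[, j]))
  lapply(seq_len(n), function(i) {
    new_motif(seqs[(i - 1L) * N + seq_len(N)], N, L)
  })
}

# assemble all motifs and per-motif ICs from an N x (n*L) letter matrix
motifs_from_columns <- function(B, N, L, n) {
  list(motifs = assemble_all_motifs(B, N, L, n),
       ic = columns_ic(B, N, L, n))
}

#' Sample motifs from a maximum-entropy model
#'
#' Draws `n` i.i.d. motifs by sampling `n * L` columns from the exact tilted
#' column distribution and adjoining them. The probability of any motif
#' depends only on its entropy.
#'
#' @param model A `maxent_model` from [fit_maxent()].
#' @param n Number of motifs.
#' @param seed Optional integer seed; a given seed makes the output
#'   reproducible.
#' @param mu Optional GC tilt parameter (used by [sample_gc()]).
#' @return A tibble of class `motif_sample` with columns `motif`
#'   (list-column of [motif] objects) and `ic` (bits). Model parameters are
#'   attached as attributes.
#' @examples
#' mod <- fit_maxent(20, 10, target_ic = 10)
#' draws <- sample_maxent(mod, 25, seed = 1)
#' mean(draws$ic)
#' @export
sample_maxent <- function(model, n, seed = NULL, mu = NULL) {
  stopifnot(inherits(model, "maxent_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tbl <- model$class_table
  cls <- sample_class_indices(tbl, model$lam, n * model$L)
  ic <- as.numeric(rowsum(2 - tbl$entropy[cls],
                          rep(seq_len(n), each = model$L)))
  B <- materialize_columns(tbl, cls, mu = mu)
  parts <- list(motifs = assemble_all_motifs(B, model$N, model$L, n), ic = ic)
  out <- tibble::tibble(motif = parts$motifs, ic = parts$ic)
  class(out) <- c("motif_sample", class(out))
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}
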