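# Motif IC p-values under the uniform null, estimated via the tilted
# (MaxEnt) family: an analytic bound, a Gaussian moment-matching estimate,
# and a Monte Carlo importance-sampling estimate. Everything is carried on
# the log10 scale so the deep tail (p far below 1e-100) stays representable.

# log of the scaled complementary error function erfcx(x) = exp(x^2) erfc(x);
# pracma's direct evaluation overflows past x ~ 26, so switch to the
# asymptotic series 1/(x sqrt(pi)) (1 - 1/(2x^2) + 3/(4x^4) - 15/(8x^6))
log_erfcx <- function(x) {
  if (x <= 15) {
    log(pracma::erfcx(x))
  } else {
    -log(x) - 0.5 * log(pi) +
      log1p(-0.5 / x^2 + 0.75 / x^4 - 1.875 / x^6)
  }
}

# natural log of Z_Q / Z_P for the IC-form tilt Q(M) = exp(lam IC(M)) / Z_Q
# over N x L motifs: log Z_Q = L (2 lam + log Z_c(lam)), log Z_P = N L log 4
log_zq_over_zp <- function(model) {
  lzc <- log_partition_column(model$class_table, model$lam)
  model$L * (2 * model$lam + lzc) - model$N * model$L * log(4)
}

#' Estimate the p-value of a motif's information content
#'
#' Probability that a uniformly random `N x L` motif has IC strictly
#' greater than `ic`. Three estimates are computed from the MaxEnt family
#' tilted so its mean IC equals `ic`:
#' \itemize{
#'   \item `log10_bound` — the analytic bound
#'     \eqn{(Z_Q/Z_P)\,\tfrac12 e^{-\lambda I}}. The factor 1/2 assumes the
#'     tilted IC distribution is symmetric about `I`; when its skewness
#'     exceeds 1 in magnitude the result is flagged `heuristic_bound`.
#'   \item `log10_moment` — the bound multiplied by
#'     \eqn{\mathrm{erfcx}(\lambda\sigma/\sqrt2)} from a Gaussian
#'     approximation to the tilted IC distribution; never above the bound
#'     for a positive tilt.
#'   \item `log10_is` — importance sampling: the mean of
#'     \eqn{[IC(M_i) > I] e^{-\lambda IC(M_i)}} over `n_is` draws from the
#'     tilted distribution, with a delta-method standard error on the log10
#'     scale.
#' }
#'
#' @param N Sites per motif.
#' @param L Motif width (bp).
#' @param ic IC threshold `I` in bits; must be strictly inside
#'   [achievable_ic_range()].
#' @param n_is Importance-sampling draws (at least 100).
#' @param seed Optional integer seed for the IS draws.
#' @return Object of class `ic_pvalue`; see [tidy.ic_pvalue()] for the
#'   tabular form.
#' @examples
#' pv <- ic_pvalue(20, 10, ic = 12, n_is = 500, seed = 1)
#' tidy(pv)
#' @export
ic_pvalue <- function(N, L, ic, n_is = 2000, seed = NULL) {
  stopifnot(n_is >= 100)
  model <- fit_maxent(N, L, target_ic = ic)
  lam <- model$lam
  logr <- log_zq_over_zp(model)
  sigma2 <- model$sigma2_ic
  sigma <- sqrt(sigma2)
  mom <- tilted_moments(model$class_table, lam)
  skew <- L * mom$mu3 / sigma^3   # third cumulant is additive over columns

  log10_bound <- (logr - lam * ic - log(2)) / log(10)
  log10_moment <- log10_bound + log_erfcx(lam * sigma / sqrt(2)) / log(10)

  draws <- sample_maxent(model, n_is, seed = seed)
  hit <- draws$ic > ic
  if (!any(hit)) {
    warning("no importance-sampling draws exceeded the IC threshold; ",
            "increase n_is")
    log10_is <- -Inf
    se <- NA_real_
  } else {
    lt <- -lam * draws$ic[hit]
    m <- max(lt)
    a <- numeric(n_is)               # weights on a common scale
    a[hit] <- exp(lt - m)
    log_mean <- m + log(sum(a[hit])) - log(n_is)
    log10_is <- (logr + log_mean) / log(10)
    se <- stats::sd(a) / (mean(a) * sqrt(n_is)) / log(10)
  }

  structure(
    list(N = as.integer(N), L = as.integer(L), ic = ic, lam = lam,
         sigma2 = sigma2, skewness = skew,
         heuristic_bound = abs(skew) > 1,
         log10_bound = log10_bound, log10_moment = log10_moment,
         log10_is = log10_is, is_se_log10 = se, n_is = as.integer(n_is)),
    class = "ic_pvalue"
  )
}

#' @export
print.ic_pvalue <- function(x, ...) {
  cat(sprintf("<ic_pvalue: N = %d, L = %d, I = %.4g bits>\n", x$N, x$L, x$ic))
  cat(sprintf("  log10 p: bound %.4g | moment %.4g | IS %.4g (se %.3g, n = %d)\n",
              x$log10_bound, x$log10_moment, x$log10_is, x$is_se_log10, x$n_is))
  if (x$heuristic_bound) {
    cat("  note: tilted IC distribution is strongly skewed; the factor-1/2\n",
        " symmetry assumption behind the bound is heuristic here\n", sep = "")
  }
  invisible(x)
}

#' Tidy an IC p-value result
#'
#' @param x An `ic_pvalue` object.
#' @param ... Unused.
#' @return One-row tibble with the threshold, tilt, variance and the three
#'   log10 estimates with the IS standard error.
#' @export
tidy.ic_pvalue <- function(x, ...) {
  tibble::tibble(
    n_sites = x$N, width = x$L, ic = x$ic, lambda = x$lam,
    sigma2 = x$sigma2, skewness = x$skewness,
    log10_bound = x$log10_bound, log10_moment = x$log10_moment,
    log10_is = x$log10_is, is_se_log10 = x$is_se_log10, n_is = x$n_is,
    heuristic_bound = x$heuristic_bound
  )
}

#' IC p-value estimates over a grid of thresholds
#'
#' Convenience wrapper running [ic_pvalue()] across a vector of IC values;
#' the rows stack into a tibble ready for plotting tail curves.
#'
#' @inheritParams ic_pvalue
#' @param ics Vector of IC thresholds in bits.
#' @return Tibble with one row per threshold (see [tidy.ic_pvalue()]).
#' @export
ic_pvalue_curve <- function(N, L, ics, n_is = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(ics, function(i) tidy(ic_pvalue(N, L, i, n_is = n_is)))
}

#' Convert a motif p-value to an E-value under the OOPS model
#'
#' Under the one-occurrence-per-sequence (OOPS) alignment model, a width-`L`
#' motif can be placed at `m_i - L + 1` offsets in a sequence of length
#' `m_i`, so the number of possible alignments is the product of these and
#' the E-value is the p-value times that count.
#'
#' @param log10_p Motif p-value on the log10 scale.
#' @param sequence_lengths Lengths (bp) of the sequences searched; all must
#'   be at least `L`.
#' @param L Motif width (bp).
#' @return log10 E-value.
#' @examples
#' evalue_oops(-12, rep(109, 10), L = 100)  # multiplier 10^10
#' @export
evalue_oops <- function(log10_p, sequence_lengths, L) {
  if (length(sequence_lengths) == 0L) {
    stop("sequence_lengths must be non-empty", call. = FALSE)
  }
  if (any(sequence_lengths < L)) {
    stop("every sequence must be at least as long as the motif width",
         call. = FALSE)
  }
  log10_p + sum(log10(sequence_lengths - L + 1))
}
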