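# GC-content control: a second tilt exp(-mu * g) on the assignment of the
# count multiset to bases, g being the column GC fraction. The entropy-class
# distribution (stage 1 of the column sampler) is untouched, so the IC
# constraint fitted through lambda is preserved exactly.

# per-class summary of realizable GC fractions and their untilted
# probabilities u(g | n); returns a list of (g, u) per class
class_gc_levels <- function(tbl) {
  lapply(seq_len(tbl$class_count), function(ci) {
    asg <- distinct_assignments(tbl$counts[ci, ])
    g <- (asg[, 2] + asg[, 3]) / tbl$N
    tab <- table(g)
    list(g = as.numeric(names(tab)), u = as.numeric(tab) / nrow(asg))
  })
}

# mean GC fraction of a column under class probs p and GC tilt mu
mean_gc_tilted <- function(levels, p, mu) {
  per_class <- vapply(levels, function(lv) {
    w <- lv$u * exp(-mu * lv$g + mu * min(lv$g))
    sum(lv$g * w) / sum(w)
  }, numeric(1))
  sum(p * per_class)
}

#' Feasible mean-GC interval of an IC-constrained ensemble
#'
#' IC and GC are not independent: a fully conserved column realizes only GC
#' fractions 0 or 1, while a perfectly balanced count vector realizes only
#' 0.5. The attainable mean GC given the fitted IC tilt is the closed
#' interval with endpoints \eqn{\sum_{\bar n} P(\bar n) \min\{g\}} and
#' \eqn{\sum_{\bar n} P(\bar n) \max\{g\}}, with `P` the tilted class
#' distribution at the model's lambda.
#'
#' @param model A `maxent_model` from [fit_maxent()].
#' @return Named numeric `c(lower, upper)` of GC fractions.
#' @export
feasible_gc_range <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  tbl <- model$class_table
  p <- class_probs(tbl, model$lam)
  lv <- class_gc_levels(tbl)
  lo <- sum(p * vapply(lv, function(x) min(x$g), numeric(1)))
  hi <- sum(p * vapply(lv, function(x) max(x$g), numeric(1)))
  c(lower = lo, upper = hi)
}

#' Add a mean-GC constraint to a fitted MaxEnt model
#'
#' Tunes the GC conjugate parameter `mu` so that the expected GC fraction,
#' \deqn{\langle GC \rangle = \sum_{\bar n} P(\bar n) \sum_{g}
#'   g \frac{u(g|\bar n) e^{-\mu g}}{Z(\bar n, \mu)},}
#' equals `target_gc`. Because the IC tilt acts on entropy classes and the
#' GC tilt only reweights base assignments within a class, `lambda` is left
#' untouched and the fitted mean IC is preserved exactly. By symmetry of
#' the A/T and G/C pairs, `target_gc = 0.5` gives `mu = 0`.
#'
#' @param model A `maxent_model`.
#' @param target_gc Desired mean GC fraction, strictly inside
#'   [feasible_gc_range()].
#' @param tol Tolerance on the achieved mean GC.
#' @return Object of class `gc_model`: list with `base` (the MaxEnt model),
#'   `mu`, `target_gc`, `achieved_mean_gc`.
#' @export
fit_gc <- function(model, target_gc, tol = 1e-10) {
  stopifnot(inherits(model, "maxent_model"))
  rng <- feasible_gc_range(model)
  if (!(target_gc > rng["lower"] && target_gc < rng["upper"])) {
    stop(sprintf(
      "target GC %.6g is not achievable at this IC constraint; the feasible mean-GC interval is (%.6g, %.6g)",
      target_gc, rng["lower"], rng["upper"]), call. = FALSE)
  }
  tbl <- model$class_table
  p <- class_probs(tbl, model$lam)
  lv <- class_gc_levels(tbl)
  f <- function(mu) mean_gc_tilted(lv, p, mu) - target_gc
  lo <- -1; hi <- 1
  while (f(hi) > 0) hi <- hi * 2     # mean GC decreases in mu
  while (f(lo) < 0) lo <- lo * 2
  mu <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  for (i in 1:100) {
    d <- f(mu)
    if (abs(d) <= tol) break
    eps <- 1e-6
    slope <- (f(mu + eps) - f(mu - eps)) / (2 * eps)
    if (!is.finite(slope) || slope == 0) break
    mu <- mu - d / slope
  }
  structure(
    list(base = model, mu = mu, target_gc = target_gc,
         achieved_mean_gc = mean_gc_tilted(lv, p, mu)),
    class = "gc_model"
  )
}

#' @export
print.gc_model <- function(x, ...) {
  cat(sprintf(
    "<gc_model: N = %d, L = %d, mean IC = %.6g bits, mean GC = %.6g (mu = %.6g)>\n",
    x$base$N, x$base$L, x$base$achieved_mean_ic, x$achieved_mean_gc, x$mu))
  invisible(x)
}

#' @export
glance.gc_model <- function(x, ...) {
  dplyr::mutate(glance(x$base), mu = x$mu, target_gc = x$target_gc,
                mean_gc = x$achieved_mean_gc)
}

#' Sample motifs matching mean IC and mean GC
#'
#' Identical to [sample_maxent()] except that within each drawn entropy
#' class the base assignment is chosen with probability proportional to
#' `exp(-mu * g)` among the distinct assignments. Large samples match both
#' the IC and the GC targets in expectation.
#'
#' @param model A `gc_model` from [fit_gc()].
#' @param n Number of motifs.
#' @param seed Optional integer seed.
#' @return A `motif_sample` tibble with columns `motif`, `ic` and `gc`.
#' @export
sample_gc <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "gc_model"))
  out <- sample_maxent(model$base, n, seed = seed, mu = model$mu)
  out$gc <- vapply(out$motif, motif_gc, numeric(1))
  attr(out, "gc_model") <- model
  out
}
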