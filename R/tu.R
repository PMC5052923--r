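# Truncated-uniform motif distribution: uniform over all N x L motifs whose
# IC lies in [I - eps, I + eps], sampled by rejection from a MaxEnt proposal
# tuned so its mean IC equals the interval center I.

#' Runtime-optimal half-width for the truncated-uniform sampler
#'
#' The cost of one accepted draw scales roughly as `exp(2 lambda eps) / eps`,
#' minimized at `eps = 1 / (2 lambda)`. The heuristic uses `|lambda|` (a
#' target below the untilted mean IC gives a negative tilt but the same
#' geometry) and is capped at 0.5 bits when `|lambda| < 1`, where the
#' runtime argument breaks down.
#'
#' @param lam Tilt parameter of the MaxEnt proposal.
#' @return Half-width in bits.
#' @examples
#' default_epsilon(5)    # 0.1
#' @export
default_epsilon <- function(lam) {
  if (abs(lam) < 1) {
    if (lam == 0) warning("lambda is 0; using the 0.5-bit cap for epsilon")
    return(0.5)
  }
  1 / (2 * abs(lam))
}

#' Fit a truncated-uniform motif model
#'
#' Prepares the rejection sampler for the uniform distribution over motifs
#' with `IC` in `center_ic +/- epsilon`. The proposal is the MaxEnt model
#' whose mean IC equals `center_ic`; the rejection constant is set at the
#' in-band IC where the proposal density is largest (the lower endpoint for
#' a positive tilt, the upper endpoint for a negative one), so the
#' acceptance ratio is `exp(lambda * (I_min - IC))` (resp. `I_max`) and is
#' never below `exp(-2 |lambda| epsilon)`.
#'
#' @param N Sites per motif.
#' @param L Motif width (bp).
#' @param center_ic Interval center `I` in bits; must be strictly inside
#'   [achievable_ic_range()].
#' @param epsilon Half-width in bits; `NULL` uses [default_epsilon()] at the
#'   fitted tilt.
#' @return Object of class `tu_model`: list with `N`, `L`, `center_ic`,
#'   `epsilon`, `lam` and the `proposal` (`maxent_model`).
#' @export
fit_tu <- function(N, L, center_ic, epsilon = NULL) {
  proposal <- fit_maxent(N, L, center_ic)
  if (is.null(epsilon)) epsilon <- default_epsilon(proposal$lam)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(
    list(N = proposal$N, L = proposal$L, center_ic = center_ic,
         epsilon = epsilon, lam = proposal$lam, proposal = proposal),
    class = "tu_model"
  )
}

#' @export
print.tu_model <- function(x, ...) {
  cat(sprintf(
    "<tu_model: N = %d, L = %d, IC in %.4g +/- %.4g bits, lambda = %.6g>\n",
    x$N, x$L, x$center_ic, x$epsilon, x$lam))
  invisible(x)
}

#' @export
glance.tu_model <- function(x, ...) {
  tibble::tibble(n_sites = x$N, width = x$L, center_ic = x$center_ic,
                 epsilon = x$epsilon, lambda = x$lam,
                 min_acceptance = exp(-2 * abs(x$lam) * x$epsilon))
}

#' Acceptance ratio of the truncated-uniform rejection step
#'
#' For an in-band IC value, the probability of accepting a proposal with
#' that IC. Equals 1 at the band endpoint where the proposal density peaks
#' and is bounded below by `exp(-2 |lambda| epsilon)`. ICs outside the band
#' are rejected before this ratio is evaluated and return `NA`.
#'
#' @param model A `tu_model`.
#' @param ic IC value(s) in bits.
#' @return Acceptance probabilities in `(0, 1]` (or `NA` out of band).
#' @export
acceptance_ratio <- function(model, ic) {
  stopifnot(inherits(model, "tu_model"))
  lam <- model$lam
  # absolute fuzz so band endpoints computed with rounding stay inside
  in_band <- abs(ic - model$center_ic) <= model$epsilon + 1e-9
  anchor <- if (lam >= 0) model$center_ic - model$epsilon else
    model$center_ic + model$epsilon
  out <- exp(lam * (anchor - ic))
  out[!in_band] <- NA_real_
  out
}

#' Sample motifs uniformly from an IC band
#'
#' Rejection sampling with the tuned MaxEnt proposal: proposals landing
#' outside the band are rejected outright (they have target density zero);
#' in-band proposals are accepted with probability [acceptance_ratio()].
#' Conditional on the band, every motif is equiprobable. Both rejection
#' kinds count toward `proposals_used`, so the reported acceptance rate is
#' the fraction of all proposals kept.
#'
#' @param model A `tu_model` from [fit_tu()].
#' @param n Number of motifs to return.
#' @param seed Optional integer seed.
#' @param max_proposals_per_motif Budget guard; if more than
#'   `n * max_proposals_per_motif` proposals are consumed an error is raised
#'   rather than looping indefinitely.
#' @return A tibble of class `tu_sample` with columns `motif` and `ic`, and
#'   attributes `proposals_used`, `acceptance_rate` (accepted over all
#'   proposals, both rejection kinds counted) and `in_band_acceptance` (the
#'   empirical acceptance probability of the ratio test: accepted over
#'   in-band proposals).
#' @examples
#' tu <- fit_tu(20, 5, center_ic = 5, epsilon = 0.25)
#' draws <- sample_tu(tu, 20, seed = 1)
#' range(draws$ic)
#' attr(draws, "acceptance_rate")
#' @export
sample_tu <- function(model, n, seed = NULL, max_proposals_per_motif = 1e6) {
  stopifnot(inherits(model, "tu_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  prop <- model$proposal
  tbl <- prop$class_table
  L <- model$L
  kept_motifs <- list()
  kept_ic <- numeric()
  used <- 0
  in_band_seen <- 0
  budget <- n * max_proposals_per_motif
  # a proposal's IC is fixed by its class draws, so acceptance is decided on
  # class indices alone; letters are materialized only for accepted motifs
  max_batch <- 1e5L
  batch <- min(max(n, 1000L), max_batch)
  while (length(kept_motifs) < n) {
    if (used >= budget) {
      stop(sprintf(
        "rejection budget exhausted after %d proposals (%d/%d accepted); the IC band is too narrow or too far into the tail for these dimensions",
        used, length(kept_motifs), n), call. = FALSE)
    }
    cls <- sample_class_indices(tbl, prop$lam, batch * L)
    ic <- as.numeric(rowsum(2 - tbl$entropy[cls], rep(seq_len(batch), each = L)))
    used <- used + batch
    ar <- acceptance_ratio(model, ic)
    in_band_seen <- in_band_seen + sum(!is.na(ar))
    acc <- which(!is.na(ar) & stats::runif(batch) <= ar)
    if (length(acc)) {
      col_idx <- rep((acc - 1L) * L, each = L) + seq_len(L)
      B <- materialize_columns(tbl, cls[col_idx])
      kept_motifs <- c(kept_motifs,
                       assemble_all_motifs(B, model$N, L, length(acc)))
      kept_ic <- c(kept_ic, ic[acc])
    }
    # adapt batch size to the observed acceptance rate
    rate <- max(length(kept_motifs) / used, 1e-4)
    batch <- as.integer(min(max(ceiling((n - length(kept_motifs)) / rate * 1.2),
                                1000), max_batch))
  }
  out <- tibble::tibble(motif = kept_motifs[seq_len(n)],
                        ic = kept_ic[seq_len(n)])
  class(out) <- c("tu_sample", class(out))
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  attr(out, "proposals_used") <- used
  attr(out, "acceptance_rate") <- n / used
  attr(out, "in_band_acceptance") <-
    if (in_band_seen > 0) length(kept_ic) / in_band_seen else NA_real_
  out
}
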