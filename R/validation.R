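# Brute-force oracles and synthetic validation experiments. Everything here
# is desk-scale: exhaustive enumeration at tiny dimensions, and seeded grid
# studies of IC recovery, IGC-given-IC agreement between the two samplers,
# and motif counting in an IC band.

#' Exhaustively enumerate all motifs of tiny dimension
#'
#' Builds the full table of `4^(N*L)` motifs with their entropies and ICs,
#' for independent verification of the class-table machinery (partition
#' functions, tilted moments, exact p-values, sampler distributions).
#'
#' @param N Sites per motif.
#' @param L Motif width; `4^(N*L)` must not exceed `1e6`.
#' @param lam Tilt parameter at which the `prob` column is normalized.
#' @return A tibble with one row per motif: `key` (the N sites joined by
#'   `|`; omitted above 1e5 motifs), `entropy`, `ic`, and `prob` (exact
#'   tilted probability at `lam`). Attributes `N`, `L`, `lam`.
#' @export
build_oracle <- function(N, L, lam = 0) {
  n_motifs <- 4^(N * L)
  if (n_motifs > 1e6) {
    stop("4^(N*L) exceeds 1e6; the exhaustive oracle is for tiny dimensions",
         call. = FALSE)
  }
  n_cols <- 4^N
  col_idx <- as.matrix(expand.grid(rep(list(1:4), N)))[, N:1, drop = FALSE]
  col_letters <- matrix(DNA_BASES[col_idx], nrow = n_cols)
  col_entropy <- apply(col_idx, 1L, function(v) {
    counts_entropy_bits(tabulate(v, nbins = 4L))
  })

  motif_cols <- as.matrix(expand.grid(rep(list(seq_len(n_cols)), L)))[, L:1, drop = FALSE]
  entropy <- rowSums(matrix(col_entropy[motif_cols], ncol = L))
  ic <- 2 * L - entropy
  lw <- -lam * entropy
  prob <- exp(lw - max(lw))
  prob <- prob / sum(prob)

  key <- if (n_motifs <= 1e5) {
    rows <- lapply(seq_len(N), function(j) {
      do.call(paste0, lapply(seq_len(L), function(l) {
        col_letters[motif_cols[, l], j]
      }))
    })
    do.call(paste, c(rows, sep = "|"))
  } else {
    NULL
  }
  out <- tibble::tibble(entropy = entropy, ic = ic, prob = prob)
  if (!is.null(key)) out <- tibble::add_column(out, key = key, .before = 1)
  attr(out, "N") <- N; attr(out, "L") <- L; attr(out, "lam") <- lam
  out
}

# canonical key of a motif for comparison against oracle tables
motif_key <- function(m) paste(unclass(as_motif(m)), collapse = "|")

#' Sample motifs uniformly at random
#'
#' Draws from the untilted (`lambda = 0`) distribution: every `N x L` motif
#' is equiprobable. Used as the direct-sampling reference for tail
#' probabilities.
#'
#' @param N Sites per motif.
#' @param L Motif width (bp).
#' @param n Number of motifs.
#' @param seed Optional integer seed.
#' @return A `motif_sample` tibble with columns `motif` and `ic`.
#' @export
sample_uniform <- function(N, L, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- sample_columns(class_table(N), 0, n * L)
  parts <- motifs_from_columns(B, N, L, n)
  out <- tibble::tibble(motif = parts$motifs, ic = parts$ic)
  class(out) <- c("motif_sample", class(out))
  out
}

#' IC recovery grid for both samplers
#'
#' For each cell of a grid over site counts and target ICs (motif width
#' fixed), fits the MaxEnt model, draws `n_per_cell` motifs from it and
#' from the truncated-uniform sampler with band `target +/- epsilon`, and
#' records the per-cell mean and SD of sampled IC plus the TU acceptance
#' rate. Each cell derives its own seed from `seed`, so the whole report is
#' reproducible.
#'
#' @param seed Integer seed for the whole grid.
#' @param N_values Site counts (default 20 to 200 in steps of 20).
#' @param targets Target ICs in bits (default 5, 10, 15).
#' @param L Motif width (default 10 bp).
#' @param n_per_cell Motifs per sampler per cell (default 100).
#' @param epsilon TU band half-width in bits (default 0.1).
#' @return A tibble with one row per (N, target, algorithm): `mean_ic`,
#'   `sd_ic`, `mean_dev` (mean minus target), `mc_se`, `acceptance_rate`
#'   and `in_band_acceptance` (TU only), `lambda`, `cell_seed`.
#' @export
ic_recovery_grid <- function(seed, N_values = seq(20, 200, by = 20),
                             targets = c(5, 10, 15), L = 10,
                             n_per_cell = 100, epsilon = 0.1) {
  grid <- tidyr::expand_grid(N = N_values, target = targets)
  rows <- purrr::pmap(grid, function(N, target) {
    cell_seed <- (seed * 7919 + N * 131 + round(target * 17)) %% 2147483647
    model <- fit_maxent(N, L, target)
    me <- sample_maxent(model, n_per_cell, seed = cell_seed)
    tu_mod <- fit_tu(N, L, target, epsilon = epsilon)
    tu <- sample_tu(tu_mod, n_per_cell, seed = cell_seed + 1)
    tibble::tibble(
      N = N, L = L, target_ic = target,
      algorithm = c("maxent", "tu"),
      mean_ic = c(mean(me$ic), mean(tu$ic)),
      sd_ic = c(stats::sd(me$ic), stats::sd(tu$ic)),
      mean_dev = mean_ic - target,
      mc_se = sd_ic / sqrt(n_per_cell),
      acceptance_rate = c(NA_real_, attr(tu, "acceptance_rate")),
      in_band_acceptance = c(NA_real_, attr(tu, "in_band_acceptance")),
      lambda = model$lam,
      cell_seed = cell_seed
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare IGC given IC between the two samplers
#'
#' Along a grid of target ICs (fixed `N`, `L`), draws `n_per_step` motifs
#' from each sampler, records their IGCs, and tests the two IGC samples for
#' a distributional difference with the Kruskal-Wallis test, controlling
#' the FDR across steps at 5% by Benjamini-Hochberg. The TU band uses the
#' runtime-optimal half-width at each step's tilt.
#'
#' @param seed Integer seed.
#' @param L Motif width (default 10 bp).
#' @param N Sites per motif (default 50).
#' @param n_steps Number of IC steps (default 100).
#' @param ic_range Range of total target IC in bits (default 0.1 to 19).
#' @param n_per_step Motifs per sampler per step (default 100).
#' @return A tibble with one row per step: target IC, mean and variance of
#'   IGC under each sampler, the Kruskal-Wallis p-value, its BH-adjusted
#'   value `p_bh`, and `significant` at 5% FDR.
#' @export
igc_ic_comparison <- function(seed, L = 10, N = 50, n_steps = 100,
                              ic_range = c(0.1, 19), n_per_step = 100) {
  targets <- seq(ic_range[1], ic_range[2], length.out = n_steps)
  rows <- purrr::imap(targets, function(target, step) {
    cell_seed <- (seed * 6007 + step * 977) %% 2147483647
    model <- fit_maxent(N, L, target)
    me <- sample_maxent(model, n_per_step, seed = cell_seed)
    tu_mod <- fit_tu(N, L, target)
    tu <- sample_tu(tu_mod, n_per_step, seed = cell_seed + 1)
    igc_me <- vapply(me$motif, function(m) suppressWarnings(igc(m)), numeric(1))
    igc_tu <- vapply(tu$motif, function(m) suppressWarnings(igc(m)), numeric(1))
    kw <- stats::kruskal.test(list(igc_me, igc_tu))
    tibble::tibble(
      step = step, target_ic = target, lambda = model$lam,
      epsilon = tu_mod$epsilon,
      mean_igc_maxent = mean(igc_me), mean_igc_tu = mean(igc_tu),
      var_igc_maxent = stats::var(igc_me), var_igc_tu = stats::var(igc_tu),
      kw_p = kw$p.value, cell_seed = cell_seed
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- stats::p.adjust(out$kw_p, method = "BH")
  out$significant <- out$p_bh < 0.05
  out
}

# log of Phi(b) - Phi(a) for a < b, stable far in the tails
log_normal_interval <- function(a, b) {
  # upper-tail complements: Phi(b) - Phi(a) = Phibar(a) - Phibar(b)
  la <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  lb <- stats::pnorm(b, lower.tail = FALSE, log.p = TRUE)
  la + log1p(-exp(lb - la))
}

#' Estimate the number of motifs in an IC band
#'
#' The count of `N x L` motifs with `IC` in `center_ic +/- epsilon`,
#' estimated on the log10 scale as
#' \eqn{Z_Q \langle [\,|IC - I| \le \epsilon\,] e^{-\lambda IC}\rangle_Q}
#' with the expectation taken by importance sampling from the tilted model
#' centered at `I`. A Gaussian moment-matching analogue (the band integral
#' of the tilted normal approximation) is reported alongside.
#'
#' @param N Sites per motif.
#' @param L Motif width (bp).
#' @param center_ic Band center `I` in bits.
#' @param epsilon Band half-width in bits.
#' @param n_is Importance-sampling draws.
#' @param seed Optional integer seed.
#' @return One-row tibble: `log10_count` (importance sampling),
#'   `se_log10`, `log10_count_moment`, `n_is`, `lambda`.
#' @examples
#' count_motifs_in_ic_band(4, 2, 6, 0.5, n_is = 500, seed = 1)
#' @export
count_motifs_in_ic_band <- function(N, L, center_ic, epsilon, n_is = 10000,
                                    seed = NULL) {
  # the importance-sampling identity is valid at any tilt; centering the
  # proposal at the band center is merely variance-optimal, so bands whose
  # center touches the achievable boundary use the nearest interior tilt
  rng <- achievable_ic_range(N, L)
  pad <- 0.02 * (rng["upper"] - rng["lower"])
  target <- unname(min(max(center_ic, rng["lower"] + pad), rng["upper"] - pad))
  model <- fit_maxent(N, L, target_ic = target)
  lam <- model$lam
  log_zq <- L * (2 * lam + log_partition_column(model$class_table, lam))
  draws <- sample_maxent(model, n_is, seed = seed)
  hit <- abs(draws$ic - center_ic) <= epsilon
  if (!any(hit)) {
    stop("no importance-sampling draws landed in the band; increase n_is",
         call. = FALSE)
  }
  lt <- -lam * draws$ic[hit]
  m <- max(lt)
  a <- numeric(n_is)
  a[hit] <- exp(lt - m)
  log_mean <- m + log(sum(a[hit])) - log(n_is)
  log10_is <- (log_zq + log_mean) / log(10)
  se <- stats::sd(a) / (mean(a) * sqrt(n_is)) / log(10)

  # Gaussian analogue with the proposal mean m (= center unless clamped):
  # int_a^b e^{-lam x} phi(x; m, s^2) dx
  sigma <- sqrt(model$sigma2_ic)
  m_q <- model$achieved_mean_ic
  a_b <- center_ic + c(-1, 1) * epsilon
  log_band <- lam^2 * sigma^2 / 2 - lam * m_q +
    log_normal_interval((a_b[1] - m_q + lam * sigma^2) / sigma,
                        (a_b[2] - m_q + lam * sigma^2) / sigma)
  log10_moment <- (log_zq + log_band) / log(10)

  tibble::tibble(log10_count = log10_is, se_log10 = se,
                 log10_count_moment = log10_moment,
                 n_is = as.integer(n_is), lambda = lam)
}
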