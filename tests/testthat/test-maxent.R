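test_that("achievable IC interval has the right endpoints", {
  # N divisible by 4: the balanced column reaches 2 bits of entropy
  expect_equal(unname(achievable_ic_range(8, 3)["lower"]), 0)
  expect_equal(unname(achievable_ic_range(8, 3)["upper"]), 6)
  # N = 2: max column entropy is 1 bit, so mean IC per column is in (1, 2)
  expect_equal(unname(achievable_ic_range(2, 1)), c(1, 2))
  # untilted mean IC lies inside the interval
  for (N in c(2, 5, 20)) {
    rng <- achievable_ic_range(N, 4)
    m0 <- fit_maxent(N, 4, mean(rng))
    expect_gt(m0$achieved_mean_ic, rng["lower"])
    expect_lt(m0$achieved_mean_ic, rng["upper"])
  }
})

test_that("lambda tuning reaches the target mean IC", {
  # N = 2, L = 1: uniform sampling gives mean H = 0.75, mean IC = 1.25
  mod <- fit_maxent(2, 1, 1.25)
  expect_lt(abs(mod$lam), 1e-7)
  expect_equal(mod$achieved_mean_ic, 1.25, tolerance = 1e-10)

  mod2 <- fit_maxent(50, 10, 10)
  expect_equal(mod2$achieved_mean_ic, 10, tolerance = 1e-10)
  # independent recomputation of the tilted mean from the raw class table
  tab <- tidy(mod2$class_table)
  lt <- tab$log_weight - mod2$lam * tab$entropy
  p <- exp(lt - max(lt)); p <- p / sum(p)
  expect_equal(10 * (2 - sum(p * tab$entropy)), 10, tolerance = 1e-9)

  expect_error(fit_maxent(4, 3, 6), "achievable")     # IC = 2L boundary
  expect_error(fit_maxent(8, 2, -0.5), "achievable")
})

test_that("achieved mean IC increases with lambda", {
  tbl <- class_table(12)
  ics <- vapply(seq(-5, 40, by = 5),
                function(l) 2 - tilted_moments(tbl, l)$mean, numeric(1))
  expect_true(all(diff(ics) > 0))
})

test_that("maxent samples recover the target mean IC", {
  mod <- fit_maxent(50, 10, 10)
  s <- sample_maxent(mod, 200, seed = 21)
  expect_equal(nrow(s), 200L)
  se <- sd(s$ic) / sqrt(200)
  expect_lt(abs(mean(s$ic) - 10), 3 * se)
  # sampled motifs have the right shape and valid letters
  m <- s$motif[[17]]
  expect_identical(attr(m, "N"), 50L)
  expect_identical(attr(m, "L"), 10L)
  expect_false(grepl("[^ACGT]", paste(unclass(m), collapse = "")))
})

test_that("untilted sampling is uniform over all columns", {
  s <- sample_uniform(2, 1, 20000, seed = 8)
  keys <- vapply(s$motif, function(m) paste(unclass(m), collapse = ""), character(1))
  tab <- table(factor(keys, levels = do.call(paste0, expand.grid(BASES, BASES))))
  expect_length(tab, 16L)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("sampling probability depends only on motif entropy (sufficiency)", {
  mod <- fit_maxent(3, 2, 3)
  s <- sample_maxent(mod, 50000, seed = 13)
  keys <- vapply(s$motif, motifnull:::motif_key, character(1))
  oracle <- build_oracle(3, 2, lam = mod$lam)
  counts <- table(factor(keys, levels = oracle$key))
  # within an entropy class all motifs are equiprobable: compare the
  # occupied classes' internal spread against multinomial expectation
  by_class <- split(as.numeric(counts), round(oracle$entropy, 9))
  for (cls in by_class) {
    if (sum(cls) < 200 || length(cls) < 2) next
    expect_gt(suppressWarnings(chisq.test(cls))$p.value, 0.001)
  }
  # and across classes the totals match the exact tilted probabilities
  probs <- vapply(split(oracle$prob, round(oracle$entropy, 9)), sum, numeric(1))
  totals <- vapply(by_class, sum, numeric(1))
  expect_gt(suppressWarnings(chisq.test(totals, p = probs))$p.value, 0.001)
})

test_that("sampling is byte-identical under a fixed seed", {
  mod <- fit_maxent(20, 6, 6)
  a <- sample_maxent(mod, 30, seed = 99)
  b <- sample_maxent(mod, 30, seed = 99)
  expect_identical(lapply(a$motif, unclass), lapply(b$motif, unclass))
  expect_identical(a$ic, b$ic)
})

test_that("model accessors expose the fitted parameters", {
  mod <- fit_maxent(20, 5, 5)
  g <- glance(mod)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$mean_ic, 5, tolerance = 1e-9)
  td <- tidy(mod)
  expect_true(all(c("lambda", "mean_ic") %in% td$term))
})
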