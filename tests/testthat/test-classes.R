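test_that("class enumeration produces the integer partitions of N", {
  ct1 <- enumerate_classes(1)
  expect_equal(ct1$class_count, 1L)
  expect_equal(ct1$counts, matrix(c(1L, 0L, 0L, 0L), 1))

  ct4 <- enumerate_classes(4)
  expect_equal(ct4$class_count, 5L)
  have <- apply(ct4$counts, 1, paste, collapse = ",")
  expect_setequal(have, c("4,0,0,0", "3,1,0,0", "2,2,0,0", "2,1,1,0", "1,1,1,1"))
  # canonical representatives are non-increasing
  expect_true(all(apply(ct4$counts, 1, function(v) all(diff(v) <= 0))))

  expect_error(enumerate_classes(5, alphabet_size = 1), "alphabet_size")
  expect_error(enumerate_classes(5, alphabet_size = 25), "alphabet_size")
})

test_that("closed-form class count matches enumeration up to N = 300", {
  for (N in c(1:50, 75, 100, 143, 200, 300)) {
    expect_identical(class_count_closed_form(N),
                     enumerate_classes(N)$class_count)
  }
})

test_that("class weights count columns exactly (brute force at N = 4)", {
  expect_equal(as.numeric(class_weight(c(4, 0, 0, 0))), 4)
  expect_equal(as.numeric(class_weight(c(1, 1, 1, 1))), 24)
  expect_equal(as.numeric(class_weight(c(2, 1, 1, 0))), 144)

  # brute force: classify all 256 columns by sorted count vector
  cols <- enumerate_columns(4)
  keys <- vapply(cols, function(cl) {
    paste(sort(tabulate(match(cl, BASES), 4), decreasing = TRUE),
          collapse = ",")
  }, character(1))
  counts <- table(keys)
  ct <- enumerate_classes(4)
  for (i in seq_len(ct$class_count)) {
    key <- paste(ct$counts[i, ], collapse = ",")
    expect_equal(exp(ct$log_weight[i]), as.numeric(counts[[key]]),
                 tolerance = 1e-12)
  }
  expect_equal(sum(exp(ct$log_weight)), 256)
})

test_that("exact and log-gamma weight paths agree", {
  set.seed(3)
  for (N in c(6, 12, 25)) {
    ct <- enumerate_classes(N)
    for (i in sample(ct$class_count, min(5, ct$class_count))) {
      exact <- as.numeric(class_weight_exact(ct$counts[i, ]))
      expect_equal(exp(ct$log_weight[i]), exact, tolerance = 1e-9)
    }
  }
})

test_that("class weights sum to 4^N exactly for a spread of N (big integers)", {
  for (N in c(1, 2, 7, 16, 30)) {
    ct <- enumerate_classes(N)
    total <- Reduce(function(acc, i) {
      motifnull:::big_add(acc, motifnull:::big_multinomial_product(
        4, as.integer(table(ct$counts[i, ])), N, ct$counts[i, ]))
    }, seq_len(ct$class_count), motifnull:::big_from_int(0))
    expect_true(motifnull:::big_eq(total, motifnull:::big_pow_small(4, N)))
  }
})

test_that("column partition function matches direct summation", {
  ct2 <- enumerate_classes(2)
  # lam = 0: Z = 4^N
  expect_equal(log_partition_column(ct2, 0), 2 * log(4), tolerance = 1e-12)
  # N = 2, lam = 1: 4 columns with H = 0, 12 with H = 1 (bits)
  expect_equal(log_partition_column(ct2, 1), log(4 + 12 * exp(-1)),
               tolerance = 1e-12)
  # strong tilt: only the 4 monomorphic columns survive
  expect_equal(log_partition_column(enumerate_classes(4), 500), log(4),
               tolerance = 1e-9)
  # brute force across N and lam
  for (N in 2:5) {
    ct <- enumerate_classes(N)
    for (lam in c(-2, 0, 1, 5)) {
      bf <- brute_force_column_stats(N, lam)
      expect_equal(log_partition_column(ct, lam), bf$log_z, tolerance = 1e-9)
      mom <- tilted_moments(ct, lam)
      expect_equal(mom$mean, bf$mean, tolerance = 1e-9)
      expect_equal(mom$var, bf$var, tolerance = 1e-9)
    }
  }
})

test_that("tilted mean entropy decreases in lam and hits its limits", {
  ct <- enumerate_classes(6)
  expect_equal(tilted_moments(enumerate_classes(2), 0)$mean, 0.75,
               tolerance = 1e-12)
  lam_grid <- seq(-10, 30, by = 2.5)
  means <- vapply(lam_grid, function(l) tilted_moments(ct, l)$mean, numeric(1))
  expect_true(all(diff(means) < 0))
  far <- tilted_moments(ct, 400)
  expect_lt(far$mean, 1e-6)
  expect_lt(far$var, 1e-6)
})

test_that("two-letter alphabet machinery matches its 2^N brute force", {
  for (N in c(3, 8, 12)) {
    ct <- enumerate_classes(N, alphabet_size = 2)
    expect_equal(sum(exp(ct$log_weight)), 2^N, tolerance = 1e-9)
    bf <- brute_force_column_stats(N, 0.7, A = 2)
    expect_equal(log_partition_column(ct, 0.7), bf$log_z, tolerance = 1e-9)
    expect_equal(tilted_moments(ct, 0.7)$mean, bf$mean, tolerance = 1e-9)
  }
})

test_that("column sampler reproduces exact class probabilities", {
  # N = 1: single class, each base 1/4
  set.seed(5)
  ct1 <- enumerate_classes(1)
  draws <- motifnull:::sample_columns(ct1, 3, 8000)
  tab <- table(factor(drop(draws), levels = BASES))
  expect_gt(chisq.test(tab)$p.value, 0.001)

  # N = 4, lam = 6: class frequencies ~ w e^{-lam H} / Z
  ct4 <- enumerate_classes(4)
  p <- motifnull:::class_probs(ct4, 6)
  cls <- motifnull:::sample_class_indices(ct4, 6, 20000)
  obs <- tabulate(cls, nbins = 5)
  expect_gt(suppressWarnings(chisq.test(obs, p = p))$p.value, 0.001)

  # letters within a sampled column realize the drawn class
  B <- motifnull:::sample_columns(ct4, 1, 500)
  keys <- apply(B, 2, function(cl) {
    paste(sort(tabulate(match(cl, BASES), 4), decreasing = TRUE), collapse = ",")
  })
  expect_true(all(keys %in% apply(ct4$counts, 1, paste, collapse = ",")))
})

test_that("class tables serialize losslessly and the cache returns them", {
  ct <- enumerate_classes(9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_class_table(ct, path)
  back <- read_class_table(path)
  expect_equal(back$counts, ct$counts)
  expect_equal(back$entropy, ct$entropy, tolerance = 1e-15)
  expect_equal(back$log_weight, ct$log_weight, tolerance = 1e-15)
  expect_identical(class_table(9)$class_count, ct$class_count)
  expect_s3_class(tidy(ct), "tbl_df")
  expect_named(tidy(ct), c(paste0("count_", 1:4), "entropy", "log_weight"))
})
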