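test_that("motif construction validates dimensions and alphabet", {
  m <- motif(c("acgt", "ACGT"))
  expect_s3_class(m, "motif")
  expect_identical(as.character(m), c("ACGT", "ACGT"))
  expect_identical(attr(m, "N"), 2L)
  expect_identical(attr(m, "L"), 4L)

  expect_error(motif(c("ACGT", "ACG")), "equal length")
  expect_error(motif(character()), "at least one site")
  expect_error(motif(c("ACGN", "ACGT")), "outside")
  expect_error(motif(c("AC-T", "ACGT")), "outside")
})

test_that("FASTA and lines round trips preserve motifs", {
  m <- motif(c("ACGTAC", "ACGTTT", "ACGTAA"))
  for (fmt in c("fasta", "lines")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_motifs(m, path, format = fmt)
    expect_identical(as.character(read_motif(path, format = fmt)), as.character(m))
  }
  # two motifs produce two header-separated blocks
  path <- withr::local_tempfile()
  write_motifs(list(m, m), path, format = "fasta")
  lines <- readLines(path)
  expect_length(grep("^>motif[12]_site", lines), 6L)
  expect_error(write_motifs(list(), tempfile()), "no motifs")
})

test_that("FASTA reading handles wrapping, comments, and empty input", {
  path <- withr::local_tempfile()
  writeLines(c(">s1", "ACG", "TAC", ">s2", "ACGTAC"), path)
  m <- read_motif(path)
  expect_identical(as.character(m), c("ACGTAC", "ACGTAC"))

  writeLines(c("# a comment", "acgt", "", "ACGT"), path)
  m2 <- read_motif(path, format = "lines")
  expect_identical(as.character(m2), c("ACGT", "ACGT"))

  writeLines(character(), path)
  expect_error(read_motif(path), "no sequences")
})

test_that("entropy and IC match hand-computed column values", {
  expect_equal(motif_entropy(motif(c("A", "A", "A", "A"))), 0)
  expect_equal(motif_entropy(motif(c("A", "C", "G", "T"))), 2)
  expect_equal(motif_entropy(motif(c("A", "A", "C", "G"))), 1.5)

  expect_equal(motif_ic(motif(c("AAA", "CCC", "GGG", "TTT"))), 0)
  expect_equal(motif_ic(motif(rep("AAA", 4))), 6)
  expect_equal(motif_ic(motif(c("A", "A", "C", "G"))), 0.5)
})

test_that("positional profile is consistent with the motif totals", {
  m <- motif(c("AA", "AC", "AG", "AT"))
  prof <- positional_ic(m)
  expect_equal(prof$ic, c(2, 0))
  expect_equal(attr(prof, "total_ic"), motif_ic(m))

  for (i in 1:25) {
    m <- random_motif(sample(2:8, 1), sample(1:6, 1))
    expect_equal(sum(positional_ic(m)$ic), motif_ic(m), tolerance = 1e-12)
  }
})

test_that("IC and entropy are complementary: IC + H = 2L", {
  set.seed(42)
  for (i in 1:200) {
    m <- random_motif(sample(1:12, 1), sample(1:8, 1))
    L <- attr(m, "L")
    expect_lt(abs(motif_ic(m) + motif_entropy(m) - 2 * L), 1e-9)
  }
})

test_that("IGC matches hand values and the mean-absolute-difference oracle", {
  # identical column ICs -> 0
  expect_equal(igc(motif(c("AT", "AT", "CG", "CG"))), 0)
  # column ICs (0, 2) at L = 2 -> (L-1)/L = 0.5
  expect_equal(igc(motif(c("AA", "CA", "GA", "TA"))), 0.5)
  # direct formula evaluation vs the Lorenz/MAD identity
  expect_equal(motifnull:::gini_sorted(c(1, 1, 1, 1)), 0)
  expect_equal(motifnull:::gini_sorted(c(0, 0, 0, 4)), 0.75)
  set.seed(7)
  for (i in 1:50) {
    x <- runif(sample(2:10, 1))
    expect_equal(motifnull:::gini_sorted(x), gini_mad(x), tolerance = 1e-12)
  }
})

test_that("IGC is invariant to column order, base relabeling, and row order", {
  set.seed(11)
  m <- random_motif(6, 5)
  mat <- as.matrix(m)
  g0 <- igc(m)
  # permute columns
  expect_equal(igc(motifnull:::motif_from_matrix(mat[, c(3, 1, 5, 2, 4)])), g0)
  # relabel bases within one column (A<->T, C<->G in column 2)
  relab <- mat
  relab[, 2] <- chartr("ACGT", "TGCA", relab[, 2])
  expect_equal(igc(motifnull:::motif_from_matrix(relab)), g0)
  # permute rows; all statistics are order-invariant
  perm <- mat[sample(nrow(mat)), ]
  expect_equal(igc(motifnull:::motif_from_matrix(perm)), g0)
  expect_equal(motif_ic(motifnull:::motif_from_matrix(perm)), motif_ic(m))
})

test_that("IGC is bounded by (L-1)/L over all tiny motifs and warns at zero IC", {
  ics <- expand.grid(rep(list(BASES), 4))
  # all 256 motifs with N = 2, L = 2 (rows: two sites of two letters)
  vals <- apply(ics, 1, function(r) {
    m <- motif(c(paste0(r[1], r[2]), paste0(r[3], r[4])))
    if (motif_ic(m) < 1e-12) return(NA_real_)
    igc(m)
  })
  expect_true(all(vals[!is.na(vals)] <= 0.5 + 1e-12))
  expect_true(all(vals[!is.na(vals)] >= -1e-12))
  expect_warning(g0 <- igc(motif(c("A", "C", "G", "T"))), "zero")
  expect_equal(g0, 0)
})

test_that("GC fraction counts G and C letters", {
  expect_equal(motif_gc(motif(c("AAAA", "AAAA"))), 0)
  expect_equal(motif_gc(motif(c("GG", "GG"))), 1)
  expect_equal(motif_gc(motif(c("AC", "GT"))), 0.5)
  st <- motif_stats(motif(c("AC", "GT")))
  expect_s3_class(st, "tbl_df")
  expect_equal(st$ic, 4 - st$entropy)
})
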