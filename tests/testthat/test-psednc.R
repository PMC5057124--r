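std_tab <- standardize_properties(builtin_property_table())

test_that("dinucleotide frequencies follow the counting conventions", {
  f <- dinucleotide_frequencies("AAAA")
  expect_equal(unname(f["AA"]), 1)
  expect_equal(sum(f), 1)

  f_ov <- dinucleotide_frequencies("ACAC")
  expect_equal(unname(f_ov["AC"]), 2 / 3)
  expect_equal(unname(f_ov["CA"]), 1 / 3)

  f_no <- dinucleotide_frequencies("ACAC", "non_overlapping")
  expect_equal(unname(f_no["AC"]), 1)
  expect_equal(sum(f_no != 0), 1L)

  # odd length: non-overlapping counts floor(L/2) dinucleotides
  f_odd <- dinucleotide_frequencies("ACACG", "non_overlapping")
  expect_equal(sum(f_odd), 1)
  expect_equal(unname(f_odd["AC"]), 1)  # positions 1-2 and 3-4

  expect_error(dinucleotide_frequencies("A"), "dinucleotide")
})

test_that("pairwise correlation is the mean squared z-score difference", {
  expect_equal(correlation_theta("AA", "AA", std_tab), 0)
  expect_equal(correlation_theta("AA", "UU", std_tab), 0)  # identical rows
  expect_equal(correlation_theta("AA", "CG", std_tab),
               oracle_theta_fun("AA", "CG", oracle_standardize(unclass(builtin_property_table()))))
  expect_gt(correlation_theta("AA", "CG", std_tab), 0)
  expect_error(correlation_theta("AA", "CG", builtin_property_table()),
               "standardized")
})

test_that("tier correlation averages over the available dinucleotide pairs", {
  polyA <- strrep("A", 51)
  for (j in c(1, 4, 10)) expect_equal(tier_correlation(polyA, j, std_tab), 0)

  # j = L - 2 leaves a single pair: Theta(T_1, T_(L-1))
  win <- "ACGUA"
  expect_equal(tier_correlation(win, 3, std_tab),
               correlation_theta("AC", "UA", std_tab))
  expect_error(tier_correlation(win, 4, std_tab), "out of range")

  # period-2 sequence: dinucleotides repeat with period 2, so theta_2 = 0
  expect_equal(tier_correlation(strrep("AC", 12), 2, std_tab), 0)
  expect_gt(tier_correlation(strrep("AC", 12), 1, std_tab), 0)
})

test_that("encoding has dimension 16 + lambda and honours the limiting cases", {
  v <- psednc(site_window(strrep("A", 51)))
  expect_identical(ncol(v), 20L)
  expect_equal(unname(v[1, "AA"]), 1)
  expect_equal(sum(v[1, -1]), 0)

  # w = 0: first 16 components are exactly the frequencies, pseudo part 0
  set.seed(7)
  win <- random_window51()
  v0 <- psednc(win, psednc_config(w = 0, lambda = 3))
  expect_identical(ncol(v0), 19L)
  expect_equal(v0[1, 1:16], dinucleotide_frequencies(win))
  expect_equal(unname(v0[1, 17:19]), c(0, 0, 0))

  expect_error(psednc("ACGU", psednc_config(lambda = 10)), "too large")
})

test_that("production encoder matches the brute-force oracle", {
  set.seed(2024)
  for (i in 1:25) {
    len <- sample(10:80, 1)
    res <- random_residues(len)
    w <- round(runif(1), 1)
    lam <- sample.int(min(8, len - 2), 1)
    mode <- sample(c("overlapping", "non_overlapping"), 1)
    got <- psednc(res, psednc_config(w = w, lambda = lam, counting_mode = mode))
    want <- oracle_psednc(res, w, lam, mode)
    expect_equal(unname(got[1, ]), unname(want), tolerance = 1e-12,
                 info = sprintf("len=%d w=%g lam=%d %s", len, w, lam, mode))
  }
})

test_that("feature vectors are non-negative and sum to one", {
  set.seed(11)
  for (i in 1:40) {
    cfg <- psednc_config(w = runif(1), lambda = sample.int(10, 1))
    v <- psednc(random_window51(), cfg)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("increasing lambda preserves composition component ratios", {
  set.seed(5)
  win <- random_window51()
  v4 <- psednc(win, psednc_config(w = 0.3, lambda = 4))
  v5 <- psednc(win, psednc_config(w = 0.3, lambda = 5))
  nz <- which(v4[1, 1:16] > 0)
  r4 <- v4[1, nz] / v4[1, nz[1]]
  r5 <- v5[1, nz] / v5[1, nz[1]]
  expect_equal(r4, r5, tolerance = 1e-12)
})

test_that("windows with equal dinucleotide counts differ only through the pseudo part", {
  # one is a rotation of the other, so the dinucleotide multisets agree
  s1 <- "AACGCA"
  s2 <- "ACGCAA"
  expect_equal(dinucleotide_frequencies(s1), dinucleotide_frequencies(s2))

  cfg <- psednc_config(w = 0.5, lambda = 2)
  v1 <- psednc(s1, cfg)[1, ]
  v2 <- psednc(s2, cfg)[1, ]
  nz <- which(v1[1:16] > 0)
  expect_equal(unname(v1[nz] / sum(v1[nz])), unname(v2[nz] / sum(v2[nz])),
               tolerance = 1e-12)
})

test_that("batch encoding writes tabular and sparse libsvm text", {
  set.seed(3)
  wins <- replicate(4, random_window51())
  feats <- psednc(as.list(wins))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(feats, tsv, labels = c(1, 1, -1, -1))
  df <- read.delim(tsv)
  expect_identical(dim(df), c(4L, 22L))  # id + label + 20 features

  svm <- withr::local_tempfile(fileext = ".txt")
  write_feature_table(feats, svm, labels = c(1, 1, -1, -1), format = "libsvm")
  lines <- readLines(svm)
  expect_length(lines, 4L)
  expect_match(lines[1], "^1 \\d+:")
})
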