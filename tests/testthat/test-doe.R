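test_that("coding and decoding are exact inverses above the clip", {
  factors <- cod_factors()
  set.seed(11)
  for (i in 1:20) {
    x <- matrix(runif(5, c(0.1, 0.1, 0.1, 0.005, 0.01),
                      c(1.5, 1.5, 1.5, 0.05, 0.3)), nrow = 1)
    expect_equal(drop(decode_values(code_values(x, factors), factors)),
                 drop(x), tolerance = 1e-12, ignore_attr = TRUE)
  }
  # the soybean factorial level and star spacing of the bundled design
  expect_equal(drop(code_values(c(1.125, 0.75, 0.75, 0.025, 0.15), factors)),
               c(1, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(unname(drop(code_values(c(1.5, 0.75, 0.75, 0.025, 0.15), factors))[1]), 2)
  # decode at the centre and clipping of a -2 NaCl star to the floor
  expect_equal(drop(decode_values(rep(0, 5), factors)),
               c(0.75, 0.75, 0.75, 0.025, 0.15), ignore_attr = TRUE)
  expect_equal(unname(drop(decode_values(c(0, 0, 0, 0, -2), factors))[5]), 5e-4)
})

test_that("generated CCDs have the Box-Wilson run counts for k = 2..10", {
  for (k in 2:10) {
    f <- lapply(seq_len(k), function(i) factor_spec(paste0("v", i), 1, 0.5))
    names(f) <- paste0("v", seq_len(k))
    half <- generate_ccd(f, n_center = 3, fraction = "half")
    full <- generate_ccd(f, n_center = 3, fraction = "full")
    expect_equal(nrow(half), 2^(k - 1) + 2 * k + 3)
    expect_equal(nrow(full), 2^k + 2 * k + 3)
    expect_equal(sum(half$point_type == "star"), 2 * k)
  }
})

test_that("design structure: centre rows coded zero, stars one-axis, factorial orthogonal", {
  des <- generate_ccd(cod_factors(), n_center = 10)
  coded <- attr(des, "coded")
  expect_true(all(coded[des$point_type == "center", ] == 0))
  star <- coded[des$point_type == "star", ]
  expect_true(all(rowSums(star != 0) == 1))
  fac <- coded[des$point_type == "factorial", ]
  expect_true(all(fac %in% c(-1, 1)))
  gram <- crossprod(fac)
  expect_equal(gram[upper.tri(gram)], rep(0, 10))
  # resolution-V half fraction: defining relation x5 = x1 x2 x3 x4
  expect_equal(fac[, 5], apply(fac[, 1:4], 1, prod))
})

test_that("invalid factor specifications are rejected", {
  expect_error(factor_spec("a", 1, 0), "half_range")
  expect_error(factor_spec("a", 1, -0.5), "half_range")
  expect_error(factor_spec("a", 1, 0.5, alpha = 0.5), "alpha")
  f <- list(factor_spec("a", 1, 0.5), factor_spec("a", 2, 0.5))
  expect_error(generate_ccd(f, 1), "duplicate")
  expect_error(code_values(c(1, 2, 3), cod_factors()), "length")
  expect_error(decode_values(1:4, cod_factors()), "columns|length")
})

test_that("bundled dataset loads with the documented layout", {
  d <- cod_design()
  expect_equal(nrow(d), 36)
  expect_equal(as.vector(table(d$point_type)[c("factorial", "star", "center")]),
               c(16, 10, 10))
  expect_equal(as.vector(table(d$split)[c("train", "test", "validation")]),
               c(24, 6, 6))
  expect_equal(d$observed[d$run == 27], 3.08)
  expect_equal(sort(d$run[d$split == "validation"]), c(2, 8, 17, 25, 31, 34))
  expect_equal(sort(d$run[d$split == "test"]), c(5, 11, 16, 20, 28, 32))
  expect_true(all(c("pred_rsm", "pred_ann") %in% names(d)))
})

test_that("regenerating the bundled design reproduces it except the flagged cell", {
  d <- cod_design()
  g <- generate_ccd(cod_factors(), n_center = 10, fraction = "half")
  Xd <- design_matrix(d)
  Xg <- design_matrix(g)
  # run 24's MgSO4 is the known suspect transcription (0.5 vs. the star
  # pattern's 0.05); every other cell must match exactly
  mism <- which(abs(Xd - Xg) > 1e-12, arr.ind = TRUE)
  expect_equal(nrow(mism), 1L)
  expect_equal(unname(mism[1, ]), c(24L, 4L))
  expect_equal(Xg[24, 4], 0.05)
  expect_equal(Xd[24, 4], 0.5)
  expect_equal(d$point_type, g$point_type)
})

test_that("design tables survive a CSV round trip", {
  d <- cod_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, path)
  d2 <- read_design_csv(path, cod_factors())
  expect_equal(as.data.frame(d2), as.data.frame(d))
  expect_s3_class(d2, "ccd_design")
})

test_that("split assignment is seeded and respects requested sizes", {
  des <- generate_ccd(cod_factors(), n_center = 10)
  a <- assign_splits(des, n_test = 6, n_validation = 6, seed = 3)
  b <- assign_splits(des, n_test = 6, n_validation = 6, seed = 3)
  expect_identical(a$split, b$split)
  expect_equal(sum(a$split == "train"), 24)
  expect_error(assign_splits(des, n_test = 20, n_validation = 20), "training")
})
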