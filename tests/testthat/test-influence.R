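test_that("forward_dose is the sparse matrix-vector product and linear", {
  infl <- random_influence(1, n_vox = 40, n_beam = 8)
  x <- stats::runif(8)
  expect_equal(forward_dose(infl, x), dense_forward(infl, x))
  expect_equal(forward_dose(infl, numeric(8)), numeric(40))
  # unit vector returns the matching column
  e3 <- replace(numeric(8), 3, 1)
  expect_equal(forward_dose(infl, e3), as.numeric(infl$dose[, 3]))
  # linearity
  x2 <- stats::runif(8)
  expect_equal(forward_dose(infl, 2 * x + 3 * x2),
               2 * forward_dose(infl, x) + 3 * forward_dose(infl, x2))
  expect_error(forward_dose(infl, numeric(5)), "does not match")
})

test_that("forward_letd is the dose-weighted mean with a zero-dose convention", {
  g <- voxel_grid(c(1, 1, 1))
  # single beamlet, single voxel: N = 6, D = 2, any fluence -> LET_d = 3
  infl <- influence_matrix(Matrix::Matrix(2, 1, 1, sparse = TRUE),
                           Matrix::Matrix(6, 1, 1, sparse = TRUE), g)
  expect_equal(forward_letd(infl, 5), 3)
  # two beamlets with LET 2 and 6 at equal dose mix to 4
  g2 <- voxel_grid(c(1, 1, 1))
  D <- Matrix::Matrix(c(1, 1), 1, 2, sparse = TRUE)
  N <- Matrix::Matrix(c(2, 6), 1, 2, sparse = TRUE)
  infl2 <- influence_matrix(D, N, g2)
  expect_equal(forward_letd(infl2, c(1, 1)), 4)
  # dose-weighted, not arithmetic: tripling the low-LET beamlet drags it down
  expect_equal(forward_letd(infl2, c(3, 1)), (3 * 2 + 6) / 4)
  # zero fluence -> zero dose -> LET_d reported 0, no division error
  expect_identical(forward_letd(infl2, c(0, 0)), 0)
  expect_error(forward_letd(infl2, c(-1, 1)), ">= 0")
})

test_that("numerator and denominator images are additive; LET_d is not", {
  infl <- random_influence(3, n_vox = 60, n_beam = 10)
  x1 <- replace(numeric(10), 1:5, stats::runif(5, 0.5, 2))
  x2 <- replace(numeric(10), 6:10, stats::runif(5, 0.5, 2))
  n_sum <- as.numeric(infl$letd_numerator %*% x1) +
    as.numeric(infl$letd_numerator %*% x2)
  n_tot <- as.numeric(infl$letd_numerator %*% (x1 + x2))
  expect_equal(n_tot, n_sum, tolerance = 1e-15)
  d_sum <- forward_dose(infl, x1) + forward_dose(infl, x2)
  expect_equal(forward_dose(infl, x1 + x2), d_sum, tolerance = 1e-15)
  # constructed counterexample: voxel dosed by both groups with different LET
  l1 <- forward_letd(infl, x1); l2 <- forward_letd(infl, x2)
  lt <- forward_letd(infl, x1 + x2)
  both <- forward_dose(infl, x1) > 0 & forward_dose(infl, x2) > 0
  expect_true(any(abs(lt[both] - (l1 + l2)[both]) > 0.1))
})

test_that("cDL equals c * N x on dosed voxels to machine precision", {
  for (seed in 1:5) {
    infl <- random_influence(seed, n_vox = 80, n_beam = 12)
    set.seed(seed)
    x <- stats::runif(12, 0, 2)
    cdl <- forward_cdl(infl, x)
    lin <- cdl_constant() * as.numeric(infl$letd_numerator %*% x)
    dosed <- forward_dose(infl, x) > 0
    expect_lt(max(abs(cdl[dosed] - lin[dosed])), 1e-12 * max(cdl))
  }
  # the defining single-voxel value: D = 1 Gy, LET_d = 1 keV/um -> 0.04 Gy
  g <- voxel_grid(c(1, 1, 1))
  infl1 <- influence_matrix(Matrix::Matrix(1, 1, 1, sparse = TRUE),
                            Matrix::Matrix(1, 1, 1, sparse = TRUE), g)
  expect_equal(forward_cdl(infl1, 1), 0.04)
  expect_identical(forward_cdl(infl1, 0), 0)
})

test_that("cdl_row reproduces forward_cdl on unit vectors and dense oracle", {
  infl <- random_influence(5, n_vox = 25, n_beam = 5)
  Nd <- as.matrix(infl$letd_numerator)
  for (v in c(1, 7, 25)) {
    row <- cdl_row(infl, v)
    expect_equal(as.numeric(row), cdl_constant() * Nd[v, ])
    for (j in 1:5) {
      ej <- replace(numeric(5), j, 1)
      expect_equal(sum(as.numeric(row) * ej),
                   forward_cdl(infl, ej)[v], tolerance = 1e-14)
    }
  }
  # an undosed voxel has an empty row
  zero_vox <- which(Matrix::rowSums(infl$dose) == 0)
  if (length(zero_vox))
    expect_identical(as.numeric(cdl_row(infl, zero_vox[1])), numeric(5))
  expect_error(cdl_row(infl, 26), "out of range")
})

test_that("influence_matrix enforces shape, sign and pattern containment", {
  g <- voxel_grid(c(2, 1, 1))
  D <- Matrix::Matrix(c(1, 0), 2, 1, sparse = TRUE)
  N_bad <- Matrix::Matrix(c(0, 1), 2, 1, sparse = TRUE)
  expect_error(influence_matrix(D, N_bad, g), "pattern")
  expect_error(influence_matrix(D, -D, g), ">= 0")
  expect_error(influence_matrix(D, Matrix::Matrix(1, 3, 1, sparse = TRUE), g),
               "shape")
  # nonnegativity preserved by forwards for x >= 0
  infl <- random_influence(9)
  x <- stats::runif(10)
  expect_true(all(forward_dose(infl, x) >= 0))
  expect_true(all(forward_letd(infl, x) >= 0))
  expect_true(all(forward_cdl(infl, x) >= 0))
})
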