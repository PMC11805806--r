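test_that("vl_compose reproduces printed matrices and rejects bad triples", {
  d <- vl_decomposition(
    h = c(1, 1, 1),
    s = -0.5 * diag(3),
    jmat = rbind(c(0, -1, 1), c(1, 0, -1), c(-1, 1, 0))
  )
  expect_equal(vl_compose(d), rps3(-0.5))

  d_id <- vl_decomposition(rep(1, 4), -diag(4), matrix(0, 4, 4))
  expect_equal(vl_compose(d_id), -diag(4))

  expect_error(vl_decomposition(c(1, -1), -diag(2), matrix(0, 2, 2)),
               "strictly positive")
  expect_error(vl_decomposition(c(1, 1), rbind(c(-1, 1), c(0, -1)),
                                matrix(0, 2, 2)), "symmetric")
  expect_error(vl_decomposition(c(1, 1), -diag(2), rbind(c(0, 1), c(1, 0))),
               "antisymmetric")
  expect_error(vl_decomposition(c(1, 1), diag(2), matrix(0, 2, 2)), "stable")
})

test_that("composed matrices satisfy the multiplier identity and a VL certificate", {
  set.seed(42)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    sys <- random_vl_stable(n)
    A <- sys$A
    dc <- sys$decomposition
    # direct matrix-algebra oracle: H^-1 A + A^T H^-1 = 2 S
    lhs <- diag(1 / dc$h) %*% A + t(A) %*% diag(1 / dc$h)
    expect_lt(max(abs(lhs - 2 * dc$s)), 1e-10)
    # independent certificate: lambda_max(H^-1 A + A^T H^-1) < 0
    expect_lt(max(eigen(lhs, symmetric = TRUE, only.values = TRUE)$values), 0)
    # round trip through the symmetric/antisymmetric split of H^-1 A
    sp <- symmetry_split(diag(1 / dc$h) %*% A)
    expect_equal(sp$a_s, dc$s, tolerance = 1e-10)
    expect_equal(sp$a_j, dc$jmat, tolerance = 1e-10)
  }
})

test_that("random_vl_stable is seed-reproducible and handles n = 1", {
  a <- random_vl_stable(10, seed = 7)
  b <- random_vl_stable(10, seed = 7)
  expect_identical(a$A, b$A)

  one <- random_vl_stable(1, seed = 3)
  expect_lt(one$A[1, 1], 0)
  expect_equal(dim(one$A), c(1L, 1L))

  expect_error(random_vl_stable(0), ">= 1")
})

test_that("symmetry_split matches hand computations", {
  sp <- symmetry_split(rpsls5(-0.5))
  expect_equal(sp$a_s, -0.5 * diag(5))
  expect_equal(sp$a_j + t(sp$a_j), matrix(0, 5, 5))
  expect_equal(sp$a_s + sp$a_j, rpsls5(-0.5))

  S <- rbind(c(-2, 1), c(1, -2))
  expect_equal(symmetry_split(S)$a_j, matrix(0, 2, 2))
  J <- rbind(c(0, 3), c(-3, 0))
  expect_equal(symmetry_split(J)$a_s, matrix(0, 2, 2))
})

test_that("entrywise norm and asym/sym ratio match hand sums", {
  A <- rpsls5(-0.5)
  sp <- symmetry_split(A)
  expect_equal(entrywise_norm(sp$a_s), 2.5)
  expect_equal(entrywise_norm(sp$a_j), 20)
  expect_equal(asym_sym_ratio(A), 8)

  expect_equal(entrywise_norm(matrix(0, 3, 3)), 0)
  expect_equal(entrywise_norm(-diag(3)), 3)
  expect_error(asym_sym_ratio(rbind(c(0, 1), c(-1, 0))), "undefined")
})

test_that("entrywise norm is absolutely homogeneous and subadditive", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    M1 <- matrix(rnorm(n * n), n, n)
    M2 <- matrix(rnorm(n * n), n, n)
    c0 <- rnorm(1)
    expect_equal(entrywise_norm(c0 * M1), abs(c0) * entrywise_norm(M1))
    expect_lte(entrywise_norm(M1 + M2),
               entrywise_norm(M1) + entrywise_norm(M2) + 1e-12)
  }
})

test_that("row norm and diagonal dominance match hand computations", {
  expect_equal(row_norm(rps3(-0.5)), 2.5)
  expect_false(is_row_dd(rps3(-0.5))) # 0.5 < 2
  expect_true(is_row_dd(-diag(4)))
  expect_true(is_col_dd(-diag(4)))
  expect_equal(row_norm(-diag(4)), 1)
  expect_false(is_row_dd(rpsls5(-1.5))) # 1.5 < 4
})

test_that("row dominance of A equals column dominance of its transpose", {
  set.seed(5)
  for (k in 1:30) {
    n <- sample(2:7, 1)
    M <- matrix(rnorm(n * n), n, n)
    expect_identical(is_row_dd(M), is_col_dd(t(M)))
  }
})

test_that("fixture matrices reproduce the printed rows", {
  expect_equal(rpsls5(-0.5)[1, ], c(-0.5, -1, 1, -1, 1))
  expect_equal(cycle4(-0.5)[2, ], c(1, -0.5, 0, -1))
  expect_equal(rps3(-0.5), rbind(c(-0.5, -1, 1), c(1, -0.5, -1), c(-1, 1, -0.5)))

  ml <- may_leonard(0.5, 1.2)
  expect_equal(diag(ml), rep(-1, 3))
  expect_equal(ml[1, ], c(-1, -1.2, -0.5))

  # alpha = beta < 1 collapses the cyclic (antisymmetric) component
  expect_warning(ml_sym <- may_leonard(0.8, 0.8), "cyclic regime")
  expect_equal(symmetry_split(ml_sym)$a_j, matrix(0, 3, 3))
})
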