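test_that("principal submatrices and subvectors read off the right entries", {
  A5 <- rpsls5(-0.5)
  expect_equal(principal_submatrix(A5, c(1, 2, 4)),
               rbind(c(-0.5, -1, -1), c(1, -0.5, 1), c(1, -1, -0.5)))
  expect_equal(principal_submatrix(A5, 3), matrix(-0.5, 1, 1))
  expect_equal(principal_submatrix(A5, 1:5), A5)
  expect_equal(subvector(c(10, 20, 30), c(1, 3)), c(10, 30))
  expect_error(principal_submatrix(A5, 6), "1..5")
  expect_error(principal_submatrix(A5, integer(0)), "nonempty")
})

test_that("solve_equilibrium matches hand solves on the RPS system", {
  A <- rps3(-0.5)
  e1 <- solve_equilibrium(A, 1, 1)
  expect_true(e1$admissible)
  expect_equal(e1$u[[1]], c(2, 0, 0))

  e12 <- solve_equilibrium(A, 1, c(1, 2))
  expect_false(e12$admissible)
  expect_equal(e12$u[[1]][1:2], c(-0.4, 1.2))

  e123 <- solve_equilibrium(A, 1, 1:3)
  expect_true(e123$admissible)
  expect_equal(e123$u[[1]], c(2, 2, 2))

  # singular submatrix is rejected with a reason, not an error
  sing <- solve_equilibrium(rbind(c(0, 0), c(0, -1)), 1, 1)
  expect_false(sing$admissible)
  expect_identical(sing$reason, "singular")
})

test_that("invasion rates match hand values and conventions", {
  A <- rps3(-0.5)
  r <- invasion_rates(A, 1, members = 1)
  expect_equal(r, c(0, 3, -1))

  expect_equal(invasion_rates(A, c(1, 1, 1), members = integer(0)), c(1, 1, 1))

  # resident rates vanish at any admissible equilibrium
  cat3 <- enumerate_admissible(A, 1)
  for (i in seq_len(nrow(cat3))) {
    members <- cat3$community[[i]]
    expect_lt(max(abs(cat3$rates[[i]][members]), 0), 1e-9)
  }
})

test_that("enumerate_admissible reproduces the canonical censuses", {
  cat3 <- enumerate_admissible(rps3(-0.5), 1)
  expect_identical(nrow(cat3), 5L)
  expect_setequal(cat3$label, c("()", "(1)", "(2)", "(3)", "(1,2,3)"))
  expect_false(any(cat3$dim == 2L))

  cat5 <- enumerate_admissible(rpsls5(-0.5), 1)
  expect_identical(nrow(cat5), 12L)
  expect_setequal(cat5$label,
                  c("()", "(1)", "(2)", "(3)", "(4)", "(5)",
                    "(1,2,3)", "(2,3,4)", "(3,4,5)", "(1,4,5)", "(1,2,5)",
                    "(1,2,3,4,5)"))
  # agreement with the brute-force subset oracle
  expect_setequal(cat5$label, oracle_admissible_labels(rpsls5(-0.5), 1))

  cat2 <- enumerate_admissible(-diag(2), c(1, 1))
  expect_identical(nrow(cat2), 4L)

  expect_error(enumerate_admissible(-diag(3), 1, max_species = 2), "cap")
})

test_that("catalogued equilibria satisfy the defining linear system", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    sys <- random_vl_stable(n)
    b <- runif(n, 0.5, 1.5)
    cat_k <- enumerate_admissible(sys$A, b)
    expect_false(any(duplicated(cat_k$label)))
    for (i in seq_len(nrow(cat_k))) {
      J <- cat_k$community[[i]]
      if (length(J) == 0L) next
      resid <- sys$A[J, J, drop = FALSE] %*% cat_k$u[[i]][J] + b[J]
      expect_lt(max(abs(resid)), 1e-8)
    }
  }
})

test_that("find_gass returns the unique saturated equilibrium", {
  g3 <- find_gass(enumerate_admissible(rps3(-0.5), 1))
  expect_identical(g3$label, "(1,2,3)")
  expect_equal(g3$u[[1]], c(2, 2, 2))

  g2 <- find_gass(enumerate_admissible(-diag(2), c(1, -1)))
  expect_identical(g2$label, "(1)")
  expect_equal(g2$u[[1]], c(1, 0))

  # restriction to the {1,2} wall of the RPS system: the GASS of the
  # subsystem is species 2 alone at abundance 2
  sub <- enumerate_admissible(principal_submatrix(rps3(-0.5), c(1, 2)), c(1, 1))
  gw <- find_gass(sub)
  expect_identical(gw$label, "(2)")
  expect_equal(gw$u[[1]], c(0, 2))
})

test_that("saturation is achieved exactly once on random VL stable systems", {
  set.seed(77)
  for (k in 1:100) {
    n <- sample(2:8, 1)
    sys <- random_vl_stable(n)
    b <- runif(n, -1, 1.5)
    cat_k <- enumerate_admissible(sys$A, b)
    gs <- find_gass(cat_k) # errors if zero or multiple saturated
    expect_identical(nrow(gs), 1L)
  }
})

test_that("the subsystem GASS on supersets of the GASS support projects consistently", {
  set.seed(55)
  for (k in 1:15) {
    n <- sample(3:6, 1)
    sys <- random_vl_stable(n)
    b <- runif(n, 0, 1.5)
    gs <- find_gass(enumerate_admissible(sys$A, b))
    supp <- gs$community[[1]]
    extra <- setdiff(seq_len(n), supp)
    J <- sort(union(supp, extra[seq_len(min(1, length(extra)))]))
    if (length(J) == 0L) next
    sub <- enumerate_admissible(sys$A[J, J, drop = FALSE], b[J])
    gsub <- find_gass(sub)
    expect_equal(gsub$u[[1]], gs$u[[1]][J], tolerance = 1e-8)
  }
})

test_that("hyperbolicity flags zero invasion rates", {
  expect_true(is_hyperbolic(enumerate_admissible(rpsls5(-0.5), 1))$hyperbolic)

  h1 <- is_hyperbolic(enumerate_admissible(rpsls5(-1), 1))
  expect_false(h1$hyperbolic)

  h2 <- is_hyperbolic(enumerate_admissible(-diag(2), c(1, 0)))
  expect_false(h2$hyperbolic)
  expect_true("()" %in% h2$violations$label)
})

test_that("catalog tidiers produce the long table and summary", {
  cat3 <- enumerate_admissible(rps3(-0.5), 1)
  td <- tidy(cat3)
  expect_identical(nrow(td), 15L) # 5 communities x 3 species
  gl <- glance(cat3)
  expect_identical(gl$n_admissible, 5L)
  expect_false(gl$frondose)
  expect_true(gl$hyperbolic)
})
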