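test_that("the edge rule reproduces the hand-checked RPS and 4-species graphs", {
  g3 <- build_ig(enumerate_admissible(rps3(-0.5), 1))
  expect_setequal(
    edge_pairs(g3),
    c("()->(1)", "()->(2)", "()->(3)", "()->(1,2,3)",
      "(1)->(2)", "(2)->(3)", "(3)->(1)")
  )

  g4 <- build_ig(enumerate_admissible(cycle4(-0.5), 1))
  expect_true(all(c("(1)->(2,3)", "(2,3)->(4)", "(4)->(1)") %in% edge_pairs(g4)))

  # the licensing rates are stored on each edge
  e <- g3$edges[g3$edges$from == "(1)" & g3$edges$to == "(2)", ]
  expect_equal(e$invader_rates[[1]], 3)
  expect_equal(e$leaver_rates[[1]], -1)
})

test_that("cycle detection finds the canonical elementary cycles", {
  g3 <- build_ig(enumerate_admissible(rps3(-0.5), 1))
  rep3 <- find_cycles(g3)
  expect_true(rep3$has_cycle)
  expect_identical(length(rep3$cycles), 1L)
  expect_setequal(rep3$cycles[[1]], c("(1)", "(2)", "(3)"))

  g5 <- build_ig(enumerate_admissible(rpsls5(-0.5), 1))
  rep5 <- find_cycles(g5)
  expect_true(rep5$has_cycle)
  singleton5 <- vapply(rep5$cycles, function(cc) {
    length(cc) == 5L && all(cc %in% c("(1)", "(2)", "(3)", "(4)", "(5)"))
  }, logical(1))
  triple5 <- vapply(rep5$cycles, function(cc) {
    length(cc) == 5L && all(grepl("^\\([0-9],[0-9],[0-9]\\)$", cc))
  }, logical(1))
  # the pentagram tournament carries two orientations of the five-cycle
  # through the singletons (1-2-3-4-5 and 1-4-2-5-3); at least one of each
  # family must be present
  expect_gte(sum(singleton5), 1L)
  expect_gte(sum(triple5), 1L)

  # an acyclic graph reports cleanly
  gd <- build_ig(enumerate_admissible(-diag(3), 1))
  repd <- find_cycles(gd)
  expect_false(repd$has_cycle)
  expect_identical(repd$cycles, list())
  expect_identical(repd$sccs, list())
  expect_false(repd$cap_hit)
})

test_that("the cycle-enumeration cap is honoured while SCCs stay exact", {
  g5 <- build_ig(enumerate_admissible(rpsls5(-0.5), 1))
  capped <- find_cycles(g5, max_cycles = 2)
  expect_true(capped$cap_hit)
  expect_identical(length(capped$cycles), 2L)
  expect_true(capped$has_cycle)
})

test_that("structure verdicts follow the RPSLS d-regimes", {
  v_low <- structure_verdict(enumerate_admissible(rpsls5(-1.5), 1))
  expect_true(v_low$gradient_certified)
  expect_true(v_low$frondose)

  v_mid <- structure_verdict(enumerate_admissible(rpsls5(-0.5), 1))
  expect_false(v_mid$acyclic)
  expect_false(v_mid$gradient_certified)

  v_crit <- structure_verdict(enumerate_admissible(rpsls5(-1), 1))
  expect_false(v_crit$hyperbolic)
  expect_false(v_crit$gradient_certified)
})

test_that("perturbing a licensing rate across zero toggles the edge", {
  # decoupled 2-species system: edge (1) -> (1,2) licensed by r_2({1}) = b2
  A <- -diag(2)
  for (b2 in c(0.01, -0.01)) {
    g <- build_ig(enumerate_admissible(A, c(1, b2)))
    has_edge <- "(1)->(1,2)" %in% edge_pairs(g)
    expect_identical(has_edge, b2 > 0)
  }
})

test_that("full frondosity with hyperbolicity gives exactly the subset order", {
  cat_f <- enumerate_admissible(rpsls5(-1.5), 1)
  g <- build_ig(cat_f)
  expected <- character(0)
  labs <- cat_f$label
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      I <- cat_f$community[[i]]; J <- cat_f$community[[j]]
      if (length(I) < length(J) && all(I %in% J)) {
        expected <- c(expected, paste0(labs[i], "->", labs[j]))
      }
    }
  }
  expect_setequal(edge_pairs(g), expected)

  # random fully cooperative samples share the property
  set.seed(101)
  for (k in 1:5) {
    n <- sample(3:5, 1)
    A <- matrix(runif(n * n, 0.05, 0.2), n, n)
    diag(A) <- -runif(n, 2, 3)
    expect_true(frondosity_sufficient_cooperative(A, rep(1, n)))
    expect_true(check_frondosity(A, 1)$frondose)
    cat_k <- enumerate_admissible(A, 1)
    if (!is_hyperbolic(cat_k)$hyperbolic) next
    gk <- build_ig(cat_k)
    n_edges_expected <- 3^n - 2^n # ordered pairs I proper-subset J
    expect_identical(nrow(gk$edges), as.integer(n_edges_expected))
    expect_false(find_cycles(gk, max_cycles = 0)$has_cycle)
  }
})

test_that("symmetric stable interaction matrices yield acyclic invasion graphs", {
  set.seed(303)
  for (k in 1:100) {
    n <- sample(3:8, 1)
    A <- random_symmetric_stable(n)
    b <- runif(n, -1, 1.5)
    g <- build_ig(enumerate_admissible(A, b))
    expect_false(find_cycles(g, max_cycles = 0)$has_cycle)
  }
})

test_that("3D rigidity: a cyclic 3-species IG forces the five-equilibria census", {
  set.seed(404)
  found_cyclic <- 0L
  for (k in 1:200) {
    sys <- random_vl_stable(3, sd_f = 0.3, margin = 0.2)
    cat_k <- enumerate_admissible(sys$A, 1)
    g <- build_ig(cat_k)
    if (!find_cycles(g, max_cycles = 0)$has_cycle) next
    found_cyclic <- found_cyclic + 1L
    expect_identical(nrow(cat_k), 5L)
    expect_false(any(cat_k$dim == 2L))
    expect_identical(find_gass(cat_k)$dim, 3L)
  }
  # the sweep must actually exercise the cyclic regime
  expect_gt(found_cyclic, 0L)
})

test_that("frondosity checks match the printed examples", {
  f5 <- check_frondosity(rpsls5(-1.5), 1)
  expect_true(f5$frondose)
  expect_identical(nrow(enumerate_admissible(rpsls5(-1.5), 1)), 32L)

  f3 <- check_frondosity(rps3(-0.5), 1)
  expect_false(f3$frondose)
  expect_identical(f3$first_failure, "(1,2)")
  expect_identical(f3$reason, "negative")

  expect_true(check_frondosity(-diag(3), c(1, 1, 1))$frondose)
})

test_that("the diagonal-dominance sufficient condition evaluates the printed inequality", {
  A <- rbind(c(-1, 0.1), c(0.1, -1))
  r1 <- frondosity_sufficient_dd(A, c(1, 1))
  expect_true(r1$holds)
  expect_equal(r1$lhs, 0.1)
  expect_equal(r1$rhs, 0.5)

  r2 <- frondosity_sufficient_dd(A, c(1, 3))
  expect_true(r2$holds)
  expect_equal(r2$rhs, 0.25)

  r3 <- frondosity_sufficient_dd(rpsls5(-1.5), 1)
  expect_false(r3$holds) # sufficient, not necessary: frondosity still holds
  expect_equal(r3$lhs, 8 / 3)

  expect_error(frondosity_sufficient_dd(A, c(1, -1)), "min\\(b\\) > 0")
  expect_error(frondosity_sufficient_dd(rbind(c(0, 1), c(1, -1)), c(1, 1)),
               "diagonal")
})

test_that("the fully cooperative criterion checks signs only", {
  A <- rbind(c(-2, 0.5), c(0.5, -2))
  expect_message(ok <- frondosity_sufficient_cooperative(A, c(1, 1)),
                 "cooperative")
  expect_true(ok)
  expect_equal(find_gass(enumerate_admissible(A, 1))$u[[1]], c(2 / 3, 2 / 3))

  expect_false(frondosity_sufficient_cooperative(rbind(c(-2, -0.5), c(0.5, -2)),
                                                 c(1, 1)))
  expect_false(frondosity_sufficient_cooperative(A, c(1, 0)))
})

test_that("single-species cycle scan matches the product criterion", {
  res3 <- single_species_cycle_test(rps3(-0.5), 1)
  expect_true(res3$has_cycle)
  expect_true(all(res3$cycles$product_holds)) # 1^3 >= 0.5^3
  expect_false(res3$row_dd)
  expect_true(res3$consistent)

  # diagonally dominant VL stable samples never produce a singleton cycle
  set.seed(606)
  for (k in 1:20) {
    n <- sample(3:5, 1)
    A <- matrix(runif(n * n, -0.2, 0.2), n, n)
    diag(A) <- 0
    diag(A) <- -(rowSums(abs(A)) + runif(n, 1, 2)) # strongly row dominant
    res <- single_species_cycle_test(A, runif(n, -1, 1))
    expect_false(res$has_cycle)
    expect_true(res$consistent)
  }

  # a graph whose SCCs contain no singleton nodes reports empty
  res_f <- single_species_cycle_test(rpsls5(-1.5), 1)
  expect_false(res_f$has_cycle)
  expect_identical(nrow(res_f$cycles), 0L)
})
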