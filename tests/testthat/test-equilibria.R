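test_that("trivial and resource-ICU equilibria are exact closed forms", {
  p <- ward_params()
  e1 <- equilibrium_trivial(p)
  expect_identical(unname(e1$state), rep(0, 4))
  expect_identical(e1$residual_norm, 0)
  expect_true(is_clinically_feasible(e1))

  e2 <- equilibrium_resource_icu(p)
  expect_equal(unname(e2$state), c(100, 0, 0, 233.3333333),
               tolerance = 1e-9)
  expect_equal(e2$residual_norm, 0, tolerance = 1e-13)

  expect_equal(equilibrium_resource_icu(ward_params(K = 200))$state[["I"]],
               200 * 3.5 / 1.5, tolerance = 1e-12)
  expect_identical(
    equilibrium_resource_icu(ward_params(omega = 0))$state[["I"]], 0)
})

test_that("E1 and E2 residuals vanish for random draws under both variants", {
  set.seed(201)
  for (i in 1:50) {
    p <- rand_params()
    for (v in c("as_printed", "balanced")) {
      expect_identical(equilibrium_trivial(p, v)$residual_norm, 0)
      expect_lt(equilibrium_resource_icu(p, v)$residual_norm, 1e-10)
    }
  }
})

test_that("ED-free point is emitted as printed, with its residual recorded", {
  p <- ward_params()
  e3 <- equilibrium_no_ed(p)                # denominator 5*5 - 2*1.5 = 22
  expect_equal(unname(e3$state), c(0, 1.5 / 22, -6 / 22, 0),
               tolerance = 1e-12)
  expect_false(is_clinically_feasible(e3))
  ## the printed G carries gamma1 where ward balance yields gamma2, so the
  ## Covid-ward equation keeps a residual m1*C*(1 - gamma1/gamma2)
  expect_equal(e3$residual_norm, 1.5 * (1.5 / 22) * (1 - 4 / 5),
               tolerance = 1e-12)
  ## but its C-component annuls the general-ward balance bracket exactly
  d <- ward_rhs(c(0, e3$state[["C"]], 1, 0), p, "balanced")
  expect_equal(d[["dG"]], 0, tolerance = 1e-12)
  ## degenerate denominator
  expect_error(equilibrium_no_ed(ward_params(beta = 2, gamma2 = 1, b2 = 1,
                                             m2 = 2)), "degenerate")
})

test_that("ward-free equilibrium matches its closed form and is exact under
          the balanced variant", {
  p <- ward_params()
  e4 <- equilibrium_ward_free(p)
  expect_equal(e4$state[["E"]], 6 / 55, tolerance = 1e-12)
  expect_equal(e4$state[["C"]], 27470 / 18906.25, tolerance = 1e-12)
  expect_identical(e4$state[["G"]], 0)
  expect_equal(e4$state[["I"]], 58725 / 28359.375, tolerance = 1e-12)
  expect_lt(e4$residual_norm, 1e-10)
  ## under as_printed the general-ward gain is unbalanced and positive
  d <- ward_rhs(e4$state, p, "as_printed")
  expect_gt(d[["dG"]], 0)
  expect_error(equilibrium_ward_free(ward_params(a = 1, gamma1 = 1.5,
                                                 b1 = 1, m1 = 1.5)),
               "a\\*gamma1 > b1\\*m1")
})

test_that("ward-free residual stays below 1e-10 across random draws", {
  set.seed(202)
  n <- 0
  while (n < 50) {
    p <- rand_params()
    if (p$a * p$gamma1 <= p$b1 * p$m1 * 1.01) next
    n <- n + 1
    expect_lt(equilibrium_ward_free(p, "balanced")$residual_norm, 1e-10)
  }
})

test_that("numeric search recovers the closed forms and verifies residuals", {
  p <- ward_params()
  eqs <- find_equilibria(p)
  d <- as.data.frame(eqs)
  expect_true(all(d$residual < 1e-8))
  states <- lapply(eqs, function(e) unname(e$state))
  near <- function(target) any(vapply(states, function(s)
    max(abs(s - target)) < 1e-6, logical(1)))
  expect_true(near(c(0, 0, 0, 0)))
  expect_true(near(c(100, 0, 0, 700 / 3)))
  expect_true(near(unname(equilibrium_ward_free(p)$state)))
  ## the strictly positive interior root is labelled E5
  expect_true("E5" %in% d$label)
})

test_that("roots persist under grid refinement", {
  p <- ward_params()
  coarse <- find_equilibria(p, search_grid = list(
    E = 10^seq(-3, log10(200), length.out = 5),
    C = 10^seq(-3, log10(200), length.out = 4)))
  fine <- find_equilibria(p)
  for (eq in coarse) {
    d <- vapply(fine, function(f) max(abs(f$state - eq$state)), numeric(1))
    expect_lt(min(d), 1e-6)
  }
})

test_that("residual operation reports the max-norm of the vector field", {
  p <- ward_params()
  expect_identical(ward_residual(c(0, 0, 0, 0), p), 0)
  expect_lt(ward_residual(c(100, 0, 0, 700 / 3), p), 1e-13)
  expect_equal(ward_residual(c(1, 1, 1, 1), p, "as_printed"), 10)
})
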