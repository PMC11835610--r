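test_that("characteristic polynomial of simple matrices is exact", {
  expect_equal(unname(as.numeric(char_poly_coeffs(diag(4)))),
               c(-4, 6, -4, 1))
  expect_equal(unname(as.numeric(char_poly_coeffs(diag(c(1, 2, 3, 4))))),
               c(-10, 35, -50, 24))
})

test_that("coefficients match the determinant-expansion oracle", {
  set.seed(301)
  for (i in 1:100) {
    J <- if (i %% 2) rand_patterned_matrix() else matrix(rnorm(16, sd = 2), 4)
    scale <- max(1, max(abs(J))^4)
    expect_lt(max(abs(as.numeric(char_poly_coeffs(J)) - charpoly_oracle(J))),
              1e-10 * scale)
  }
})

test_that("published coefficient formulas hold under the model zero pattern", {
  set.seed(302)
  for (i in 1:100) {
    J <- rand_patterned_matrix()
    expect_equal(as.numeric(char_poly_coeffs(J)),
                 unname(charpoly_printed(J)), tolerance = 1e-12)
  }
})

test_that("Routh-Hurwitz verdicts on hand-built polynomials", {
  ## (lambda+1)^4
  rh <- routh_hurwitz(c(4, 6, 4, 1))
  expect_true(all(rh$conditions))
  expect_true(rh$rh_stable)
  ## (lambda-1)(lambda+1)(lambda+2)(lambda+3) has a positive root
  rh2 <- routh_hurwitz(c(5, 5, -5, -6))
  expect_false(rh2$rh_stable)
  ## the four published conditions alone are not sufficient: A4 < 0 always
  ## leaves a positive real root even when all four hold
  cp <- c(1, 1, 0.4, -0.1)
  rh3 <- routh_hurwitz(cp)
  expect_true(all(rh3$conditions))
  expect_false(rh3$a4_positive)
  expect_false(rh3$rh_stable)
  roots <- polyroot(rev(c(1, cp)))
  expect_true(any(Re(roots) > 0))
})

test_that("Routh-Hurwitz verdict coincides with the eigenvalue verdict", {
  set.seed(303)
  n <- 0
  while (n < 500) {
    J <- rand_patterned_matrix()
    ev <- eigen(J, only.values = TRUE)$values
    tol <- 1e-6 * (1 + max(Mod(ev)))
    if (any(abs(Re(ev)) < tol)) next      # exclude near-nonhyperbolic draws
    n <- n + 1
    rh <- routh_hurwitz(char_poly_coeffs(J))
    expect_identical(rh$rh_stable, all(Re(ev) < 0))
  }
})

test_that("eigenvalue classification covers the taxonomy", {
  expect_identical(eigen_classify(diag(c(-1, -2, -3, -4)))$classification,
                   "stable_node")
  expect_identical(eigen_classify(diag(c(1, 2, 3, 4)))$classification,
                   "unstable_node")
  expect_identical(eigen_classify(diag(c(-1, 1, -3, -4)))$classification,
                   "saddle")
  ## complex pair with negative real part
  J <- diag(c(-1, -1, -2, -3)); J[1, 2] <- 5; J[2, 1] <- -5
  expect_identical(eigen_classify(J)$classification, "stable_focus")
  expect_identical(eigen_classify(diag(c(0, -1, -2, -3)))$classification,
                   "nonhyperbolic")
  expect_error(eigen_classify(matrix(NA_real_, 4, 4)), "finite")
})

test_that("origin and resource-ICU equilibria classify as saddles", {
  p <- ward_params()
  r1 <- analyze_equilibrium(equilibrium_trivial(p), p)
  expect_identical(r1$classification, "saddle")
  expect_equal(sort(Re(r1$eigenvalues)), c(-1.5, -1.5, -1.5, 5))

  r2 <- analyze_equilibrium(equilibrium_resource_icu(p), p)
  expect_identical(r2$classification, "saddle")
  expect_false(r2$rh_stable)
  expect_equal(sort(Re(r2$eigenvalues)),
               sort(c(-5, 1373.5 / 151, -1.5, -1.5)), tolerance = 1e-9)
})

test_that("spectra at E1 and E2 match the triangular closed forms across
          random draws", {
  set.seed(304)
  for (i in 1:40) {
    p <- rand_params()
    ev1 <- analyze_equilibrium(equilibrium_trivial(p), p)$eigenvalues
    expect_equal(sort(Re(ev1)), sort(c(p$r, -p$m1, -p$m2, -p$m3)),
                 tolerance = 1e-8)
    expect_equal(max(abs(Im(ev1))), 0)
    lam2 <- (p$a * p$K * p$gamma1 - p$K * p$b1 * p$m1 - p$m1) /
      (p$K * p$b1 + 1)
    ev2 <- analyze_equilibrium(equilibrium_resource_icu(p), p)$eigenvalues
    expect_equal(sort(Re(ev2)), sort(c(-p$r, lam2, -p$m2, -p$m3)),
                 tolerance = 1e-8 * (1 + max(abs(ev2))))
  }
})

test_that("analyzing a point with visible residual warns instead of hiding it", {
  p <- ward_params()
  e4 <- equilibrium_ward_free(p, variant = "as_printed")
  expect_gt(e4$residual_norm, 1e-6)
  expect_warning(analyze_equilibrium(e4, p, "as_printed"),
                 "non-equilibrium")
  ## the balanced report is produced cleanly
  expect_s3_class(analyze_equilibrium(equilibrium_ward_free(p), p),
                  "stability_report")
})
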