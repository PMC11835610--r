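test_that("a single-point sweep reproduces the plain equilibrium search", {
  p <- ward_params()
  sw <- sweep_parameter(p, "zeta", 0.2)
  eqs <- as.data.frame(find_equilibria(p))
  expect_setequal(sw$table$label, eqs$label)
  for (k in seq_len(nrow(eqs))) {
    row <- sw$table[sw$table$label == eqs$label[k], ]
    expect_equal(unlist(row[1, c("E", "C", "G", "I")]),
                 unlist(eqs[k, c("E", "C", "G", "I")]), tolerance = 1e-8)
  }
})

test_that("the resource-ICU branch is constant across a zeta sweep", {
  p <- ward_params()
  sw <- sweep_parameter(p, "zeta", seq(0, 3, length.out = 7))
  e2 <- sw$table[sw$table$label == "E2", ]
  expect_identical(nrow(e2), 7L)
  expect_identical(length(unique(e2$branch_id)), 1L)
  expect_equal(e2$E, rep(100, 7), tolerance = 1e-9)
  expect_equal(e2$I, rep(700 / 3, 7), tolerance = 1e-9)
})

test_that("all swept equilibria satisfy the residual contract", {
  p <- ward_params()
  sw <- sweep_parameter(p, "zeta", c(0.1, 1, 2.5))
  expect_true(all(sw$table$residual < 1e-8))
  expect_error(sweep_parameter(p, "nope", 1), "not a model parameter")
  expect_error(sweep_parameter(p, "zeta", c(2, 1)), "increasing")
})

test_that("Hopf detection on synthetic branches", {
  ## exact zero on a grid point
  syn <- data.frame(param_value = seq(0, 4, by = 0.5), branch_id = 1L,
                    lead_pair_re = seq(0, 4, by = 0.5) - 2,
                    lead_pair_im = 1)
  hp <- detect_hopf(syn)
  expect_identical(nrow(hp), 1L)
  expect_equal(hp$param_value, 2)
  ## crossing between grid points, located by interpolation
  syn$lead_pair_re <- syn$param_value - 1.75
  hp2 <- detect_hopf(syn)
  expect_equal(hp2$param_value, 1.75)
  ## no sign change -> empty
  syn$lead_pair_re <- syn$param_value + 1
  expect_identical(nrow(detect_hopf(syn)), 0L)
  ## real eigenvalue crossings are not Hopf points
  syn$lead_pair_re <- syn$param_value - 2
  syn$lead_pair_im <- 0
  expect_identical(nrow(detect_hopf(syn)), 0L)
})

test_that("a genuine Hopf of the model is found and refined to the axis", {
  ## the coexistence branch loses stability in the discharge-rate direction
  p <- ward_params(K = 20, r = 4.455, zeta = 2.3)
  sw <- sweep_parameter(p, "omega", seq(0.01, 0.06, by = 0.01),
                        variant = "as_printed")
  hp <- detect_hopf(sw)
  expect_identical(nrow(hp), 1L)
  expect_true(hp$refined)
  expect_gt(hp$frequency, 0)
  ## verify |Re| < tol at the returned parameter by an independent re-solve
  pv <- ward_params(K = 20, r = 4.455, zeta = 2.3, omega = hp$param_value)
  eqs <- find_equilibria(pv, "as_printed")
  lab <- vapply(eqs, `[[`, character(1), "label")
  st <- eqs[[which(lab == "E5")[1]]]$state
  ev <- eigen(ward_jacobian(st, pv, "as_printed"), only.values = TRUE)$values
  cplx <- ev[abs(Im(ev)) > 1e-8]
  expect_lt(abs(max(Re(cplx))), 1e-6)
})

test_that("warm-started sweep values agree with cold re-solves", {
  p <- ward_params()
  values <- c(0.5, 1.5, 2.5)
  sw <- sweep_parameter(p, "zeta", values)
  for (v in values) {
    cold <- as.data.frame(find_equilibria(validate_params(
      utils::modifyList(as.list(unclass(p)), list(zeta = v)))))
    warm <- sw$table[sw$table$param_value == v, ]
    for (k in seq_len(nrow(cold))) {
      d <- apply(warm[, c("E", "C", "G", "I")], 1, function(s)
        max(abs(s - unlist(cold[k, c("E", "C", "G", "I")]))))
      expect_lt(min(d), 1e-6)
    }
  }
})

test_that("heat-map cells match single-point analyses and are order
          independent", {
  p <- ward_params()
  hm1 <- stability_heatmap(p, 100, 0.2)
  expect_identical(nrow(hm1$grid), 1L)
  expect_false(hm1$grid$missing)
  eqs <- as.data.frame(find_equilibria(p))
  e5 <- eqs[eqs$label == "E5", ]
  expect_equal(unlist(hm1$grid[1, c("E", "C", "G", "I")]),
               unlist(e5[1, c("E", "C", "G", "I")]), tolerance = 1e-8)

  Ks <- c(50, 100, 150); zs <- c(0.1, 1)
  hm <- stability_heatmap(p, Ks, zs)
  expect_identical(nrow(hm$grid), 6L)
  expect_lt(mean(hm$grid$missing), 0.05)
  hm_rev <- stability_heatmap(p, rev(Ks), zs)
  a <- hm$grid[order(hm$grid$K, hm$grid$zeta), ]
  b <- hm_rev$grid[order(hm_rev$grid$K, hm_rev$grid$zeta), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("the resource-ICU branch of a heat map is linear in K", {
  p <- ward_params()
  Ks <- c(50, 100, 200)
  hm <- stability_heatmap(p, Ks, 0.2, branch_selector = "resource_icu")
  expect_equal(hm$grid$I, Ks * p$omega / p$m3, tolerance = 1e-9)
  expect_equal(hm$grid$E, Ks, tolerance = 1e-9)
})
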