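test_that("symmetric constants and equimolar loadings give 50% conversion", {
  # with K_donor = K_product and vanishing phosphate the coupled system
  # reduces to ([B_d][N_p])/([N_d][B_p]) = 1, forcing x = 1/2
  sys <- transgly_system(1, 1, 1e-6, 1, 1)
  res <- solve_equilibrium(sys)
  expect_equal(res$conversion, 0.5, tolerance = 1e-5)
  expect_true(res$converged)
})

test_that("degenerate loadings return the boundary state with a flag", {
  res0 <- solve_equilibrium(transgly_system(0, 1, 0.09, 0.3, 9.37))
  expect_identical(res0$flag, "boundary")
  expect_identical(res0$conversion, 0)
  expect_identical(res0$extent_phosphorolysis, 0)
  expect_identical(res0$extent_glycosylation, 0)
  resP <- solve_equilibrium(transgly_system(5, 1, 0, 0.3, 9.37))
  expect_identical(resP$flag, "boundary")
  expect_error(transgly_system(-1, 1, 0.09, 0.3, 9.37), "loadings")
  expect_error(solve_equilibrium(transgly_system(5, 0, 0.09, 0.3, 9.37)),
               "base_0")
})

test_that("solver matches the frozen extent-grid oracle fixture", {
  # value computed with the brute-force oracle (grid_n = 4000) before the
  # solver was written: conversion 0.3914
  sys <- transgly_system(5, 1, 0.5, K_donor = 0.2, K_product = 2.0)
  expect_equal(solve_equilibrium(sys)$conversion, 0.3914, tolerance = 1e-3)
})

test_that("mass balances hold to 1e-12 relative on solver output", {
  set.seed(101)
  for (i in 1:50) {
    sys <- random_system()
    res <- solve_equilibrium(sys)
    if (res$flag != "ok") next
    sp <- res$species
    D0 <- sys$mix[["donor_0"]]; B0 <- sys$mix[["base_0"]]
    P0 <- sys$mix[["phosphate_0"]]
    expect_lt(abs(sp[["donor_nucleoside"]] + sp[["pentose1P"]] +
                    sp[["product_nucleoside"]] - D0), 1e-12 * D0)
    expect_lt(abs(sp[["donor_nucleoside"]] + sp[["donor_base"]] - D0),
              1e-12 * D0)
    expect_lt(abs(sp[["acceptor_base"]] + sp[["product_nucleoside"]] - B0),
              1e-12 * B0)
    expect_lt(abs(sp[["phosphate"]] + sp[["pentose1P"]] - P0), 1e-12 * P0)
    expect_true(all(sp >= 0))
    expect_equal(res$extent_phosphorolysis, sp[["donor_base"]])
    expect_equal(res$extent_glycosylation, sp[["product_nucleoside"]])
  }
})

test_that("inference round-trips the forward solver to 1e-6 relative", {
  set.seed(202)
  n_ok <- 0
  for (i in 1:200) {
    sys <- random_system()
    res <- solve_equilibrium(sys)
    if (res$flag != "ok" || res$conversion <= 0 || res$conversion >= 1) next
    n_ok <- n_ok + 1
    Kp <- infer_K_product(sys$mix, sys$constants[["K_donor"]], res$conversion)
    Kd <- infer_K_donor(sys$mix, sys$constants[["K_product"]], res$conversion)
    expect_equal(Kp, sys$constants[["K_product"]], tolerance = 1e-6)
    expect_equal(Kd, sys$constants[["K_donor"]], tolerance = 1e-6)
  }
  expect_gt(n_ok, 150)
})

test_that("solver agrees with the extent-grid oracle on random small systems", {
  set.seed(303)
  for (i in 1:10) {
    sys <- random_system(-1, 1)
    dev <- abs(solve_equilibrium(sys)$conversion -
                 gibbs_grid_oracle(sys, 2000)$conversion)
    expect_lt(dev, 1e-3)
  }
})

test_that("conversion approaches the closed-form limit as phosphate vanishes", {
  cases <- list(c(0.34, 9.37, 10, 1), c(1.5, 0.7, 3, 2), c(0.05, 5, 20, 1))
  for (cs in cases) {
    sys <- transgly_system(cs[3], cs[4], 1e-8 * cs[4], cs[1], cs[2])
    expect_equal(solve_equilibrium(sys)$conversion,
                 closed_form_limit(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-4)
  }
})

test_that("conversion is monotone in donor loading and both constants", {
  conv <- function(D0, Kd, Kp)
    solve_equilibrium(transgly_system(D0, 1, 0.09, Kd, Kp))$conversion
  expect_true(conv(5, 0.3, 5) < conv(10, 0.3, 5))
  expect_true(conv(10, 0.3, 5) < conv(20, 0.3, 5))
  expect_true(conv(5, 0.1, 5) < conv(5, 0.3, 5))   # increasing in K_donor
  expect_true(conv(5, 0.3, 10) < conv(5, 0.3, 5))  # decreasing in K_product
})

test_that("inference rejects thermodynamically impossible observations", {
  expect_error(infer_K_product(study_mix, 0.3, 0.999 * 5 / 1 + 0.01),
               "between 0 and 1")
  # x * B0 >= D0 violates the sugar balance
  mix <- c(donor_0 = 1, base_0 = 2, phosphate_0 = 0.09)
  expect_error(infer_K_product(mix, 0.3, 0.6), "inconsistent")
  expect_error(infer_K_donor(mix, 5, 0.6), "inconsistent")
  # a huge product constant can push the implied donor nucleoside negative
  expect_error(infer_K_donor(c(donor_0 = 1.05, base_0 = 1, phosphate_0 = 0.2),
                             1e6, 0.9), "inconsistent")
})

test_that("donor-constant inference handles the K_donor = 1 linear branch", {
  sys <- transgly_system(5, 1, 0.5, 1, 2)
  x <- solve_equilibrium(sys)$conversion
  expect_equal(infer_K_product(sys$mix, 1, x), 2, tolerance = 1e-6)
})

test_that("the inferred constant shrinks to zero with the observed conversion", {
  kds <- vapply(c(1e-2, 1e-4, 1e-6),
                function(x) infer_K_donor(study_mix, 9.37, x), numeric(1))
  expect_true(all(diff(kds) < 0))
  expect_lt(kds[3], 1e-6)
})

test_that("printed-pair self-consistency: product constant is recovered", {
  # product constant 9.37 and 5-fold conversion 30.5% must be mutually
  # consistent through the model once the donor constant is calibrated
  Kd <- infer_K_donor(study_mix, 9.37, 0.305)
  expect_equal(infer_K_product(study_mix, Kd, 0.305), 9.37, tolerance = 1e-6)
})

test_that("conversion curve is strictly increasing in donor excess", {
  constants <- c(K_donor = 0.3357, K_product = 9.37)
  curve <- conversion_curve(1, 0.09, constants, c(2, 5, 10, 20, 50))
  expect_true(all(diff(curve$conversion) > 0))
  # self-consistency at the calibration point: excess 5 reproduces the
  # calibrating conversion
  Kd <- infer_K_donor(study_mix, 9.37, 0.305)
  cal <- conversion_curve(1, 0.09, c(K_donor = Kd, K_product = 9.37), 5)
  expect_equal(cal$conversion, 0.305, tolerance = 1e-9)
})

test_that("required_excess honors boundaries, targets and the cap", {
  constants <- c(K_donor = 0.3357, K_product = 9.37)
  # target below the conversion at unit excess -> boundary value 1
  low <- required_excess(1, 0.09, constants, target_conversion = 0.01)
  expect_true(low$attained)
  expect_identical(low$excess, 1)
  # attained target: smallest excess, consistent with the curve
  r <- required_excess(1, 0.09, constants, 0.4)
  expect_true(r$attained)
  expect_equal(conversion_curve(1, 0.09, constants, r$excess)$conversion,
               0.4, tolerance = 1e-6)
  # proportional-phosphate policy with an unfavorable product constant keeps
  # 50% out of reach at any practical excess -> typed flag, no error
  u <- required_excess(1, 0.09, c(K_donor = 0.05, K_product = 10), 0.5, 100,
                       phosphate_policy = "proportional")
  expect_false(u$attained)
  expect_true(is.na(u$excess))
  expect_lt(u$conversion_at_cap, 0.5)
})
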