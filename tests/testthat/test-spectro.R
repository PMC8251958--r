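test_that("unmixing recovers pure states and exact mixtures", {
  refs <- two_state_refs()
  A <- refs$prot; B <- refs$deprot; wl <- refs$wavelength_nm
  pure <- unmix(uv_spectrum(wl, A), refs)
  expect_equal(unname(pure$fractions), c(1, 0), tolerance = 1e-10)
  expect_lt(pure$residual, 1e-10)
  mixd <- unmix(uv_spectrum(wl, 0.3 * A + 0.7 * B), refs)
  expect_equal(unname(mixd$fractions), c(0.3, 0.7), tolerance = 1e-10)
})

test_that("noisy unmixing matches a dense two-parameter grid-search oracle", {
  refs <- two_state_refs()
  wl <- refs$wavelength_nm
  set.seed(404)
  obs <- 0.5 * refs$prot + 0.5 * refs$deprot + rnorm(length(wl), 0, 0.002)
  # independent oracle: exhaustive search over the two scale factors, with
  # the residual sum of squares expanded in inner products so the full
  # (f_a, f_b) grid is evaluated exactly
  fgrid <- seq(0, 1.2, by = 1e-3)
  aa <- sum(refs$prot^2); bb <- sum(refs$deprot^2)
  ab <- sum(refs$prot * refs$deprot)
  ao <- sum(refs$prot * obs); bo <- sum(refs$deprot * obs)
  sse <- outer(fgrid^2 * aa - 2 * fgrid * ao, fgrid^2 * bb - 2 * fgrid * bo, `+`) +
    2 * ab * outer(fgrid, fgrid)
  i <- arrayInd(which.min(sse), dim(sse))
  best <- c(fgrid[i[1]], fgrid[i[2]])
  oracle_frac <- best / sum(best)

  res <- unmix(uv_spectrum(wl, obs), refs)
  expect_equal(unname(res$fractions), oracle_frac, tolerance = 2e-3)
  expect_equal(unname(res$fractions), c(0.5, 0.5), tolerance = 0.02)
})

test_that("unmixing fractions are invariant to spectrum scaling", {
  refs <- two_state_refs()
  wl <- refs$wavelength_nm
  obs <- 0.25 * refs$prot + 0.75 * refs$deprot
  f1 <- unmix(uv_spectrum(wl, obs), refs)
  f3 <- unmix(uv_spectrum(wl, 3 * obs), refs)
  expect_equal(f3$fractions, f1$fractions, tolerance = 1e-10)
  expect_equal(unname(f3$coefficients), 3 * unname(f1$coefficients),
               tolerance = 1e-8)
})

test_that("collinear references are rejected as ill-conditioned", {
  wl <- 250:350
  shape <- exp(-(wl - 300)^2 / 400)
  refs <- reference_set(wl, a = shape, b = 2 * shape)
  expect_error(unmix(uv_spectrum(wl, shape), refs), "ill-conditioned")
})

test_that("off-grid spectra are resampled with a warning", {
  refs <- two_state_refs()
  wl2 <- seq(250, 350, by = 0.5)
  obs <- approx(refs$wavelength_nm, 0.4 * refs$prot + 0.6 * refs$deprot,
                xout = wl2)$y
  expect_warning(res <- unmix(uv_spectrum(wl2, obs), refs), "resampled")
  expect_true(res$resampled)
  expect_equal(unname(res$fractions), c(0.4, 0.6), tolerance = 1e-6)
})

test_that("a noiseless titration is self-fitted to machine precision", {
  refs <- two_state_refs()
  tit <- make_titration(7.00, seq(4, 10, 0.5), refs, noise_sd = 0)
  fit <- fit_pka(tit, refs)
  expect_equal(fit$pKa, 7.00, tolerance = 1e-6)
  # midpoint identity: alpha = 0.5 exactly at pH = pKa
  tit49 <- make_titration(7.49, seq(4.49, 10.49, 0.5), refs, noise_sd = 0)
  expect_equal(fit_pka(tit49, refs)$pKa, 7.49, tolerance = 1e-6)
})

test_that("noisy pKa fit matches a fine grid search over the same loss", {
  refs <- two_state_refs()
  tit <- make_titration(7.2, seq(4, 10, 0.5), refs, noise_sd = 0.002,
                        seed = 505)
  fit <- fit_pka(tit, refs)
  alpha <- fit$data$alpha_observed
  pH <- fit$data$pH
  pka_grid <- seq(6.5, 8.0, by = 1e-4)
  loss <- vapply(pka_grid, function(pk)
    sum((alpha - 10^(pH - pk) / (1 + 10^(pH - pk)))^2), numeric(1))
  expect_equal(fit$pKa, pka_grid[which.min(loss)], tolerance = 2e-4)
})

test_that("pKa recovery over seeded synthetic titrations is accurate", {
  refs <- two_state_refs()
  set.seed(606)
  pkas <- runif(50, 6.5, 8.5)
  errs <- vapply(seq_along(pkas), function(i) {
    tit <- make_titration(pkas[i], seq(4, 10, 0.5), refs, noise_sd = 0.002,
                          seed = 1000 + i)
    abs(fit_pka(tit, refs)$pKa - pkas[i])
  }, numeric(1))
  expect_lt(mean(errs), 0.03)
})

test_that("series without a transition or with too few points are rejected", {
  refs <- two_state_refs()
  flat <- make_titration(2.0, seq(6, 10, 0.5), refs, noise_sd = 0)
  expect_error(fit_pka(flat, refs), "no protonation transition")
  short <- make_titration(7, c(5, 6, 7, 8), refs, noise_sd = 0)
  expect_error(fit_pka(short, refs), "5 distinct pH")
})

test_that("state fractions convert to product concentrations", {
  expect_equal(progress_to_concentration(0, 0, substrate_0 = 1)$product_mM, 0)
  expect_equal(progress_to_concentration(c(0, 5), c(0, 0.5), 1)$product_mM,
               c(0, 0.5))
  us <- list(list(fractions = c(substrate = 1, product = 0)),
             list(fractions = c(substrate = 0.4, product = 0.6)))
  out <- progress_to_concentration(c(0, 10), us, substrate_0 = 2)
  expect_equal(out$product_mM, c(0, 1.2))
})

test_that("specific activity follows the unit definition arithmetic", {
  course <- data.frame(time_min = 0:2, product_mM = 0.06 * (0:2))
  act <- specific_activity(course, substrate_0 = 1, enzyme_conc = 0.001,
                           volume = 1)
  expect_equal(act$specific_activity, 60)
  expect_equal(act$units, 0.06)
  flat <- data.frame(time_min = 0:5, product_mM = rep(0, 6))
  expect_equal(specific_activity(flat, 1, 0.001)$specific_activity, 0)
})

test_that("specific activity is volume-invariant at fixed enzyme concentration", {
  course <- data.frame(time_min = 0:4, product_mM = 0.02 * (0:4))
  a1 <- specific_activity(course, 1, 0.005, volume = 1)
  a2 <- specific_activity(course, 1, 0.005, volume = 10)
  expect_equal(a1$specific_activity, a2$specific_activity)
  expect_equal(a2$units, 10 * a1$units)
})

test_that("initial slope of a saturating course is recovered from the window", {
  # exponential approach to 1 mM with initial slope 0.005 mM/min
  tt <- seq(0, 40, by = 1)
  course <- data.frame(time_min = tt, product_mM = 1 - exp(-0.005 * tt))
  act <- specific_activity(course, substrate_0 = 1, enzyme_conc = 0.001,
                           linear_fraction_max = 0.08)
  expect_equal(act$initial_rate, 0.005, tolerance = 0.05)
  short <- data.frame(time_min = c(0, 1), product_mM = c(0, 0.01))
  expect_error(specific_activity(short, 1, 0.001), "insufficient")
})
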