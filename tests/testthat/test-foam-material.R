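# hysteretic foam point model and parameter identification

test_that("loading_stress interpolates the curve and refuses extrapolation", {
  lc <- cbind(c(0, 0.5), c(0, 0.1))
  expect_equal(loading_stress(0.25, lc), 0.05)
  expect_equal(loading_stress(0, lc), 0)
  expect_error(loading_stress(0.6, lc), "outside the load curve domain")
  # random monotone curve vs an independent interpolation oracle
  set.seed(3)
  eps <- c(0, sort(stats::runif(8, 0.01, 0.7)))
  sig <- c(0, cumsum(stats::runif(8, 0, 0.05)))
  x <- stats::runif(40, 0, max(eps))
  expect_equal(loading_stress(x, cbind(eps, sig)),
               stats::approx(eps, sig, xout = x)$y, tolerance = 1e-12)
})

test_that("unloading collapses to loading at hu = 1 and joins at reversal", {
  lc <- foam_curve()
  eps <- seq(0, 0.6, by = 0.02)
  expect_equal(unloading_stress(eps, 0.6, lc, hu = 1, shape = 3),
               loading_stress(eps, lc), tolerance = 1e-12)
  for (hu in c(0.2, 0.5, 0.9))
    for (shape in c(0.5, 1, 4))
      expect_equal(unloading_stress(0.6, 0.6, lc, hu, shape),
                   loading_stress(0.6, lc), tolerance = 1e-12)
  expect_error(unloading_stress(0.1, 0, lc, 0.5, 1), "degenerate")
})

test_that("linear loading curve gives the closed-form unloading branch", {
  E <- 5
  lc <- cbind(c(0, 1), c(0, E))
  eps_max <- 0.5
  eps <- seq(0, eps_max, length.out = 101)
  # W(e) = E e^2/2, so W(e)/W(em) = (e/em)^2 and with shape = 1:
  closed <- E * eps * (0.5 + 0.5 * (eps / eps_max)^2)
  expect_equal(unloading_stress(eps, eps_max, lc, hu = 0.5, shape = 1),
               closed, tolerance = 1e-9)
})

test_that("unloading never exceeds loading for hu <= 1", {
  set.seed(8)
  for (rep in 1:20) {
    eps_k <- c(0, sort(stats::runif(6, 0.05, 0.8)))
    sig_k <- c(0, cumsum(stats::runif(6, 0.001, 0.05)))
    lc <- cbind(eps_k, sig_k)
    hu <- stats::runif(1, 0.05, 1); shape <- stats::runif(1, 0.1, 6)
    em <- stats::runif(1, 0.3, max(eps_k))
    eps <- seq(0, em, length.out = 50)
    expect_true(all(unloading_stress(eps, em, lc, hu, shape) <=
                      loading_stress(eps, lc) + 1e-12))
  }
})

test_that("dissipated energy matches the closed-form loop area", {
  E <- 5
  lc <- cbind(c(0, 1), c(0, E))
  # loop area for hu = 0.5, shape = 1: int E*e*0.5*(1 - (e/em)^2) de = E em^2 / 8
  expect_equal(dissipated_energy(load_curve = lc, hu = 0.5, shape = 1,
                                 eps_max = 0.5),
               E * 0.5^2 / 8, tolerance = 1e-6)
  expect_equal(dissipated_energy(load_curve = lc, hu = 1, shape = 1,
                                 eps_max = 0.5), 0)
  # strictly decreasing toward hu = 1 on a fixed curve
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8, 1),
                  function(h) dissipated_energy(load_curve = foam_curve(),
                                                hu = h, shape = 2,
                                                eps_max = 0.65), numeric(1))
  expect_true(all(diff(areas) < 0))
  # measured-cycle route agrees with the model route
  fp <- foam_params(30, 2, foam_curve(), hu = 0.4, shape = 2)
  tst <- gen_foam_test(fp, eps_max = 0.65, n_points = 400)
  expect_equal(dissipated_energy(tst),
               dissipated_energy(load_curve = foam_curve(), hu = 0.4,
                                 shape = 2, eps_max = 0.65),
               tolerance = 1e-3)
  incomplete <- uniaxial_test(c(0, 0.3, 0.65, 0.5, 0.4),
                              c(0, 0.04, 0.14, 0.1, 0.08))
  expect_error(dissipated_energy(incomplete), "incomplete cycle")
})

test_that("noise-free parameter recovery is within 1 percent", {
  fp <- foam_params(30, 2, foam_curve(), hu = 0.3, shape = 2)
  tst <- gen_foam_test(fp, eps_max = 0.65, n_points = 60)
  fit <- fit_foam_params(tst, foam_curve(), seed = 5)
  expect_equal(fit$hu, 0.3, tolerance = 0.01)
  expect_equal(fit$shape, 2, tolerance = 0.01)
  expect_true(fit$converged)
  # fitted objective cannot exceed the truth's objective on clean data
  truth_obj <- 0
  expect_lte(fit$objective, truth_obj + 1e-9)
})

test_that("recovery from 2 percent noise stays within 5 percent over replicates", {
  fp <- foam_params(30, 2, foam_curve(), hu = 0.3, shape = 2)
  peak <- loading_stress(0.65, foam_curve())
  ests <- t(vapply(1:20, function(s) {
    tst <- gen_foam_test(fp, eps_max = 0.65, n_points = 80,
                         noise_sd = 0.02 * peak, seed = s)
    fit <- fit_foam_params(tst, foam_curve(), seed = s + 1000L)
    c(fit$hu, fit$shape)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1L]) - 0.3) / 0.3, 0.05)
  expect_lt(abs(mean(ests[, 2L]) - 2) / 2, 0.05)
})

test_that("a non-hysteretic test drives hu to the upper bound", {
  fp <- foam_params(30, 2, foam_curve(), hu = 1, shape = 1)
  tst <- gen_foam_test(fp, eps_max = 0.6, n_points = 50)
  fit <- fit_foam_params(tst, foam_curve(), seed = 2)
  expect_gte(fit$hu, 0.99)
})

test_that("fitting without an unloading branch fails", {
  load_only <- uniaxial_test(c(0, 0.2, 0.4), c(0, 0.02, 0.06))
  expect_error(fit_foam_params(load_only, foam_curve()), "no unloading branch")
})
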