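test_that("cost function matches hand values and the double-loop oracle", {
  m <- ref_n4(); g <- ref_cyl()
  f <- default_freq_grid()
  eps_self <- complex_permittivity(m, f)
  # data generated from the very model under test: zero cost
  expect_equal(debye_cost(m, f, eps_self), 0)

  # single-frequency toy: one decade of mismatch in the real part
  toy_f <- 1e3
  D <- complex_permittivity(m, toy_f)
  E <- complex(real = Re(D) / 10, imaginary = Im(D))
  expect_equal(debye_cost(m, toy_f, E), 1, tolerance = 1e-12)

  # 4-pole model scored against a 2-pole-generated spectrum, vs the oracle
  m2 <- potato_debye_models()$n2
  eps2 <- complex_permittivity(m2, f)
  cf <- debye_cost(m, f, eps2)
  expect_gt(cf, 0)
  expect_equal(cf, oracle_cost(m, f, eps2), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    mm <- random_model(2)
    dd <- complex_permittivity(random_model(2), f[seq(1, 109, by = 10)])
    expect_equal(debye_cost(mm, f[seq(1, 109, by = 10)], dd),
                 oracle_cost(mm, f[seq(1, 109, by = 10)], dd),
                 tolerance = 1e-12)
  }
})

test_that("GA recovers a 1-pole model from noiseless data", {
  truth <- debye_model(sigma_s = 0.02, eps_inf = 100,
                       delta_eps = 1e4, tau = 1e-5)
  spec <- synth_spectrum(truth, ref_cyl(), noise_cv = 0, n_replicates = 1)
  best <- NULL
  for (s in 1:3) {
    fit <- debye_fit(spec, n_poles = 1, seed = s,
                     control = ga_config(population_size = 200,
                                         max_generations = 300))
    if (is.null(best) || fit$cf < best$cf) best <- fit
  }
  expect_lt(best$cf, 1e-3)
  truth_vec <- c(0.02, 100, 1e4, 1e-5)
  expect_true(all(abs(coef(best) - truth_vec) / truth_vec < 0.05))
})

test_that("elitism retains an injected perfect individual at zero cost", {
  m <- ref_n4()
  spec <- synth_spectrum(m, ref_cyl(), noise_cv = 0, n_replicates = 1)
  fit <- debye_fit(spec, n_poles = 4, seed = 9, init_models = list(m),
                   control = ga_config(population_size = 50,
                                       max_generations = 30))
  expect_equal(fit$cf, 0, tolerance = 1e-20)
})

test_that("best-cost history is monotone non-increasing and runs are reproducible", {
  truth <- debye_model(0.02, 100, 1e4, 1e-5)
  spec <- synth_spectrum(truth, ref_cyl(), noise_cv = 0.02,
                         n_replicates = 3, seed = 4)
  ctrl <- ga_config(population_size = 80, max_generations = 60)
  f1 <- debye_fit(spec, 1, seed = 42, control = ctrl)
  f2 <- debye_fit(spec, 1, seed = 42, control = ctrl)
  expect_true(all(diff(f1$history) <= 1e-15))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)
  expect_equal(f1$cf, min(f1$history), tolerance = 1e-12)
  # returned parameters respect the log10 bounds
  expect_true(f1$model$sigma_s >= 1e-4 && f1$model$sigma_s <= 1)
  expect_true(f1$model$eps_inf >= 1 && f1$model$eps_inf <= 1e8)
  expect_true(all(f1$model$tau >= 1e-12 & f1$model$tau <= 10))
  expect_true(all(f1$model$delta_eps >= 1e-3 & f1$model$delta_eps <= 1e8))
})

test_that("pole-count scan: nested models do not worsen, empty list allowed", {
  truth <- debye_model(0.02, 100, 1e4, 1e-5)
  spec <- synth_spectrum(truth, ref_cyl(), noise_cv = 0, n_replicates = 1)
  ctrl <- ga_config(population_size = 150, max_generations = 200)
  best_cf <- function(n) min(vapply(1:3, function(s)
    debye_fit(spec, n, seed = s, control = ctrl)$cf, numeric(1)))
  expect_lte(best_cf(2), best_cf(1) * 1.5 + 1e-6)

  scan <- multi_pole_fit(spec, c(1, 2), control = ctrl, seed = 1)
  expect_equal(scan$summary$n_poles, c(1L, 2L))
  expect_true(all(scan$summary$cf >= 0))

  empty <- multi_pole_fit(spec, integer(0))
  expect_equal(nrow(empty$summary), 0)
})

test_that("fit errors on unusable inputs", {
  spec <- synth_spectrum(ref_n4(), ref_cyl(), noise_cv = 0, n_replicates = 1)
  small <- admittance_spectrum(spec$freqs[1:3], spec$G[1:3, ], spec$B[1:3, ],
                               geometry = ref_cyl())
  expect_error(debye_fit(small, n_poles = 4), "2\\(N\\+1\\)")
  bad_bounds <- ga_config(bounds = matrix(c(1, 1, 0, 0), 2))
  expect_error(debye_fit(spec, 0, control = bad_bounds), "bounds")
  expect_error(debye_fit(data.frame(x = 1), 1), "admittance_spectrum")
})

test_that("fit object methods: coef, predict, residuals, summary print", {
  truth <- debye_model(0.02, 100, 1e4, 1e-5)
  spec <- synth_spectrum(truth, ref_cyl(), noise_cv = 0, n_replicates = 1)
  fit <- debye_fit(spec, 1, seed = 1, init_models = list(truth),
                   control = ga_config(population_size = 40,
                                       max_generations = 10))
  expect_named(coef(fit), c("sigma_s", "eps_inf", "delta_eps1", "tau1"))
  p <- predict(fit, freq = c(1e3, 1e5), type = "properties")
  expect_equal(p$sigma, effective_properties(fit$model, c(1e3, 1e5))$sigma)
  Y <- predict(fit, freq = 1e3, type = "admittance", geometry = ref_cyl())
  expect_equal(Y, terminal_admittance(fit$model, ref_cyl(), 1e3))
  r <- residuals(fit)
  expect_equal(nrow(r), length(spec$freqs))
  expect_true(all(abs(r$real) < 1e-10))  # perfect fit injected
  expect_output(print(fit), "Debye fit")
  expect_output(summary(fit), "final cost")
})
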