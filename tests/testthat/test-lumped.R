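test_that("zero source gives identically zero current", {
  m <- ref_n4(); g <- ref_cyl()
  zero <- source_custom(function(t) 0 * t, function(t) 0 * t,
                        max_step = 1e-5)
  r <- simulate_lumped(m, g, zero, t_end = 1e-3)
  expect_true(all(r$I == 0))
  rs <- simulate_static_conductivity(m$sigma_s, g, zero, 1e-3)
  expect_true(all(rs$I == 0))
})

test_that("single-pole step response follows the closed-form exponential", {
  # step field applied via a fast-rising pulse; after the transition the
  # pole current must decay as (eps0*de/tau) * E0 * exp(-t/tau)
  de <- 5e3; tau <- 2e-5; l <- 5e-3; A <- 50
  m <- debye_model(sigma_s = 1e-6, eps_inf = 1, delta_eps = de, tau = tau)
  g <- sample_geometry(length = l, area = 1)  # unit area: I = J
  tr <- 1e-8  # transition much faster than tau: effectively a step
  src <- source_pulse_burst(amplitude = A, n_pulses = 1, width = 2e-4,
                            period = 4e-4, transition = tr)
  r <- simulate_lumped(m, g, src, t_end = 1.5e-4, max_step = 5e-7)
  E0 <- A / l
  sel <- r$t > 10 * tr & r$t < 1.9e-4
  analytic <- (eps0_ref * de / tau) * E0 * exp(-(r$t[sel] - tr / 2) / tau) +
    m$sigma_s * E0
  expect_lt(max(abs(r$I[sel] - analytic)) / max(abs(analytic)), 1e-3)
})

test_that("amplitude/phase extraction is exact on synthetic sinusoids", {
  f <- 1e4; w <- 2 * pi * f
  t <- seq(0, 5 / f, length.out = 5000)
  V <- 50 * sin(w * t)
  I <- 2 * sin(w * t + 30 * pi / 180)
  r <- structure(list(t = t, I = I, V = V, solver = list()),
                 class = "time_sim")
  ap <- extract_amplitude_phase(r, f)
  expect_equal(unname(ap["amplitude"]), 2, tolerance = 1e-9)
  expect_equal(unname(ap["phase_deg"]), 30, tolerance = 1e-9)
  # a DC offset is absorbed by the constant term
  r$I <- I + 0.7
  ap2 <- extract_amplitude_phase(r, f)
  expect_equal(unname(ap2["amplitude"]), 2, tolerance = 1e-9)
  # too-short window errors
  expect_error(extract_amplitude_phase(r, f, window = 10), "span")
})

test_that("sinusoidal steady state matches the frequency-domain admittance", {
  m <- ref_n4(); g <- ref_cyl()
  for (f in c(1e3, 1e5)) {
    r <- simulate_lumped(m, g, source_sine(50, f), t_end = 5 / f)
    ap <- extract_amplitude_phase(r, f)
    I <- 50 * terminal_admittance(m, g, f)
    expect_equal(unname(ap["amplitude"]), Mod(I), tolerance = 5e-3)
    expect_lt(abs(ap["phase_deg"] - Arg(I) * 180 / pi), 0.2)
  }
  # property over random models: the lumped system is linear time-invariant
  set.seed(13)
  for (i in 1:3) {
    mm <- random_model(2)
    f <- 10^stats::runif(1, 3, 5)
    r <- simulate_lumped(mm, g, source_sine(10, f), t_end = 5 / f)
    ap <- extract_amplitude_phase(r, f)
    I <- 10 * terminal_admittance(mm, g, f)
    expect_lt(abs(ap["amplitude"] / Mod(I) - 1), 5e-3)
    expect_lt(abs(ap["phase_deg"] - Arg(I) * 180 / pi), 0.2)
  }
})

test_that("halving the max step leaves the trace essentially unchanged", {
  m <- ref_n4(); g <- ref_cyl()
  f <- 1e3
  r1 <- simulate_lumped(m, g, source_sine(50, f), t_end = 3 / f)
  r2 <- simulate_lumped(m, g, source_sine(50, f), t_end = 3 / f,
                        max_step = 1 / (200 * f))
  I2 <- stats::approx(r2$t, r2$I, xout = r1$t)$y
  expect_lt(max(abs(r1$I - I2)) / max(abs(r1$I)), 1e-3)
})

test_that("superposition holds for summed sources", {
  m <- ref_n4(); g <- ref_cyl()
  f1 <- 1e3; f2 <- 3.7e3
  s1 <- source_sine(30, f1); s2 <- source_sine(20, f2)
  s12 <- source_custom(function(t) s1$value(t) + s2$value(t),
                       function(t) s1$deriv(t) + s2$deriv(t),
                       max_step = 1 / (100 * f2))
  t_end <- 2 / f1
  r1 <- simulate_lumped(m, g, s1, t_end, max_step = 1 / (100 * f2))
  r2 <- simulate_lumped(m, g, s2, t_end, max_step = 1 / (100 * f2))
  r12 <- simulate_lumped(m, g, s12, t_end)
  I1 <- stats::approx(r1$t, r1$I, xout = r12$t)$y
  I2 <- stats::approx(r2$t, r2$I, xout = r12$t)$y
  expect_lt(max(abs(r12$I - (I1 + I2))) / max(abs(r12$I)), 1e-4)
})

test_that("auxiliary states decay after the source returns to zero", {
  # current after a pulse ends decays on the pole time scales toward zero
  m <- debye_model(1e-6, 1, delta_eps = 1e4, tau = 1e-5)
  g <- ref_cyl()
  src <- source_pulse_burst(amplitude = 50, n_pulses = 1, width = 50e-6,
                            period = 100e-6, transition = 2e-6)
  r <- simulate_lumped(m, g, src, t_end = 1e-4)
  late <- abs(r$I[r$t > 50e-6 + 8 * 1e-5])
  expect_true(all(late < 1e-3 * max(abs(r$I))))
})

test_that("static-conductivity comparator is a scalar multiple of the voltage", {
  g <- ref_cyl()
  src <- source_pulse_burst()
  r <- simulate_static_conductivity(2.159e-2, g, src, t_end = 800e-6)
  expect_equal(max(r$I), 0.05804, tolerance = 1e-3)
  k <- 2.159e-2 * g$area / g$length
  expect_equal(r$I, k * r$V, tolerance = 1e-14)
})

test_that("dispersive pulse response droops within the pulse; comparator is flat", {
  m <- ref_n4(); g <- ref_cyl()
  src <- source_pulse_burst()
  rd <- simulate_lumped(m, g, src, t_end = 200e-6)
  rs <- simulate_static_conductivity(m$sigma_s, g, src, t_end = 200e-6)
  # sample the flat top of the first pulse away from the edges
  at <- function(r, t) stats::approx(r$t, r$I, xout = t)$y
  early <- at(rd, 15e-6); late <- at(rd, 90e-6)
  expect_gt(early, late)            # intra-pulse droop of the dispersive trace
  expect_gt(early, at(rs, 15e-6))   # dispersive current exceeds the comparator
  expect_equal(at(rs, 15e-6), at(rs, 90e-6), tolerance = 1e-10)  # flat top
})

test_that("source constructors validate and carry consistent derivatives", {
  expect_error(source_custom(function(t) t, deriv = NULL), "derivative")
  src <- source_pulse_burst()
  t <- seq(0, 800e-6, by = 1e-7)
  V <- src$value(t)
  expect_true(all(abs(diff(V)) < 50 * 1e-7 / 8e-6 + 1e-9))  # continuity
  # derivative consistent with finite differences away from kinks
  tt <- seq(1e-6, 7e-6, by = 1e-8)
  fd <- (src$value(tt + 1e-9) - src$value(tt - 1e-9)) / 2e-9
  expect_equal(src$deriv(tt), fd, tolerance = 1e-6)
  s <- source_sine(50, 1e3)
  expect_equal(s$value(0.25e-3), 50, tolerance = 1e-12)
})
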