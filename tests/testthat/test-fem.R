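test_that("structured mesh has the expected counts, tags and volume", {
  mesh <- build_mesh(9.25e-3, 5e-3, nr = 16, nz = 16)
  expect_equal(nrow(mesh$elements), 512)
  expect_equal(nrow(mesh$nodes), 17 * 17)
  expect_length(mesh$boundary$terminal, 17)
  expect_length(mesh$boundary$ground, 17)
  expect_true(all(mesh$nodes[mesh$boundary$axis, 1] == 0))
  expect_true(all(mesh$nodes[mesh$boundary$terminal, 2] == 5e-3))
  expect_true(all(mesh$nodes[, 1] >= 0))
  # every boundary edge carries exactly one tag
  expect_equal(anyDuplicated(mesh$edges[, c("n1", "n2")]), 0L)
  expect_equal(nrow(mesh$edges), 2 * 16 + 2 * 16)
  # axisymmetric volume
  expect_equal(mesh_volume(mesh), pi * 9.25e-3^2 * 5e-3, tolerance = 1e-3)
  # minimal mesh still solvable
  tiny <- build_mesh(1e-2, 1e-2, 1, 1)
  expect_equal(nrow(tiny$elements), 2)
  r <- solve_frequency(tiny, NULL, 1e3, 10, conductivity = 0.1 + 0i)
  expect_equal(Mod(r$terminal_current), 0.1 * pi * 1e-2^2 / 1e-2 * 10,
               tolerance = 1e-10)
})

test_that("purely resistive medium gives the exact series conductance at any resolution", {
  for (nr in c(2, 7)) {
    mesh <- build_mesh(9.25e-3, 5e-3, nr, nr)
    r <- solve_frequency(mesh, NULL, 1e3, 50, conductivity = 0.02 + 0i)
    expect_equal(Re(r$terminal_current), 0.02 * pi * 9.25e-3^2 / 5e-3 * 50,
                 tolerance = 1e-10)
    expect_lt(abs(Im(r$terminal_current)), 1e-12)
  }
})

test_that("two stacked layers reproduce the series-conductance closed form", {
  mesh <- build_mesh(9.25e-3, 5e-3, 4, 8)
  # bottom half sigma1, top half sigma2 (element centroids decide)
  zc <- (mesh$nodes[mesh$elements[, 1], 2] + mesh$nodes[mesh$elements[, 2], 2] +
         mesh$nodes[mesh$elements[, 3], 2]) / 3
  s1 <- 0.05; s2 <- 0.01
  sig <- ifelse(zc < 2.5e-3, s1, s2) + 0i
  r <- solve_frequency(mesh, NULL, 1e3, 50, conductivity = sig)
  S <- pi * 9.25e-3^2
  G_series <- S / (2.5e-3 / s1 + 2.5e-3 / s2)
  expect_equal(Re(r$terminal_current), G_series * 50, tolerance = 1e-10)
})

test_that("homogeneous dispersive cylinder matches the lumped analytic in frequency domain", {
  m <- ref_n4(); g <- ref_cyl()
  mesh <- build_mesh(9.25e-3, 5e-3, 16, 16)
  for (f in c(1e3, 1e5, 1e6)) {
    r <- solve_frequency(mesh, m, f, 50)
    I_ref <- 50 * terminal_admittance(m, g, f)
    expect_lt(Mod(r$terminal_current - I_ref) / Mod(I_ref), 2e-3)
  }
  r1k <- solve_frequency(mesh, m, 1e3, 50)
  expect_equal(Mod(r1k$terminal_current), 0.0734, tolerance = 2e-3)
})

test_that("terminal and ground currents balance (discrete conservation)", {
  m <- ref_n4()
  mesh <- build_mesh(9.25e-3, 5e-3, 8, 8)
  for (f in c(1e3, 1e6)) {
    r <- solve_frequency(mesh, m, f, 50)
    expect_lt(Mod(r$terminal_current + r$ground_current) /
              Mod(r$terminal_current), 1e-10)
  }
})

test_that("time-domain FEM matches the lumped solver for a homogeneous sine drive", {
  m <- ref_n4(); g <- ref_cyl()
  mesh <- build_mesh(9.25e-3, 5e-3, 8, 8)
  f <- 1e3
  fem <- solve_time(mesh, m, source_sine(50, f), t_end = 5 / f)
  lump <- simulate_lumped(m, g, source_sine(50, f), t_end = 5 / f)
  sel <- fem$t > 1 / f
  I_ref <- stats::approx(lump$t, lump$I, xout = fem$t[sel])$y
  expect_lt(max(abs(fem$I[sel] - I_ref)) / max(abs(I_ref)), 5e-3)
})

test_that("zero source leaves the FEM time solution identically zero", {
  m <- ref_n4()
  mesh <- build_mesh(9.25e-3, 5e-3, 4, 4)
  zero <- source_custom(function(t) 0 * t, function(t) 0 * t,
                        max_step = 1e-5)
  r <- solve_time(mesh, m, zero, t_end = 1e-4)
  expect_true(all(abs(r$I) < 1e-15))
})

test_that("pulse burst on a static-conductivity medium hits the closed-form plateau", {
  mesh <- build_mesh(9.25e-3, 5e-3, 8, 8)
  src <- source_pulse_burst()
  r <- solve_time(mesh, NULL, src, t_end = 200e-6, conductivity = 2.159e-2)
  plateau <- 2.159e-2 * pi * 9.25e-3^2 / 5e-3 * 50
  expect_equal(max(r$I), plateau, tolerance = 2e-3)
})

test_that("mesh refinement does not move the homogeneous terminal current", {
  m <- ref_n4()
  I4 <- solve_frequency(build_mesh(9.25e-3, 5e-3, 4, 4), m, 1e5, 50)$terminal_current
  I16 <- solve_frequency(build_mesh(9.25e-3, 5e-3, 16, 16), m, 1e5, 50)$terminal_current
  expect_lt(Mod(I4 - I16) / Mod(I16), 1e-8)
})

test_that("degenerate mesh dimensions are rejected", {
  expect_error(build_mesh(-1, 5e-3), "radius")
  expect_error(build_mesh(1e-2, 0), "height")
})
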