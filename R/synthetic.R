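#' Default impedance-sweep frequency grid
#'
#' Logarithmic grid emulating a plate-electrode impedance-analyser sweep:
#' 20 points per decade anchored at `f_min`, truncated strictly below
#' `f_max`, with `f_max` itself appended as the final point.  With the
#' defaults (40 Hz to 10 MHz) this yields 109 frequencies.
#'
#' @param f_min,f_max Sweep limits in Hz.
#' @param points_per_decade Grid density.
#' @return Numeric vector of frequencies, strictly increasing.
#' @export
#' @examples
#' length(default_freq_grid())  # 109
default_freq_grid <- function(f_min = 40, f_max = 10e6, points_per_decade = 20) {
  stopifnot(f_min > 0, f_max > f_min, points_per_decade >= 1)
  n_dec <- log10(f_max / f_min)
  i <- 0:ceiling(n_dec * points_per_decade)
  f <- f_min * 10^(i / points_per_decade)
  f <- f[f < f_max * (1 - 1e-12)]
  c(f, f_max)
}

#' Generate a synthetic admittance spectrum
#'
#' Emulates replicate impedance-spectroscopy measurements of a sample whose
#' true dispersion is a known Debye model: the noiseless admittance comes
#' from [terminal_admittance()], and each replicate's G and B are multiplied
#' by independent lognormal noise with unit mean and coefficient of
#' variation `noise_cv` (independent across frequency, replicate and the
#' G/B channels).
#'
#' @param model True [debye_model()].
#' @param geometry [sample_geometry()] of the sample.
#' @param freqs Frequency grid, Hz; defaults to [default_freq_grid()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.02); zero gives noiseless replicates.
#' @param n_replicates Number of replicate sweeps (default 10).
#' @param seed Optional integer seed for reproducibility.
#' @return An [admittance_spectrum()] carrying `geometry`.
#' @export
#' @examples
#' m <- debye_model(0.02, 100, 1e4, 1e-5)
#' g <- cylinder_geometry(9.25e-3, 5e-3)
#' s <- synth_spectrum(m, g, noise_cv = 0.02, n_replicates = 3, seed = 1)
synth_spectrum <- function(model, geometry, freqs = default_freq_grid(),
                           noise_cv = 0.02, n_replicates = 10, seed = NULL) {
  stopifnot(noise_cv >= 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  Y <- terminal_admittance(model, geometry, freqs)
  nf <- length(freqs)
  G0 <- matrix(Re(Y), nf, n_replicates)
  B0 <- matrix(Im(Y), nf, n_replicates)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    mlog <- -sdlog^2 / 2  # unit-mean lognormal
    G0 <- G0 * matrix(stats::rlnorm(nf * n_replicates, mlog, sdlog), nf)
    B0 <- B0 * matrix(stats::rlnorm(nf * n_replicates, mlog, sdlog), nf)
  }
  admittance_spectrum(freqs, G0, B0, geometry = geometry)
}

#' Published multipole Debye parameterisations of potato tissue
#'
#' Named list of Debye models (`n2`, `n4`, `n6`: 2, 4 and 6 poles)
#' describing the 40 Hz-10 MHz dielectric dispersion of potato tuber tissue,
#' as obtained by genetic-algorithm parameterisation of plate-electrode
#' impedance measurements.  The 4-pole model is the reference material for
#' the package's worked examples and simulations.
#'
#' @return Named list of [debye_model()] objects.
#' @export
#' @examples
#' potato_debye_models()$n4
potato_debye_models <- function() {
  path <- system.file("extdata", "potato_debye_models.json",
                      package = "debyesim", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j, function(m) {
    de <- vapply(m$poles, `[[`, numeric(1), "delta_eps")
    ta <- vapply(m$poles, `[[`, numeric(1), "tau")
    debye_model(m$sigma_s, m$eps_inf, de, ta)
  })
}
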