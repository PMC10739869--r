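#' Compare frequency- and time-domain terminal currents
#'
#' For each frequency, computes the terminal current magnitude and phase
#' from the frequency-domain admittance ([terminal_admittance()]) and from
#' a sinusoidal time-domain simulation ([simulate_lumped()] over `periods`
#' periods with the period/100 step policy, amplitude and phase extracted
#' from the final period).  For a linear dispersive sample the two must
#' agree once the time domain reaches its sinusoidal steady state; the
#' tabulated differences quantify the fidelity of the frequency-to-time
#' domain transformation.
#'
#' @param model A [debye_model()].
#' @param geometry A [sample_geometry()].
#' @param freqs Frequencies to compare, Hz.
#' @param v Applied voltage amplitude, V.
#' @param periods Number of simulated periods per frequency.
#' @param window Trailing periods used for amplitude/phase extraction.
#' @param check If `TRUE`, error when any difference exceeds `tol_mag`
#'   (amperes) or `tol_phase` (degrees).
#' @param tol_mag,tol_phase Agreement bounds used when `check = TRUE`.
#' @return A data frame of class `domain_comparison` with columns `freq`,
#'   `mag_freq`, `phase_freq`, `mag_time`, `phase_time`, `dmag`, `dphase`.
#' @export
#' @examples
#' m <- potato_debye_models()$n4
#' g <- cylinder_geometry(9.25e-3, 5e-3)
#' compare_domains(m, g, freqs = 1e3)
compare_domains <- function(model, geometry, freqs = c(1e3, 1e5, 1e6),
                            v = 50, periods = 5, window = 1,
                            check = FALSE, tol_mag = 0.01, tol_phase = 1.5) {
  stopifnot(all(freqs > 0), periods > window)
  rows <- lapply(freqs, function(f) {
    Y <- terminal_admittance(model, geometry, f)
    I <- v * Y
    sim <- simulate_lumped(model, geometry, source_sine(v, f),
                           t_end = periods / f)
    ap <- extract_amplitude_phase(sim, f, window = window)
    data.frame(freq = f,
               mag_freq = Mod(I), phase_freq = Arg(I) * 180 / pi,
               mag_time = unname(ap["amplitude"]),
               phase_time = unname(ap["phase_deg"]))
  })
  out <- do.call(rbind, rows)
  out$dmag <- abs(out$mag_time - out$mag_freq)
  out$dphase <- abs(out$phase_time - out$phase_freq)
  class(out) <- c("domain_comparison", "data.frame")
  if (check) {
    if (any(out$dmag > tol_mag))
      stop(sprintf("magnitude disagreement %.4g A exceeds %.4g A",
                   max(out$dmag), tol_mag))
    if (any(out$dphase > tol_phase))
      stop(sprintf("phase disagreement %.4g deg exceeds %.4g deg",
                   max(out$dphase), tol_phase))
  }
  out
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat("Frequency-domain vs time-domain terminal current\n")
  df <- as.data.frame(x)
  df$freq <- formatC(df$freq, format = "g")
  print(format(df, digits = 5), row.names = FALSE)
  cat(sprintf("max |dI| = %.4g A, max |dphase| = %.4g deg\n",
              max(x$dmag), max(x$dphase)))
  invisible(x)
}
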