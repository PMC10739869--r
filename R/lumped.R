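# Source waveforms carry an analytic derivative: the eps_inf displacement
# term needs dV/dt, and differentiating numerically would amplify noise.

#' Source voltage waveforms
#'
#' Applied-voltage waveforms with value `V(t)` and analytic derivative
#' `dV/dt`.  `source_sine()` is `A sin(2 pi f t)`; `source_pulse_burst()`
#' is a train of trapezoidal pulses (linear rise/fall edges of duration
#' `transition`, contained within each pulse's `width`) with defaults
#' matching a typical electroporation burst: 4 pulses, 100 us wide, one
#' every 200 us, 50 V, 8 us transitions.  `source_custom()` wraps arbitrary
#' value/derivative functions.
#'
#' @param amplitude Peak voltage, V.
#' @param frequency Sine frequency, Hz.
#' @return An object of class `source_signal` with callable fields `value`
#'   and `deriv`, and a `segments(t_end)` function returning integration
#'   windows with the recommended maximum time step for each.
#' @export
#' @examples
#' s <- source_sine(50, 1e3)
#' s$value(2.5e-4)
source_sine <- function(amplitude = 50, frequency) {
  stopifnot(frequency > 0)
  w <- 2 * pi * frequency
  structure(list(
    kind = "sine", amplitude = amplitude, frequency = frequency,
    value = function(t) amplitude * sin(w * t),
    deriv = function(t) amplitude * w * cos(w * t),
    segments = function(t_end)
      data.frame(start = 0, end = t_end, max_step = 1 / (100 * frequency))
  ), class = "source_signal")
}

#' @rdname source_sine
#' @param n_pulses Number of pulses in the burst.
#' @param width Pulse width in seconds, measured from the start of the rise
#'   to the end of the fall (so the flat top lasts `width - 2 * transition`).
#' @param period Pulse repetition period, s.
#' @param transition Rise/fall edge duration, s.
#' @export
source_pulse_burst <- function(amplitude = 50, n_pulses = 4, width = 100e-6,
                               period = 200e-6, transition = 8e-6) {
  stopifnot(n_pulses >= 1, width > 2 * transition, period >= width,
            transition > 0)
  value1 <- function(u) {  # one pulse on [0, width], u may be outside
    v <- numeric(length(u))
    r <- u >= 0 & u < transition
    v[r] <- amplitude * u[r] / transition
    p <- u >= transition & u <= width - transition
    v[p] <- amplitude
    f <- u > width - transition & u <= width
    v[f] <- amplitude * (width - u[f]) / transition
    v
  }
  deriv1 <- function(u) {
    d <- numeric(length(u))
    d[u >= 0 & u < transition] <- amplitude / transition
    d[u > width - transition & u <= width] <- -amplitude / transition
    d
  }
  fold <- function(t) {
    i <- pmin(pmax(floor(t / period), 0), n_pulses - 1)
    t - i * period
  }
  structure(list(
    kind = "pulse_burst", amplitude = amplitude, n_pulses = n_pulses,
    width = width, period = period, transition = transition,
    value = function(t) value1(fold(t)),
    deriv = function(t) deriv1(fold(t)),
    segments = function(t_end) {
      # fine steps (0.1 us) through the edges, coarse (1 us) elsewhere
      edges <- c(outer(c(0, transition, width - transition, width),
                       period * (seq_len(n_pulses) - 1), "+"))
      brk <- sort(unique(c(0, edges[edges < t_end], t_end)))
      seg <- data.frame(start = brk[-length(brk)], end = brk[-1])
      mid <- (seg$start + seg$end) / 2
      u <- mid - pmin(pmax(floor(mid / period), 0), n_pulses - 1) * period
      in_edge <- (u >= 0 & u <= transition) |
                 (u >= width - transition & u <= width)
      seg$max_step <- ifelse(in_edge, 0.1e-6, 1e-6)
      seg
    }
  ), class = "source_signal")
}

#' @rdname source_sine
#' @param value Function of time returning the voltage, V.
#' @param deriv Function of time returning dV/dt, V/s; required.
#' @param max_step Default maximum integration step for this source, s.
#' @export
source_custom <- function(value, deriv, max_step = NULL) {
  if (!is.function(value)) stop("`value` must be a function of time")
  if (!is.function(deriv))
    stop("a custom source must supply an analytic derivative function")
  structure(list(kind = "custom", value = value, deriv = deriv,
                 segments = function(t_end)
                   data.frame(start = 0, end = t_end,
                              max_step = if (is.null(max_step)) t_end / 1000
                                         else max_step)),
            class = "source_signal")
}

#' @export
print.source_signal <- function(x, ...) {
  cat(sprintf("Source waveform: %s", x$kind))
  if (x$kind == "sine")
    cat(sprintf(" (%.4g V, %.4g Hz)", x$amplitude, x$frequency))
  if (x$kind == "pulse_burst")
    cat(sprintf(" (%d x %.4g V, width %.4g s, period %.4g s, transition %.4g s)",
                x$n_pulses, x$amplitude, x$width, x$period, x$transition))
  cat("\n")
  invisible(x)
}

.time_sim_result <- function(t, I, V, meta) {
  structure(list(t = t, I = I, V = V, solver = meta), class = "time_sim")
}

#' @export
print.time_sim <- function(x, ...) {
  cat(sprintf("Time-domain simulation: %d samples over %.4g s (%s)\n",
              length(x$t), max(x$t), x$solver$method))
  cat(sprintf("  peak |I| = %.4g A, max step honoured = %.4g s\n",
              max(abs(x$I)), x$solver$max_step))
  invisible(x)
}

#' @export
plot.time_sim <- function(x, ...) {
  graphics::plot(x$t, x$I, type = "l", xlab = "time (s)",
                 ylab = "terminal current (A)", ...)
  invisible(x)
}

#' Lumped (uniform-field) time-domain simulation of the terminal current
#'
#' Integrates the auxiliary-differential-equation form of the multipole
#' Debye dispersion for a homogeneous plate-electrode sample.  The uniform
#' field is `E(t) = V(t)/l`; each pole k carries an auxiliary field obeying
#' \deqn{\tau_k \frac{de_k}{dt} = E(t) - e_k, \qquad e_k(0) = 0,} and the
#' terminal current is
#' \deqn{I(t) = S\left[\sigma_s E + \varepsilon_0\varepsilon_\infty
#'   \frac{dE}{dt} + \sum_k \frac{\varepsilon_0\Delta\varepsilon_k}{\tau_k}
#'   (E - e_k)\right].}
#' Integration uses the adaptive stiff solver [deSolve::lsoda()] with the
#' maximum step capped per integration window: one hundredth of the period
#' for sine sources, 0.1 us inside pulse transitions and 1 us elsewhere for
#' pulse bursts.
#'
#' @param model A [debye_model()].
#' @param geometry A [sample_geometry()].
#' @param source A `source_signal` (see [source_sine()]).
#' @param t_end Simulation end time, s.
#' @param max_step Optional cap overriding the source's step policy, s.
#' @param rtol,atol Solver tolerances passed to [deSolve::lsoda()].
#' @return A `time_sim` object with fields `t`, `I`, `V` and solver
#'   metadata.
#' @seealso [extract_amplitude_phase()], [simulate_static_conductivity()],
#'   [solve_time()] for the finite-element counterpart.
#' @export
#' @examples
#' m <- potato_debye_models()$n4
#' g <- cylinder_geometry(9.25e-3, 5e-3)
#' r <- simulate_lumped(m, g, source_sine(50, 1e3), t_end = 5e-3)
simulate_lumped <- function(model, geometry, source, t_end,
                            max_step = NULL, rtol = 1e-9, atol = NULL) {
  stopifnot(inherits(model, "debye_model"),
            inherits(geometry, "sample_geometry"),
            inherits(source, "source_signal"), t_end > 0)
  if (inherits(model, "cole_cole_model") && any(model$lambda != 0))
    stop("time-domain simulation requires a pure Debye model (all lambda = 0)")
  l <- geometry$length; S <- geometry$area
  np <- n_poles(model)
  E_of <- function(t) source$value(t) / l
  dE_of <- function(t) source$deriv(t) / l
  if (is.null(atol)) atol <- 1e-9 * max(abs(source$value(seq(0, t_end, length.out = 257))) / l, 1)

  seg <- source$segments(t_end)
  if (!is.null(max_step)) seg$max_step <- pmin(seg$max_step, max_step)
  state <- rep(0, np)
  ts <- list(); es <- list()
  deriv_fun <- function(t, y, parms) {
    E <- E_of(t)
    list((E - y) / model$tau)
  }
  for (i in seq_len(nrow(seg))) {
    h <- seg$max_step[i]
    times <- unique(c(seq(seg$start[i], seg$end[i], by = h / 2), seg$end[i]))
    if (np == 0L) {
      out <- cbind(times)
      e_mat <- matrix(0, length(times), 0)
    } else {
      out <- deSolve::lsoda(y = state, times = times, func = deriv_fun,
                            parms = NULL, rtol = rtol, atol = atol, hmax = h)
      if (attr(out, "istate")[1] < 0)
        stop("stiff solver failed; try a smaller max_step than ", h)
      e_mat <- out[, -1, drop = FALSE]
      state <- e_mat[nrow(e_mat), ]
    }
    keep <- if (i == 1L) seq_along(times) else -1L
    ts[[i]] <- times[keep]
    es[[i]] <- e_mat[keep, , drop = FALSE]
  }
  t <- do.call(c, ts)
  e <- do.call(rbind, es)
  E <- E_of(t); dE <- dE_of(t)
  I <- model$sigma_s * E + .eps0 * model$eps_inf * dE
  for (k in seq_len(np))
    I <- I + (.eps0 * model$delta_eps[k] / model$tau[k]) * (E - e[, k])
  I <- S * I
  .time_sim_result(t, I, source$value(t),
                   list(method = "lsoda (adaptive stiff, ADE states)",
                        max_step = max(seg$max_step), n_states = np,
                        rtol = rtol, atol = atol))
}

#' Static-conductivity comparator simulation
#'
#' Purely resistive reference trace `I(t) = S sigma_s V(t) / l`, the
#' response of the same sample if its dispersion were ignored and only the
#' static conductivity retained.  Contrasting it with [simulate_lumped()]
#' shows what the dispersion contributes (edge spikes and intra-pulse
#' droop) for pulsed fields.
#'
#' @param sigma_s Static conductivity, S/m.
#' @inheritParams simulate_lumped
#' @param n_out Number of output samples.
#' @return A `time_sim` object.
#' @export
simulate_static_conductivity <- function(sigma_s, geometry, source, t_end,
                                         n_out = 2001) {
  stopifnot(sigma_s > 0, inherits(geometry, "sample_geometry"),
            inherits(source, "source_signal"))
  t <- seq(0, t_end, length.out = n_out)
  V <- source$value(t)
  I <- geometry$area * sigma_s * V / geometry$length
  .time_sim_result(t, I, V, list(method = "static conductivity (algebraic)",
                                 max_step = t[2] - t[1], n_states = 0))
}

#' Amplitude and phase of a steady-state sinusoidal trace
#'
#' Least-squares fit of `a cos(wt) + b sin(wt) + c` to the final `window`
#' periods of the simulated current and voltage.  The constant term absorbs
#' any DC offset.  Returns the current amplitude and the phase lead of the
#' current relative to the applied voltage, in degrees (positive = current
#' leads, as for a capacitive sample).
#'
#' @param result A `time_sim` from [simulate_lumped()] or [solve_time()].
#' @param freq Drive frequency, Hz.
#' @param window Number of trailing periods used for the fit.
#' @return Named numeric vector `c(amplitude, phase_deg)`.
#' @export
extract_amplitude_phase <- function(result, freq, window = 1) {
  stopifnot(inherits(result, "time_sim"), freq > 0, window >= 1)
  t_end <- max(result$t)
  if (t_end < (window + 1) / freq)
    stop("trace must span at least window + 1 periods of the drive frequency")
  sel <- result$t >= t_end - window / freq - 1e-12 * t_end
  t <- result$t[sel]; w <- 2 * pi * freq
  X <- cbind(cos(w * t), sin(w * t), 1)
  ab_i <- qr.solve(X, result$I[sel])
  ab_v <- qr.solve(X, result$V[sel])
  amp <- sqrt(ab_i[1]^2 + ab_i[2]^2)
  ph <- (atan2(ab_i[1], ab_i[2]) - atan2(ab_v[1], ab_v[2])) * 180 / pi
  ph <- ((ph + 180) %% 360) - 180
  c(amplitude = amp, phase_deg = ph)
}
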