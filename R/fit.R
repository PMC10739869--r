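# Genome layout (all log10): sigma_s, eps_inf, then (delta_eps_k, tau_k) pairs.

.default_bounds <- function(n_poles) {
  lo <- c(-4, 0, rep(c(-3, -12), n_poles))
  hi <- c(0, 8, rep(c(8, 1), n_poles))
  nm <- c("sigma_s", "eps_inf",
          as.vector(rbind(paste0("delta_eps", seq_len(n_poles)),
                          paste0("tau", seq_len(n_poles)))))
  if (n_poles == 0L) nm <- c("sigma_s", "eps_inf")
  matrix(c(lo, hi), ncol = 2, dimnames = list(nm, c("lower", "upper")))
}

#' Genetic-algorithm settings for Debye fitting
#'
#' Controls the tournament genetic algorithm used by [debye_fit()].  The
#' defaults follow the configuration used for tissue parameterisation:
#' population 1000, tournament size 20, mutation probability 10%, up to
#' 2000 generations, with genomes encoded in log10 space inside the bounds
#' log10(delta_eps) in (-3, 8), log10(tau) in (-12, 1), log10(sigma_s) in
#' (-4, 0) and log10(eps_inf) in \[0, 8\].
#'
#' @param population_size Individuals per generation.
#' @param tournament_size Tournament draw size for parent selection
#'   (lowest cost wins, ties to the earliest index).
#' @param mutation_prob Per-gene mutation probability; a mutated gene is
#'   redrawn uniformly within its bounds half of the time (global
#'   exploration) and perturbed by a Gaussian creep of `creep_sd` log10
#'   units otherwise (local refinement).
#' @param creep_sd Standard deviation, in log10 units, of the creep
#'   mutation.
#' @param crossover_prob Probability that an offspring is produced by
#'   uniform per-gene crossover of two parents (otherwise it clones the
#'   first parent).
#' @param max_generations Generation budget.
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation (>= 1 guarantees a non-increasing best-cost history).
#' @param stagnation_window Stop early after this many generations without
#'   an improvement larger than `stagnation_tol`.
#' @param stagnation_tol Improvement threshold for the stagnation stop.
#' @param bounds Optional `(2 + 2 n_poles) x 2` matrix of log10 bounds
#'   overriding the defaults.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 1000, tournament_size = 20,
                      mutation_prob = 0.10, crossover_prob = 0.9,
                      max_generations = 2000, elitism = 1,
                      stagnation_window = 200, stagnation_tol = 1e-12,
                      creep_sd = 0.05, bounds = NULL) {
  stopifnot(population_size >= 2, tournament_size >= 1,
            tournament_size <= population_size,
            mutation_prob >= 0, mutation_prob <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            max_generations >= 1, elitism >= 0, elitism < population_size)
  structure(list(population_size = as.integer(population_size),
                 tournament_size = as.integer(tournament_size),
                 mutation_prob = mutation_prob,
                 crossover_prob = crossover_prob,
                 max_generations = as.integer(max_generations),
                 elitism = as.integer(elitism),
                 stagnation_window = as.integer(stagnation_window),
                 stagnation_tol = stagnation_tol,
                 creep_sd = creep_sd,
                 bounds = bounds),
            class = "ga_config")
}

# Cost of every row of a log10-genome population matrix against precomputed
# log10 |real| / |imag| data vectors. Vectorised over the population.
.cost_population <- function(P, w, logEr, logEi) {
  n <- nrow(P)
  np <- (ncol(P) - 2L) / 2L
  sig <- 10^P[, 1L]
  einf <- 10^P[, 2L]
  # D = eps_inf + sum_k de_k/(1 + jw tau_k) + sig/(jw eps0), rows = individuals
  Dre <- matrix(einf, n, length(w))
  Dim <- -outer(sig, 1 / (w * .eps0))
  for (k in seq_len(np)) {
    de <- 10^P[, 2L * k + 1L]
    ta <- 10^P[, 2L * k + 2L]
    wt <- outer(ta, w)            # tau_k * w
    den <- 1 + wt^2
    Dre <- Dre + de / den
    Dim <- Dim - (de * wt) / den  # de recycled down columns
  }
  rowSums((log10(Dre) - rep(logEr, each = n))^2 +
          (log10(-Dim) - rep(logEi, each = n))^2)
}

#' Log-space fitting cost of a Debye model against a measured spectrum
#'
#' The dimensionless cost summed over every measured frequency,
#' \deqn{C_f = \sum_f (\log_{10} E_r - \log_{10} D_r)^2 +
#'   (\log_{10}|E_i| - \log_{10}|D_i|)^2,}
#' where E is the measured complex relative permittivity and D the model's.
#' Imaginary parts are negative for passive materials, so their magnitudes
#' are compared.
#'
#' @param model A [debye_model()].
#' @param freqs Frequencies of the measured spectrum, Hz.
#' @param eps Complex measured relative permittivity at `freqs` (e.g. from
#'   [dielectric_to_complex_eps()]).
#' @return Non-negative scalar cost.
#' @export
debye_cost <- function(model, freqs, eps) {
  stopifnot(length(freqs) == length(eps))
  if (any(Re(eps) <= 0))
    stop("measured spectrum has non-positive real permittivity; cannot take log10")
  D <- complex_permittivity(model, freqs)
  sum((log10(Re(D)) - log10(Re(eps)))^2 +
      (log10(abs(Im(D))) - log10(abs(Im(eps))))^2)
}

.as_fit_data <- function(data, geometry) {
  if (inherits(data, "admittance_spectrum")) {
    d <- admittance_to_dielectric(data, geometry = if (is.null(geometry))
      data$geometry else geometry)
  } else if (inherits(data, "dielectric_spectrum")) {
    d <- data
  } else {
    stop("`data` must be an admittance_spectrum or dielectric_spectrum")
  }
  list(freqs = d$freqs, eps = dielectric_to_complex_eps(d))
}

.genome_to_model <- function(g) {
  np <- (length(g) - 2L) / 2L
  v <- 10^g
  if (np == 0L) return(debye_model(v[1L], max(1, v[2L])))
  debye_model(v[1L], max(1, v[2L]),
              delta_eps = v[2L * seq_len(np) + 1L],
              tau = v[2L * seq_len(np) + 2L])
}

.model_to_genome <- function(model, np) {
  stopifnot(n_poles(model) == np)
  g <- c(log10(model$sigma_s), log10(model$eps_inf))
  for (k in seq_len(np))
    g <- c(g, log10(model$delta_eps[k]), log10(model$tau[k]))
  g
}

#' Fit a multipole Debye model to a spectrum with a genetic algorithm
#'
#' Minimises [debye_cost()] over the log10-encoded parameter vector
#' (sigma_s, eps_inf, and N (delta_eps, tau) pairs) with a tournament
#' genetic algorithm: uniform per-gene crossover, per-gene uniform-redraw
#' mutation, elitism, and a stagnation stop.  Given the same `seed`, data
#' and configuration the result is bit-identical.
#'
#' @param data An [admittance_spectrum()] (with a geometry) or a
#'   [dielectric_spectrum()].  Replicates are averaged before fitting.
#' @param n_poles Number N of Debye poles to fit.
#' @param geometry Optional [sample_geometry()] overriding the spectrum's.
#' @param control A [ga_config()].
#' @param seed Integer RNG seed; recorded in the result.
#' @param init_models Optional list of [debye_model()]s injected into the
#'   initial population (e.g. to warm-start from a previous fit).
#' @return An object of class `debye_fit` with components `model` (the best
#'   [debye_model()]), `cf` (its cost), `history` (best cost per
#'   generation), `evaluations`, `generations`, `seed`, `freqs`, `eps`
#'   (the fitted data) and `control`.
#' @seealso [multi_pole_fit()] to scan several pole counts.
#' @export
#' @examples
#' truth <- debye_model(0.02, 100, 1e4, 1e-5)
#' geom <- cylinder_geometry(9.25e-3, 5e-3)
#' spec <- synth_spectrum(truth, geom, noise_cv = 0, n_replicates = 1)
#' fit <- debye_fit(spec, n_poles = 1, seed = 1,
#'                  control = ga_config(population_size = 60,
#'                                      max_generations = 40))
#' coef(fit)
debye_fit <- function(data, n_poles, geometry = NULL, control = ga_config(),
                      seed = NULL, init_models = NULL) {
  stopifnot(inherits(control, "ga_config"), n_poles >= 0)
  fd <- .as_fit_data(data, geometry)
  if (length(fd$freqs) == 0L) stop("empty spectrum")
  if (length(fd$freqs) < 2 * (n_poles + 1))
    stop("need at least 2(N+1) frequency points to fit ", n_poles, " poles")
  if (any(Re(fd$eps) <= 0))
    stop("spectrum has non-positive real permittivity")
  bounds <- if (is.null(control$bounds)) .default_bounds(n_poles) else control$bounds
  ng <- 2L + 2L * as.integer(n_poles)
  if (nrow(bounds) != ng) stop("bounds must have one row per genome entry")
  if (any(bounds[, 2] <= bounds[, 1])) stop("infeasible bounds")
  if (!is.null(seed)) set.seed(seed)

  npop <- control$population_size
  lo <- bounds[, 1]; span <- bounds[, 2] - bounds[, 1]
  P <- matrix(stats::runif(npop * ng), npop, ng)
  P <- sweep(sweep(P, 2, span, "*"), 2, lo, "+")
  if (!is.null(init_models)) {
    for (i in seq_along(init_models)) {
      g <- .model_to_genome(init_models[[i]], n_poles)
      P[i, ] <- pmin(pmax(g, bounds[, 1]), bounds[, 2])
    }
  }

  w <- 2 * pi * fd$freqs
  logEr <- log10(Re(fd$eps))
  logEi <- log10(abs(Im(fd$eps)))
  cf <- .cost_population(P, w, logEr, logEi)
  evals <- npop
  history <- numeric(0)
  best_cf <- Inf; last_improve <- 0L
  gen <- 0L

  while (gen < control$max_generations) {
    gen <- gen + 1L
    ord <- order(cf)
    n_off <- npop - control$elitism
    # tournament selection, vectorised: earliest index wins ties
    pick <- function() {
      idx <- matrix(sample.int(npop, n_off * control$tournament_size,
                               replace = TRUE), n_off)
      sel <- max.col(-matrix(cf[idx], n_off), ties.method = "first")
      idx[cbind(seq_len(n_off), sel)]
    }
    p1 <- P[pick(), , drop = FALSE]
    p2 <- P[pick(), , drop = FALSE]
    cross <- stats::runif(n_off) < control$crossover_prob
    take2 <- matrix(stats::runif(n_off * ng) < 0.5, n_off) & cross
    off <- ifelse(take2, p2, p1)
    # mutation: half the hits redraw uniformly inside the bounds (global
    # exploration), half apply a small log-space creep (local refinement)
    mut <- matrix(stats::runif(n_off * ng) < control$mutation_prob, n_off)
    if (any(mut)) {
      draw <- sweep(sweep(matrix(stats::runif(n_off * ng), n_off),
                          2, span, "*"), 2, lo, "+")
      creep <- off + matrix(stats::rnorm(n_off * ng, 0, control$creep_sd), n_off)
      use_draw <- matrix(stats::runif(n_off * ng) < 0.5, n_off)
      off[mut & use_draw] <- draw[mut & use_draw]
      off[mut & !use_draw] <- creep[mut & !use_draw]
      off <- pmin(pmax(off, rep(lo, each = n_off)),
                  rep(bounds[, 2], each = n_off))
    }
    newP <- rbind(P[ord[seq_len(control$elitism)], , drop = FALSE], off)
    newcf <- c(cf[ord[seq_len(control$elitism)]],
               .cost_population(off, w, logEr, logEi))
    evals <- evals + n_off
    P <- newP; cf <- newcf
    gen_best <- min(cf)
    history <- c(history, gen_best)
    if (gen_best < best_cf - control$stagnation_tol) {
      best_cf <- gen_best; last_improve <- gen
    } else if (gen_best < best_cf) {
      best_cf <- gen_best
    }
    if (gen - last_improve >= control$stagnation_window) break
  }

  ibest <- which.min(cf)
  model <- .genome_to_model(P[ibest, ])
  structure(list(model = model,
                 cf = debye_cost(model, fd$freqs, fd$eps),
                 history = history, evaluations = evals, generations = gen,
                 seed = seed, freqs = fd$freqs, eps = fd$eps,
                 n_poles = as.integer(n_poles), control = control),
            class = "debye_fit")
}

#' Fit a range of pole counts
#'
#' Runs [debye_fit()] for each requested number of poles and tabulates the
#' final costs, supporting the usual model-selection argument: pick the
#' smallest N whose cost has plateaued.
#'
#' @inheritParams debye_fit
#' @param n_poles_list Integer vector of pole counts to try; may be empty.
#' @return A list of class `debye_fit_scan`: `fits` (named list of
#'   [debye_fit()] results) and `summary` (data frame with columns
#'   `n_poles`, `cf`, `generations`, `evaluations`).
#' @export
multi_pole_fit <- function(data, n_poles_list, geometry = NULL,
                           control = ga_config(), seed = NULL) {
  fits <- list()
  for (i in seq_along(n_poles_list)) {
    fits[[paste0("n", n_poles_list[i])]] <-
      debye_fit(data, n_poles_list[i], geometry = geometry, control = control,
                seed = if (is.null(seed)) NULL else seed + i - 1L)
  }
  summary <- data.frame(
    n_poles = as.integer(n_poles_list),
    cf = vapply(fits, `[[`, numeric(1), "cf"),
    generations = vapply(fits, `[[`, numeric(1), "generations"),
    evaluations = vapply(fits, `[[`, numeric(1), "evaluations"),
    row.names = NULL)
  structure(list(fits = fits, summary = summary), class = "debye_fit_scan")
}

#' @export
print.debye_fit_scan <- function(x, ...) {
  cat("Debye pole-count scan\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
print.debye_fit <- function(x, ...) {
  cat(sprintf("Genetic-algorithm Debye fit: %d pole(s), cost %.6g after %d generations\n",
              x$n_poles, x$cf, x$generations))
  print(x$model)
  invisible(x)
}

#' @export
summary.debye_fit <- function(object, ...) {
  cat(sprintf("Multipole Debye fit (%d poles) over %d frequencies, %.4g Hz - %.4g Hz\n",
              object$n_poles, length(object$freqs),
              min(object$freqs), max(object$freqs)))
  cat(sprintf("  final cost          %.6g\n", object$cf))
  cat(sprintf("  generations         %d (%d model evaluations)\n",
              object$generations, object$evaluations))
  if (!is.null(object$seed)) cat(sprintf("  seed                %d\n", object$seed))
  r <- residuals(object)
  cat(sprintf("  log10 residual RMS  real %.3g, imag %.3g\n",
              sqrt(mean(r$real^2)), sqrt(mean(r$imag^2))))
  cat("\nFitted model:\n")
  print(object$model)
  invisible(object)
}

#' @export
coef.debye_fit <- function(object, ...) {
  m <- object$model
  v <- c(sigma_s = m$sigma_s, eps_inf = m$eps_inf)
  if (n_poles(m)) {
    de <- m$delta_eps; ta <- m$tau
    names(de) <- paste0("delta_eps", seq_along(de))
    names(ta) <- paste0("tau", seq_along(ta))
    v <- c(v, de, ta)
  }
  v
}

#' Predict from a fitted Debye model
#'
#' @param object A [debye_fit()].
#' @param freq Frequencies in Hz; defaults to the fitted grid.
#' @param type `"permittivity"` (complex relative permittivity),
#'   `"properties"` (data frame of sigma and eps_r), or `"admittance"`
#'   (complex Y; requires `geometry`).
#' @param geometry [sample_geometry()] for `type = "admittance"`.
#' @param ... Unused.
#' @export
predict.debye_fit <- function(object, freq = object$freqs,
                              type = c("permittivity", "properties", "admittance"),
                              geometry = NULL, ...) {
  type <- match.arg(type)
  switch(type,
    permittivity = complex_permittivity(object$model, freq),
    properties = {
      p <- effective_properties(object$model, freq)
      data.frame(freq = freq, sigma = p$sigma, eps_r = p$eps_r)
    },
    admittance = {
      if (is.null(geometry)) stop("geometry required for admittance prediction")
      terminal_admittance(object$model, geometry, freq)
    })
}

#' @export
residuals.debye_fit <- function(object, ...) {
  D <- complex_permittivity(object$model, object$freqs)
  data.frame(freq = object$freqs,
             real = log10(Re(D)) - log10(Re(object$eps)),
             imag = log10(abs(Im(D))) - log10(abs(Im(object$eps))))
}

#' Plot a Debye fit against its data
#'
#' Two log-log panels: conductivity and relative permittivity versus
#' frequency, measured points with the fitted curve.
#'
#' @param x A [debye_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.debye_fit <- function(x, ...) {
  w <- 2 * pi * x$freqs
  sig_d <- -w * .eps0 * Im(x$eps); er_d <- Re(x$eps)
  p <- effective_properties(x$model, x$freqs)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$freqs, sig_d, log = "xy", xlab = "frequency (Hz)",
                 ylab = "conductivity (S/m)", ...)
  graphics::lines(x$freqs, p$sigma, col = 2)
  graphics::plot(x$freqs, er_d, log = "xy", xlab = "frequency (Hz)",
                 ylab = "relative permittivity", ...)
  graphics::lines(x$freqs, p$eps_r, col = 2)
  invisible(x)
}

#' Simulate the time-domain terminal current of a fitted model
#'
#' Convenience method: runs [simulate_lumped()] with the fitted model.
#'
#' @param object A [debye_fit()].
#' @param nsim Unused (one trace).
#' @param seed Unused; the simulation is deterministic.
#' @param geometry [sample_geometry()] of the sample.
#' @param source A [source_sine()] or [source_pulse_burst()].
#' @param t_end Simulation end time, s.
#' @param ... Passed to [simulate_lumped()].
#' @export
simulate.debye_fit <- function(object, nsim = 1, seed = NULL, geometry,
                               source, t_end, ...) {
  simulate_lumped(object$model, geometry, source, t_end, ...)
}
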