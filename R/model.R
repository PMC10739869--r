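#' Multipole Debye dispersion model
#'
#' A first-order multipole Debye description of a tissue's complex relative
#' permittivity,
#' \deqn{\varepsilon^*_r(\omega) = \frac{\sigma_s}{j\omega\varepsilon_0}
#'   + \varepsilon_\infty
#'   + \sum_{k=1}^{N} \frac{\Delta\varepsilon_k}{1 + j\omega\tau_k},}
#' with static conductivity \eqn{\sigma_s} (S/m), high-frequency relative
#' permittivity \eqn{\varepsilon_\infty}, and N relaxation poles each with a
#' permittivity increment \eqn{\Delta\varepsilon_k} and relaxation time
#' \eqn{\tau_k} (s).  Poles are stored sorted by decreasing relaxation time;
#' pole labelling carries no physical meaning, so this canonical order makes
#' models comparable.
#'
#' @param sigma_s Static conductivity, S/m (> 0).
#' @param eps_inf High-frequency relative permittivity (>= 1).
#' @param delta_eps Numeric vector of pole permittivity increments (> 0);
#'   may be empty for a non-dispersive medium.
#' @param tau Numeric vector of pole relaxation times in seconds (> 0),
#'   same length as `delta_eps`.
#' @return An object of class `debye_model`.
#' @seealso [cole_cole_model()], [complex_permittivity()],
#'   [effective_properties()], [terminal_admittance()]
#' @export
#' @examples
#' m <- debye_model(sigma_s = 0.02, eps_inf = 100,
#'                  delta_eps = c(1e6, 1e4), tau = c(1e-3, 1e-6))
#' complex_permittivity(m, 1e3)
debye_model <- function(sigma_s, eps_inf, delta_eps = numeric(), tau = numeric()) {
  stopifnot(length(sigma_s) == 1L, length(eps_inf) == 1L,
            length(delta_eps) == length(tau))
  if (!is.finite(sigma_s) || sigma_s <= 0)
    stop("sigma_s must be a positive finite number (S/m)")
  if (!is.finite(eps_inf) || eps_inf < 1)
    stop("eps_inf must be >= 1")
  if (length(delta_eps) && (any(delta_eps <= 0) || any(tau <= 0)))
    stop("all delta_eps and tau must be positive")
  ord <- order(tau, decreasing = TRUE)
  structure(list(sigma_s = sigma_s, eps_inf = eps_inf,
                 delta_eps = as.numeric(delta_eps[ord]),
                 tau = as.numeric(tau[ord])),
            class = "debye_model")
}

#' Cole-Cole dispersion model
#'
#' Generalises [debye_model()] by a per-pole broadening exponent
#' \eqn{\lambda_k \in [0, 1)}: each pole term becomes
#' \eqn{\Delta\varepsilon_k / (1 + (j\omega\tau_k)^{1-\lambda_k})}.
#' With all \eqn{\lambda_k = 0} evaluation reduces exactly to the Debye
#' model.  Only evaluation is supported; fitting is restricted to the Debye
#' form, whose poles map to ordinary differential equations in time.
#'
#' @inheritParams debye_model
#' @param lambda Broadening exponents, one per pole, each in `[0, 1)`.
#' @return An object of class `c("cole_cole_model", "debye_model")`.
#' @export
cole_cole_model <- function(sigma_s, eps_inf, delta_eps = numeric(),
                            tau = numeric(), lambda = numeric()) {
  stopifnot(length(lambda) == length(delta_eps))
  if (length(lambda) && (any(lambda < 0) || any(lambda >= 1)))
    stop("all lambda must lie in [0, 1)")
  m <- debye_model(sigma_s, eps_inf, delta_eps, tau)
  ord <- order(tau, decreasing = TRUE)
  m$lambda <- as.numeric(lambda[ord])
  class(m) <- c("cole_cole_model", "debye_model")
  m
}

n_poles <- function(model) length(model$tau)

#' Complex relative permittivity of a dispersion model
#'
#' Evaluates \eqn{\varepsilon^*_r(\omega)} of a Debye or Cole-Cole model at
#' the given frequencies, \eqn{\omega = 2\pi f}.
#'
#' @param model A [debye_model()] or [cole_cole_model()].
#' @param freq Frequencies in Hz (all > 0); vectorised.
#' @return Complex vector, same length as `freq`.
#' @export
#' @examples
#' m <- debye_model(0.02, 100, 1e4, 1e-5)
#' complex_permittivity(m, c(1e2, 1e4, 1e6))
complex_permittivity <- function(model, freq) {
  stopifnot(inherits(model, "debye_model"), is.numeric(freq))
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("all frequencies must be positive and finite (Hz)")
  w <- 2 * pi * freq
  eps <- model$sigma_s / (1i * w * .eps0) + model$eps_inf
  lam <- if (is.null(model$lambda)) rep(0, n_poles(model)) else model$lambda
  for (k in seq_len(n_poles(model))) {
    eps <- eps + model$delta_eps[k] / (1 + (1i * w * model$tau[k])^(1 - lam[k]))
  }
  eps
}

#' Effective conductivity and permittivity spectrum
#'
#' The real material properties seen at each frequency:
#' \eqn{\varepsilon_r(\omega) = \Re\,\varepsilon^*_r} and
#' \eqn{\sigma(\omega) = -\omega\varepsilon_0 \Im\,\varepsilon^*_r}.
#' For a Debye model \eqn{\sigma(f)} is non-decreasing and
#' \eqn{\varepsilon_r(f)} non-increasing in frequency.
#'
#' @inheritParams complex_permittivity
#' @return A list with numeric vectors `sigma` (S/m) and `eps_r`.
#' @export
effective_properties <- function(model, freq) {
  eps <- complex_permittivity(model, freq)
  list(sigma = -2 * pi * freq * .eps0 * Im(eps), eps_r = Re(eps))
}

#' Terminal admittance of a sample
#'
#' Complex admittance Y seen at the electrodes of a homogeneous sample with
#' the given geometry: \eqn{Y = (S/l)(\sigma(\omega) +
#' j\omega\varepsilon_0\varepsilon_r(\omega))}.  For an applied voltage V the
#' complex terminal current is \eqn{I = V Y}.
#'
#' @inheritParams complex_permittivity
#' @param geometry A [sample_geometry()].
#' @return Complex admittance in siemens, same length as `freq`.
#' @export
#' @examples
#' m <- debye_model(0.02, 100)
#' g <- cylinder_geometry(9.25e-3, 5e-3)
#' terminal_admittance(m, g, 1e3)
terminal_admittance <- function(model, geometry, freq) {
  stopifnot(inherits(geometry, "sample_geometry"))
  p <- effective_properties(model, freq)
  (geometry$area / geometry$length) *
    (p$sigma + 1i * 2 * pi * freq * .eps0 * p$eps_r)
}

#' @export
print.debye_model <- function(x, ...) {
  cc <- inherits(x, "cole_cole_model")
  cat(sprintf("%s dispersion model, %d pole(s)\n",
              if (cc) "Cole-Cole" else "Multipole Debye", n_poles(x)))
  cat(sprintf("  sigma_s = %.4g S/m, eps_inf = %.4g\n", x$sigma_s, x$eps_inf))
  if (n_poles(x)) {
    for (k in seq_len(n_poles(x))) {
      cat(sprintf("  pole %d: delta_eps = %.4g, tau = %.4g s%s\n",
                  k, x$delta_eps[k], x$tau[k],
                  if (cc) sprintf(", lambda = %.3g", x$lambda[k]) else ""))
    }
  }
  invisible(x)
}

#' Read or write a dispersion model as JSON
#'
#' Layout: `{"sigma_s": ..., "eps_inf": ..., "poles": [{"delta_eps": ...,
#' "tau": ..., "lambda": ...}, ...]}`; `lambda` is optional and zero means a
#' pure Debye pole.
#'
#' @param path File path.
#' @return `read_debye_model()` returns a [debye_model()] (or
#'   [cole_cole_model()] if any pole carries a nonzero `lambda`).
#' @export
read_debye_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- vapply(j$poles, function(p) p$delta_eps, numeric(1))
  ta <- vapply(j$poles, function(p) p$tau, numeric(1))
  lam <- vapply(j$poles, function(p) if (is.null(p$lambda)) 0 else p$lambda,
                numeric(1))
  if (any(lam != 0))
    cole_cole_model(j$sigma_s, j$eps_inf, de, ta, lam)
  else
    debye_model(j$sigma_s, j$eps_inf, de, ta)
}

#' @rdname read_debye_model
#' @param model The model to serialise.
#' @export
write_debye_model <- function(model, path) {
  lam <- if (is.null(model$lambda)) rep(0, n_poles(model)) else model$lambda
  poles <- lapply(seq_len(n_poles(model)), function(k) {
    p <- list(delta_eps = model$delta_eps[k], tau = model$tau[k])
    if (lam[k] != 0) p$lambda <- lam[k]
    p
  })
  jsonlite::write_json(list(sigma_s = model$sigma_s, eps_inf = model$eps_inf,
                            poles = poles),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
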