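# Shared fixtures and independent brute-force oracles.  The oracles
# deliberately re-derive every quantity term by term, without calling the
# package's evaluation path.

eps0_ref <- 8.8541878128e-12

# 4-pole reference tissue model, written out longhand
ref_n4 <- function() {
  debye_model(sigma_s = 2.159e-2, eps_inf = 1.747e2,
              delta_eps = c(2.251e6, 2.918e4, 1.836e4, 1.053e4),
              tau = c(3.783e-3, 2.309e-5, 1.005e-6, 1.658e-7))
}

ref_cyl <- function() cylinder_geometry(radius = 9.25e-3, height = 5e-3)

# term-by-term complex permittivity, independent of complex_permittivity()
oracle_eps <- function(sigma_s, eps_inf, delta_eps, tau, f, lambda = NULL) {
  w <- 2 * pi * f
  acc <- complex(real = eps_inf, imaginary = -sigma_s / (w * eps0_ref))
  for (k in seq_along(delta_eps)) {
    lam <- if (is.null(lambda)) 0 else lambda[k]
    acc <- acc + delta_eps[k] / (1 + (1i * w * tau[k])^(1 - lam))
  }
  acc
}

# naive double-loop log-space cost
oracle_cost <- function(model, freqs, eps) {
  total <- 0
  for (i in seq_along(freqs)) {
    D <- oracle_eps(model$sigma_s, model$eps_inf, model$delta_eps,
                    model$tau, freqs[i])
    total <- total +
      (log10(Re(D)) - log10(Re(eps[i])))^2 +
      (log10(abs(Im(D))) - log10(abs(Im(eps[i]))))^2
  }
  total
}

# random valid Debye model for property tests
random_model <- function(n_poles = sample(0:4, 1)) {
  debye_model(sigma_s = 10^stats::runif(1, -3, -1),
              eps_inf = 10^stats::runif(1, 0.5, 3),
              delta_eps = 10^stats::runif(n_poles, 1, 6),
              tau = 10^stats::runif(n_poles, -8, -2))
}
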