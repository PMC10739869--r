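# Minimal axisymmetric P1 finite-element solver for quasi-static electric
# currents in a dispersive cylinder: structured triangulation of the (r, z)
# rectangle, one-point (centroid) quadrature with the 2*pi*r axisymmetric
# weight (exact for P1, since integrands are linear in r), Dirichlet
# terminal/ground plates and natural (zero-flux) axis/outer boundaries.

#' Build a structured axisymmetric mesh of a cylinder
#'
#' Triangulates the meridian rectangle `[0, radius] x [0, height]` into
#' `2 * nr * nz` linear triangles.  Boundary nodes are tagged `axis`
#' (r = 0), `terminal` (z = height), `ground` (z = 0) and `outer`
#' (r = radius, electrically insulated).
#'
#' @param radius Cylinder radius, m.
#' @param height Cylinder height (electrode gap), m.
#' @param nr,nz Number of cell divisions along r and z (>= 1).
#' @return An object of class `axisym_mesh`: `nodes` (n x 2 matrix of r, z),
#'   `elements` (ne x 3 node indices, counterclockwise), `boundary` (list of
#'   node-index vectors per tag) and `edges` (boundary edge table with tags).
#' @export
#' @examples
#' m <- build_mesh(9.25e-3, 5e-3, nr = 16, nz = 16)
#' nrow(m$elements)  # 512
build_mesh <- function(radius, height, nr = 16, nz = 16) {
  stopifnot(radius > 0, height > 0, nr >= 1, nz >= 1)
  r <- seq(0, radius, length.out = nr + 1)
  z <- seq(0, height, length.out = nz + 1)
  nodes <- cbind(r = rep(r, nz + 1), z = rep(z, each = nr + 1))
  nid <- function(i, j) i + (nr + 1) * j + 1L  # i in 0..nr, j in 0..nz
  ii <- rep(0:(nr - 1), nz)
  jj <- rep(0:(nz - 1), each = nr)
  n00 <- nid(ii, jj); n10 <- nid(ii + 1, jj)
  n01 <- nid(ii, jj + 1); n11 <- nid(ii + 1, jj + 1)
  elements <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  colnames(elements) <- NULL
  boundary <- list(
    axis = nid(0, 0:nz),
    outer = nid(nr, 0:nz),
    ground = nid(0:nr, 0),
    terminal = nid(0:nr, nz))
  edges <- rbind(
    data.frame(n1 = nid(0:(nr - 1), 0), n2 = nid(1:nr, 0), tag = "ground"),
    data.frame(n1 = nid(0:(nr - 1), nz), n2 = nid(1:nr, nz), tag = "terminal"),
    data.frame(n1 = nid(0, 0:(nz - 1)), n2 = nid(0, 1:nz), tag = "axis"),
    data.frame(n1 = nid(nr, 0:(nz - 1)), n2 = nid(nr, 1:nz), tag = "outer"))
  structure(list(nodes = nodes, elements = elements, boundary = boundary,
                 edges = edges, radius = radius, height = height,
                 nr = nr, nz = nz),
            class = "axisym_mesh")
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric mesh: %d nodes, %d triangles, %.4g mm x %.4g mm\n",
              nrow(x$nodes), nrow(x$elements), 1e3 * x$radius, 1e3 * x$height))
  invisible(x)
}

# Per-element geometry: signed area, centroid radius, P1 gradient
# components (ne x 3 each for d/dr and d/dz), axisymmetric weight 2*pi*rbar*A.
.fem_setup <- function(mesh) {
  el <- mesh$elements
  x <- matrix(mesh$nodes[el, 1], nrow(el)); y <- matrix(mesh$nodes[el, 2], nrow(el))
  area <- 0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
                 (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
  if (any(area <= 0)) stop("degenerate or inverted element in mesh")
  rbar <- rowMeans(x)
  gx <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * area)
  gz <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * area)
  list(area = area, rbar = rbar, gx = gx, gz = gz, w = 2 * pi * rbar * area)
}

#' Axisymmetric volume of a mesh
#'
#' Sum of element volumes under the `2 pi r` measure; equals
#' `pi * radius^2 * height` up to quadrature.
#'
#' @param mesh An [build_mesh()] result.
#' @return Volume in cubic metres.
#' @export
mesh_volume <- function(mesh) sum(.fem_setup(mesh)$w)

# Stiffness matrix for per-element scalar conductivity sig_e (real vector).
.assemble_K <- function(mesh, fs, sig_e) {
  ne <- nrow(mesh$elements); nn <- nrow(mesh$nodes)
  ii <- jj <- vv <- vector("list", 9L)
  m <- 0L
  for (a in 1:3) for (b in 1:3) {
    m <- m + 1L
    ii[[m]] <- mesh$elements[, a]
    jj[[m]] <- mesh$elements[, b]
    vv[[m]] <- sig_e * fs$w * (fs$gx[, a] * fs$gx[, b] + fs$gz[, a] * fs$gz[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(nn, nn))
}

# Scatter per-element RHS density b = (bx, bz) into nodal loads
# F_i = sum_e w_e (b . grad phi_i).
.assemble_F <- function(mesh, fs, bx, bz) {
  nn <- nrow(mesh$nodes)
  val <- cbind(fs$w * (bx * fs$gx[, 1] + bz * fs$gz[, 1]),
               fs$w * (bx * fs$gx[, 2] + bz * fs$gz[, 2]),
               fs$w * (bx * fs$gx[, 3] + bz * fs$gz[, 3]))
  as.numeric(Matrix::sparseMatrix(i = as.vector(mesh$elements),
                                  j = rep(1L, length(mesh$elements)),
                                  x = as.vector(val), dims = c(nn, 1L)))
}

.dirichlet_sets <- function(mesh) {
  term <- mesh$boundary$terminal
  gnd <- setdiff(mesh$boundary$ground, term)
  fixed <- c(term, gnd)
  list(term = term, gnd = gnd, fixed = fixed,
       free = setdiff(seq_len(nrow(mesh$nodes)), fixed))
}

#' Frequency-domain axisymmetric solve of the terminal current
#'
#' Solves the complex quasi-static potential equation
#' \eqn{\nabla\cdot(\sigma^*(\omega)\nabla V) = 0} with
#' \eqn{\sigma^*(\omega) = j\omega\varepsilon_0\varepsilon^*_r(\omega)} on
#' the axisymmetric mesh, with `v_terminal` applied on the terminal plate,
#' 0 on the ground plate, and natural zero-flux conditions on the axis and
#' the outer (insulated) wall.  The terminal current is recovered from the
#' weak-form reaction forces at the terminal nodes, which is conservative:
#' the terminal and ground currents balance to solver precision.
#'
#' @param mesh An [build_mesh()] result.
#' @param model A [debye_model()] for a homogeneous sample, or `NULL` when
#'   `conductivity` is given.
#' @param freq Frequency, Hz (> 0).
#' @param v_terminal Applied terminal voltage, V.
#' @param conductivity Optional per-element complex conductivity (S/m)
#'   overriding `model`, for layered or otherwise inhomogeneous media.
#' @return An object of class `fem_freq_result`: `terminal_current` and
#'   `ground_current` (complex A, signed into the sample), `potential`
#'   (complex nodal vector), `freq`.
#' @export
solve_frequency <- function(mesh, model = NULL, freq, v_terminal = 50,
                            conductivity = NULL) {
  stopifnot(inherits(mesh, "axisym_mesh"), freq > 0)
  fs <- .fem_setup(mesh)
  ne <- nrow(mesh$elements)
  sig <- if (!is.null(conductivity)) {
    rep_len(as.complex(conductivity), ne)
  } else {
    stopifnot(inherits(model, "debye_model"))
    rep(1i * 2 * pi * freq * .eps0 * complex_permittivity(model, freq), ne)
  }
  Kr <- .assemble_K(mesh, fs, Re(sig))
  Ki <- .assemble_K(mesh, fs, Im(sig))
  d <- .dirichlet_sets(mesh)
  Vc <- numeric(nrow(mesh$nodes))
  Vc[d$term] <- v_terminal
  rhs_r <- -(Kr[d$free, d$fixed, drop = FALSE] %*% Vc[d$fixed])
  rhs_i <- -(Ki[d$free, d$fixed, drop = FALSE] %*% Vc[d$fixed])
  A <- rbind(cbind(Kr[d$free, d$free], -Ki[d$free, d$free]),
             cbind(Ki[d$free, d$free], Kr[d$free, d$free]))
  sol <- Matrix::solve(A, rbind(rhs_r, rhs_i))
  nf <- length(d$free)
  V <- complex(real = Vc, imaginary = numeric(length(Vc)))
  V[d$free] <- complex(real = sol[seq_len(nf), 1], imaginary = sol[nf + seq_len(nf), 1])
  react <- complex(real = as.vector(Kr %*% Re(V) - Ki %*% Im(V)),
                   imaginary = as.vector(Kr %*% Im(V) + Ki %*% Re(V)))
  structure(list(terminal_current = sum(react[d$term]),
                 ground_current = sum(react[d$gnd]),
                 potential = V, freq = freq, v_terminal = v_terminal),
            class = "fem_freq_result")
}

#' @export
print.fem_freq_result <- function(x, ...) {
  I <- x$terminal_current
  cat(sprintf("FEM frequency-domain solve at %.4g Hz: |I| = %.5g A, phase = %.4g deg\n",
              x$freq, Mod(I), Arg(I) * 180 / pi))
  invisible(x)
}

#' Time-domain axisymmetric solve with per-element auxiliary fields
#'
#' Advances the coupled potential / auxiliary-field system of the multipole
#' Debye dispersion on the mesh.  Each element carries one auxiliary field
#' per pole with (r, z) components obeying
#' \eqn{\tau_k \partial \vec e_k/\partial t = \vec E - \vec e_k}; over each
#' step the pole update is the exact exponential solution for the field
#' held at its mid-step value, and the potential is advanced with a
#' trapezoidal (Crank-Nicolson) update of the total current density
#' \eqn{\vec J = \sigma_s\vec E + \varepsilon_0\varepsilon_\infty
#' \partial\vec E/\partial t + \sum_k
#' (\varepsilon_0\Delta\varepsilon_k/\tau_k)(\vec E - \vec e_k)}.
#' The scheme is unconditionally stable and second-order accurate; current
#' samples are reported at the step midpoints where the discrete divergence
#' is enforced.  Step sizes honour the source's policy (period/100 for
#' sine, 0.1 us in pulse transitions / 1 us elsewhere).
#'
#' @inheritParams solve_frequency
#' @param source A `source_signal` (see [source_sine()]).
#' @param t_end Simulation end time, s.
#' @param max_step Optional cap overriding the source's step policy, s.
#' @param conductivity Optional per-element real conductivity (S/m):
#'   simulates a non-dispersive (purely resistive) medium instead of
#'   `model`.
#' @return A `time_sim` object (`t`, `I`, `V`, solver metadata).
#' @export
solve_time <- function(mesh, model = NULL, source, t_end, max_step = NULL,
                       conductivity = NULL) {
  stopifnot(inherits(mesh, "axisym_mesh"), inherits(source, "source_signal"),
            t_end > 0)
  fs <- .fem_setup(mesh)
  d <- .dirichlet_sets(mesh)
  ne <- nrow(mesh$elements); nn <- nrow(mesh$nodes)
  seg <- source$segments(t_end)
  if (!is.null(max_step)) seg$max_step <- pmin(seg$max_step, max_step)

  if (!is.null(conductivity)) {
    # resistive medium: no storage, the potential is algebraic in V(t)
    sig_e <- rep_len(conductivity, ne)
    K <- .assemble_K(mesh, fs, sig_e)
    Kff <- Matrix::forceSymmetric(K[d$free, d$free])
    fac <- Matrix::Cholesky(Kff)
    tout <- unique(unlist(lapply(seq_len(nrow(seg)), function(i)
      seq(seg$start[i], seg$end[i], by = seg$max_step[i]))))
    tout <- sort(unique(c(tout, t_end)))
    # linear in the applied voltage: solve once at unit voltage
    Vc <- numeric(nn); Vc[d$term] <- 1
    rhs <- -(K[d$free, d$fixed, drop = FALSE] %*% Vc[d$fixed])
    Vc[d$free] <- as.vector(Matrix::solve(fac, rhs))
    I_unit <- sum(as.vector(K %*% Vc)[d$term])
    V <- source$value(tout)
    return(.time_sim_result(tout, I_unit * V, V,
                            list(method = "FEM static conductivity",
                                 max_step = max(seg$max_step),
                                 n_elements = ne)))
  }

  stopifnot(inherits(model, "debye_model"))
  if (inherits(model, "cole_cole_model") && any(model$lambda != 0))
    stop("time-domain FEM requires a pure Debye model")
  np <- n_poles(model)
  ex <- matrix(0, ne, np); ez <- matrix(0, ne, np)  # auxiliary fields
  Ex <- numeric(ne); Ez <- numeric(ne)              # field at step start
  Vn <- numeric(nn)                                  # potential at step start
  t_out <- I_out <- V_out <- list()
  n_steps <- 0L

  elem <- mesh$elements
  field_of <- function(V) {
    Vm <- matrix(V[elem], ne)
    list(x = -rowSums(fs$gx * Vm), z = -rowSums(fs$gz * Vm))
  }

  for (s in seq_len(nrow(seg))) {
    h <- seg$max_step[s]
    nst <- max(1L, ceiling((seg$end[s] - seg$start[s]) / h * (1 - 1e-9)))
    h <- (seg$end[s] - seg$start[s]) / nst
    mu <- exp(-h / model$tau)
    # step-averaged pole-current weight: (1/h) int J_ek dt = beta (Emid - e^n);
    # tends to eps0*de/tau for h << tau and to eps0*de/h (displacement-like)
    # for h >> tau, so stiff poles keep their quasi-steady contribution
    beta <- (.eps0 * model$delta_eps / h) * (1 - mu)
    sig_c <- model$sigma_s / 2 + .eps0 * model$eps_inf / h + sum(beta) / 2
    K <- .assemble_K(mesh, fs, rep(sig_c, ne))
    Kff <- Matrix::forceSymmetric(K[d$free, d$free])
    Kfc <- K[d$free, d$fixed, drop = FALSE]
    fac <- Matrix::Cholesky(Kff)
    tI <- II <- VV <- numeric(nst)
    for (n in seq_len(nst)) {
      t1 <- seg$start[s] + n * h
      cb <- model$sigma_s / 2 + sum(beta) / 2 - .eps0 * model$eps_inf / h
      bx <- cb * Ex - if (np) as.vector(ex %*% beta) else 0
      bz <- cb * Ez - if (np) as.vector(ez %*% beta) else 0
      Fv <- .assemble_F(mesh, fs, bx, bz)
      Vc <- numeric(nn); Vc[d$term] <- source$value(t1)
      rhs <- Fv[d$free] - as.vector(Kfc %*% Vc[d$fixed])
      Vc[d$free] <- as.vector(Matrix::solve(fac, rhs))
      react <- as.vector(K %*% Vc) - Fv
      Enew <- field_of(Vc)
      Emx <- (Ex + Enew$x) / 2; Emz <- (Ez + Enew$z) / 2
      if (np) {
        ex <- Emx + sweep(ex - Emx, 2, mu, "*")
        ez <- Emz + sweep(ez - Emz, 2, mu, "*")
      }
      Ex <- Enew$x; Ez <- Enew$z; Vn <- Vc
      tI[n] <- t1 - h / 2
      II[n] <- sum(react[d$term])
      VV[n] <- source$value(t1 - h / 2)
    }
    n_steps <- n_steps + nst
    t_out[[s]] <- tI; I_out[[s]] <- II; V_out[[s]] <- VV
  }
  .time_sim_result(do.call(c, t_out), do.call(c, I_out), do.call(c, V_out),
                   list(method = "FEM trapezoidal ADE", steps = n_steps,
                        max_step = max(seg$max_step), n_elements = ne,
                        n_states = 2L * np * ne))
}
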