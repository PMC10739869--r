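#' Admittance spectrum container
#'
#' Terminal admittance Y = G + jB of a sample over a frequency sweep, as
#' recorded by an impedance analyser.  `G` and `B` may be vectors (one
#' sample) or matrices with one column per replicate sample; frequencies are
#' kept strictly increasing.
#'
#' @param freqs Frequencies in Hz, strictly increasing after sorting.
#' @param G Conductance in S: vector or `length(freqs)` x n_replicates matrix,
#'   all entries > 0 (a passive sample always conducts).
#' @param B Susceptance in S, same shape as `G`.
#' @param geometry Optional [sample_geometry()] carried with the spectrum.
#' @return An object of class `admittance_spectrum`.
#' @export
admittance_spectrum <- function(freqs, G, B, geometry = NULL) {
  freqs <- as.numeric(freqs)
  G <- as.matrix(G); B <- as.matrix(B)
  if (nrow(G) != length(freqs) || nrow(B) != length(freqs) ||
      ncol(G) != ncol(B))
    stop("G and B must have one row per frequency and equal replicate counts")
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    stop("frequencies must be positive and finite")
  if (anyDuplicated(freqs))
    stop("duplicate frequencies in spectrum")
  ord <- order(freqs)
  freqs <- freqs[ord]; G <- G[ord, , drop = FALSE]; B <- B[ord, , drop = FALSE]
  if (any(G <= 0)) stop("conductance must be positive everywhere (passive sample)")
  if (!is.null(geometry)) stopifnot(inherits(geometry, "sample_geometry"))
  structure(list(freqs = freqs, G = G, B = B, geometry = geometry),
            class = "admittance_spectrum")
}

#' @export
print.admittance_spectrum <- function(x, ...) {
  cat(sprintf("Admittance spectrum: %d frequencies, %.4g Hz - %.4g Hz, %d replicate(s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$G)))
  if (!is.null(x$geometry)) print(x$geometry)
  invisible(x)
}

n_replicates <- function(spec) ncol(spec$G)

#' Average replicates of an admittance spectrum
#'
#' Per-frequency mean of G and B across replicate columns; fitting operates
#' on the averaged spectrum.
#'
#' @param spec An [admittance_spectrum()].
#' @return An [admittance_spectrum()] with a single replicate.
#' @export
average_replicates <- function(spec) {
  stopifnot(inherits(spec, "admittance_spectrum"))
  admittance_spectrum(spec$freqs, rowMeans(spec$G), rowMeans(spec$B),
                      geometry = spec$geometry)
}

#' Dielectric spectrum container
#'
#' Bulk material properties over frequency: real relative permittivity
#' `eps_r` and conductivity `sigma` (S/m).
#'
#' @param freqs Frequencies in Hz.
#' @param eps_r Relative permittivity, > 0.
#' @param sigma Conductivity in S/m, > 0.
#' @return An object of class `dielectric_spectrum`.
#' @export
dielectric_spectrum <- function(freqs, eps_r, sigma) {
  stopifnot(length(freqs) == length(eps_r), length(freqs) == length(sigma))
  if (any(freqs <= 0)) stop("frequencies must be positive")
  structure(list(freqs = as.numeric(freqs), eps_r = as.numeric(eps_r),
                 sigma = as.numeric(sigma)),
            class = "dielectric_spectrum")
}

#' Convert terminal admittance to bulk dielectric properties
#'
#' Inverts the geometry factor: \eqn{\varepsilon_r = B l / (\omega
#' \varepsilon_0 S)} and \eqn{\sigma = G l / S}.  Replicates are averaged
#' first.
#'
#' @param spec An [admittance_spectrum()].
#' @param geometry A [sample_geometry()]; defaults to the one stored in the
#'   spectrum.
#' @return A [dielectric_spectrum()].
#' @export
admittance_to_dielectric <- function(spec, geometry = spec$geometry) {
  stopifnot(inherits(spec, "admittance_spectrum"))
  if (is.null(geometry))
    stop("a sample geometry is required to convert admittance to bulk properties")
  spec <- average_replicates(spec)
  l_S <- geometry$length / geometry$area
  w <- 2 * pi * spec$freqs
  dielectric_spectrum(spec$freqs,
                      eps_r = drop(spec$B) * l_S / (w * .eps0),
                      sigma = drop(spec$G) * l_S)
}

#' Complex permittivity samples of a dielectric spectrum
#'
#' \eqn{\varepsilon^*_r = \varepsilon_r - j\,\sigma/(\omega\varepsilon_0)}.
#'
#' @param spec A [dielectric_spectrum()].
#' @return Complex vector, one value per frequency.
#' @export
dielectric_to_complex_eps <- function(spec) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  spec$eps_r - 1i * spec$sigma / (2 * pi * spec$freqs * .eps0)
}

#' Read an admittance spectrum from CSV
#'
#' The CSV must have a header; `column_map` names the frequency column and
#' one of three value-column pairs:
#' * `G`, `B` — conductance and susceptance in S;
#' * `re`, `im` — real and imaginary part of Y in S;
#' * `zmag`, `zphase_deg` — impedance magnitude (ohm) and phase (degrees),
#'   converted by complex inversion `Y = 1/Z`.
#' Replicates may be stacked with a `replicate` entry in `column_map` naming
#' a replicate-id column.  Rows are reordered to ascending frequency.
#'
#' @param path CSV file path.
#' @param column_map Named character vector or list, e.g.
#'   `c(freq = "freq_hz", G = "G_S", B = "B_S")`.
#' @return An [admittance_spectrum()].
#' @export
read_spectrum <- function(path,
                          column_map = c(freq = "freq_hz", G = "G_S", B = "B_S")) {
  column_map <- as.list(column_map)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- unlist(column_map)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("columns not found in ", path, ": ", paste(missing_cols, collapse = ", "))
  num <- function(nm) {
    v <- df[[column_map[[nm]]]]
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x) & !is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   column_map[[nm]], bad[1]))
    x
  }
  f <- num("freq")
  if (!is.null(column_map$G)) {
    G <- num("G"); B <- num("B")
  } else if (!is.null(column_map$re)) {
    G <- num("re"); B <- num("im")
  } else if (!is.null(column_map$zmag)) {
    zmag <- num("zmag"); phi <- num("zphase_deg") * pi / 180
    Y <- 1 / (zmag * exp(1i * phi))
    G <- Re(Y); B <- Im(Y)
  } else {
    stop("column_map must provide (G,B), (re,im) or (zmag,zphase_deg)")
  }
  if (!is.null(column_map$replicate)) {
    rep_id <- df[[column_map$replicate]]
    ids <- unique(rep_id)
    fr <- sort(unique(f))
    Gm <- Bm <- matrix(NA_real_, length(fr), length(ids))
    for (j in seq_along(ids)) {
      sel <- rep_id == ids[j]
      fj <- f[sel]
      if (anyDuplicated(fj))
        stop(sprintf("duplicate frequency %g within replicate '%s'",
                     fj[anyDuplicated(fj)], ids[j]))
      m <- match(fr, fj)
      Gm[, j] <- G[sel][m]; Bm[, j] <- B[sel][m]
    }
    if (anyNA(Gm)) stop("replicates do not share a common frequency grid")
    return(admittance_spectrum(fr, Gm, Bm))
  }
  dup <- which(duplicated(f))
  if (length(dup))
    stop(sprintf("duplicate frequency %g at data row %d", f[dup[1]], dup[1]))
  admittance_spectrum(f, G, B)
}

#' Write an admittance spectrum to CSV
#'
#' Columns `freq_hz,G_S,B_S` (plus `replicate` when the spectrum holds more
#' than one sample), full double precision, so that write-then-read is a
#' lossless round trip.
#'
#' @param spec An [admittance_spectrum()].
#' @param path Output CSV path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "admittance_spectrum"))
  nr <- n_replicates(spec)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (nr == 1L) {
    df <- data.frame(freq_hz = fmt(spec$freqs),
                     G_S = fmt(drop(spec$G)), B_S = fmt(drop(spec$B)))
  } else {
    df <- data.frame(freq_hz = fmt(rep(spec$freqs, nr)),
                     G_S = fmt(as.vector(spec$G)), B_S = fmt(as.vector(spec$B)),
                     replicate = rep(seq_len(nr), each = length(spec$freqs)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
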